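#' Consensus genotype for one locus of one sample
#'
#' Applies the multitube acceptance rule to a set of replicate single-locus
#' genotype calls: a genotype is accepted when the replicates contain at
#' least three identical homozygote profiles or at least two identical
#' heterozygote profiles. Failed amplifications (`NA` alleles) never match.
#' If no genotype qualifies the locus is undetermined; if two distinct
#' genotypes both qualify the locus is flagged conflicting and treated as
#' undetermined.
#'
#' Allele order within a call is irrelevant: `A/B` and `B/A` are the same
#' heterozygote.
#'
#' @param allele1,allele2 character vectors of replicate allele calls (`NA`
#'   for failed amplification).
#' @return List with `determined` (logical), `allele1`, `allele2` (the
#'   accepted call or `NA`), and `conflicting` (logical).
#' @export
consensus_single_locus <- function(allele1, allele2) {
  stopifnot(length(allele1) == length(allele2))
  if (length(allele1) == 0) stop("empty replicate set")
  ok <- !is.na(allele1) & !is.na(allele2)
  a <- pmin(allele1[ok], allele2[ok])
  b <- pmax(allele1[ok], allele2[ok])
  und <- list(determined = FALSE, allele1 = NA_character_,
              allele2 = NA_character_, conflicting = FALSE)
  if (!length(a)) return(und)
  key <- paste(a, b, sep = "/")
  counts <- table(key)
  hom <- a[match(names(counts), key)] == b[match(names(counts), key)]
  qualifies <- (hom & counts >= 3) | (!hom & counts >= 2)
  qn <- names(counts)[qualifies]
  if (length(qn) == 0) return(und)
  if (length(qn) > 1) {
    und$conflicting <- TRUE
    return(und)
  }
  al <- strsplit(qn, "/", fixed = TRUE)[[1]]
  list(determined = TRUE, allele1 = al[1], allele2 = al[2], conflicting = FALSE)
}

#' Consensus genotypes for a replicate table
#'
#' Runs [consensus_single_locus()] over every sample x locus combination of a
#' replicate table.
#'
#' @param replicates data frame with columns `sample_id`, `locus`,
#'   `replicate_index`, `allele1`, `allele2`.
#' @return Data frame `sample_id, locus, allele1, allele2, determined,
#'   conflicting`, one row per sample x locus.
#' @export
consensus_genotypes <- function(replicates) {
  need <- c("sample_id", "locus", "allele1", "allele2")
  stopifnot(all(need %in% names(replicates)))
  sp <- split(replicates, list(replicates$sample_id, replicates$locus), drop = TRUE)
  rows <- lapply(sp, function(d) {
    cc <- consensus_single_locus(d$allele1, d$allele2)
    data.frame(sample_id = d$sample_id[1], locus = d$locus[1],
               allele1 = cc$allele1, allele2 = cc$allele2,
               determined = cc$determined, conflicting = cc$conflicting,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$locus), ]
  rownames(out) <- NULL
  out
}

#' Genotype quality index of a sample
#'
#' Per locus, the proportion of replicates whose call equals the consensus
#' call (failed amplifications and calls at undetermined loci count as
#' non-matching); the quality index is the unweighted mean of these
#' per-locus fractions. Samples from individuals represented by a single
#' sample are conventionally discarded below a threshold of 0.8.
#'
#' @param replicates replicate table for one sample (columns `locus`,
#'   `allele1`, `allele2`).
#' @param consensus consensus table for the same sample (output rows of
#'   [consensus_genotypes()]).
#' @return List with `qi` in \[0, 1\] and `per_locus` (named fractions).
#' @export
quality_index <- function(replicates, consensus) {
  loci <- unique(consensus$locus)
  if (length(loci) == 0) stop("sample has zero loci")
  frac <- vapply(loci, function(loc) {
    d <- replicates[replicates$locus == loc, ]
    cc <- consensus[consensus$locus == loc, ]
    if (nrow(d) == 0) return(0)
    if (!cc$determined[1]) return(0)
    a <- pmin(d$allele1, d$allele2)
    b <- pmax(d$allele1, d$allele2)
    match_call <- !is.na(a) & !is.na(b) & a == cc$allele1[1] & b == cc$allele2[1]
    mean(match_call)
  }, numeric(1))
  list(qi = mean(frac), per_locus = frac)
}

#' Probability of identity for unrelated individuals
#'
#' Per locus, the probability that two unrelated individuals drawn from a
#' population in Hardy-Weinberg proportions share a genotype:
#' \eqn{\sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}; across loci the values
#' multiply (independent loci).
#'
#' @param allele_freqs named list of per-locus allele frequency vectors.
#' @return List with `per_locus` (named vector) and `overall` (product).
#' @export
pid_unrelated <- function(allele_freqs) {
  per <- vapply(allele_freqs, function(p) {
    check_freqs(p)
    hom <- sum(p^4)
    het <- 0
    if (length(p) > 1) {
      pr <- outer(p, p)
      het <- sum((2 * pr[upper.tri(pr)])^2)
    }
    hom + het
  }, numeric(1))
  list(per_locus = per, overall = prod(per))
}

#' Probability of identity for full siblings
#'
#' Per locus, the probability that two full siblings share a genotype:
#' \eqn{0.25 + 0.5\sum p_i^2 + 0.5(\sum p_i^2)^2 - 0.25\sum p_i^4};
#' multiplied across loci. Always at least as large as the unrelated value,
#' making it the conservative choice for deciding whether a marker panel can
#' separate close relatives.
#'
#' @inheritParams pid_unrelated
#' @return List with `per_locus` and `overall`.
#' @export
pid_sib <- function(allele_freqs) {
  per <- vapply(allele_freqs, function(p) {
    check_freqs(p)
    s2 <- sum(p^2); s4 <- sum(p^4)
    0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  }, numeric(1))
  list(per_locus = per, overall = prod(per))
}

check_freqs <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must be non-negative and sum to 1")
  invisible(p)
}

#' Group samples into individuals by exact multilocus genotype match
#'
#' Samples whose consensus genotypes are identical at every locus (and whose
#' recorded sex agrees) are assigned one individual ID. Matching is exact -
#' zero mismatching loci tolerated - because replicate consensus upstream is
#' expected to have removed genotyping error. Samples with any undetermined
#' locus cannot be matched reliably and are excluded and reported.
#'
#' @param consensus consensus table ([consensus_genotypes()] output) covering
#'   all samples.
#' @param sex optional named character vector, sample ID -> sex; when given,
#'   sex participates in the match key.
#' @return List with `assignments` (data frame `sample_id, individual_id`),
#'   `n_individuals`, and `excluded` (sample IDs with undetermined loci).
#'   Individual IDs are assigned in order of first-seen sample
#'   (lexicographic by sample ID).
#' @export
match_individuals <- function(consensus, sex = NULL) {
  sp <- split(consensus, consensus$sample_id)
  keys <- vapply(names(sp), function(sid) {
    d <- sp[[sid]]
    if (any(!d$determined)) return(NA_character_)
    d <- d[order(d$locus), ]
    k <- paste(d$locus, d$allele1, d$allele2, sep = ":", collapse = ";")
    if (!is.null(sex)) k <- paste(sex[[sid]], k, sep = "|")
    k
  }, character(1))
  sids <- sort(names(sp))
  keys <- keys[sids]
  excluded <- sids[is.na(keys)]
  sids <- sids[!is.na(keys)]
  keys <- keys[!is.na(keys)]
  uid <- integer(0)
  seen <- character(0)
  ind <- vapply(keys, function(k) {
    i <- match(k, seen)
    if (is.na(i)) {
      seen <<- c(seen, k)
      i <- length(seen)
    }
    i
  }, integer(1))
  list(assignments = data.frame(sample_id = sids,
                                individual_id = sprintf("ID%03d", ind),
                                stringsAsFactors = FALSE),
       n_individuals = length(unique(ind)),
       excluded = excluded)
}

#' Full genotype-QC pass over a replicate table
#'
#' Convenience wrapper: consensus for every sample, quality index, the
#' single-sample QI filter, and individual matching.
#'
#' @param replicates replicate table (`sample_id, locus, replicate_index,
#'   allele1, allele2`).
#' @param sex optional named vector sample ID -> sex.
#' @param qi_threshold QI below which a single-sample individual is discarded
#'   (default 0.8).
#' @return List with `consensus`, `individuals` (per-sample table with
#'   `individual_id`, `qi`, `passed`), and `excluded`.
#' @export
genotype_qc <- function(replicates, sex = NULL, qi_threshold = 0.8) {
  cons <- consensus_genotypes(replicates)
  mi <- match_individuals(cons, sex = sex)
  qi <- vapply(mi$assignments$sample_id, function(sid) {
    quality_index(replicates[replicates$sample_id == sid, ],
                  cons[cons$sample_id == sid, ])$qi
  }, numeric(1))
  tab <- mi$assignments
  tab$qi <- unname(qi)
  n_per_ind <- table(tab$individual_id)
  singleton <- n_per_ind[tab$individual_id] == 1
  tab$passed <- !(singleton & tab$qi < qi_threshold)
  list(consensus = cons, individuals = tab, excluded = mi$excluded)
}
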