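#' Configuration for the territorial scat-sampling simulator
#'
#' Builds the parameter list consumed by [simulate_population()],
#' [simulate_scats()] and [simulate_genotype_replicates()]. The generator
#' emulates noninvasive genetic sampling of a territorial mustelid
#' population: individuals hold bivariate-normal utilization distributions
#' whose spread differs by sex, same-sex neighbors avoid each other's core
#' areas while the owner is alive, and each collected scat yields replicated
#' microsatellite genotypes subject to allelic dropout and false alleles.
#'
#' Default spatial scales are chosen so that 95% kernel ranges are of
#' realistic size for a large mustelid: `sigma_female = 4200` m gives a
#' bivariate-normal 95% area of about 330 km^2, and `sigma_male` is scaled by
#' `sqrt(2.3)` so male ranges are 2.3 times larger in area.
#'
#' @param n_males,n_females numbers of individuals per sex.
#' @param sigma_female,sigma_male standard deviation (m) of the isotropic
#'   bivariate-normal utilization distribution, per sex.
#' @param min_center_separation minimum distance (m) between same-sex
#'   territory centers at placement.
#' @param exclusion_radius radius (m) of the same-sex exclusion zone around a
#'   living owner's center.
#' @param exclusion_prob probability in \[0, 1\] that a proposed location
#'   falling inside a living same-sex neighbor's exclusion zone is rejected
#'   and redrawn.
#' @param n_years number of monitoring seasons.
#' @param scat_rate expected number of scats per individual per active season
#'   (Poisson).
#' @param death_schedule named integer vector mapping individual IDs (as
#'   produced by [simulate_population()]: "M01", "F01", ...) to the season
#'   index (1-based) of death, or `NULL` for no deaths.
#' @param study_bounds rectangle `c(xmin, ymin, xmax, ymax)` in meters.
#' @param allele_freqs named list, one numeric vector of allele frequencies
#'   per microsatellite locus; each vector must sum to 1.
#' @param dropout_rate per-replicate probability that a heterozygote loses
#'   one allele.
#' @param false_allele_rate per-replicate probability of a spurious allele
#'   substitution.
#' @param site_fidelity between-season fraction of the UD spread, in
#'   \[0, 1). At 0 (default) every location is an independent draw from the
#'   individual's bivariate-normal UD. Above 0, each individual-season gets
#'   a seasonal activity center drawn from N(center, (f sigma)^2 I) and
#'   locations scatter around it with the complementary spread
#'   sigma * sqrt(1 - f^2), emulating the within-season clustering of scat
#'   deposition (repeated travel routes, marking sites) while leaving the
#'   marginal UD exactly N(center, sigma^2 I).
#' @param retry_budget maximum redraws per scat before the record is dropped.
#' @param start_year calendar year such that season 1 is labeled
#'   `start_year + 1`.
#' @param seed integer seed making every generator output reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_males = 11, n_females = 11,
                       sigma_female = 4200,
                       sigma_male = 4200 * sqrt(2.3),
                       min_center_separation = 3000,
                       exclusion_radius = 10000,
                       exclusion_prob = 0.9,
                       n_years = 10,
                       scat_rate = 5,
                       death_schedule = NULL,
                       study_bounds = c(0, 0, 45000, 45000),
                       allele_freqs = default_allele_freqs(),
                       dropout_rate = 0.1,
                       false_allele_rate = 0.02,
                       site_fidelity = 0,
                       retry_budget = 100,
                       start_year = 2000,
                       seed = 1L) {
  stopifnot(n_males >= 0, n_females >= 0, n_males + n_females >= 1,
            sigma_female > 0, sigma_male > 0,
            exclusion_prob >= 0, exclusion_prob <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            false_allele_rate >= 0, false_allele_rate <= 1,
            site_fidelity >= 0, site_fidelity < 1,
            n_years >= 1, scat_rate >= 0, retry_budget >= 1,
            length(study_bounds) == 4,
            study_bounds[3] > study_bounds[1], study_bounds[4] > study_bounds[2])
  for (loc in names(allele_freqs)) {
    p <- allele_freqs[[loc]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies at locus ", loc, " must be non-negative and sum to 1")
  }
  cfg <- list(n_males = n_males, n_females = n_females,
              sigma_female = sigma_female, sigma_male = sigma_male,
              min_center_separation = min_center_separation,
              exclusion_radius = exclusion_radius,
              exclusion_prob = exclusion_prob,
              n_years = as.integer(n_years), scat_rate = scat_rate,
              death_schedule = death_schedule,
              study_bounds = study_bounds,
              allele_freqs = allele_freqs,
              dropout_rate = dropout_rate,
              false_allele_rate = false_allele_rate,
              site_fidelity = site_fidelity,
              retry_budget = as.integer(retry_budget),
              start_year = as.integer(start_year),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default microsatellite allele frequencies
#'
#' Eleven autosomal loci with five alleles each at moderately uneven
#' frequencies, a typical panel size for individual identification of
#' carnivores from scat DNA.
#'
#' @return Named list of frequency vectors.
#' @export
default_allele_freqs <- function() {
  p <- c(0.35, 0.25, 0.20, 0.12, 0.08)
  names(p) <- LETTERS[1:5]
  stats::setNames(rep(list(p), 11), sprintf("L%02d", 1:11))
}

#' Simulate territory centers with same-sex inhibition
#'
#' Places `n_males + n_females` territory centers uniformly in the study
#' rectangle, rejecting proposals closer than `min_center_separation` to an
#' already-placed center of the same sex (a hard-core inhibition process).
#' Opposite-sex centers may be arbitrarily close, mirroring intersexual
#' tolerance.
#'
#' @param config a [sim_config()].
#' @return Data frame (class `territories`) with columns `individual_id`,
#'   `sex`, `cx`, `cy`, `sigma`, `first_season`, `last_season` (season
#'   indices; `last_season` is the death season for scheduled deaths).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  b <- config$study_bounds
  ids <- c(sprintf("M%02d", seq_len(config$n_males)),
           sprintf("F%02d", seq_len(config$n_females)))
  sexes <- c(rep("M", config$n_males), rep("F", config$n_females))
  cx <- cy <- numeric(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (attempt in 1:5000) {
      px <- stats::runif(1, b[1], b[3])
      py <- stats::runif(1, b[2], b[4])
      same <- which(sexes[seq_len(i - 1)] == sexes[i])
      if (length(same) == 0 ||
          all(sqrt((cx[same] - px)^2 + (cy[same] - py)^2) >=
              config$min_center_separation)) {
        cx[i] <- px; cy[i] <- py; placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place territory ", ids[i],
           ": study_bounds cannot host ", sum(sexes == sexes[i]),
           " same-sex centers at min_center_separation = ",
           config$min_center_separation, " m")
  }
  last <- rep(config$n_years, length(ids))
  if (!is.null(config$death_schedule)) {
    dd <- config$death_schedule
    unknown <- setdiff(names(dd), ids)
    if (length(unknown))
      stop("death_schedule names unknown individuals: ",
           paste(unknown, collapse = ", "))
    last[match(names(dd), ids)] <- as.integer(dd)
  }
  out <- data.frame(individual_id = ids, sex = sexes, cx = cx, cy = cy,
                    sigma = ifelse(sexes == "M", config$sigma_male,
                                   config$sigma_female),
                    first_season = 1L, last_season = as.integer(last),
                    stringsAsFactors = FALSE)
  class(out) <- c("territories", "data.frame")
  out
}

#' Simulate genotyped scat locations under same-sex exclusion
#'
#' For every individual and every season it is alive, draws a
#' Poisson(`scat_rate`) number of scats. Each scat location is proposed from
#' the owner's bivariate-normal utilization distribution; a proposal inside
#' the exclusion zone (radius `exclusion_radius`) of a *living* same-sex
#' neighbor's center is rejected with probability `exclusion_prob` and
#' redrawn. From the season after a neighbor's death onward its exclusion
#' zone no longer applies, so survivors' locations can shift into the vacated
#' area - the contrast the downstream selection analysis estimates. Proposals
#' exhausting the retry budget are dropped and counted, never silently lost.
#'
#' Dates are placed uniformly in the February-May peak of the assigned
#' monitoring season.
#'
#' @param territories output of [simulate_population()].
#' @param config the same [sim_config()].
#' @return Data frame of scat records (`sample_id`, `individual_id`, `sex`,
#'   `date`, `x`, `y`) with attribute `dropped` giving the number of records
#'   abandoned after `retry_budget` redraws.
#' @export
simulate_scats <- function(territories, config) {
  stopifnot(inherits(territories, "territories"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  recs <- list()
  dropped <- 0L
  n_ind <- nrow(territories)
  for (season in seq_len(config$n_years)) {
    alive <- territories$first_season <= season & territories$last_season >= season
    for (i in seq_len(n_ind)) {
      if (!alive[i]) next
      n_scat <- stats::rpois(1, config$scat_rate)
      if (n_scat == 0) next
      # same-sex neighbors whose exclusion is active this season
      excl <- which(territories$sex == territories$sex[i] &
                    seq_len(n_ind) != i &
                    territories$last_season >= season)
      f <- config$site_fidelity
      mu_x <- territories$cx[i]; mu_y <- territories$cy[i]
      sd_prop <- territories$sigma[i]
      if (f > 0) {
        # seasonal activity center; the marginal UD stays N(center, sigma^2)
        mu_x <- stats::rnorm(1, mu_x, f * sd_prop)
        mu_y <- stats::rnorm(1, territories$cy[i], f * sd_prop)
        sd_prop <- sd_prop * sqrt(1 - f^2)
      }
      for (s in seq_len(n_scat)) {
        accepted <- FALSE
        for (try in seq_len(config$retry_budget)) {
          px <- stats::rnorm(1, mu_x, sd_prop)
          py <- stats::rnorm(1, mu_y, sd_prop)
          reject <- FALSE
          if (length(excl) && config$exclusion_prob > 0) {
            d <- sqrt((territories$cx[excl] - px)^2 +
                      (territories$cy[excl] - py)^2)
            if (any(d < config$exclusion_radius))
              reject <- stats::runif(1) < config$exclusion_prob
          }
          if (!reject) { accepted <- TRUE; break }
        }
        if (!accepted) { dropped <- dropped + 1L; next }
        day <- sample.int(120L, 1L)  # Feb 1 + 0..119 days spans Feb-May
        date <- as.Date(sprintf("%d-02-01", config$start_year + season)) + day - 1L
        recs[[length(recs) + 1L]] <- data.frame(
          individual_id = territories$individual_id[i],
          sex = territories$sex[i],
          date = date, x = px, y = py, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(individual_id = character(), sex = character(),
               date = as.Date(character()), x = numeric(), y = numeric())
  out <- cbind(sample_id = sprintf("S%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  if (dropped > 0)
    message(dropped, " scat proposal(s) dropped after exhausting the retry budget")
  attr(out, "dropped") <- dropped
  out
}

#' Simulate replicated microsatellite genotypes for scat samples
#'
#' Draws a true multilocus genotype for every individual under Hardy-Weinberg
#' proportions from the configured allele frequencies, then generates
#' `n_replicates` PCR replicates per sample and locus. A heterozygote
#' replicate loses one allele (allelic dropout) with probability
#' `dropout_rate`; any replicate then has one allele substituted by a random
#' different allele (false allele) with probability `false_allele_rate`.
#' Dropout by definition cannot alter a homozygote.
#'
#' @param samples data frame with columns `sample_id` and `individual_id`
#'   (typically the output of [simulate_scats()]).
#' @param config a [sim_config()]; `allele_freqs` must be non-empty.
#' @param n_replicates replicates per sample per locus (multitube design,
#'   default 3).
#' @return Data frame `sample_id, locus, replicate_index, allele1, allele2`
#'   with attribute `truth`: the true genotype table
#'   (`individual_id, locus, allele1, allele2`).
#' @export
simulate_genotype_replicates <- function(samples, config, n_replicates = 3L) {
  stopifnot(inherits(config, "sim_config"),
            all(c("sample_id", "individual_id") %in% names(samples)))
  if (length(config$allele_freqs) == 0) stop("allele_freqs is empty")
  set.seed(config$seed + 2L)
  loci <- names(config$allele_freqs)
  ids <- unique(samples$individual_id)
  # true genotypes under Hardy-Weinberg
  truth <- do.call(rbind, lapply(ids, function(id) {
    g <- lapply(loci, function(loc) {
      p <- config$allele_freqs[[loc]]
      sort(sample(names(p), 2L, replace = TRUE, prob = p))
    })
    data.frame(individual_id = id, locus = loci,
               allele1 = vapply(g, `[`, "", 1L),
               allele2 = vapply(g, `[`, "", 2L), stringsAsFactors = FALSE)
  }))
  ns <- nrow(samples)
  nl <- length(loci)
  rows <- ns * nl * n_replicates
  rep_tab <- data.frame(
    sample_id = rep(samples$sample_id, each = nl * n_replicates),
    locus = rep(rep(loci, each = n_replicates), times = ns),
    replicate_index = rep(seq_len(n_replicates), times = ns * nl),
    allele1 = character(rows), allele2 = character(rows),
    stringsAsFactors = FALSE)
  truth_key <- paste(truth$individual_id, truth$locus)
  ind_of_sample <- samples$individual_id[match(rep_tab$sample_id, samples$sample_id)]
  ti <- match(paste(ind_of_sample, rep_tab$locus), truth_key)
  a1 <- truth$allele1[ti]; a2 <- truth$allele2[ti]
  # allelic dropout on heterozygotes
  het <- a1 != a2
  drop <- het & stats::runif(rows) < config$dropout_rate
  keep_first <- stats::runif(rows) < 0.5
  a1[drop & !keep_first] <- a2[drop & !keep_first]
  a2[drop & keep_first] <- a1[drop & keep_first]
  # false allele: substitute one allele with a random different one
  fa <- stats::runif(rows) < config$false_allele_rate
  for (k in which(fa)) {
    alleles <- names(config$allele_freqs[[rep_tab$locus[k]]])
    slot <- if (stats::runif(1) < 0.5) 1L else 2L
    cur <- if (slot == 1L) a1[k] else a2[k]
    new <- sample(setdiff(alleles, cur), 1L)
    if (slot == 1L) a1[k] <- new else a2[k] <- new
  }
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  rep_tab$allele1 <- a1; rep_tab$allele2 <- a2
  attr(rep_tab, "truth") <- truth
  rep_tab
}

#' Reference simulation scenario
#'
#' The package's standard study conditions for end-to-end verification: a
#' closed population of 22 individuals (11 per sex) monitored over 10
#' seasons in a 45 x 45 km region, with heavily overlapping utilization
#' distributions (same-sex centers may sit as close as 3 km), same-sex
#' exclusion zones of 10 km radius enforced at probability 0.9 while the
#' owner lives, and ten scheduled deaths (five per sex, staggered over
#' seasons 4-6) providing focal individuals with both before- and
#' after-death neighbor observations inside the 3-season analysis window.
#'
#' @param seed integer seed.
#' @param exclusion_prob override of the same-sex exclusion probability
#'   (default 0.9; 0 gives the no-territoriality null).
#' @return List with `config`, `territories`, `scats`, `mortality`.
#' @export
study_simulation <- function(seed, exclusion_prob = 0.9) {
  schedule <- c(M01 = 4L, M02 = 4L, M03 = 5L, M04 = 5L, M05 = 6L,
                F01 = 4L, F02 = 4L, F03 = 5L, F04 = 5L, F05 = 6L)
  config <- sim_config(death_schedule = schedule,
                       exclusion_prob = exclusion_prob, seed = seed)
  territories <- simulate_population(config)
  scats <- simulate_scats(territories, config)
  list(config = config, territories = territories, scats = scats,
       mortality = sim_mortality(territories, config))
}

#' Mortality table of a simulated population
#'
#' One row per individual with a scheduled death: death date mid-season
#' (March 15 of the death season's labeling year), location at the territory
#' center.
#'
#' @param territories output of [simulate_population()].
#' @param config the [sim_config()] used.
#' @return Data frame `individual_id, death_date, x, y`.
#' @export
sim_mortality <- function(territories, config) {
  dead <- territories[territories$individual_id %in%
                        names(config$death_schedule), , drop = FALSE]
  data.frame(individual_id = dead$individual_id,
             death_date = as.Date(sprintf("%d-03-15",
                                          config$start_year + dead$last_season)),
             x = dead$cx, y = dead$cy, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Emits the file set the analysis pipeline reads: `scats.csv`,
#' `mortality.csv`, `replicates.csv`, the ground truth (`truth.json`) and the
#' generating configuration (`config.yaml`). Mortality locations are the
#' territory centers; death dates are placed mid-season (March 15 of the
#' death season's labeling year).
#'
#' @param dir output directory (created if missing).
#' @param territories,scats,replicates generator outputs; `replicates` may be
#'   `NULL`.
#' @param config the [sim_config()] used.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, territories, scats, config, replicates = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(scats[, c("sample_id", "individual_id", "sex", "date", "x", "y")],
                   file.path(dir, "scats.csv"), row.names = FALSE)
  dead <- territories[territories$last_season < config$n_years |
                      territories$individual_id %in% names(config$death_schedule), ]
  mort <- data.frame(
    individual_id = dead$individual_id,
    death_date = as.Date(sprintf("%d-03-15", config$start_year + dead$last_season)),
    x = dead$cx, y = dead$cy, stringsAsFactors = FALSE)
  utils::write.csv(mort, file.path(dir, "mortality.csv"), row.names = FALSE)
  if (!is.null(replicates)) {
    utils::write.csv(replicates, file.path(dir, "replicates.csv"), row.names = FALSE)
    truth_g <- attr(replicates, "truth")
  } else truth_g <- NULL
  truth <- list(territories = territories,
                seed = config$seed,
                genotypes = truth_g)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$allele_freqs <- lapply(cfg$allele_freqs, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
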