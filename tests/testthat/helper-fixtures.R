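# shared fixture builders: everything generated in code, nothing on disk

# small population for fast unit tests (not the reference study conditions)
tiny_sim <- function(seed = 1, ...) {
  args <- list(n_males = 4, n_females = 4, n_years = 4,
               study_bounds = c(0, 0, 30000, 30000),
               scat_rate = 4, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# a pvc contour object built directly from rings (for geometry-only tests)
manual_pvc <- function(rings, level = 95) {
  structure(list(level = level, threshold = 0, rings = rings,
                 area_km2 = ngsterr:::rings_area(rings) / 1e6),
            class = "pvc")
}

square_ring <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# replicate-table row builder for genotype QC tests
rep_rows <- function(sample_id, locus, calls) {
  a1 <- vapply(calls, function(cc) if (is.na(cc[1])) NA_character_ else cc[1], "")
  a2 <- vapply(calls, function(cc) if (is.na(cc[1])) NA_character_ else cc[2], "")
  data.frame(sample_id = sample_id, locus = locus,
             replicate_index = seq_along(calls),
             allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
}

# use-availability rows with one observation per grouping level: the
# random-intercept variances are then estimated at (essentially) zero, the
# regime in which the mixed model must reduce to plain logistic regression
singleton_rsf <- function(n = 600, beta_real = -0.8, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    focal_id = paste0("F", seq_len(n)), neighbor_id = paste0("N", seq_len(n)),
    is_real = sample(c("real", "random"), n, TRUE),
    period = sample(c("before", "after"), n, TRUE),
    sex_focal = sample(c("F", "M"), n, TRUE),
    sex_neighbor = sample(c("F", "M"), n, TRUE),
    stringsAsFactors = FALSE)
  d$inside <- runif(n) < plogis(-0.5 + beta_real * (d$is_real == "real"))
  d
}

# exhaustive-enumeration oracles for the probability of identity
pid_unrelated_oracle <- function(p) {
  k <- length(p)
  total <- 0
  for (i in 1:k) for (j in i:k) {
    pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
    total <- total + pg^2
  }
  total
}

pid_sib_oracle <- function(p) {
  k <- length(p)
  # genotype distribution of a child given two parental genotypes: each
  # parent transmits one of its two alleles with probability 1/2
  child_dist <- function(g1, g2) {
    d <- new.env()
    for (a in g1) for (b in g2) {
      key <- paste(sort(c(a, b)), collapse = "/")
      d[[key]] <- (if (is.null(d[[key]])) 0 else d[[key]]) + 0.25
    }
    d
  }
  total <- 0
  for (i1 in 1:k) for (j1 in i1:k) {
    pg1 <- if (i1 == j1) p[i1]^2 else 2 * p[i1] * p[j1]
    for (i2 in 1:k) for (j2 in i2:k) {
      pg2 <- if (i2 == j2) p[i2]^2 else 2 * p[i2] * p[j2]
      d <- child_dist(c(i1, j1), c(i2, j2))
      total <- total + pg1 * pg2 * sum(vapply(ls(d), function(k2) d[[k2]]^2,
                                              numeric(1)))
    }
  }
  total
}
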