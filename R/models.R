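#' Sex effect on log home-range size
#'
#' Ordinary least squares on log-transformed home-range area with a sex
#' indicator and a natural cubic spline in the number of monitoring seasons
#' the individual was detected (ranges built from more seasons are larger
#' even without true range shifts, so the spline absorbs that nuisance
#' trend). Per-sex predictions are back-transformed at a reference number of
#' seasons (default 1, i.e. annual ranges) with normal-theory confidence
#' intervals computed on the log scale.
#'
#' @param hr_table output of [home_range_table()]: needs `area_km2` (> 0),
#'   `sex` (two levels, "F"/"M"), `n_years`.
#' @param spline_df degrees of freedom of the spline basis (default 3;
#'   automatically reduced when `n_years` has few distinct values).
#' @param ref_years reference number of seasons for predictions (default 1).
#' @param conf_level confidence level (default 0.95).
#' @return List of class `hr_size_model`: `model` (the `lm`),
#'   `sex_coefficient` (estimate, se, t, df, p for male vs female on the log
#'   scale), `ratio` (back-transformed male:female area ratio),
#'   `predictions` (per-sex area and CI at `ref_years`), `spline_df`.
#' @export
fit_hr_size_model <- function(hr_table, spline_df = 3, ref_years = 1,
                              conf_level = 0.95) {
  d <- hr_table[hr_table$area_km2 > 0, , drop = FALSE]
  if (length(unique(d$sex)) < 2)
    stop("sex effect undefined: only one sex present")
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$log_area <- log(d$area_km2)
  du <- length(unique(d$n_years))
  df_eff <- max(0L, min(spline_df, du - 1L))
  fml <- if (df_eff >= 1)
    stats::as.formula(sprintf("log_area ~ sex + splines::ns(n_years, df = %d)", df_eff))
  else log_area ~ sex
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  sc <- sm["sexM", ]
  rdf <- fit$df.residual
  alpha <- 1 - conf_level
  nd <- data.frame(sex = factor(c("F", "M"), levels = c("F", "M")),
                   n_years = ref_years)
  pr <- stats::predict(fit, newdata = nd, se.fit = TRUE)
  crit <- stats::qt(1 - alpha / 2, rdf)
  preds <- data.frame(sex = c("F", "M"),
                      area_km2 = exp(pr$fit),
                      lwr = exp(pr$fit - crit * pr$se.fit),
                      upr = exp(pr$fit + crit * pr$se.fit))
  structure(list(model = fit,
                 sex_coefficient = list(estimate = unname(sc["Estimate"]),
                                        se = unname(sc["Std. Error"]),
                                        t = unname(sc["t value"]),
                                        df = rdf,
                                        p = unname(sc["Pr(>|t|)"])),
                 ratio = exp(unname(sc["Estimate"])),
                 predictions = preds, spline_df = df_eff),
            class = "hr_size_model")
}

#' Enumerate hierarchical candidate fixed-effect structures
#'
#' All subsets of the main effects and interactions of the given factors
#' that (a) respect marginality - an interaction may enter only together
#' with all its lower-order relatives - and (b) contain the `required` main
#' effect. For the four-factor use-availability design (real/random, period,
#' focal sex, neighbor sex) with the real/random term always retained this
#' yields 148 candidate models, including the saturated one.
#'
#' @param factors character vector of factor names.
#' @param required main effect every model must contain (default the first
#'   factor).
#' @return List of character vectors of term labels (interactions written
#'   `a:b`), in deterministic order (by size, then lexicographic).
#' @export
enumerate_candidate_models <- function(factors = c("is_real", "period",
                                                   "sex_focal", "sex_neighbor"),
                                       required = factors[1]) {
  stopifnot(required %in% factors)
  nf <- length(factors)
  # all non-empty subsets of factors, as terms
  term_sets <- list()
  for (mask in 1:(2^nf - 1))
    term_sets[[mask]] <- factors[bitwAnd(mask, 2^(0:(nf - 1))) != 0]
  labels <- vapply(term_sets, paste, "", collapse = ":")
  nt <- length(term_sets)
  is_marginal_of <- function(i, j)
    length(term_sets[[i]]) < length(term_sets[[j]]) &&
      all(term_sets[[i]] %in% term_sets[[j]])
  req_idx <- which(labels == required)
  models <- list()
  for (mask in 0:(2^nt - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(nt - 1))) != 0)
    if (!(req_idx %in% sel)) next
    ok <- TRUE
    for (j in sel) {
      for (i in seq_len(nt)) {
        if (is_marginal_of(i, j) && !(i %in% sel)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) models[[length(models) + 1L]] <- labels[sel]
  }
  sizes <- vapply(models, length, integer(1))
  keys <- vapply(models, paste, "", collapse = " + ")
  models[order(sizes, keys)]
}

rsf_factorize <- function(rsf) {
  rsf$is_real <- factor(rsf$is_real, levels = c("random", "real"))
  rsf$period <- factor(rsf$period, levels = c("before", "after"))
  rsf$sex_focal <- factor(rsf$sex_focal, levels = c("F", "M"))
  rsf$sex_neighbor <- factor(rsf$sex_neighbor, levels = c("F", "M"))
  rsf$inside <- as.numeric(rsf$inside)
  rsf
}

#' Corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`, with `k` counting all estimated
#' parameters (fixed effects plus variance components).
#'
#' @param aic AIC value.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc (infinite when `n <= k + 1`).
#' @export
aicc <- function(aic, k, n) {
  if (n <= k + 1) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the use-availability logistic mixed model
#'
#' Logistic regression of the inside/outside response on a candidate set of
#' fixed-effect terms, with crossed random intercepts for the focal and the
#' neighbor individual (non-independence of observations sharing an animal).
#' Estimation is maximum likelihood with the Laplace approximation
#' (`lme4::glmer`, `nAGQ = 1`); ML rather than REML-type estimation is
#' required for information-criterion comparison across fixed-effect
#' structures.
#'
#' @param rsf an `rsf_table` (or compatible data frame).
#' @param terms character vector of fixed-effect term labels (e.g.
#'   `c("is_real", "period", "is_real:period")`).
#' @param random character subset of `c("focal", "neighbor")`; empty fits a
#'   plain logistic regression.
#' @return Object of class `glmm_fit`: list with `model`, `terms`, `k`
#'   (parameter count), `n`, `logLik`, `AIC`, `AICc`, `converged`,
#'   `messages`, `separation` (complete-separation flag).
#' @export
fit_logistic_glmm <- function(rsf, terms, random = c("focal", "neighbor")) {
  d <- rsf_factorize(as.data.frame(rsf))
  if (length(unique(d$inside)) < 2)
    stop("response is degenerate: only one inside/outside level present")
  re <- c(focal = "(1 | focal_id)", neighbor = "(1 | neighbor_id)")[random]
  rhs <- paste(c(if (length(terms)) terms else "1", re), collapse = " + ")
  fml <- stats::as.formula(paste("inside ~", rhs))
  msgs <- character(0)
  fit <- withCallingHandlers(
    if (length(re)) lme4::glmer(fml, data = d, family = stats::binomial(),
                                nAGQ = 1L,
                                control = lme4::glmerControl(
                                  optimizer = "bobyqa", calc.derivs = FALSE))
    else stats::glm(fml, data = d, family = stats::binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- nrow(d)
  aic <- stats::AIC(fit)
  conv_msgs <- if (length(re)) unlist(fit@optinfo$conv$lme4$messages) else NULL
  converged <- !any(grepl("failed to converge|Model failed", c(msgs, conv_msgs)))
  beta <- if (length(re)) lme4::fixef(fit) else stats::coef(fit)
  separation <- any(abs(beta) > 15)
  structure(list(model = fit, terms = terms, random = random,
                 k = k, n = n, logLik = as.numeric(ll),
                 AIC = aic, AICc = aicc(aic, k, n),
                 converged = converged,
                 messages = c(msgs, conv_msgs), separation = separation),
            class = "glmm_fit")
}

#' Fit and rank candidate models
#'
#' Fits every candidate fixed-effect structure with [fit_logistic_glmm()]
#' and ranks the converged fits by the chosen information criterion,
#' reporting delta values and Akaike weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}. Non-converged
#' or separated candidates are excluded from the ranking with their
#' diagnostics retained.
#'
#' @param rsf an `rsf_table`.
#' @param candidates list of term-label vectors (default
#'   [enumerate_candidate_models()]).
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @param random passed to [fit_logistic_glmm()].
#' @return List with `table` (one row per candidate: terms, k, AIC, AICc,
#'   delta, weight, converged) and `best` (the top `glmm_fit`).
#' @export
select_best_model <- function(rsf, candidates = enumerate_candidate_models(),
                              criterion = c("AICc", "AIC"),
                              random = c("focal", "neighbor")) {
  criterion <- match.arg(criterion)
  fits <- lapply(candidates, function(tt) fit_logistic_glmm(rsf, tt, random))
  tab <- data.frame(
    terms = vapply(candidates, paste, "", collapse = " + "),
    k = vapply(fits, `[[`, numeric(1), "k"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    converged = vapply(fits, function(f) f$converged && !f$separation,
                       logical(1)),
    stringsAsFactors = FALSE)
  usable <- which(tab$converged)
  if (!length(usable)) stop("no candidate model converged")
  crit <- tab[[criterion]]
  delta <- rep(NA_real_, nrow(tab))
  delta[usable] <- crit[usable] - min(crit[usable])
  w <- rep(NA_real_, nrow(tab))
  w[usable] <- exp(-delta[usable] / 2) / sum(exp(-delta[usable] / 2))
  tab$delta <- delta
  tab$weight <- w
  ord <- order(!tab$converged, delta)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(table = tab, best = fits[[usable[which.min(crit[usable])]]],
       criterion = criterion)
}

#' Stratum-specific selection coefficients
#'
#' For each stratum (focal sex x neighbor sex x before/after period), the
#' real-vs-random contrast on the log-odds of a point falling inside the
#' focal home range: the linear combination of all fixed-effect terms
#' involving the real/random factor, evaluated at the stratum's factor
#' levels. Negative values indicate avoidance or exclusion of the focal
#' range by neighbors of that stratum; positive values indicate attraction.
#' Standard errors come from the quadratic form of the contrast vector with
#' the fixed-effect covariance matrix; z and two-sided p follow.
#'
#' @param fit a `glmm_fit` whose terms include `is_real`.
#' @return Data frame `sex_focal, sex_neighbor, period, estimate, se, z, p`.
#' @export
selection_coefficients <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!("is_real" %in% fit$terms))
    stop("fit does not include the real/random term")
  beta <- if (length(fit$random)) lme4::fixef(fit$model) else stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  strata <- expand.grid(sex_focal = c("F", "M"), sex_neighbor = c("F", "M"),
                        period = c("before", "after"),
                        stringsAsFactors = FALSE)
  rhs <- stats::reformulate(fit$terms)
  mm_row <- function(is_real, st) {
    nd <- data.frame(is_real = is_real, period = st$period,
                     sex_focal = st$sex_focal, sex_neighbor = st$sex_neighbor,
                     stringsAsFactors = FALSE)
    nd <- rsf_factorize(cbind(nd, inside = 0))
    stats::model.matrix(rhs, nd)[1, , drop = TRUE]
  }
  out <- strata
  out$estimate <- out$se <- out$z <- out$p <- NA_real_
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    cvec <- mm_row("real", st) - mm_row("random", st)
    cvec <- cvec[names(beta)]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    out$estimate[i] <- est
    out$se[i] <- se
    out$z[i] <- est / se
    out$p[i] <- 2 * stats::pnorm(-abs(est / se))
  }
  out[, c("sex_focal", "sex_neighbor", "period", "estimate", "se", "z", "p")]
}

#' Likelihood-ratio comparison of random-effect structures
#'
#' Fits the use-availability model with no random effects, a focal-only
#' intercept, a neighbor-only intercept, and both crossed intercepts, and
#' reports likelihood-ratio statistics for the nested comparisons. The null
#' value of a variance component lies on the boundary of its parameter
#' space, so the naive chi-square reference distribution is conservative;
#' this caveat is recorded in the output.
#'
#' @param rsf an `rsf_table`.
#' @param terms fixed-effect terms held constant across structures (default
#'   `"is_real"`).
#' @return List with `fits` (structure, logLik, k), `tests` (comparison,
#'   statistic, df, p), and `note` (boundary caveat).
#' @export
lrt_random_effects <- function(rsf, terms = "is_real") {
  structures <- list(none = character(0), focal = "focal",
                     neighbor = "neighbor", both = c("focal", "neighbor"))
  fits <- lapply(structures, function(re) fit_logistic_glmm(rsf, terms, re))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  k <- vapply(fits, `[[`, numeric(1), "k")
  comp <- data.frame(
    comparison = c("focal vs none", "neighbor vs none",
                   "both vs focal", "both vs neighbor"),
    full = c("focal", "neighbor", "both", "both"),
    reduced = c("none", "none", "focal", "neighbor"),
    stringsAsFactors = FALSE)
  comp$statistic <- pmax(0, 2 * (ll[comp$full] - ll[comp$reduced]))
  comp$df <- k[comp$full] - k[comp$reduced]
  comp$p <- stats::pchisq(comp$statistic, comp$df, lower.tail = FALSE)
  list(fits = data.frame(structure = names(structures), logLik = ll, k = k,
                         row.names = NULL),
       tests = comp[, c("comparison", "statistic", "df", "p")],
       note = paste("variance components are tested on the boundary of the",
                    "parameter space; chi-square p-values are conservative"))
}

#' Mixed-model slope of log area on relocation count
#'
#' For each estimator in a [subsample_hr_curve()] table, fits
#' `log(area) ~ n` with a per-individual random intercept (maximum
#' likelihood) and returns the slope: the sample-size sensitivity of the
#' home-range estimator.
#'
#' @param tab output of [subsample_hr_curve()] (possibly row-bound across
#'   estimators).
#' @return Data frame `estimator, slope, se, t`.
#' @export
subsample_slope_model <- function(tab) {
  rows <- lapply(split(tab, tab$estimator), function(d) {
    if (length(unique(d$n)) < 2)
      stop("need at least two subsample sizes per estimator")
    d <- d[d$area_km2 > 0, , drop = FALSE]
    fit <- lme4::lmer(log(area_km2) ~ n + (1 | individual_id), data = d,
                      REML = FALSE)
    sm <- summary(fit)$coefficients
    data.frame(estimator = d$estimator[1], slope = sm["n", "Estimate"],
               se = sm["n", "Std. Error"], t = sm["n", "t value"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
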