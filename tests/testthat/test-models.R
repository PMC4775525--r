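# independent brute-force oracle: powerset filter over term subsets
enumerate_oracle <- function(factors, required) {
  nf <- length(factors)
  sets <- list()
  for (m in 1:(2^nf - 1))
    sets[[m]] <- factors[bitwAnd(m, 2^(0:(nf - 1))) != 0]
  nt <- length(sets)
  count <- 0
  for (m in 0:(2^nt - 1)) {
    sel <- which(bitwAnd(m, 2^(0:(nt - 1))) != 0)
    if (!any(vapply(sel, function(i) identical(sets[[i]], required),
                    logical(1)))) next
    ok <- TRUE
    for (j in sel) for (i in seq_len(nt)) {
      if (length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]]) && !(i %in% sel)) ok <- FALSE
    }
    if (ok) count <- count + 1
  }
  count
}

null_rsf <- function(n = 400, beta_real = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    focal_id = sample(paste0("F", 1:8), n, TRUE),
    neighbor_id = sample(paste0("N", 1:15), n, TRUE),
    is_real = sample(c("real", "random"), n, TRUE),
    period = sample(c("before", "after"), n, TRUE),
    sex_focal = sample(c("F", "M"), n, TRUE),
    sex_neighbor = sample(c("F", "M"), n, TRUE),
    stringsAsFactors = FALSE)
  eta <- -0.5 + beta_real * (d$is_real == "real")
  d$inside <- runif(n) < plogis(eta)
  d
}

test_that("candidate enumeration matches the powerset-filter oracle", {
  two <- enumerate_candidate_models(c("A", "B"), required = "A")
  expect_length(two, enumerate_oracle(c("A", "B"), "A"))
  expect_length(two, 3)
  three <- enumerate_candidate_models(c("A", "B", "C"), required = "A")
  expect_length(three, enumerate_oracle(c("A", "B", "C"), "A"))
  expect_length(three, 14)
  full <- enumerate_candidate_models()
  expect_length(full, 148)
  # every model contains the real/random term and respects marginality
  for (m in full) {
    expect_true("is_real" %in% m)
    for (term in m) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (length(parts) > 1) {
        for (i in seq_along(parts)) {
          sub <- utils::combn(parts, length(parts) - 1, simplify = FALSE)
          for (s in sub)
            expect_true(any(vapply(m, function(t2)
              setequal(strsplit(t2, ":", fixed = TRUE)[[1]], s), logical(1))))
        }
      }
    }
  }
  # saturated model present
  expect_true(any(vapply(full, length, integer(1)) == 15))
})

test_that("the size model recovers null and link-scale algebra", {
  hr <- data.frame(individual_id = paste0("i", 1:20),
                   sex = rep(c("F", "M"), 10),
                   area_km2 = 400, n_years = rep(1:5, 4))
  fit <- suppressWarnings(fit_hr_size_model(hr))  # zero-residual fit
  expect_equal(fit$sex_coefficient$estimate, 0, tolerance = 1e-10)
  set.seed(5)
  hr$area_km2 <- exp(rnorm(20, log(400), 0.3)) * ifelse(hr$sex == "M", 2.3, 1)
  fit <- fit_hr_size_model(hr)
  pred <- fit$predictions
  expect_equal(pred$area_km2[pred$sex == "M"] / pred$area_km2[pred$sex == "F"],
               exp(fit$sex_coefficient$estimate))
  expect_true(all(pred$lwr < pred$area_km2 & pred$area_km2 < pred$upr))
  expect_error(fit_hr_size_model(hr[hr$sex == "F", ]), "one sex")
})

test_that("the mixed model reduces to plain logistic ML when variances vanish", {
  d <- singleton_rsf(n = 600, beta_real = -0.8, seed = 11)
  fit <- suppressWarnings(fit_logistic_glmm(d, c("is_real", "period")))
  # independent oracle: ordinary logistic regression via glm
  od <- ngsterr:::rsf_factorize(d)
  oracle <- stats::glm(inside ~ is_real + period, data = od,
                       family = stats::binomial())
  expect_lt(max(abs(lme4::fixef(fit$model) - coef(oracle))), 1e-3)
})

test_that("AICc applies the small-sample correction to AIC", {
  d <- null_rsf(n = 300, seed = 2)
  fit <- fit_logistic_glmm(d, "is_real")
  k <- fit$k; n <- fit$n
  expect_equal(fit$AICc, fit$AIC + 2 * k * (k + 1) / (n - k - 1))
  expect_gt(fit$AICc, fit$AIC)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * k)
})

test_that("duplicating every row doubles the log-likelihood, not the estimates", {
  d <- null_rsf(n = 400, beta_real = -0.6, seed = 3)
  f1 <- fit_logistic_glmm(d, "is_real", random = character(0))
  f2 <- fit_logistic_glmm(rbind(d, d), "is_real", random = character(0))
  expect_equal(coef(f1$model), coef(f2$model), tolerance = 1e-8)
  expect_equal(f2$logLik, 2 * f1$logLik, tolerance = 1e-8)
})

test_that("model selection ranks by the criterion with normalized weights", {
  d <- null_rsf(n = 600, beta_real = -1, seed = 4)
  cands <- list("is_real", c("is_real", "period"),
                c("is_real", "period", "is_real:period"))
  sel <- select_best_model(d, cands, criterion = "AICc")
  expect_equal(sum(sel$table$weight), 1)
  expect_equal(sel$table$delta[1], 0)
  expect_true(all(diff(sel$table$AICc) >= 0))
  single <- select_best_model(d, list("is_real"))
  expect_equal(single$table$weight, 1)
})

test_that("stratum selection coefficients follow the contrast algebra", {
  d <- null_rsf(n = 600, beta_real = -0.9, seed = 6)
  # with is_real as the only term, all 8 strata share one contrast
  fit <- fit_logistic_glmm(d, "is_real")
  sc <- selection_coefficients(fit)
  expect_equal(nrow(sc), 8)
  expect_equal(sc$estimate, rep(sc$estimate[1], 8))
  expect_equal(sc$estimate[1], unname(lme4::fixef(fit$model)["is_realreal"]))
  expect_equal(sc$p, 2 * pnorm(-abs(sc$z)))
  # a fit without the real/random term is rejected
  expect_error(selection_coefficients(fit_logistic_glmm(d, "period")),
               "real/random")
})

test_that("null data give selection coefficients within 2 SE of zero", {
  d <- null_rsf(n = 1200, beta_real = 0, seed = 7)
  fit <- fit_logistic_glmm(d, unlist(tail(enumerate_candidate_models(), 1)))
  sc <- selection_coefficients(fit)
  expect_true(all(abs(sc$estimate) < 2.5 * sc$se))
})

test_that("random-effect likelihood ratios are non-negative and near zero under the null", {
  d <- null_rsf(n = 500, beta_real = -0.5, seed = 8)
  out <- lrt_random_effects(d)
  expect_true(all(out$tests$statistic >= 0))
  expect_true(all(out$tests$statistic < 4))  # no true group variance
  expect_identical(out$tests$df, c(1, 1, 1, 1))
  expect_match(out$note, "boundary")
})

test_that("subsampling slopes recover flat and log-linear generative curves", {
  tab <- expand.grid(individual_id = paste0("i", 1:6), n = c(5, 10, 15, 20),
                     rep = 1:3, stringsAsFactors = FALSE)
  tab$estimator <- "kernel"
  tab$area_km2 <- 500
  flat <- suppressWarnings(subsample_slope_model(tab))  # flat: singular fit
  expect_equal(flat$slope, 0, tolerance = 1e-8)
  # exact per-individual intercepts with a common log-linear slope of -0.05
  set.seed(9)
  icpt <- stats::setNames(rnorm(6, log(500), 0.4), paste0("i", 1:6))
  tab$area_km2 <- exp(icpt[tab$individual_id] - 0.05 * tab$n +
                        rnorm(nrow(tab), 0, 0.01))
  got <- suppressWarnings(subsample_slope_model(tab))
  expect_equal(got$slope, -0.05, tolerance = 0.005)
  expect_error(subsample_slope_model(tab[tab$n == 5, ]), "two subsample")
})
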