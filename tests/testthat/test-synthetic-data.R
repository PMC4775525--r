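test_that("a single individual is placed inside the study bounds", {
  cfg <- tiny_sim(n_males = 1, n_females = 0)
  terr <- simulate_population(cfg)
  expect_equal(nrow(terr), 1)
  b <- cfg$study_bounds
  expect_true(terr$cx >= b[1] && terr$cx <= b[3])
  expect_true(terr$cy >= b[2] && terr$cy <= b[4])
  expect_identical(terr$sex, "M")
})

test_that("every generator output is a pure function of config and seed", {
  cfg <- tiny_sim(seed = 11)
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_scats(t1, cfg)
  s2 <- simulate_scats(t2, cfg)
  expect_identical(s1, s2)
  r1 <- simulate_genotype_replicates(s1, cfg)
  r2 <- simulate_genotype_replicates(s2, cfg)
  expect_identical(r1, r2)
  # a different seed changes the output
  expect_false(identical(s1$x, simulate_scats(
    simulate_population(tiny_sim(seed = 12)), tiny_sim(seed = 12))$x))
})

test_that("same-sex centers respect the hard-core separation (exhaustive)", {
  cfg <- sim_config(n_males = 10, n_females = 0,
                    min_center_separation = 10000,
                    study_bounds = c(0, 0, 100000, 100000), seed = 3)
  terr <- simulate_population(cfg)
  d <- as.matrix(dist(cbind(terr$cx, terr$cy)))
  expect_true(all(d[upper.tri(d)] >= 10000))
})

test_that("infeasible packing fails naming the separation constraint", {
  cfg <- sim_config(n_males = 10, n_females = 0,
                    min_center_separation = 60000,
                    study_bounds = c(0, 0, 50000, 50000), seed = 1)
  expect_error(simulate_population(cfg), "min_center_separation")
})

test_that("disabling exclusion accepts every proposal", {
  cfg <- tiny_sim(exclusion_prob = 0, seed = 5)
  scats <- simulate_scats(simulate_population(cfg), cfg)
  expect_identical(attr(scats, "dropped"), 0L)
})

test_that("certain exclusion empties living same-sex neighbors' zones", {
  cfg <- tiny_sim(n_males = 5, n_females = 5, exclusion_prob = 1,
                  exclusion_radius = 6000, min_center_separation = 4000,
                  death_schedule = c(M01 = 2L, F01 = 2L), seed = 8)
  terr <- simulate_population(cfg)
  scats <- suppressMessages(simulate_scats(terr, cfg))
  season <- season_label(scats$date)
  # brute force: every accepted point against every other same-sex
  # individual alive (exclusion active) in that season
  for (k in seq_len(nrow(scats))) {
    others <- terr[terr$sex == scats$sex[k] &
                   terr$individual_id != scats$individual_id[k] &
                   terr$last_season >= (season[k] - cfg$start_year), ]
    if (nrow(others) == 0) next
    d <- sqrt((others$cx - scats$x[k])^2 + (others$cy - scats$y[k])^2)
    expect_true(all(d >= cfg$exclusion_radius))
  }
})

test_that("per-season scat counts are Poisson-dispersed", {
  cfg <- sim_config(n_males = 20, n_females = 0, n_years = 10, scat_rate = 4,
                    exclusion_prob = 0, min_center_separation = 1000,
                    study_bounds = c(0, 0, 100000, 100000), seed = 21)
  scats <- simulate_scats(simulate_population(cfg), cfg)
  season <- season_label(scats$date)
  counts <- as.vector(table(factor(paste(scats$individual_id, season),
                                   levels = as.vector(outer(
                                     sprintf("M%02d", 1:20),
                                     2001:2010, paste)))))
  expect_equal(mean(counts), 4, tolerance = 0.15)
  # dispersion index of a Poisson is 1; 200 samples give tight bounds
  expect_gt(var(counts) / mean(counts), 0.7)
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("error-free replicates reproduce the true genotypes exactly", {
  cfg <- tiny_sim(dropout_rate = 0, false_allele_rate = 0, seed = 9)
  scats <- simulate_scats(simulate_population(cfg), cfg)
  reps <- simulate_genotype_replicates(scats, cfg)
  truth <- attr(reps, "truth")
  key <- paste(truth$individual_id, truth$locus)
  ind <- scats$individual_id[match(reps$sample_id, scats$sample_id)]
  ti <- match(paste(ind, reps$locus), key)
  expect_identical(reps$allele1, truth$allele1[ti])
  expect_identical(reps$allele2, truth$allele2[ti])
})

test_that("dropout only affects heterozygotes and occurs at the nominal rate", {
  cfg <- sim_config(n_males = 40, n_females = 0, n_years = 1, scat_rate = 3,
                    min_center_separation = 500,
                    study_bounds = c(0, 0, 100000, 100000),
                    dropout_rate = 0.2, false_allele_rate = 0, seed = 13)
  scats <- simulate_scats(simulate_population(cfg), cfg)
  reps <- simulate_genotype_replicates(scats, cfg, n_replicates = 5)
  truth <- attr(reps, "truth")
  key <- paste(truth$individual_id, truth$locus)
  ind <- scats$individual_id[match(reps$sample_id, scats$sample_id)]
  ti <- match(paste(ind, reps$locus), key)
  het <- truth$allele1[ti] != truth$allele2[ti]
  # homozygous true genotypes are never altered
  hom <- !het
  expect_identical(reps$allele1[hom], truth$allele1[ti][hom])
  expect_identical(reps$allele2[hom], truth$allele2[ti][hom])
  # heterozygote replicates become homozygous at the dropout rate
  dropped <- reps$allele1[het] == reps$allele2[het]
  n <- sum(het)
  mc_se <- sqrt(0.2 * 0.8 / n)
  expect_gt(n, 3000)
  expect_lt(abs(mean(dropped) - 0.2), 3 * mc_se)
})

test_that("an empty locus list is rejected", {
  cfg <- tiny_sim()
  cfg$allele_freqs <- list()
  scats <- data.frame(sample_id = "S1", individual_id = "M01")
  expect_error(simulate_genotype_replicates(scats, cfg), "allele_freqs")
})

test_that("the written dataset round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_sim(death_schedule = c(M01 = 2L), seed = 30)
  terr <- simulate_population(cfg)
  scats <- simulate_scats(terr, cfg)
  write_simulation(dir, terr, scats, cfg)
  back <- read_scats(file.path(dir, "scats.csv"))
  expect_equal(nrow(back), nrow(scats))
  expect_equal(back$x, scats$x)
  mort <- read_mortality(file.path(dir, "mortality.csv"))
  expect_identical(mort$individual_id, "M01")
  expect_identical(death_season(mort$death_date),
                   cfg$start_year + 2L)
})
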