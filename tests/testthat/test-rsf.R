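make_scats <- function(id, sex, xy, seasons) {
  data.frame(sample_id = paste0(id, "_", seq_len(nrow(xy))),
             individual_id = id, sex = sex,
             date = as.Date(sprintf("%d-03-01", seasons)),
             x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

test_that("focal selection requires both the threshold and a death record", {
  ring <- function(n, cx = 0, cy = 0) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-1]
    cbind(cx + 1000 * cos(th), cy + 1000 * sin(th))
  }
  scats <- rbind(make_scats("A", "F", ring(4), rep(2005, 4)),
                 make_scats("B", "F", ring(5), rep(2005, 5)),
                 make_scats("C", "M", ring(20), rep(2005, 20)))
  mort <- data.frame(individual_id = c("A", "B"),
                     death_date = as.Date("2006-03-01"))
  f <- select_focals(scats, mort, min_reloc = 5)
  expect_identical(f$individual_id, "B")     # A below threshold, C no death
  expect_identical(f$death_season, 2006L)
  expect_equal(c(f$cx, f$cy), c(0, 0), tolerance = 1e-9)
})

test_that("outlier exclusion drops distant points only, with full bookkeeping", {
  th <- seq(0, 2 * pi, length.out = 10)[-10]
  relocs <- data.frame(sample_id = paste0("s", 1:10),
                       x = c(4000 * cos(th), 200000),
                       y = c(4000 * sin(th), 0))
  none <- exclude_outliers(relocs, rule = "none")
  expect_identical(none$kept, relocs)
  got <- exclude_outliers(relocs, rule = "distance", k = 4)
  expect_identical(got$report$sample_id, "s10")
  expect_identical(got$report$reason, "distance")
  expect_equal(nrow(got$kept), 9)
  man <- exclude_outliers(relocs, rule = "none", manual_list = c("s1", "s10"))
  expect_setequal(man$report$sample_id, c("s1", "s10"))
  expect_error(exclude_outliers(relocs, rule = "manual",
                                manual_list = "missing"), "not found")
})

test_that("context construction applies the circle, window, and death-season rules", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  focal_xy <- cbind(3000 * cos(th), 3000 * sin(th))
  scats <- rbind(
    make_scats("F1", "F", focal_xy, rep(c(2003, 2004), 6)),
    # neighbor exactly on the circle boundary (distance 45000 from centroid)
    make_scats("N1", "F", cbind(c(45000, 1000), c(0, 0)), c(2004, 2004)),
    # neighbor observed only in the death season
    make_scats("N2", "M", cbind(c(2000, 2500), c(0, 0)), c(2005, 2005)),
    # neighbor with one point 4 seasons before death (outside the window)
    make_scats("N3", "M", cbind(c(1500, 1800), c(500, 0)), c(2001, 2003)))
  focal <- select_focals(scats, data.frame(individual_id = "F1",
                                           death_date = as.Date("2005-03-01")))
  ctx <- build_context(focal, scats, min_buffer_points = 5)
  expect_true(ctx$usable)
  obs <- ctx$neighbor_obs
  # boundary point included (closed disk), death-season points dropped,
  # out-of-window point dropped
  expect_true(any(obs$neighbor_id == "N1" & obs$x == 45000))
  expect_false(any(obs$neighbor_id == "N2"))
  expect_identical(obs$season[obs$neighbor_id == "N3"], 2003L)
  expect_true(all(obs$season != 2005))
  expect_true(all(abs(obs$season - 2005) <= 3))
  expect_identical(unique(obs$period[obs$season < 2005]), "before")
})

test_that("availability sampling is uniform on the polygon and seeded", {
  unitkm <- manual_pvc(list(square_ring(0, 0, 1000)))
  pts <- sample_availability_points(unitkm, 2000, seed = 5)
  expect_true(all(ngsterr:::points_in_rings(pts[, 1], pts[, 2], unitkm$rings)))
  expect_identical(pts, sample_availability_points(unitkm, 2000, seed = 5))
  expect_equal(nrow(sample_availability_points(unitkm, 0)), 0)
  # chi-square goodness of fit on a 4x4 grid
  cells <- table(factor(findInterval(pts[, 1], seq(0, 1000, 250),
                                     rightmost.closed = TRUE), levels = 1:4),
                 factor(findInterval(pts[, 2], seq(0, 1000, 250),
                                     rightmost.closed = TRUE), levels = 1:4))
  p <- stats::chisq.test(as.vector(cells))$p.value
  expect_gt(p, 0.001)
})

test_that("the RSF table is a 1:1 matched real/random design", {
  cfg <- tiny_sim(n_males = 6, n_females = 6, n_years = 6, scat_rate = 5,
                  death_schedule = c(M01 = 3L, F01 = 3L), seed = 23)
  terr <- simulate_population(cfg)
  scats <- suppressMessages(simulate_scats(terr, cfg))
  mort <- sim_mortality(terr, cfg)
  focals <- select_focals(scats, mort)
  contexts <- lapply(seq_len(nrow(focals)), function(i)
    build_context(focals[i, ], scats))
  rsf <- assemble_rsf_table(contexts, seed = 31)
  expect_true(check_matched_pairs(rsf))
  expect_equal(sum(rsf$is_real == "real"), sum(rsf$is_real == "random"))
  strat <- table(rsf$is_real, paste(rsf$sex_focal, rsf$sex_neighbor,
                                    rsf$period))
  expect_equal(unname(strat["real", ]), unname(strat["random", ]))
  # no observation from a death season, all within the window
  for (ctx in contexts) {
    if (!ctx$usable) next
    rows <- rsf[rsf$focal_id == ctx$focal_id, ]
    expect_true(all(rows$season != ctx$death_season))
    expect_true(all(abs(rows$season - ctx$death_season) <= 3))
  }
  # determinism
  expect_identical(rsf, assemble_rsf_table(contexts, seed = 31))
})

test_that("inside labels come from the focal polygon, unioned over parts", {
  hr <- manual_pvc(list(square_ring(0, 0, 1000),
                        square_ring(5000, 5000, 1000)))
  avail <- manual_pvc(list(square_ring(-20000, -20000, 2000)))
  obs <- data.frame(neighbor_id = "N", sex = "F",
                    x = c(500, 5500, 3000), y = c(500, 5500, 3000),
                    season = 2004, period = "before",
                    stringsAsFactors = FALSE)
  ctx <- structure(list(focal_id = "F1", sex = "F", death_season = 2005,
                        centroid = c(0, 0), radius = 45000,
                        home_range = hr, availability = avail,
                        neighbor_obs = obs, outlier_report = NULL,
                        usable = TRUE, reason = NA_character_),
                   class = "focal_context")
  rsf <- assemble_rsf_table(list(ctx), seed = 2)
  real <- rsf[rsf$is_real == "real", ]
  expect_identical(real$inside[order(real$x)], c(TRUE, FALSE, TRUE))
  # availability polygon is disjoint from the home range: every random
  # point must be labeled outside
  expect_true(all(!rsf$inside[rsf$is_real == "random"]))
})
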