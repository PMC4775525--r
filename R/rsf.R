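#' Select focal individuals
#'
#' Focal individuals are the animals whose territories the selection analysis
#' tests: individuals with at least `min_reloc` genotyped relocations and a
#' known date of death.
#'
#' @param scats scat table (`sample_id, individual_id, sex, date, x, y`).
#' @param mortality mortality table (`individual_id, death_date`).
#' @param min_reloc minimum relocation count (default 5).
#' @return Data frame `individual_id, sex, death_season, n_relocations, cx,
#'   cy` (centroid of all the individual's sample coordinates).
#' @export
select_focals <- function(scats, mortality, min_reloc = 5) {
  stopifnot(all(c("individual_id", "death_date") %in% names(mortality)))
  sp <- split(scats, scats$individual_id)
  rows <- lapply(sp, function(d) {
    mi <- match(d$individual_id[1], mortality$individual_id)
    if (is.na(mi) || nrow(d) < min_reloc) return(NULL)
    data.frame(individual_id = d$individual_id[1], sex = d$sex[1],
               death_season = death_season(mortality$death_date[mi]),
               n_relocations = nrow(d),
               cx = mean(d$x), cy = mean(d$y), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual_id = character(), sex = character(),
                      death_season = integer(), n_relocations = integer(),
                      cx = numeric(), cy = numeric())
  rownames(out) <- NULL
  out
}

#' Filter spatial outliers from a relocation set
#'
#' Replaces case-by-case visual screening with a reproducible rule: under
#' the `"distance"` rule, points farther than `k` times the median
#' centroid distance are dropped. A `"manual"` list of sample IDs is always
#' honored (and may be combined with the distance rule); `"none"` returns
#' the input unchanged. Outlier removal is applied only when constructing a
#' focal individual's home range - never to the neighbor or availability
#' point sets.
#'
#' @param relocs data frame with `sample_id`, `x`, `y`.
#' @param rule one of `"distance"`, `"none"`, `"manual"`.
#' @param k distance-rule multiplier (default 4).
#' @param manual_list sample IDs to drop unconditionally.
#' @return List with `kept` (filtered data frame) and `report` (data frame
#'   `sample_id, reason` of dropped rows).
#' @export
exclude_outliers <- function(relocs, rule = c("distance", "none", "manual"),
                             k = 4, manual_list = NULL) {
  rule <- match.arg(rule)
  drop <- rep(FALSE, nrow(relocs))
  reason <- rep(NA_character_, nrow(relocs))
  if (!is.null(manual_list) && length(manual_list)) {
    miss <- setdiff(manual_list, relocs$sample_id)
    if (length(miss))
      stop("manual outlier IDs not found: ", paste(miss, collapse = ", "))
    m <- relocs$sample_id %in% manual_list
    drop <- drop | m
    reason[m] <- "manual"
  }
  if (rule == "distance" && nrow(relocs) >= 3) {
    cx <- mean(relocs$x); cy <- mean(relocs$y)
    d <- sqrt((relocs$x - cx)^2 + (relocs$y - cy)^2)
    far <- d > k * stats::median(d)
    reason[far & !drop] <- "distance"
    drop <- drop | far
  }
  list(kept = relocs[!drop, , drop = FALSE],
       report = data.frame(sample_id = relocs$sample_id[drop],
                           reason = reason[drop], stringsAsFactors = FALSE))
}

#' Build the use-availability context around one focal individual
#'
#' Assembles everything the selection analysis needs for one focal animal:
#' its outlier-filtered kernel home range, a circular neighborhood of radius
#' `radius` around its sample centroid (closed disk: boundary points are
#' in), the availability polygon (a kernel contour at `availability_level`
#' over *all* in-buffer points from the entire study period, delineating the
#' searched area), and the neighbor observations - points of other
#' individuals inside the circle, from seasons within `window` years of the
#' focal's death season, excluding the death season itself (whether such a
#' scat predates or postdates the death is unknowable).
#'
#' @param focal one row of [select_focals()] output.
#' @param scats the full scat table.
#' @param window temporal window in seasons (default 3).
#' @param radius neighborhood radius in meters (default 45000).
#' @param availability_level kernel contour level of the availability polygon
#'   (default 85).
#' @param focal_level contour level delineating the focal home range
#'   (default 95; 75 and 50 for sensitivity analyses).
#' @param outlier_rule,outlier_k,manual_list passed to [exclude_outliers()].
#' @param min_buffer_points minimum in-buffer points required for a usable
#'   availability polygon (default 10).
#' @return Object of class `focal_context`: list with `focal_id`, `sex`,
#'   `death_season`, `centroid`, `radius`, `home_range` (a `pvc`),
#'   `availability` (a `pvc`), `neighbor_obs` (data frame `neighbor_id, sex,
#'   x, y, season, period`), `outlier_report`, `usable`, `reason`.
#' @export
build_context <- function(focal, scats, window = 3, radius = 45000,
                          availability_level = 85, focal_level = 95,
                          outlier_rule = "distance", outlier_k = 4,
                          manual_list = NULL, min_buffer_points = 10) {
  fid <- focal$individual_id
  ds <- focal$death_season
  unusable <- function(reason)
    structure(list(focal_id = fid, sex = focal$sex, death_season = ds,
                   centroid = c(focal$cx, focal$cy), radius = radius,
                   home_range = NULL, availability = NULL,
                   neighbor_obs = NULL, outlier_report = NULL,
                   usable = FALSE, reason = reason),
              class = "focal_context")

  own <- scats[scats$individual_id == fid, , drop = FALSE]
  filt <- exclude_outliers(own, rule = outlier_rule, k = outlier_k,
                           manual_list = manual_list)
  if (nrow(filt$kept) < 3) return(unusable("too few relocations after outlier filter"))
  hr_ud <- fit_kud(filt$kept$x, filt$kept$y)
  hr <- percent_volume_contour(hr_ud, focal_level)

  d <- sqrt((scats$x - focal$cx)^2 + (scats$y - focal$cy)^2)
  in_buffer <- scats[d <= radius, , drop = FALSE]
  if (nrow(in_buffer) < min_buffer_points)
    return(unusable("too few points inside the neighborhood"))
  av_ud <- fit_kud(in_buffer$x, in_buffer$y)
  availability <- percent_volume_contour(av_ud, availability_level)

  nb <- in_buffer[in_buffer$individual_id != fid, , drop = FALSE]
  season <- season_label(nb$date)
  keep <- !is.na(season) & season != ds & abs(season - ds) <= window
  nb <- nb[keep, , drop = FALSE]
  season <- season[keep]
  obs <- data.frame(neighbor_id = nb$individual_id, sex = nb$sex,
                    x = nb$x, y = nb$y, season = season,
                    period = ifelse(season < ds, "before", "after"),
                    stringsAsFactors = FALSE)
  if (nrow(obs) == 0) return(unusable("no neighbor observations in window"))
  structure(list(focal_id = fid, sex = focal$sex, death_season = ds,
                 centroid = c(focal$cx, focal$cy), radius = radius,
                 home_range = hr, availability = availability,
                 neighbor_obs = obs, outlier_report = filt$report,
                 usable = TRUE, reason = NA_character_),
            class = "focal_context")
}

#' Uniform random points inside a contour polygon
#'
#' Rejection sampling from the polygon's bounding box; points are accepted
#' when they fall inside the ring set under the even-odd rule.
#'
#' @param pvc a `pvc` contour polygon with positive area.
#' @param n number of points.
#' @param seed optional integer seed.
#' @return Two-column matrix of coordinates (m); zero rows when `n = 0`.
#' @export
sample_availability_points <- function(pvc, n, seed = NULL) {
  stopifnot(inherits(pvc, "pvc"))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  if (pvc$area_km2 <= 0) stop("availability polygon has no area")
  allx <- unlist(lapply(pvc$rings, function(r) r[, 1]))
  ally <- unlist(lapply(pvc$rings, function(r) r[, 2]))
  bb <- c(min(allx), max(allx), min(ally), max(ally))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  tried <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 100L)
    px <- stats::runif(m, bb[1], bb[2])
    py <- stats::runif(m, bb[3], bb[4])
    ok <- points_in_rings(px, py, pvc$rings)
    tried <- tried + m
    take <- min(sum(ok), n - got)
    if (take > 0) {
      idx <- which(ok)[seq_len(take)]
      out[(got + 1):(got + take), ] <- cbind(px[idx], py[idx])
      got <- got + take
    }
    if (tried > 1e4 && got / tried < 1e-4)
      stop("rejection acceptance rate below 1e-4; polygon is degenerate ",
           "relative to its bounding box")
  }
  out
}

#' Assemble the use-availability table
#'
#' For every real neighbor observation in every usable context, draws one
#' matched random point uniformly from that context's availability polygon,
#' copying all stratum labels (focal and neighbor sex, period, season,
#' IDs). Each point - real and random - is labeled inside or outside the
#' focal individual's home range (boundary counts as inside; multipart
#' ranges are unions over parts).
#'
#' @param contexts list of `focal_context` objects.
#' @param seed integer seed for the random-point draws.
#' @return Data frame of class `rsf_table`: `focal_id, neighbor_id, pair_id,
#'   is_real, inside, sex_focal, sex_neighbor, period, season, x, y`.
#' @export
assemble_rsf_table <- function(contexts, seed = 1L) {
  set.seed(seed)
  rows <- list()
  pair <- 0L
  for (ctx in contexts) {
    if (!isTRUE(ctx$usable)) next
    obs <- ctx$neighbor_obs
    nreal <- nrow(obs)
    rnd <- sample_availability_points(ctx$availability, nreal)
    inside_real <- points_in_rings(obs$x, obs$y, ctx$home_range$rings)
    inside_rnd <- points_in_rings(rnd[, 1], rnd[, 2], ctx$home_range$rings)
    pid <- pair + seq_len(nreal)
    pair <- pair + nreal
    base <- data.frame(focal_id = ctx$focal_id, neighbor_id = obs$neighbor_id,
                       pair_id = pid, sex_focal = ctx$sex,
                       sex_neighbor = obs$sex, period = obs$period,
                       season = obs$season, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(base, is_real = "real",
                                       inside = inside_real,
                                       x = obs$x, y = obs$y,
                                       stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cbind(base, is_real = "random",
                                       inside = inside_rnd,
                                       x = rnd[, 1], y = rnd[, 2],
                                       stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no usable focal contexts: cannot assemble an RSF table")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rsf_table", "data.frame")
  out
}

#' Validate the matched-pair structure of an RSF table
#'
#' Every `pair_id` must appear exactly twice - once real, once random - with
#' identical stratum labels.
#'
#' @param rsf an `rsf_table`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
check_matched_pairs <- function(rsf) {
  sp <- split(rsf, rsf$pair_id)
  for (d in sp) {
    if (nrow(d) != 2 || !setequal(d$is_real, c("real", "random")))
      stop("pair ", d$pair_id[1], " is not one real + one random point")
    lab <- c("focal_id", "neighbor_id", "sex_focal", "sex_neighbor",
             "period", "season")
    if (!all(d[1, lab] == d[2, lab]))
      stop("pair ", d$pair_id[1], " has mismatched stratum labels")
  }
  invisible(TRUE)
}
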