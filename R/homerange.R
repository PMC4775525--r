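#' Reference ("ad hoc") kernel bandwidth
#'
#' The classical reference rule for bivariate kernel home-range estimation:
#' \eqn{h = \sigma \, n^{-1/6}} with \eqn{\sigma^2} the mean of the x and y
#' coordinate variances. Scale-equivariant: scaling the points by a factor
#' scales the bandwidth by the same factor.
#'
#' @param x,y relocation coordinates (m).
#' @return Bandwidth in input units.
#' @export
href_bandwidth <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  s2 <- mean(c(stats::var(x), stats::var(y)))
  if (!is.finite(s2) || s2 <= 0)
    stop("all points identical: bandwidth undefined")
  sqrt(s2) * length(x)^(-1 / 6)
}

#' Fit a kernel utilization distribution on a grid
#'
#' Bivariate Gaussian product-kernel density, averaged over the relocation
#' points and evaluated on a regular grid covering the points plus a margin,
#' then mass-normalized so that the cell densities times the cell area sum
#' to 1.
#'
#' @param x,y relocation coordinates (m).
#' @param h kernel bandwidth (m); defaults to [href_bandwidth()].
#' @param cell grid cell size (m); default `h / 4`.
#' @param margin grid margin beyond the point bounding box (m); default
#'   `3 * h` so that essentially all kernel mass falls on the grid.
#' @return Object of class `kud`: list with `gx`, `gy` (cell-center
#'   coordinates), `z` (density matrix, rows indexed by `gx`), `cell`, `h`.
#' @export
fit_kud <- function(x, y, h = NULL, cell = NULL, margin = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n == 0) stop("no points")
  if (is.null(h)) h <- href_bandwidth(x, y)
  stopifnot(h > 0)
  if (is.null(cell)) cell <- h / 4
  if (is.null(margin)) margin <- 3 * h
  if (cell > h)
    warning("grid cell size exceeds the bandwidth; contours may be inaccurate")
  gx <- seq(min(x) - margin, max(x) + margin + cell, by = cell)
  gy <- seq(min(y) - margin, max(y) + margin + cell, by = cell)
  # separable Gaussian kernel: density = Kx %*% t(Ky) / n
  kx <- outer(gx, x, function(g, p) stats::dnorm(g, p, h))
  ky <- outer(gy, y, function(g, p) stats::dnorm(g, p, h))
  z <- (kx %*% t(ky)) / n
  mass <- sum(z) * cell^2
  z <- z / mass
  structure(list(gx = gx, gy = gy, z = z, cell = cell, h = h),
            class = "kud")
}

#' Percent-volume contour of a utilization distribution
#'
#' The smallest-area region containing `level` percent of the UD mass: cells
#' are ranked by descending density, the density threshold at which the
#' cumulative mass reaches `level`/100 is found, and the iso-density boundary
#' at that threshold is polygonized (contour extraction on the grid, with the
#' grid zero-padded so rings always close). Holes are retained and handled
#' by the even-odd rule.
#'
#' @param ud a `kud` object.
#' @param level percent of UD mass in (0, 100).
#' @return Object of class `pvc`: list with `level`, `threshold` (density),
#'   `rings` (list of two-column matrices, m), `area_km2`.
#' @export
percent_volume_contour <- function(ud, level) {
  stopifnot(inherits(ud, "kud"), level > 0, level < 100)
  cellm <- ud$cell^2
  ord <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(ud$z[ord]) * cellm
  if (max(cum) < level / 100)
    stop("grid holds only ", round(100 * max(cum), 2),
         "% of the UD mass; increase the grid margin")
  k <- which(cum >= level / 100)[1]
  thr <- ud$z[ord][k]
  # zero-pad so contour lines always close into rings
  nx <- length(ud$gx); ny <- length(ud$gy)
  px <- c(ud$gx[1] - ud$cell, ud$gx, ud$gx[nx] + ud$cell)
  py <- c(ud$gy[1] - ud$cell, ud$gy, ud$gy[ny] + ud$cell)
  pz <- matrix(0, nx + 2, ny + 2)
  pz[2:(nx + 1), 2:(ny + 1)] <- ud$z
  cl <- grDevices::contourLines(px, py, pz, levels = thr)
  rings <- lapply(cl, function(l) cbind(l$x, l$y))
  structure(list(level = level, threshold = thr, rings = rings,
                 area_km2 = rings_area(rings) / 1e6),
            class = "pvc")
}

#' Kernel home-range area
#'
#' Composition of [href_bandwidth()], [fit_kud()] and
#' [percent_volume_contour()]: the area of the percent-volume contour of the
#' kernel UD fitted to the points.
#'
#' @inheritParams fit_kud
#' @param level percent-volume level (default 95).
#' @return Area in km^2 (inputs are meters).
#' @export
kernel_area <- function(x, y, level = 95, h = NULL, cell = NULL, margin = NULL) {
  ud <- fit_kud(x, y, h = h, cell = cell, margin = margin)
  percent_volume_contour(ud, level)$area_km2
}

#' Minimum convex polygon home-range area
#'
#' Convex-hull area of the relocations retained after removing the
#' `100 - percent` percent of points farthest from the arithmetic-mean
#' centroid (computed once; ties broken by input order).
#'
#' @param x,y relocation coordinates (m).
#' @param percent percent of points retained (default 95; 100 keeps all).
#' @return List with `area` (square input units), `area_km2`, `n_used`, and
#'   `degenerate` (`TRUE` when fewer than 3 distinct non-collinear points
#'   remain, in which case the area is 0).
#' @export
mcp_area <- function(x, y, percent = 95) {
  stopifnot(length(x) == length(y), percent > 0, percent <= 100)
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  n_keep <- ceiling(n * percent / 100)
  keep <- order(d, seq_len(n))[seq_len(n_keep)]
  hull <- convex_hull_area(x[keep], y[keep])
  list(area = hull$area, area_km2 = hull$area / 1e6,
       n_used = n_keep, degenerate = hull$degenerate)
}

#' Home-range areas for every individual in a scat table
#'
#' @param scats data frame with `individual_id`, `x`, `y`, `date`.
#' @param level percent-volume (or MCP retention) level.
#' @param min_reloc minimum relocations required to estimate a range
#'   (default 8 for the size analysis).
#' @param estimator `"kernel"` or `"mcp"`.
#' @return Data frame `individual_id, sex, estimator, level, area_km2,
#'   n_relocations, n_years` (`n_years` counts distinct monitoring seasons).
#' @export
home_range_table <- function(scats, level = 95, min_reloc = 8,
                             estimator = c("kernel", "mcp")) {
  estimator <- match.arg(estimator)
  sp <- split(scats, scats$individual_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < min_reloc) return(NULL)
    area <- if (estimator == "kernel") kernel_area(d$x, d$y, level = level)
            else mcp_area(d$x, d$y, percent = level)$area_km2
    data.frame(individual_id = d$individual_id[1],
               sex = if ("sex" %in% names(d)) d$sex[1] else NA_character_,
               estimator = estimator, level = level, area_km2 = area,
               n_relocations = nrow(d),
               n_years = length(unique(season_label(d$date))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(individual_id = character(), sex = character(),
                      estimator = character(), level = numeric(),
                      area_km2 = numeric(), n_relocations = integer(),
                      n_years = integer())
  rownames(out) <- NULL
  out
}

#' Home-range area under repeated subsampling
#'
#' For each individual, repeatedly subsamples its relocations without
#' replacement at each requested sample size and re-estimates the home-range
#' area, quantifying the sample-size sensitivity of the estimator (kernel
#' areas shrink with more relocations because the reference bandwidth
#' shrinks; MCP areas grow because the hull can only expand).
#'
#' @param scats data frame with `individual_id`, `x`, `y`.
#' @param n_grid vector of subsample sizes; sizes exceeding an individual's
#'   relocation count are skipped for that individual.
#' @param reps subsample replicates per size.
#' @param estimator `"kernel"` or `"mcp"`.
#' @param level contour / retention level (default 95).
#' @param seed integer seed.
#' @return Data frame `individual_id, n, rep, estimator, area_km2`.
#' @export
subsample_hr_curve <- function(scats, n_grid, reps = 10,
                               estimator = c("kernel", "mcp"),
                               level = 95, seed = 1L) {
  estimator <- match.arg(estimator)
  set.seed(seed)
  sp <- split(scats, scats$individual_id)
  rows <- list()
  for (id in names(sp)) {
    d <- sp[[id]]
    for (n in n_grid) {
      if (n > nrow(d) || n < 3) next
      for (r in seq_len(reps)) {
        idx <- if (n == nrow(d)) seq_len(n) else sample.int(nrow(d), n)
        area <- if (estimator == "kernel")
          kernel_area(d$x[idx], d$y[idx], level = level)
        else mcp_area(d$x[idx], d$y[idx], percent = level)$area_km2
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, n = n, rep = r, estimator = estimator,
          area_km2 = area, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
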