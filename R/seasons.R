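#' Monitoring-season labels
#'
#' Scat collection runs from October through June of the following calendar
#' year; that window is one monitoring season, labeled by the calendar year in
#' which it ends (the season Oct 2009 - Jun 2010 is season 2010). Dates in
#' July-September fall outside the collection window and get `NA`.
#'
#' @param date a `Date` vector (or something coercible via `as.Date`).
#' @return Integer vector of season labels.
#' @examples
#' season_label(as.Date(c("2009-11-15", "2010-03-01", "2010-08-01")))
#' @export
season_label <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  out <- ifelse(m >= 10L, y + 1L, ifelse(m <= 6L, y, NA_integer_))
  as.integer(out)
}

#' Season label of a death date
#'
#' Deaths during the collection window are labeled like samples. A death in
#' the July-September gap is assigned to the following season (the first
#' season during which the animal is no longer present).
#'
#' @param date a `Date` vector.
#' @return Integer vector of season labels.
#' @export
death_season <- function(date) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  as.integer(ifelse(m >= 7L, y + 1L, y))
}
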