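#' @importFrom stats var sd quantile rnorm runif rpois rbinom rlnorm rbeta
#'   rexp median setNames complete.cases predict coef kmeans
#' @importFrom utils head tail combn
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
clamp01 <- function(x) clamp(x, 0, 1)

#' Decimal clock hour of a timestamp
#' @param t POSIXct vector (study-local, timezone-naive convention: UTC)
#' @return numeric hours in [0, 24)
#' @keywords internal
hour_of <- function(t) {
  (as.numeric(t) %% 86400) / 3600
}

#' Day-of-week helper (Mon = 1 ... Sun = 7)
#' @keywords internal
wday_of <- function(t) {
  # 1970-01-01 (epoch day 0) was a Thursday (= 4)
  ((as.numeric(t) %/% 86400 + 3) %% 7) + 1
}

is_weekend <- function(t) wday_of(t) >= 6L

#' Ray-casting point-in-polygon test
#'
#' Vectorized over query points; the polygon is a two-column (lon, lat)
#' matrix or data.frame, implicitly closed.
#' @param lon,lat numeric query coordinates
#' @param poly matrix/data.frame with columns lon, lat
#' @return logical vector
#' @keywords internal
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[[1]]
  py <- poly[[2]]
  n <- length(px)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > lat) != (py[j] > lat)) &
      (lon < (px[j] - px[i]) * (lat - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Classical Lomb-Scargle normalized periodogram
#'
#' Computes the Lomb normalized power of an unevenly sampled series at the
#' requested periods. Power is normalized by the series variance, so a pure
#' sinusoid sampled over many cycles approaches N/2 at its true period and
#' white noise has expectation ~1.
#'
#' @param t sample times (numeric, in the same unit as `periods`)
#' @param y sample values
#' @param periods periods at which to evaluate the power
#' @return numeric vector of normalized powers (0 for a constant series)
#' @export
lomb_scargle_power <- function(t, y, periods) {
  stopifnot(length(t) == length(y), length(t) > 2)
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 3) return(rep(0, length(periods)))
  v <- var(y)
  if (!is.finite(v) || v <= .Machine$double.eps) return(rep(0, length(periods)))
  yc <- y - mean(y)
  vapply(periods, function(p) {
    w <- 2 * pi / p
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(yc * ct)^2 / sum(ct^2) + sum(yc * st)^2 / sum(st^2)) / (2 * v)
  }, numeric(1))
}

#' Local equirectangular projection to meters
#' @keywords internal
local_xy <- function(lat, lon, lat0 = mean(lat), lon0 = mean(lon)) {
  R <- 6371008.8
  list(
    x = (lon - lon0) * pi / 180 * R * cos(lat0 * pi / 180),
    y = (lat - lat0) * pi / 180 * R
  )
}

#' Haversine distance in meters between paired coordinates
#'
#' Vectorized great-circle distance on the sphere geosphere uses
#' (radius 6378137 m); kept free of per-call input marshalling because it
#' sits inside the DBSCAN neighbour search. Agreement with
#' `geosphere::distHaversine()` is asserted in the test suite.
#' @keywords internal
dist_m <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * 6378137 * asin(pmin(1, sqrt(a)))
}

# run-length episodes over a logical/label vector with gap tolerance:
# returns data.table(start_idx, end_idx, value, n)
rle_episodes <- function(values) {
  r <- rle(as.character(values))
  e <- cumsum(r$lengths)
  s <- c(1L, head(e, -1L) + 1L)
  data.table::data.table(start_idx = s, end_idx = e, value = r$values, n = r$lengths)
}

new_feature_map <- function(names = character(), values = numeric()) {
  stats::setNames(as.numeric(values), names)
}

# stat block helper: min/max/mean/sd of x, NA-safe; returns named numeric
stat_block <- function(x, prefix) {
  if (length(x) == 0) {
    return(new_feature_map(paste0(prefix, c("_min", "_max", "_mean", "_sd")),
                           rep(NA_real_, 4)))
  }
  new_feature_map(
    paste0(prefix, c("_min", "_max", "_mean", "_sd")),
    c(min(x), max(x), mean(x), if (length(x) > 1) sd(x) else 0)
  )
}
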