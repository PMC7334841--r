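#' Effective population size from nucleotide diversity
#'
#' The classical neutral-equilibrium estimator pi = 4 Ne mu, inverted as
#' Ne = pi / (4 mu). Confidence bounds on the mutation rate map inversely
#' to bounds on Ne (high mu gives low Ne).
#'
#' @param pi per-site nucleotide diversity (>= 0).
#' @param mu mutation rate per site per generation (> 0).
#' @param mu_ci optional length-2 vector (low, high) of mutation-rate
#'   bounds.
#' @return list: pi, mu, ne, and ne_ci = c(pi/(4*mu_high), pi/(4*mu_low))
#'   when bounds are given.
#' @export
ne_from_pi <- function(pi, mu, mu_ci = NULL) {
  if (mu <= 0) stop("mutation rate must be positive")
  stopifnot(pi >= 0)
  ne <- pi / (4 * mu)
  ne_ci <- NULL
  if (!is.null(mu_ci)) {
    stopifnot(length(mu_ci) == 2L, all(mu_ci > 0))
    ne_ci <- c(low = pi / (4 * max(mu_ci)), high = pi / (4 * min(mu_ci)))
  }
  list(pi = pi, mu = mu, ne = ne, ne_ci = ne_ci)
}

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distance in km.
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2), r = 6371.0088)
}

#' Geographic midpoint of a set of points
#'
#' Converts each point to a unit 3-vector, averages, renormalises and
#' converts back. An error is raised when the points average to the
#' sphere's center (antipodal degenerate case).
#'
#' @param lat,lon numeric vectors of coordinates in degrees.
#' @return list with \code{lat} and \code{lon} in degrees.
#' @export
geographic_midpoint <- function(lat, lon) {
  stopifnot(length(lat) >= 1L, length(lat) == length(lon))
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  x <- mean(cos(phi) * cos(lam))
  y <- mean(cos(phi) * sin(lam))
  z <- mean(sin(phi))
  r <- sqrt(x^2 + y^2 + z^2)
  if (r < 1e-12) stop("points average to the sphere's center; ",
                      "midpoint undefined")
  list(lat = asin(z / r) * 180 / pi, lon = atan2(y, x) * 180 / pi)
}

#' Isolation-by-distance regression
#'
#' Regresses linearised differentiation F_ST / (1 - F_ST) on pairwise
#' geodesic distance between population locations. Population locations
#' are the geographic midpoints of their members' coordinates. Negative
#' F_ST estimates are set to 0 before linearisation; pairs at F_ST = 1 are
#' excluded with a warning (infinite linearised value).
#'
#' @param fst_pairs data.frame with columns popA, popB, fst.
#' @param popmap a \code{pop_map} with coordinates.
#' @return list of class \code{ibd_result}: \code{pairs} (popA, popB,
#'   distance_km, fst, linearized), \code{slope} (per km),
#'   \code{intercept}, \code{r_squared}.
#' @export
ibd_regression <- function(fst_pairs, popmap) {
  if (is.null(popmap$lat)) stop("population map carries no coordinates")
  pts <- lapply(unique(popmap$population), function(p) {
    i <- popmap$population == p & !is.na(popmap$lat)
    if (!any(i)) stop("no coordinates for population ", p)
    geographic_midpoint(popmap$lat[i], popmap$lon[i])
  })
  names(pts) <- unique(popmap$population)
  fst <- pmax(fst_pairs$fst, 0)
  keep <- !is.na(fst) & fst < 1
  if (any(!keep, na.rm = TRUE))
    warning("excluding pairs with F_ST = 1 or undefined")
  pr <- fst_pairs[keep, , drop = FALSE]
  fst <- fst[keep]
  if (nrow(pr) < 3L) stop("need at least 3 usable population pairs")
  dist_km <- mapply(function(a, b)
    geodesic_distance(pts[[a]]$lat, pts[[a]]$lon,
                      pts[[b]]$lat, pts[[b]]$lon),
    pr$popA, pr$popB)
  lin <- fst / (1 - fst)
  fit <- stats::lm(lin ~ dist_km)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((lin - mean(lin))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(
    pairs = data.frame(popA = pr$popA, popB = pr$popB,
                       distance_km = dist_km, fst = fst,
                       linearized = lin, stringsAsFactors = FALSE),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    residuals = res
  ), class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat(sprintf(
    "isolation by distance: %d pairs, slope %.3g per km, r^2 %.3f\n",
    nrow(x$pairs), x$slope, x$r_squared))
  invisible(x)
}

#' Ratio of two isolation-by-distance slopes
#'
#' @param result_a,result_b \code{ibd_result} objects (or lists with a
#'   \code{slope} element).
#' @return slope_a / slope_b.
#' @export
slope_ratio <- function(result_a, result_b) {
  if (result_b$slope == 0) stop("denominator slope is zero")
  result_a$slope / result_b$slope
}
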