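#' Pairwise inter-location distances
#'
#' Distance matrix between all spatial units, either planar euclidean in the
#' units of the coordinates, or great-circle (haversine) distances in km for
#' longitude/latitude input (sphere radius 6371 km).
#'
#' @param u,v numeric coordinate vectors (easting/longitude and
#'   northing/latitude).
#' @param metric \code{"euclidean"} (default) or \code{"haversine"}.
#' @return symmetric \eqn{n \times n} matrix with zero diagonal.
#'   Duplicated coordinate pairs are allowed (distance 0) but reported via
#'   a message, because they make the corresponding local fits identical.
#' @examples
#' pairwise_distance(c(0, 3), c(0, 4))  # off-diagonal 5
#' @export
pairwise_distance <- function(u, v, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  if (!is.numeric(u) || !is.numeric(v) || length(u) != length(v))
    stop("'u' and 'v' must be numeric vectors of equal length", call. = FALSE)
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("coordinates must be finite", call. = FALSE)
  n <- length(u)
  if (n < 2L) stop("at least two locations are required", call. = FALSE)
  if (metric == "haversine") {
    if (any(u < -180 | u > 180) || any(v < -90 | v > 90))
      stop("haversine metric requires lon in [-180, 180] and lat in [-90, 90]",
           call. = FALSE)
    # geosphere works on a sphere of radius 6378137 m; haversine distance is
    # linear in the radius, so rescale to the conventional R = 6371 km
    D <- geosphere::distm(cbind(u, v), fun = geosphere::distHaversine)
    D <- D / 6378137 * 6371
  } else {
    D <- as.matrix(stats::dist(cbind(u, v)))
  }
  dimnames(D) <- NULL
  dup <- duplicated(cbind(u, v))
  if (any(dup))
    message(sprintf("note: %d duplicated coordinate pair(s); local fits at those locations coincide",
                    sum(dup)))
  D
}

#' Spatial kernel weights for one regression location
#'
#' Converts a row of distances into the diagonal of the spatial weight
#' matrix \eqn{W(u_i, v_i)} used by the local weighted least-squares fit.
#' All kernels give weight 1 at distance 0 and are non-increasing in
#' distance; bisquare and tricube have compact support (weight 0 at and
#' beyond the bandwidth).
#'
#' @param d numeric vector of non-negative distances from the regression
#'   location to every observation.
#' @param bandwidth positive kernel bandwidth in the units of \code{d};
#'   \code{Inf} gives uniform (all-ones) weights for every kernel.
#' @param kernel one of \code{"gaussian"} (\eqn{\exp(-d^2/2b^2)}),
#'   \code{"bisquare"} (\eqn{(1-(d/b)^2)^2} inside the bandwidth) or
#'   \code{"tricube"} (\eqn{(1-(d/b)^3)^3} inside the bandwidth).
#' @return numeric weight vector of the same length as \code{d}.
#' @examples
#' kernel_weights(c(0, 1, 2), bandwidth = 2, kernel = "bisquare")
#' @export
kernel_weights <- function(d, bandwidth,
                           kernel = c("gaussian", "bisquare", "tricube")) {
  kernel <- match.arg(kernel)
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("'d' must be finite non-negative distances", call. = FALSE)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      is.na(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be a single positive number", call. = FALSE)
  if (is.infinite(bandwidth)) return(rep(1, length(d)))
  r <- d / bandwidth
  w <- switch(kernel,
              gaussian = exp(-0.5 * r^2),
              bisquare = ifelse(r < 1, (1 - r^2)^2, 0),
              tricube  = ifelse(r < 1, (1 - r^3)^3, 0))
  if (all(w <= 0))
    gwnr_degenerate("all kernel weights are zero; increase the bandwidth")
  w
}

# Resolve an adaptive bandwidth (k nearest neighbours) to the k-th smallest
# distance in the row; the row includes the self-distance 0.
adaptive_bandwidth <- function(d, k) {
  k <- check_count(k, "adaptive_k", min = 2L)
  if (k > length(d)) stop("'adaptive_k' exceeds the number of locations",
                          call. = FALSE)
  sort(d)[k]
}

#' Leave-one-out cross-validation bandwidth selection
#'
#' Scores each candidate bandwidth by the leave-one-out prediction error
#' \eqn{\sum_i (y_i - \hat y_{(-i)})^2}, where \eqn{\hat y_{(-i)}} is the
#' local fit at location \eqn{i} with its own weight forced to zero (the
#' usual convention for geographically weighted regression).  Candidates at
#' which any local fit is degenerate score \code{Inf}; exact ties are broken
#' toward the larger bandwidth.
#'
#' @param y response vector.
#' @param design design matrix from \code{\link{build_design}} /
#'   \code{\link{assemble_design}}.
#' @param D distance matrix from \code{\link{pairwise_distance}}.
#' @param candidates numeric vector of candidate bandwidths.
#' @param kernel kernel family, see \code{\link{kernel_weights}}.
#' @return the selected bandwidth, with the score vector attached as
#'   attribute \code{"cv"}.
#' @export
select_bandwidth <- function(y, design, D, candidates,
                             kernel = c("gaussian", "bisquare", "tricube")) {
  kernel <- match.arg(kernel)
  if (!length(candidates)) stop("empty candidate grid", call. = FALSE)
  candidates <- sort(as.numeric(candidates))
  n <- length(y)
  scores <- vapply(candidates, function(b) {
    se <- 0
    for (i in seq_len(n)) {
      w <- tryCatch(kernel_weights(D[i, ], b, kernel),
                    gwnr_degenerate_error = function(e) NULL)
      if (is.null(w)) return(Inf)
      w[i] <- 0
      fit <- tryCatch(local_wls(y, design, w, i),
                      error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      se <- se + (y[i] - fit$yhat)^2
    }
    se
  }, numeric(1))
  if (all(is.infinite(scores)))
    stop("bandwidth selection failed: every candidate yields a degenerate local fit",
         call. = FALSE)
  best <- max(which(scores == min(scores)))  # tie -> larger bandwidth
  structure(candidates[best], cv = stats::setNames(scores, format(candidates)))
}

# Default candidate grid: 10 bandwidths spanning moderate locality to the
# near-global fit, on the scale of the observed distances.
default_bw_grid <- function(D) {
  pos <- D[upper.tri(D)]
  pos <- pos[pos > 0]
  if (!length(pos)) stop("all locations coincide; cannot build a bandwidth grid",
                         call. = FALSE)
  seq(stats::quantile(pos, 0.1), max(pos), length.out = 10)
}
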