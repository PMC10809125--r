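# The assembled design carries both an all-ones intercept and the all-1/2
# column of the Fourier constant, which are exactly collinear by
# construction.  Every fit therefore works on the reduced design with the
# half-constant column removed; the estimated constant b is split back as
# beta0 = 0.8 b, theta0 = 0.4 b (the minimum-norm solution of
# beta0 + theta0/2 = b).  Fitted values, hat matrices and all sums of
# squares are invariant to the split.  Rank deficiency beyond this
# structural aliasing is an error.
design_parts <- function(Q) {
  hc <- attr(Q, "half_col")
  M <- unclass(Q)
  attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))] <- NULL
  if (is.null(hc))
    return(list(Qr = M, half_col = NA_integer_, m = ncol(M)))
  list(Qr = M[, -hc, drop = FALSE], half_col = hc, m = ncol(M))
}

expand_eta <- function(eta_r, parts, labels) {
  if (is.na(parts$half_col)) {
    names(eta_r) <- labels
    return(eta_r)
  }
  eta <- numeric(parts$m)
  eta[-parts$half_col] <- eta_r
  b <- eta[1L]
  eta[1L] <- 0.8 * b                 # beta0
  eta[parts$half_col] <- 0.4 * b     # theta0 (enters the model as theta0/2)
  names(eta) <- labels
  eta
}

check_rank <- function(Qr, context = "design") {
  qrd <- qr(Qr, tol = 1e-10)
  if (qrd$rank < ncol(Qr)) {
    bad <- colnames(Qr)[qrd$pivot[(qrd$rank + 1L):ncol(Qr)]]
    stop(sprintf("singular %s: column(s) %s are linearly dependent on the others",
                 context, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  qrd
}

#' Fit the global mixed nonparametric regression by least squares
#'
#' Workhorse fitter (design-matrix interface, in the spirit of
#' \code{\link[stats]{lm.fit}}) for the global MNR model: ordinary least
#' squares on the mixed spline + Fourier design.  Returns the hat matrix
#' \eqn{L = Q(Q^\top Q)^{-1}Q^\top} (computed on the reduced,
#' full-rank parameterization), which is the symmetric idempotent projector
#' the goodness-of-fit test requires.
#'
#' @param y numeric response vector.
#' @param design design matrix (a \code{"gwnr_design"} or a plain full-rank
#'   numeric matrix).
#' @return list with components \code{eta} (coefficients on the full column
#'   layout, aliased constant split as documented), \code{eta_reduced},
#'   \code{L}, \code{fitted}, \code{residuals}, \code{sse}, \code{rank}
#'   (effective number of parameters, \code{tr(L)}), \code{df_residual} and
#'   \code{sigma2}.
#' @seealso \code{\link{mnr}} for the formula interface.
#' @export
mnr_fit <- function(y, design) {
  n <- length(y)
  parts <- design_parts(design)
  if (nrow(parts$Qr) != n)
    stop("length of 'y' does not match the design", call. = FALSE)
  if (n <= ncol(parts$Qr))
    stop("need more observations than estimable parameters", call. = FALSE)
  qrd <- check_rank(parts$Qr)
  eta_r <- qr.coef(qrd, y)
  fitted <- drop(parts$Qr %*% eta_r)
  L <- parts$Qr %*% solve(crossprod(parts$Qr), t(parts$Qr))
  res <- y - fitted
  sse <- sum(res^2)
  rank <- qrd$rank
  list(eta = expand_eta(eta_r, parts, attr(design, "labels") %||% colnames(design)),
       eta_reduced = stats::setNames(eta_r, colnames(parts$Qr)),
       L = L, fitted = fitted, residuals = res, sse = sse,
       rank = rank, df_residual = n - rank, sigma2 = sse / (n - rank))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single-location weighted least squares: eta_i = (Q'WQ)^{-1} Q'Wy and the
# i-th row of the hat matrix, g_i' = q_i'(Q'WQ)^{-1}Q'W.
local_wls <- function(y, design, w, i) {
  parts <- design_parts(design)
  Qr <- parts$Qr
  A <- crossprod(Qr, w * Qr)
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-10)
    stop(sprintf("near-singular local system at location %d (rcond = %.2e); try a larger bandwidth",
                 i, rc), call. = FALSE)
  s <- solve(A, Qr[i, ])
  g_row <- unname(drop(Qr %*% s) * w)
  eta_r <- drop(solve(A, crossprod(Qr, w * y)))
  list(eta_reduced = eta_r, yhat = sum(Qr[i, ] * eta_r), g_row = g_row)
}

#' Local weighted least-squares fit at one regression location
#'
#' Estimates the coefficient vector at location \eqn{i} with spatial weights
#' \eqn{W = \mathrm{diag}(w)}: \eqn{\hat\eta(u_i,v_i) =
#' (Q^\top W Q)^{-1} Q^\top W y}, together with the fitted value
#' \eqn{\hat y_i = q_i^\top \hat\eta(u_i,v_i)} and the \eqn{i}-th row of the
#' GWNR hat matrix.  With all-ones weights this reproduces the global fit.
#'
#' @param y response vector.
#' @param design design matrix (see \code{\link{build_design}}).
#' @param w non-negative weight vector (diagonal of \eqn{W(u_i,v_i)}).
#' @param i regression location index.
#' @return list with \code{eta} (full column layout), \code{yhat} and
#'   \code{g_row}.
#' @export
gwnr_fit_local <- function(y, design, w, i) {
  if (length(w) != length(y) || any(!is.finite(w)) || any(w < 0))
    stop("'w' must be finite non-negative and match 'y'", call. = FALSE)
  fit <- local_wls(y, design, w, i)
  parts <- design_parts(design)
  list(eta = expand_eta(fit$eta_reduced, parts,
                        attr(design, "labels") %||% colnames(design)),
       yhat = fit$yhat, g_row = fit$g_row)
}

#' Fit the geographically weighted model at every location
#'
#' Workhorse fitter (design-matrix interface): runs the local weighted
#' least-squares estimator at each of the \eqn{n} locations, stacks the
#' hat-matrix rows into \eqn{G}, and computes residuals,
#' \eqn{SSE = y^\top (I-G)^\top (I-G) y}, the trace degrees of freedom
#' \eqn{\gamma_1 = n - 2\,\mathrm{tr}(G) + \mathrm{tr}(G^\top G)} and the
#' unbiased error-variance estimate \eqn{\hat\sigma^2 = SSE/\gamma_1}.
#'
#' @param y response vector.
#' @param design design matrix shared by all locations.
#' @param W \eqn{n \times n} matrix whose \eqn{i}-th row is the diagonal of
#'   the spatial weight matrix \eqn{W(u_i, v_i)}.
#' @return list with \code{eta_local} (\eqn{n \times m}, row \eqn{i} is
#'   \eqn{\hat\eta(u_i,v_i)^\top}), \code{G}, \code{fitted},
#'   \code{residuals}, \code{sse}, \code{gamma1} and \code{sigma2}.
#' @seealso \code{\link{gwnr}} for the formula interface.
#' @export
gwnr_fit <- function(y, design, W) {
  n <- length(y)
  if (!is.matrix(W) || nrow(W) != n || ncol(W) != n)
    stop("'W' must be an n x n matrix of weight rows", call. = FALSE)
  m <- ncol(design)
  labels <- attr(design, "labels") %||% colnames(design)
  eta_local <- matrix(NA_real_, n, m, dimnames = list(NULL, labels))
  G <- matrix(NA_real_, n, n)
  parts <- design_parts(design)
  for (i in seq_len(n)) {
    fit <- local_wls(y, design, W[i, ], i)
    eta_local[i, ] <- expand_eta(fit$eta_reduced, parts, labels)
    G[i, ] <- fit$g_row
  }
  fitted <- drop(G %*% y)
  res <- y - fitted
  sse <- sum(res^2)
  IG <- -G
  diag(IG) <- diag(IG) + 1
  gamma1 <- sum(IG^2)   # tr((I-G)'(I-G))
  if (gamma1 <= .Machine$double.eps * n)
    stop("gamma1 <= 0: the local fits saturate the data; increase the bandwidth",
         call. = FALSE)
  list(eta_local = eta_local, G = G, fitted = fitted, residuals = res,
       sse = sse, gamma1 = gamma1, sigma2 = sse / gamma1)
}

# ---- formula interface ------------------------------------------------

# Terms are marked sp(x) for spline-role and fr(z) for Fourier-role
# predictors; a bare name defaults to the spline role.
parse_roles <- function(formula, data) {
  if (length(formula) != 3L)
    stop("the model formula needs a response, e.g. y ~ sp(x1) + fr(z1)",
         call. = FALSE)
  response <- deparse(formula[[2]])
  labs <- attr(stats::terms(formula), "term.labels")
  if (!length(labs)) stop("at least one predictor is required", call. = FALSE)
  spline <- character(); fourier <- character()
  for (lab in labs) {
    m <- regmatches(lab, regexec("^(sp|fr)\\(\\s*([^)]+?)\\s*\\)$", lab))[[1]]
    if (length(m) == 3L) {
      if (m[2] == "sp") spline <- c(spline, m[3]) else fourier <- c(fourier, m[3])
    } else {
      spline <- c(spline, lab)
    }
  }
  both <- intersect(spline, fourier)
  if (length(both))
    stop(sprintf("column(s) %s given both spline and fourier roles",
                 paste(sQuote(both), collapse = ", ")), call. = FALSE)
  for (nm in c(response, spline, fourier)) {
    if (!nm %in% names(data))
      stop(sprintf("column '%s' not found in 'data'", nm), call. = FALSE)
    if (!is.numeric(data[[nm]]))
      stop(sprintf("column '%s' must be numeric", nm), call. = FALSE)
    if (anyNA(data[[nm]]))
      stop(sprintf("column '%s' contains missing values", nm), call. = FALSE)
  }
  list(response = response, spline = spline, fourier = fourier)
}

design_from_formula <- function(formula, data, degree, knots, harmonics,
                                rescale_period) {
  roles <- parse_roles(formula, data)
  sd <- if (length(roles$spline)) as.matrix(data[roles$spline]) else NULL
  fd <- if (length(roles$fourier)) as.matrix(data[roles$fourier]) else NULL
  design <- build_design(sd, fd, degree = degree, knots = knots,
                         harmonics = harmonics,
                         rescale_period = rescale_period)
  list(roles = roles, design = design, y = data[[roles$response]])
}

#' Global mixed nonparametric regression (MNR)
#'
#' Fits the location-invariant mixed model in which each spline-role
#' predictor enters through a truncated-power spline of the given degree
#' and knots, and each Fourier-role predictor through a linear term plus
#' cosine harmonics.  This is the null model of the goodness-of-fit test in
#' \code{\link{gwnr_test}}.
#'
#' Predictor roles are marked in the formula: \code{y ~ sp(x1) + fr(z1)}
#' puts \code{x1} in the spline block and \code{z1} in the Fourier block
#' (bare names default to the spline role).
#'
#' @param formula model formula with \code{sp()} / \code{fr()} role markers.
#' @param data data frame containing all referenced columns.
#' @param degree spline degree \eqn{M} (default 1).
#' @param knots either a knot count per spline predictor (placed at
#'   equispaced quantiles, see \code{\link{place_knots}}) or a list of
#'   explicit knot vectors, one per spline predictor.
#' @param harmonics number of cosine harmonics \eqn{H} per Fourier predictor
#'   (default 1).
#' @param rescale_period rescale Fourier predictors to \eqn{[0, 2\pi]}
#'   before taking cosines (default \code{FALSE}: raw units).
#' @return an object of class \code{"mnr"} with \code{print},
#'   \code{summary}, \code{coef}, \code{fitted}, \code{residuals} and
#'   \code{predict} methods.
#' @examples
#' sim <- gwnr_sim(n = 40, seed = 1)
#' fit <- mnr(y ~ sp(x1) + fr(z1), sim$data)
#' coef(fit)
#' @export
mnr <- function(formula, data, degree = 1L, knots = 1L, harmonics = 1L,
                rescale_period = FALSE) {
  fd <- design_from_formula(formula, data, degree, knots, harmonics,
                            rescale_period)
  fit <- mnr_fit(fd$y, fd$design)
  structure(c(list(call = match.call(), formula = formula, roles = fd$roles,
                   design = fd$design, y = fd$y, n = length(fd$y)),
              fit),
            class = "mnr")
}

#' Geographically weighted nonparametric regression (GWNR)
#'
#' Fits the geographically weighted extension of \code{\link{mnr}}: the full
#' coefficient vector of the mixed spline + Fourier basis is re-estimated at
#' every location by weighted least squares, with weights that decay with
#' distance from the regression location.  The returned object also carries
#' the global fit on the identical design, so \code{\link{gwnr_test}} can
#' compare the two.
#'
#' @inheritParams mnr
#' @param coords the spatial coordinates: a one-sided formula such as
#'   \code{~ u + v} referring to columns of \code{data}, a character vector
#'   of two column names, or an \eqn{n \times 2} numeric matrix/data frame.
#' @param kernel spatial kernel family, see \code{\link{kernel_weights}}.
#' @param bandwidth fixed kernel bandwidth (distance units).  If neither
#'   \code{bandwidth} nor \code{adaptive_k} is given, a bandwidth is chosen
#'   by leave-one-out cross-validation over \code{bw_grid} (or a default
#'   grid, see \code{\link{select_bandwidth}}).
#' @param adaptive_k adaptive bandwidth: at each location use the distance
#'   to its \code{adaptive_k}-th nearest neighbour as the bandwidth.
#' @param metric distance metric, see \code{\link{pairwise_distance}}.
#' @param bw_grid optional candidate grid for bandwidth selection.
#' @return an object of class \code{"gwnr"}; its component \code{global} is
#'   the \code{\link{mnr_fit}} on the same design.
#' @examples
#' sim <- gwnr_sim(n = 40, amplitude = 2, mode = "varying", seed = 1)
#' fit <- gwnr(y ~ sp(x1) + fr(z1), sim$data, coords = ~ u + v,
#'             bandwidth = 3)
#' summary(fit)
#' gwnr_test(fit)
#' @export
gwnr <- function(formula, data, coords,
                 kernel = c("gaussian", "bisquare", "tricube"),
                 bandwidth = NULL, adaptive_k = NULL,
                 metric = c("euclidean", "haversine"),
                 degree = 1L, knots = 1L, harmonics = 1L,
                 rescale_period = FALSE, bw_grid = NULL) {
  kernel <- match.arg(kernel)
  metric <- match.arg(metric)
  fd <- design_from_formula(formula, data, degree, knots, harmonics,
                            rescale_period)
  uv <- resolve_coords(coords, data, n = length(fd$y))
  D <- pairwise_distance(uv[, 1], uv[, 2], metric)
  n <- length(fd$y)

  if (!is.null(adaptive_k)) {
    bw_row <- vapply(seq_len(n), function(i)
      adaptive_bandwidth(D[i, ], adaptive_k), numeric(1))
    bw_label <- sprintf("adaptive (k = %d)", as.integer(adaptive_k))
  } else {
    if (is.null(bandwidth)) {
      grid <- if (is.null(bw_grid)) default_bw_grid(D) else bw_grid
      bandwidth <- select_bandwidth(fd$y, fd$design, D, grid, kernel)
    }
    if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
    bw_row <- rep(as.numeric(bandwidth), n)
    bw_label <- sprintf("fixed (%s)", fmt_num(as.numeric(bandwidth)))
  }
  W <- t(vapply(seq_len(n), function(i)
    kernel_weights(D[i, ], bw_row[i], kernel), numeric(n)))

  fit <- gwnr_fit(fd$y, fd$design, W)
  global <- mnr_fit(fd$y, fd$design)
  structure(c(list(call = match.call(), formula = formula, roles = fd$roles,
                   design = fd$design, y = fd$y, n = n, coords = uv, D = D,
                   kernel = kernel, bandwidth = bw_row, bw_label = bw_label,
                   W = W, global = global),
              fit),
            class = "gwnr")
}

resolve_coords <- function(coords, data, n) {
  if (inherits(coords, "formula")) {
    vars <- all.vars(coords)
    if (length(vars) != 2L)
      stop("'coords' formula must name exactly two columns, e.g. ~ u + v",
           call. = FALSE)
    coords <- vars
  }
  if (is.character(coords)) {
    if (length(coords) != 2L)
      stop("'coords' must name two columns", call. = FALSE)
    missing_cols <- setdiff(coords, names(data))
    if (length(missing_cols))
      stop(sprintf("coordinate column(s) %s not found in 'data'",
                   paste(sQuote(missing_cols), collapse = ", ")), call. = FALSE)
    coords <- as.matrix(data[coords])
  }
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L || nrow(coords) != n)
    stop("'coords' must resolve to an n x 2 numeric matrix", call. = FALSE)
  coords
}
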