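#' Truncated power function
#'
#' Evaluates the truncated power basis term \eqn{(x - t)_+^M}, i.e.
#' \eqn{(x - t)^M} for \eqn{x > t} and 0 otherwise.  This is the building
#' block of the truncated-power spline representation: a degree-\eqn{M}
#' polynomial augmented with one such term per knot yields a piecewise
#' polynomial with \eqn{M - 1} continuous derivatives at each knot.
#'
#' @param x numeric vector of evaluation points.
#' @param knot single numeric knot location \eqn{t}.
#' @param degree positive integer power \eqn{M}.
#' @return numeric vector, \code{(x - knot)^degree * (x > knot)}.
#' @examples
#' truncated_power(2, 1, 1)    # 1
#' truncated_power(0.5, 1, 3)  # 0
#' truncated_power(3, 1, 2)    # 4
#' @export
truncated_power <- function(x, knot, degree) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  if (!is.numeric(knot) || length(knot) != 1L || !is.finite(knot))
    stop("'knot' must be a single finite number", call. = FALSE)
  degree <- check_count(degree, "degree", min = 1L)
  ifelse(x > knot, (x - knot)^degree, 0)
}

#' Truncated-power spline basis block for one predictor
#'
#' Builds the \eqn{n \times (M + R)} block of basis columns for a single
#' spline-role predictor: the polynomial columns \eqn{x, x^2, \dots, x^M}
#' followed by one truncated term \eqn{(x - t_r)_+^M} per knot, in knot
#' order.  No intercept column is included; the assembled design carries a
#' single shared intercept.
#'
#' @param x numeric predictor vector.
#' @param degree polynomial degree \eqn{M \ge 1}.
#' @param knots strictly increasing numeric vector of knot locations
#'   (possibly empty, in which case the block is purely polynomial).
#'   A knot outside the closed range of \code{x} is allowed but flagged
#'   with a warning, because it yields a zero or collinear column.
#' @param name predictor name used in column labels.
#' @return numeric matrix with \code{length(x)} rows and
#'   \code{degree + length(knots)} columns, with descriptive column names.
#' @examples
#' spline_block(c(0, 1, 2), degree = 1, knots = 1)
#' @export
spline_block <- function(x, degree = 1L, knots = numeric(), name = "x") {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  degree <- check_count(degree, "degree", min = 1L)
  knots <- as.numeric(knots)
  if (length(knots)) {
    if (any(!is.finite(knots)))
      stop("knots must be finite", call. = FALSE)
    if (is.unsorted(knots, strictly = TRUE))
      stop("knots must be strictly increasing", call. = FALSE)
    out <- knots <= min(x) | knots >= max(x)
    if (any(out))
      warning(sprintf(
        "knot(s) %s for predictor '%s' lie outside the open range of the data; the corresponding truncated column is zero or collinear",
        paste(format(knots[out]), collapse = ", "), name), call. = FALSE)
  }
  poly_cols <- outer(x, seq_len(degree), `^`)
  colnames(poly_cols) <- if (degree == 1L) name else
    c(name, paste0(name, "^", 2:degree))
  if (!length(knots))
    return(poly_cols)
  trunc_cols <- vapply(knots, function(t) truncated_power(x, t, degree),
                       numeric(length(x)))
  trunc_cols <- matrix(trunc_cols, nrow = length(x))
  colnames(trunc_cols) <- sprintf("(%s-%.6g)+^%d", name, knots, degree)
  cbind(poly_cols, trunc_cols)
}

#' Fourier-series basis block for one predictor
#'
#' Builds the \eqn{n \times (1 + H)} block for a single periodic-role
#' predictor: the linear column \eqn{z} followed by the cosine harmonics
#' \eqn{\cos(z), \cos(2z), \dots, \cos(Hz)}.  Angles are in radians; the
#' predictor is used on its raw scale unless \code{rescale = TRUE}, which
#' maps its observed range onto \eqn{[0, 2\pi]} first.
#'
#' @param z numeric predictor vector (radians).
#' @param harmonics non-negative integer \eqn{H}; with \code{harmonics = 0}
#'   the block is the linear column only.
#' @param name predictor name used in column labels.
#' @param rescale logical; rescale \code{z} to \eqn{[0, 2\pi]} before taking
#'   cosines (default \code{FALSE}).
#' @return numeric matrix with \code{1 + harmonics} named columns.
#' @examples
#' fourier_block(c(0, pi), harmonics = 1)
#' @export
fourier_block <- function(z, harmonics = 1L, name = "z", rescale = FALSE) {
  if (!is.numeric(z) || any(!is.finite(z)))
    stop("'z' must be finite numeric", call. = FALSE)
  harmonics <- check_count(harmonics, "harmonics", min = 0L)
  zc <- if (rescale && diff(range(z)) > 0)
    (z - min(z)) / diff(range(z)) * 2 * pi else z
  cols <- cbind(z)
  colnames(cols) <- name
  if (harmonics > 0L) {
    cos_cols <- vapply(seq_len(harmonics), function(h) cos(h * zc),
                       numeric(length(z)))
    cos_cols <- matrix(cos_cols, nrow = length(z))
    colnames(cos_cols) <- ifelse(seq_len(harmonics) == 1L,
                                 sprintf("cos(%s)", name),
                                 sprintf("cos(%d*%s)", seq_len(harmonics), name))
    cols <- cbind(cols, cos_cols)
  }
  cols
}

#' Default knot placement at equispaced quantiles
#'
#' Places \code{n_knots} knots at the \eqn{r/(R+1)} sample quantiles of the
#' predictor, \eqn{r = 1, \dots, R}, so knots sit strictly inside the
#' observed range for continuous data.
#'
#' @param x numeric predictor vector.
#' @param n_knots number of knots \eqn{R \ge 0}.
#' @return numeric vector of knot locations (strictly increasing).
#' @export
place_knots <- function(x, n_knots = 1L) {
  n_knots <- check_count(n_knots, "n_knots", min = 0L)
  if (n_knots == 0L) return(numeric())
  k <- unname(stats::quantile(x, probs = seq_len(n_knots) / (n_knots + 1)))
  if (anyDuplicated(k))
    stop("quantile knot placement produced duplicated knots; supply explicit knots",
         call. = FALSE)
  k
}

#' Assemble the mixed spline + Fourier design matrix
#'
#' Stacks the blocks into the design matrix shared by the global (MNR) and
#' geographically weighted (GWNR) models, in the fixed column order
#' \emph{intercept, spline blocks (predictor order), half-constant, Fourier
#' blocks (predictor order)}.  The half-constant column of \eqn{1/2}
#' carries the Fourier constant \eqn{\theta_0} (the series contributes
#' \eqn{\theta_0/2}); it is structurally collinear with the intercept, an
#' aliasing the fitting functions resolve explicitly (see
#' \code{\link{mnr_fit}}).  The total width is
#' \eqn{m = 2 + P(M+R) + Q(1+H)}.
#'
#' Rank deficiency is deliberately not checked here; it is diagnosed at fit
#' time where the offending columns can be named.
#'
#' @param spline_blocks list of matrices from \code{\link{spline_block}}
#'   (possibly empty).
#' @param fourier_blocks list of matrices from \code{\link{fourier_block}}
#'   (possibly empty).
#' @return an object of class \code{"gwnr_design"}: the numeric design
#'   matrix with attributes \code{half_col} (index of the half-constant
#'   column), \code{labels} (column labels) and \code{blocks} (block
#'   bookkeeping).
#' @examples
#' sb <- spline_block(runif(10), degree = 1, knots = 0.5)
#' fb <- fourier_block(runif(10, 0, 2 * pi), harmonics = 1)
#' dim(assemble_design(list(sb), list(fb)))  # 10 x 6
#' @export
assemble_design <- function(spline_blocks = list(), fourier_blocks = list()) {
  blocks <- c(spline_blocks, fourier_blocks)
  if (!length(blocks))
    stop("at least one spline or fourier block is required", call. = FALSE)
  ns <- vapply(blocks, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all basis blocks must have the same number of rows", call. = FALSE)
  n <- ns[[1]]
  X <- cbind(`(Intercept)` = rep(1, n))
  for (b in spline_blocks) X <- cbind(X, b)
  half_col <- ncol(X) + 1L
  X <- cbind(X, `(Fourier const)/2` = rep(0.5, n))
  for (b in fourier_blocks) X <- cbind(X, b)
  if (any(!is.finite(X)))
    stop("assembled design contains non-finite entries", call. = FALSE)
  structure(X,
            half_col = half_col,
            labels = colnames(X),
            blocks = list(n_spline = length(spline_blocks),
                          n_fourier = length(fourier_blocks),
                          spline_cols = vapply(spline_blocks, ncol, integer(1)),
                          fourier_cols = vapply(fourier_blocks, ncol, integer(1))),
            class = c("gwnr_design", "matrix", "array"))
}

#' Build the mixed design matrix straight from data columns
#'
#' Convenience wrapper around \code{\link{spline_block}},
#' \code{\link{fourier_block}} and \code{\link{assemble_design}}.
#'
#' @param spline_data matrix/data frame of spline-role predictors (or
#'   \code{NULL}).
#' @param fourier_data matrix/data frame of Fourier-role predictors (or
#'   \code{NULL}).
#' @param degree spline degree \eqn{M}.
#' @param knots either a single knot count (quantile placement per
#'   predictor, see \code{\link{place_knots}}) or a list of explicit knot
#'   vectors, one per spline predictor.
#' @param harmonics cosine harmonics \eqn{H} per Fourier predictor.
#' @param rescale_period rescale Fourier predictors to \eqn{[0, 2\pi]}.
#' @return a \code{"gwnr_design"} (see \code{\link{assemble_design}}) with
#'   the resolved hyperparameters in attribute \code{"spec"}.
#' @export
build_design <- function(spline_data, fourier_data, degree = 1L,
                         knots = 1L, harmonics = 1L, rescale_period = FALSE) {
  spline_data <- as_named_matrix(spline_data)
  fourier_data <- as_named_matrix(fourier_data)
  P <- ncol(spline_data)
  knot_list <- vector("list", P)
  if (is.list(knots)) {
    if (length(knots) != P)
      stop("'knots' list must have one element per spline predictor",
           call. = FALSE)
    knot_list <- lapply(knots, as.numeric)
  } else {
    for (p in seq_len(P))
      knot_list[[p]] <- place_knots(spline_data[, p], knots)
  }
  sb <- lapply(seq_len(P), function(p)
    spline_block(spline_data[, p], degree, knot_list[[p]],
                 name = colnames(spline_data)[p]))
  fb <- lapply(seq_len(ncol(fourier_data)), function(q)
    fourier_block(fourier_data[, q], harmonics,
                  name = colnames(fourier_data)[q],
                  rescale = rescale_period))
  Q <- assemble_design(sb, fb)
  attr(Q, "spec") <- list(degree = degree, knots = knot_list,
                          harmonics = harmonics,
                          rescale_period = rescale_period,
                          spline_names = colnames(spline_data),
                          fourier_names = colnames(fourier_data))
  Q
}

as_named_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(), nrow = 0L, ncol = 0L))
  x <- as.matrix(x)
  if (ncol(x) && is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}
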