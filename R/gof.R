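#' Trace degrees of freedom of the GWNR error quadratic form
#'
#' Computes \eqn{\gamma_i = \mathrm{tr}\big(((I-G)^\top(I-G))^i\big)} for
#' \eqn{i = 1, 2} from the GWNR hat matrix \eqn{G}, working with the
#' symmetric product \eqn{A = (I-G)^\top(I-G)} directly.  \eqn{\gamma_1}
#' is the mean of \eqn{SSE/\sigma^2} and \eqn{2\gamma_2} its variance, the
#' two moments matched by the Satterthwaite approximation.
#'
#' @param G square numeric hat matrix.
#' @return named numeric vector \code{c(gamma1, gamma2)}.
#' @export
gamma_traces <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G) || any(!is.finite(G)))
    stop("'G' must be a finite square matrix", call. = FALSE)
  IG <- -G
  diag(IG) <- diag(IG) + 1
  A <- crossprod(IG)
  c(gamma1 = sum(diag(A)), gamma2 = sum(A * A))  # tr(A), tr(A^2) (A symmetric)
}

#' Trace degrees of freedom of the improvement quadratic form
#'
#' Computes \eqn{\tau_i = \mathrm{tr}\big(((I-L) - (I-G)^\top(I-G))^i\big)}
#' for \eqn{i = 1, 2}, where \eqn{L} is the (symmetric idempotent) hat
#' matrix of the global model and \eqn{G} the GWNR hat matrix.  The matrix
#' \eqn{B = (I-L) - (I-G)^\top(I-G)} generates the numerator quadratic form
#' of the goodness-of-fit statistic; because \eqn{L} is a projection,
#' \eqn{y^\top B y = SSE_{MNR} - SSE_{GWNR}}.
#'
#' Non-positive \eqn{\tau_1} (the local fits do not improve on the global
#' fit) is returned as computed; \code{\link{gwnr_test}} raises the
#' degenerate-test error when it occurs.
#'
#' @param L global-model hat matrix; validated to be symmetric idempotent
#'   (tolerance \code{1e-8}).
#' @param G GWNR hat matrix of the same dimension.
#' @return named numeric vector \code{c(tau1, tau2)}.
#' @export
tau_traces <- function(L, G) {
  if (!is.matrix(L) || nrow(L) != ncol(L) || any(!is.finite(L)))
    stop("'L' must be a finite square matrix", call. = FALSE)
  if (!is.matrix(G) || !all(dim(G) == dim(L)) || any(!is.finite(G)))
    stop("'G' must be a finite square matrix of the same dimension as 'L'",
         call. = FALSE)
  if (max(abs(L - t(L))) > 1e-8 || max(abs(L %*% L - L)) > 1e-8)
    stop("'L' must be a symmetric idempotent projection (global hat matrix)",
         call. = FALSE)
  n <- nrow(L)
  IG <- -G
  diag(IG) <- diag(IG) + 1
  B <- -L - crossprod(IG)
  diag(B) <- diag(B) + 1          # B = (I - L) - (I-G)'(I-G)
  c(tau1 = sum(diag(B)), tau2 = sum(B * B))
}

#' Satterthwaite scaled chi-square constants
#'
#' Matches the first two moments of a non-negative quadratic form with mean
#' \eqn{\gamma_1} and variance \eqn{2\gamma_2} to a scaled chi-square
#' \eqn{c\,\chi^2_r}: solving \eqn{cr = \gamma_1}, \eqn{2c^2r = 2\gamma_2}
#' gives \eqn{c = \gamma_2/\gamma_1} and \eqn{r = \gamma_1^2/\gamma_2}.
#' For an idempotent form of rank \eqn{k} (\eqn{\gamma_1 = \gamma_2 = k})
#' this recovers the exact \eqn{\chi^2_k}.
#'
#' @param gamma1,gamma2 positive trace moments, see
#'   \code{\link{gamma_traces}}.
#' @return named numeric vector \code{c(c, r)}.
#' @export
satterthwaite <- function(gamma1, gamma2) {
  gamma1 <- check_scalar(gamma1, "gamma1", 0, Inf, open = c(TRUE, TRUE))
  gamma2 <- check_scalar(gamma2, "gamma2", 0, Inf, open = c(TRUE, TRUE))
  c(c = gamma2 / gamma1, r = gamma1^2 / gamma2)
}

#' Upper-tail F quantile with continuous degrees of freedom
#'
#' The critical value \eqn{F_{(\alpha;\, df_1,\, df_2)}} of the
#' goodness-of-fit test; degrees of freedom may be non-integer, as produced
#' by the Satterthwaite trace ratios.
#'
#' @param alpha upper-tail probability in (0, 1).
#' @param df1,df2 positive (possibly non-integer) degrees of freedom.
#' @return the quantile \eqn{q} with \eqn{P(F_{df_1, df_2} > q) = \alpha}.
#' @examples
#' f_quantile(0.05, 53.85, 37.49)  # 1.67
#' @export
f_quantile <- function(alpha, df1, df2) {
  alpha <- check_scalar(alpha, "alpha", 0, 1, open = c(TRUE, FALSE))
  if (!is.numeric(df1) || df1 <= 0 || !is.numeric(df2) || df2 <= 0)
    stop("'df1' and 'df2' must be positive", call. = FALSE)
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Monte-Carlo check of the scaled chi-square approximation to SSE
#'
#' Diagnostic for the quality of the Satterthwaite approximation: simulates
#' \eqn{SSE/\sigma^2 = \sum_i \lambda_i \zeta_i^2} (with \eqn{\lambda_i}
#' the eigenvalues of \eqn{(I-G)^\top(I-G)} and \eqn{\zeta_i} i.i.d.
#' standard normal) and returns the Kolmogorov--Smirnov distance between
#' the simulated sample and the fitted \eqn{c\,\chi^2_r} distribution.
#' This is a diagnostic, not a fitting step: for an idempotent form the
#' distance shrinks to zero, and small values indicate the approximation is
#' adequate at the given design.
#'
#' @param G GWNR hat matrix.
#' @param reps number of simulated draws (at least 1000).
#' @param seed integer seed for reproducibility.
#' @return the KS distance (scalar in [0, 1]), with the Satterthwaite
#'   constants attached as attribute \code{"satterthwaite"}.
#' @export
sse_chi2_check <- function(G, reps = 5000L, seed = 1L) {
  reps <- check_count(reps, "reps", min = 1000L)
  IG <- -G
  diag(IG) <- diag(IG) + 1
  A <- crossprod(IG)
  lambda <- pmax(eigen(A, symmetric = TRUE, only.values = TRUE)$values, 0)
  cr <- satterthwaite(sum(lambda), sum(lambda^2))
  set.seed(seed)
  Z2 <- matrix(stats::rnorm(reps * length(lambda))^2, nrow = reps)
  sims <- drop(Z2 %*% lambda)
  # one-sample KS distance against the cdf of c * chisq_r
  x <- sort(sims)
  Fx <- stats::pchisq(x / cr[["c"]], df = cr[["r"]])
  i <- seq_along(x)
  ks <- max(i / reps - Fx, Fx - (i - 1) / reps)
  structure(ks, satterthwaite = cr)
}

#' Goodness-of-fit test: do geographically varying coefficients help?
#'
#' Tests the null hypothesis that every basis coefficient is constant over
#' space (the global MNR model holds) against the alternative that at least
#' one coefficient varies with location (GWNR).  The statistic
#' \deqn{F_1^* = \frac{y^\top[(I-L) - (I-G)^\top(I-G)]y / \tau_1}
#'                    {y^\top(I-G)^\top(I-G)y / \gamma_1}}
#' is referred to an F distribution with Satterthwaite degrees of freedom
#' \eqn{df_1 = \tau_1^2/\tau_2} and \eqn{df_2 = \gamma_1^2/\gamma_2};
#' the null is rejected when \eqn{F_1^*} exceeds the upper-\eqn{\alpha}
#' quantile.  Because \eqn{L} is a projection the numerator equals
#' \eqn{(SSE_{MNR} - SSE_{GWNR})/\tau_1}; the equivalence is asserted
#' internally.
#'
#' A non-positive \eqn{\tau_1} (local fits no better than the global fit,
#' e.g. under uniform weights) raises a classed degenerate-test error
#' rather than returning a meaningless statistic.
#'
#' @param object a fitted \code{"gwnr"} model (which carries its own global
#'   fit on the identical design).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return an object of class \code{"gwnr_gof"}: a list with the SSE pair,
#'   trace set (\eqn{\gamma_1, \gamma_2, \tau_1, \tau_2}, Satterthwaite
#'   \eqn{c, r}), degrees of freedom, \code{f_stat}, \code{critical},
#'   \code{p_value} and \code{reject_h0}.
#' @examples
#' sim <- gwnr_sim(n = 40, amplitude = 2, mode = "varying", seed = 7)
#' fit <- gwnr(y ~ sp(x1) + fr(z1), sim$data, coords = ~ u + v, bandwidth = 3)
#' gwnr_test(fit, alpha = 0.05)
#' @export
gwnr_test <- function(object, alpha = 0.05) {
  if (!inherits(object, "gwnr"))
    stop("'object' must be a fitted 'gwnr' model", call. = FALSE)
  # alpha = 1 is allowed as a boundary case: the critical value is 0 and
  # every fit with a positive SSE improvement rejects
  alpha <- check_scalar(alpha, "alpha", 0, 1, open = c(TRUE, FALSE))
  y <- object$y
  L <- object$global$L
  G <- object$G
  gam <- gamma_traces(G)
  tau <- tau_traces(L, G)
  eps <- 1e-8 * nrow(G)   # numerical zero for trace quantities
  if (tau[["tau1"]] <= eps || tau[["tau2"]] <= eps^2)
    gwnr_degenerate(sprintf(
      "degenerate goodness-of-fit test: tau1 = %.3g, tau2 = %.3g (the local fits do not improve on the global fit; a smaller bandwidth may restore a testable contrast)",
      tau[["tau1"]], tau[["tau2"]]))
  sse_gwnr <- object$sse
  if (sse_gwnr <= 0)
    gwnr_degenerate("SSE of the geographically weighted fit is zero; the F ratio is undefined")
  sse_mnr <- object$global$sse

  IG <- -G
  diag(IG) <- diag(IG) + 1
  A <- crossprod(IG)
  B <- -L - A
  diag(B) <- diag(B) + 1
  num_qf <- drop(crossprod(y, B %*% y))
  den_qf <- drop(crossprod(y, A %*% y))
  # with L idempotent, y'By = SSE_MNR - SSE_GWNR and y'Ay = SSE_GWNR
  stopifnot(abs(num_qf - (sse_mnr - sse_gwnr)) <=
              1e-8 * max(1, sse_mnr, sse_gwnr),
            abs(den_qf - sse_gwnr) <= 1e-8 * max(1, sse_gwnr))

  f_stat <- (num_qf / tau[["tau1"]]) / (den_qf / gam[["gamma1"]])
  df1 <- tau[["tau1"]]^2 / tau[["tau2"]]
  df2 <- gam[["gamma1"]]^2 / gam[["gamma2"]]
  critical <- f_quantile(alpha, df1, df2)
  p_value <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  structure(list(sse_mnr = sse_mnr, sse_gwnr = sse_gwnr,
                 traces = c(gam, tau, satterthwaite(gam[["gamma1"]],
                                                    gam[["gamma2"]])),
                 df1 = df1, df2 = df2, f_stat = f_stat,
                 critical = critical, p_value = p_value, alpha = alpha,
                 reject_h0 = f_stat > critical, n = length(y)),
            class = "gwnr_gof")
}

#' @export
print.gwnr_gof <- function(x, ...) {
  cat("Goodness-of-fit test: geographically weighted vs global mixed model\n\n")
  cat(sprintf("  SSE (global MNR):  %s\n", fmt_num(x$sse_mnr)))
  cat(sprintf("  SSE (GWNR):        %s\n", fmt_num(x$sse_gwnr)))
  cat(sprintf("  F* = %.4f on df1 = %.2f, df2 = %.2f\n",
              x$f_stat, x$df1, x$df2))
  cat(sprintf("  critical value F(%g; %.2f, %.2f) = %.4f,  p-value = %.4g\n",
              x$alpha, x$df1, x$df2, x$critical, x$p_value))
  cat(if (x$reject_h0)
    "  H0 rejected: location-varying coefficients fit significantly better.\n"
    else
      "  H0 retained: no significant evidence that coefficients vary over space.\n")
  invisible(x)
}
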