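#' @export
print.mnr <- function(x, ...) {
  cat("Global mixed nonparametric regression (truncated spline + Fourier)\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d, basis columns m = %d (effective parameters %d)\n",
              x$n, ncol(x$design), x$rank))
  cat("\nCoefficients:\n")
  print(round(x$eta, 4))
  cat(sprintf("\nSSE = %s,  sigma^2 = %s\n", fmt_num(x$sse), fmt_num(x$sigma2)))
  invisible(x)
}

#' @export
summary.mnr <- function(object, ...) {
  # inference on the identified (reduced) parameterization: the intercept
  # shown is the combined constant beta0 + theta0/2
  Qr <- design_parts(object$design)$Qr
  V <- object$sigma2 * solve(crossprod(Qr))
  se <- sqrt(diag(V))
  est <- object$eta_reduced
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), df = object$df_residual, lower.tail = FALSE)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = pval)
  out <- list(call = object$call, coefficients = tab, sigma2 = object$sigma2,
              sse = object$sse, df_residual = object$df_residual,
              r_squared = 1 - object$sse / sum((object$y - mean(object$y))^2))
  class(out) <- "summary.mnr"
  out
}

#' @export
print.summary.mnr <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\nCoefficients (identified parameterization; intercept = beta0 + theta0/2):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nSSE = %s on %d residual df,  sigma^2 = %s,  R^2 = %.4f\n",
              fmt_num(x$sse), x$df_residual, fmt_num(x$sigma2), x$r_squared))
  invisible(x)
}

#' @export
coef.mnr <- function(object, ...) object$eta

#' @export
fitted.mnr <- function(object, ...) object$fitted

#' @export
residuals.mnr <- function(object, ...) object$residuals

#' Predict from a global mixed nonparametric regression
#'
#' Evaluates the fitted mean at new predictor values, rebuilding the basis
#' with the knots and harmonics of the training fit.
#'
#' @param object a fitted \code{"mnr"} model.
#' @param newdata data frame with the predictor columns of the training
#'   formula; omitted for in-sample fitted values.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mnr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  spec <- attr(object$design, "spec")
  for (nm in c(spec$spline_names, spec$fourier_names))
    if (!nm %in% names(newdata))
      stop(sprintf("column '%s' missing from 'newdata'", nm), call. = FALSE)
  sd <- if (length(spec$spline_names)) as.matrix(newdata[spec$spline_names]) else NULL
  fd <- if (length(spec$fourier_names)) as.matrix(newdata[spec$fourier_names]) else NULL
  Qnew <- build_design(sd, fd, degree = spec$degree, knots = spec$knots,
                       harmonics = spec$harmonics,
                       rescale_period = spec$rescale_period)
  unname(drop(unclass(Qnew) %*% object$eta))
}

#' @export
print.gwnr <- function(x, ...) {
  cat("Geographically weighted nonparametric regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d locations, basis columns m = %d\n", x$n, ncol(x$design)))
  cat(sprintf("kernel: %s, bandwidth: %s\n", x$kernel, x$bw_label))
  cat(sprintf("effective parameters tr(G) = %.2f (global fit: %d)\n",
              sum(diag(x$G)), x$global$rank))
  cat(sprintf("SSE = %s (global %s),  sigma^2 = %s\n",
              fmt_num(x$sse), fmt_num(x$global$sse), fmt_num(x$sigma2)))
  invisible(x)
}

#' @export
summary.gwnr <- function(object, ...) {
  qtab <- t(apply(object$eta_local, 2, stats::quantile,
                  probs = c(0, 0.25, 0.5, 0.75, 1)))
  colnames(qtab) <- c("Min", "Q1", "Median", "Q3", "Max")
  out <- list(call = object$call, n = object$n, kernel = object$kernel,
              bw_label = object$bw_label, coef_quartiles = qtab,
              global_eta = object$global$eta,
              sse = object$sse, sse_global = object$global$sse,
              sigma2 = object$sigma2, gamma1 = object$gamma1,
              tr_G = sum(diag(object$G)),
              r_squared = 1 - object$sse / sum((object$y - mean(object$y))^2))
  class(out) <- "summary.gwnr"
  out
}

#' @export
print.summary.gwnr <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat(sprintf("\n%d locations, kernel %s, bandwidth %s\n",
              x$n, x$kernel, x$bw_label))
  cat("\nLocal coefficients across locations:\n")
  print(round(x$coef_quartiles, 4))
  cat("\nGlobal coefficients:\n")
  print(round(x$global_eta, 4))
  cat(sprintf("\nSSE = %s (global %s),  sigma^2 = %s,  gamma1 = %.2f,  R^2 = %.4f\n",
              fmt_num(x$sse), fmt_num(x$sse_global), fmt_num(x$sigma2),
              x$gamma1, x$r_squared))
  invisible(x)
}

#' @export
coef.gwnr <- function(object, ...) object$eta_local

#' @export
fitted.gwnr <- function(object, ...) object$fitted

#' @export
residuals.gwnr <- function(object, ...) object$residuals

#' @export
predict.gwnr <- function(object, newdata = NULL, ...) {
  if (!is.null(newdata))
    stop("prediction at unobserved locations is not supported; refit including the new locations",
         call. = FALSE)
  object$fitted
}

#' Map a local coefficient or the residuals over the study area
#'
#' Bubble map in coordinate space: symbol area proportional to magnitude,
#' colour by sign (blue positive, red negative).
#'
#' @param x a fitted \code{"gwnr"} model.
#' @param which \code{"coefficients"} or \code{"residuals"}.
#' @param coef column (index or label) of the local coefficient matrix to
#'   map when \code{which = "coefficients"}.
#' @param ... further arguments passed to \code{\link[graphics]{plot}}.
#' @export
plot.gwnr <- function(x, which = c("coefficients", "residuals"), coef = 2L,
                      ...) {
  which <- match.arg(which)
  val <- if (which == "coefficients") x$eta_local[, coef] else x$residuals
  lab <- if (which == "coefficients") {
    if (is.character(coef)) coef else colnames(x$eta_local)[coef]
  } else "residual"
  sc <- abs(val) / max(abs(val), .Machine$double.eps)
  graphics::plot(x$coords[, 1], x$coords[, 2],
                 cex = 0.5 + 2.5 * sqrt(sc),
                 col = ifelse(val >= 0, "#2166AC", "#B2182B"),
                 pch = 16, xlab = "u", ylab = "v",
                 main = sprintf("Local %s", lab), ...)
  invisible(x)
}
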