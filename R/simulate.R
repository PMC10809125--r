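#' Seeded synthetic spatial dataset from the mixed spline + Fourier model
#'
#' Generates a dataset from the model the package fits, so every stage can
#' be exercised without external data: \eqn{n} locations with planar
#' coordinates, spline-role predictors with a piecewise-linear (or higher
#' degree) effect, Fourier-role predictors with a linear-plus-cosine
#' effect, and i.i.d. Normal(0, \eqn{\sigma^2}) errors.  Under the null
#' configuration (\code{mode = "constant"}) the basis coefficients are the
#' same everywhere; under the alternative (\code{mode = "varying"}) each
#' coefficient is modulated by a smooth linear-plus-interaction surface in
#' the (scaled) coordinates, with strength \code{amplitude}:
#' \deqn{\eta_j(u, v) = \eta_j\,[1 + a\, s_j (\tilde u + \tilde v +
#'   \tilde u \tilde v)/3],}
#' where \eqn{\tilde u, \tilde v \in [-1, 1]} and \eqn{s_j = \pm 1}
#' alternates across coefficients.
#'
#' Default conditions: coordinates uniform on \eqn{[0,10]^2} (or an evenly
#' spaced grid), one spline predictor \eqn{x_1 \sim U(0, 4)} with degree 1
#' and one knot at 2, one Fourier predictor \eqn{z_1 \sim U(0, 2\pi)} with
#' one harmonic, base coefficients
#' \eqn{(\beta_0, \beta_{11}, \beta_{12}, \theta_0, \gamma_1, \theta_{11})
#' = (1, 1.5, -2, 1, 0.5, 2)}, and \eqn{\sigma = 1}.
#'
#' @param n number of locations.
#' @param layout \code{"uniform"} (uniform-random coordinates) or
#'   \code{"grid"} (near-square lattice).
#' @param mode \code{"constant"} (null: coefficients constant over space)
#'   or \code{"varying"} (alternative).
#' @param amplitude strength \eqn{a} of the coefficient surfaces; must be 0
#'   exactly when \code{mode = "constant"}.  Defaults to 0 or 1 according
#'   to \code{mode}.
#' @param sigma error standard deviation (> 0).
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @param P,Q number of spline / Fourier predictors.
#' @param degree,n_knots,harmonics basis hyperparameters of the generating
#'   (and intended fitting) model.
#' @return an object of class \code{"gwnr_sim"}: list with \code{data} (a
#'   data frame with columns \code{y}, \code{x1..xP}, \code{z1..zQ},
#'   \code{u}, \code{v}), \code{mu} (true mean), \code{eta_true}
#'   (\eqn{n \times m} true coefficient matrix), \code{eta_base},
#'   \code{knots} (true knot list), \code{formula} (ready-to-use model
#'   formula) and \code{scenario}.
#' @examples
#' sim <- gwnr_sim(n = 50, seed = 42)
#' head(sim$data)
#' @export
gwnr_sim <- function(n = 60L, layout = c("uniform", "grid"),
                     mode = c("constant", "varying"), amplitude = NULL,
                     sigma = 1, seed = 1L, P = 1L, Q = 1L,
                     degree = 1L, n_knots = 1L, harmonics = 1L) {
  layout <- match.arg(layout)
  mode <- match.arg(mode)
  n <- check_count(n, "n", min = 4L)
  P <- check_count(P, "P", min = 0L)
  Q <- check_count(Q, "Q", min = 0L)
  if (P + Q < 1L) stop("need at least one predictor (P + Q >= 1)", call. = FALSE)
  sigma <- check_scalar(sigma, "sigma", 0, Inf, open = c(TRUE, TRUE))
  if (is.null(amplitude)) amplitude <- if (mode == "constant") 0 else 1
  if ((mode == "constant") != (amplitude == 0))
    stop("'amplitude' must be 0 exactly when mode = \"constant\"", call. = FALSE)
  seed <- check_count(seed, "seed", min = 0L)

  set.seed(seed)
  if (layout == "grid") {
    side <- ceiling(sqrt(n))
    g <- expand.grid(u = seq(0, 10, length.out = side),
                     v = seq(0, 10, length.out = side))
    u <- g$u[seq_len(n)]; v <- g$v[seq_len(n)]
  } else {
    u <- stats::runif(n, 0, 10)
    v <- stats::runif(n, 0, 10)
  }

  X <- if (P) matrix(stats::runif(n * P, 0, 4), n,
                     dimnames = list(NULL, paste0("x", seq_len(P)))) else NULL
  Z <- if (Q) matrix(stats::runif(n * Q, 0, 2 * pi), n,
                     dimnames = list(NULL, paste0("z", seq_len(Q)))) else NULL

  # knots at the middle of the generating range so the fitted design can
  # reproduce the true mean exactly when given the same knots
  knots <- if (P) rep(list(seq(0, 4, length.out = n_knots + 2)[-c(1, n_knots + 2)]),
                      P) else list()
  design <- build_design(X, Z, degree = degree, knots = knots,
                         harmonics = harmonics)
  m <- ncol(design)

  eta_base <- numeric(m)
  eta_base[1L] <- 1                                    # beta0
  j <- 1L
  for (p in seq_len(P)) {
    eta_base[j + seq_len(degree)] <- 1.5 * (-0.6)^(seq_len(degree) - 1)
    j <- j + degree
    if (n_knots)
      eta_base[j + seq_len(n_knots)] <- -2 * 0.8^(seq_len(n_knots) - 1)
    j <- j + n_knots
  }
  hc <- attr(design, "half_col")
  eta_base[hc] <- 1                                    # theta0 (enters as /2)
  j <- hc
  for (q in seq_len(Q)) {
    eta_base[j + 1L] <- 0.5                            # linear term
    if (harmonics)
      eta_base[j + 1L + seq_len(harmonics)] <- 2 / seq_len(harmonics)
    j <- j + 1L + harmonics
  }
  names(eta_base) <- attr(design, "labels")

  ut <- if (diff(range(u)) > 0) 2 * (u - min(u)) / diff(range(u)) - 1 else rep(0, n)
  vt <- if (diff(range(v)) > 0) 2 * (v - min(v)) / diff(range(v)) - 1 else rep(0, n)
  surface <- (ut + vt + ut * vt) / 3
  s_j <- rep_len(c(1, -1), m)
  eta_true <- matrix(eta_base, n, m, byrow = TRUE,
                     dimnames = list(NULL, names(eta_base)))
  if (amplitude != 0)
    eta_true <- eta_true * (1 + amplitude * outer(surface, s_j))

  mu <- rowSums(unclass(design) * eta_true)
  y <- mu + stats::rnorm(n, 0, sigma)

  dat <- data.frame(y = y)
  if (P) dat <- cbind(dat, as.data.frame(X))
  if (Q) dat <- cbind(dat, as.data.frame(Z))
  dat$u <- u; dat$v <- v

  rhs <- c(if (P) sprintf("sp(x%d)", seq_len(P)),
           if (Q) sprintf("fr(z%d)", seq_len(Q)))
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")),
                           env = globalenv())

  structure(list(data = dat, mu = mu, eta_true = eta_true,
                 eta_base = eta_base, knots = knots, formula = fml,
                 scenario = list(n = n, layout = layout, mode = mode,
                                 amplitude = amplitude, sigma = sigma,
                                 seed = seed, P = P, Q = Q, degree = degree,
                                 n_knots = n_knots, harmonics = harmonics)),
            class = "gwnr_sim")
}

#' Redraw the noise of a synthetic dataset
#'
#' Keeps the design (coordinates, predictors, true coefficient surfaces and
#' mean) of a \code{\link{gwnr_sim}} dataset fixed and draws a fresh error
#' vector, as needed for Monte-Carlo studies conditional on one design.
#'
#' @param sim a \code{"gwnr_sim"} object.
#' @param seed integer seed for the new errors.
#' @return the \code{"gwnr_sim"} object with a new response.
#' @export
sim_redraw_noise <- function(sim, seed) {
  stopifnot(inherits(sim, "gwnr_sim"))
  set.seed(check_count(seed, "seed", min = 0L))
  sim$data$y <- sim$mu + stats::rnorm(length(sim$mu), 0, sim$scenario$sigma)
  sim
}

#' Monte-Carlo rejection rate of the goodness-of-fit test
#'
#' Repeatedly generates a dataset from \code{\link{gwnr_sim}}, fits the
#' global and geographically weighted models with the generating basis
#' hyperparameters, runs \code{\link{gwnr_test}}, and reports the fraction
#' of rejections.  Under \code{mode = "constant"} this estimates the size
#' of the test; under \code{mode = "varying"} its power.  Replicates in
#' which the test is degenerate (classed degenerate-test errors) are
#' counted and reported separately, never silently dropped; the rejection
#' rate is taken over the non-degenerate replicates.  More than 20\%
#' degenerate replicates aborts with a scenario-misconfiguration error.
#'
#' Per-replicate seeds are \code{seed + rep}, so replicates are
#' order-independent and reproducible.  By default the bandwidth is set per
#' replicate to half the median pairwise distance (a fixed locality
#' heuristic that keeps the local fits genuinely local at the default
#' coordinate layout); pass \code{bandwidth} to override.
#'
#' @inheritParams gwnr_sim
#' @param reps number of replicates (at least 100 for a meaningful rate).
#' @param alpha significance level; at the boundary \code{alpha -> 1} every
#'   non-degenerate replicate rejects.
#' @param kernel,bandwidth spatial weighting for the fitted models;
#'   \code{bandwidth = NULL} uses the half-median-distance rule.
#' @param redraw \code{"all"} regenerates the whole dataset each replicate;
#'   \code{"noise"} fixes the design of the first replicate and redraws
#'   only the errors.
#' @param ... further arguments passed to \code{\link{gwnr_sim}}.
#' @return an object of class \code{"gwnr_mc"}: list with \code{rate},
#'   \code{se} (binomial standard error), \code{n_reject}, \code{n_ok},
#'   \code{n_degenerate}, \code{reps}, \code{alpha} and the per-replicate
#'   statistics (\code{f_stats}, \code{df1}, \code{df2}).
#' @export
mc_rejection_rate <- function(n = 60L, mode = c("constant", "varying"),
                              amplitude = NULL, reps = 500L, alpha = 0.05,
                              kernel = "gaussian", bandwidth = NULL,
                              seed = 1L, redraw = c("all", "noise"), ...) {
  mode <- match.arg(mode)
  redraw <- match.arg(redraw)
  reps <- check_count(reps, "reps", min = 2L)
  alpha <- check_scalar(alpha, "alpha", 0, 1, open = c(TRUE, FALSE))
  seed <- check_count(seed, "seed", min = 0L)

  base_sim <- if (redraw == "noise")
    gwnr_sim(n = n, mode = mode, amplitude = amplitude, seed = seed, ...) else NULL

  n_reject <- 0L; n_degen <- 0L
  f_stats <- df1s <- df2s <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    rs <- (seed + r) %% .Machine$integer.max
    sim <- if (redraw == "noise") sim_redraw_noise(base_sim, rs)
    else gwnr_sim(n = n, mode = mode, amplitude = amplitude, seed = rs, ...)
    res <- tryCatch({
      fit <- gwnr(sim$formula, sim$data, coords = ~ u + v, kernel = kernel,
                  bandwidth = bandwidth %||% half_median_bw(sim$data),
                  degree = sim$scenario$degree, knots = sim$knots,
                  harmonics = sim$scenario$harmonics)
      gwnr_test(fit, alpha = alpha)
    }, gwnr_degenerate_error = function(e) e)
    if (inherits(res, "gwnr_degenerate_error")) {
      n_degen <- n_degen + 1L
    } else {
      f_stats[r] <- res$f_stat; df1s[r] <- res$df1; df2s[r] <- res$df2
      if (res$reject_h0) n_reject <- n_reject + 1L
    }
  }
  if (n_degen > 0.2 * reps)
    stop(sprintf("scenario misconfiguration: %d of %d replicates were degenerate",
                 n_degen, reps), call. = FALSE)
  n_ok <- reps - n_degen
  rate <- n_reject / n_ok
  structure(list(rate = rate, se = sqrt(rate * (1 - rate) / n_ok),
                 n_reject = n_reject, n_ok = n_ok, n_degenerate = n_degen,
                 reps = reps, alpha = alpha, mode = mode,
                 f_stats = f_stats, df1 = df1s, df2 = df2s),
            class = "gwnr_mc")
}

half_median_bw <- function(data) {
  D <- as.matrix(stats::dist(cbind(data$u, data$v)))
  0.5 * stats::median(D[upper.tri(D)])
}

#' @export
print.gwnr_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo rejection rate (%s coefficients, alpha = %g)\n",
              x$mode, x$alpha))
  cat(sprintf("  rate = %.4f (SE %.4f), %d/%d rejections; %d degenerate of %d reps\n",
              x$rate, x$se, x$n_reject, x$n_ok, x$n_degenerate, x$reps))
  invisible(x)
}
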