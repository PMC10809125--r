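# shared fixtures, all generated in code

# a small fitted model on synthetic data, with the generating knots so the
# null mean lies exactly in the basis span
fixture_fit <- function(n = 30, seed = 1, amplitude = 0, bandwidth = 3,
                        kernel = "gaussian", ...) {
  mode <- if (amplitude == 0) "constant" else "varying"
  sim <- gwnr_sim(n = n, mode = mode, amplitude = amplitude, seed = seed, ...)
  fit <- suppressMessages(
    gwnr(sim$formula, sim$data, coords = ~ u + v, kernel = kernel,
         bandwidth = bandwidth, knots = sim$knots,
         degree = sim$scenario$degree, harmonics = sim$scenario$harmonics))
  list(sim = sim, fit = fit)
}

# independent eigenvalue-sum oracle for trace quantities: tr(M^i) as the
# sum of i-th powers of the (symmetric) eigenvalues
eigen_trace <- function(M, i) sum(eigen((M + t(M)) / 2,
                                        symmetric = TRUE,
                                        only.values = TRUE)$values^i)

# a random square matrix that behaves like a smoother (entries shrunk so
# I - G stays well conditioned)
random_G <- function(n, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * n, sd = 1 / n), n)
}

# a random symmetric idempotent projection of rank k
random_projection <- function(n, k, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * k), n)))
  tcrossprod(Q)
}
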