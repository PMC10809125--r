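test_that("gamma traces match the eigenvalue-sum oracle", {
  expect_equal(gamma_traces(matrix(0, 7, 7)),
               c(gamma1 = 7, gamma2 = 7))
  expect_equal(gamma_traces(diag(7)), c(gamma1 = 0, gamma2 = 0))
  expect_error(gamma_traces(matrix(1, 2, 3)), "square")

  for (n in c(6, 10, 20)) {
    G <- random_G(n, seed = n)
    A <- crossprod(diag(n) - G)
    g <- gamma_traces(G)
    expect_equal(g[["gamma1"]], eigen_trace(A, 1), tolerance = 1e-8)
    expect_equal(g[["gamma2"]], eigen_trace(A, 2), tolerance = 1e-8)
    # Cauchy-Schwarz on the eigenvalues
    expect_lte(g[["gamma2"]], g[["gamma1"]]^2 + 1e-12)
  }

  # and on a genuine GWNR hat matrix
  G <- fixture_fit(n = 18, seed = 21, bandwidth = 2)$fit$G
  A <- crossprod(diag(18) - G)
  g <- gamma_traces(G)
  expect_equal(g[["gamma1"]], eigen_trace(A, 1), tolerance = 1e-8)
  expect_equal(g[["gamma2"]], eigen_trace(A, 2), tolerance = 1e-8)
})

test_that("tau traces match the eigenvalue-sum oracle and validate L", {
  n <- 8
  L <- random_projection(n, 3, seed = 31)
  expect_equal(tau_traces(L, L), c(tau1 = 0, tau2 = 0), tolerance = 1e-10)

  # saturated global model: B = -A so tau1 = -gamma1
  G <- random_G(n, seed = 32)
  tt <- tau_traces(diag(n), G)
  expect_equal(tt[["tau1"]], -gamma_traces(G)[["gamma1"]], tolerance = 1e-10)

  B <- (diag(n) - L) - crossprod(diag(n) - G)
  tt2 <- tau_traces(L, G)
  expect_equal(tt2[["tau1"]], eigen_trace(B, 1), tolerance = 1e-8)
  expect_equal(tt2[["tau2"]], eigen_trace(B, 2), tolerance = 1e-8)

  # a non-idempotent L is rejected
  expect_error(tau_traces(0.5 * L, G), "idempotent")
})

test_that("Satterthwaite constants solve the moment-matching system", {
  expect_equal(satterthwaite(5, 5), c(c = 1, r = 5))
  expect_equal(satterthwaite(4, 2), c(c = 0.5, r = 8))
  expect_error(satterthwaite(0, 1), "gamma1")
  expect_error(satterthwaite(1, -2), "gamma2")

  for (s in 1:5) {
    G <- random_G(10, seed = 40 + s)
    g <- gamma_traces(G)
    cr <- satterthwaite(g[["gamma1"]], g[["gamma2"]])
    expect_equal(cr[["c"]] * cr[["r"]], g[["gamma1"]], tolerance = 1e-10)
    expect_equal(cr[["c"]]^2 * cr[["r"]], g[["gamma2"]], tolerance = 1e-10)
  }
})

test_that("F quantiles reproduce printed critical values and the quadrature oracle", {
  expect_lt(abs(f_quantile(0.05, 53.85, 37.49) - 1.67), 0.01)
  expect_lt(abs(f_quantile(0.05, 27.88, 11.15) - 2.56), 0.01)

  # median quantile has CDF 1/2 by numerical integration of the F density
  for (d in c(3.7, 12.4)) {
    q <- f_quantile(0.5, d, d)
    cdf <- integrate(function(x) df(x, d, d), 0, q, rel.tol = 1e-10)$value
    expect_equal(cdf, 0.5, tolerance = 1e-6)
  }
  expect_error(f_quantile(1.2, 3, 3), "alpha")
})

test_that("scaled chi-square approximation to SSE is exact for projections and close otherwise", {
  # G a projection of rank k: SSE/sigma^2 is exactly chi^2_{n-k}
  G <- random_projection(12, 4, seed = 51)
  ks <- sse_chi2_check(G, reps = 5000, seed = 1)
  cr <- attr(ks, "satterthwaite")
  expect_equal(cr[["c"]], 1, tolerance = 1e-8)
  expect_equal(cr[["r"]], 8, tolerance = 1e-8)
  expect_lt(as.numeric(ks), 0.03)

  # heterogeneous eigenvalues from a genuine GWNR hat matrix
  G2 <- fixture_fit(n = 20, seed = 52, bandwidth = 2)$fit$G
  ks2 <- sse_chi2_check(G2, reps = 5000, seed = 1)
  expect_lt(as.numeric(ks2), 0.05)

  expect_error(sse_chi2_check(G, reps = 10), "reps")
})

test_that("the F statistic equals its SSE-difference form and decisions are coherent", {
  for (s in c(1, 2, 3)) {
    fx <- fixture_fit(n = 20, seed = 60 + s, amplitude = s - 1, bandwidth = 2.5)
    res <- gwnr_test(fx$fit, alpha = 0.05)
    f_sse <- ((res$sse_mnr - res$sse_gwnr) / res$traces[["tau1"]]) /
      (res$sse_gwnr / res$traces[["gamma1"]])
    expect_equal(res$f_stat, f_sse, tolerance = 1e-10)
    expect_identical(res$reject_h0, res$f_stat > res$critical)
    expect_identical(res$reject_h0, res$p_value < res$alpha)
    expect_equal(res$df1, res$traces[["tau1"]]^2 / res$traces[["tau2"]])
    expect_equal(res$df2, res$traces[["gamma1"]]^2 / res$traces[["gamma2"]])
    expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
  }
})

test_that("alpha moves only the threshold, never the statistic", {
  fx <- fixture_fit(n = 25, seed = 70, amplitude = 1, bandwidth = 2.5)
  r05 <- gwnr_test(fx$fit, alpha = 0.05)
  r01 <- gwnr_test(fx$fit, alpha = 0.01)
  expect_equal(r05$f_stat, r01$f_stat)
  expect_equal(r05$p_value, r01$p_value)
  expect_lt(r05$critical, r01$critical)
})

test_that("uniform weights leave nothing to test: classed degenerate error", {
  fx <- fixture_fit(n = 15, seed = 71, bandwidth = Inf)
  expect_error(gwnr_test(fx$fit), class = "gwnr_degenerate_error")
})

test_that("under the null the relative SSE gap shrinks as the bandwidth grows", {
  # median over noise redraws of (SSE_MNR - SSE_GWNR)/SSE_GWNR, computed
  # from the fixed hat matrices at each bandwidth
  sim <- gwnr_sim(n = 40, mode = "constant", seed = 72)
  gaps <- vapply(c(1.5, 3, 6), function(bw) {
    fit <- suppressMessages(gwnr(sim$formula, sim$data, coords = ~ u + v,
                                 bandwidth = bw, knots = sim$knots))
    A <- crossprod(diag(40) - fit$G)
    IL <- diag(40) - fit$global$L
    set.seed(73)
    g <- replicate(60, {
      y <- sim$mu + rnorm(40)
      sse_g <- drop(crossprod(y, A %*% y))
      (drop(crossprod(y, IL %*% y)) - sse_g) / sse_g
    })
    median(g)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})
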