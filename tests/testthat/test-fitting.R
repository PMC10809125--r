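test_that("global least-squares fit matches a normal-equations oracle", {
  set.seed(11)
  Q <- cbind(1, matrix(rnorm(12 * 3), 12))
  colnames(Q) <- paste0("c", 1:4)
  y <- rnorm(12)
  fit <- mnr_fit(y, Q)
  eta_oracle <- solve(crossprod(Q), crossprod(Q, y))   # direct elimination
  expect_equal(unname(fit$eta), unname(drop(eta_oracle)), tolerance = 1e-8)
  expect_equal(fit$rank, 4L)
  expect_equal(sum(diag(fit$L)), 4, tolerance = 1e-10)

  # y in the column span -> zero SSE
  fit0 <- mnr_fit(drop(Q %*% c(1, -2, 0.5, 3)), Q)
  expect_lt(fit0$sse, 1e-18)

  # y orthogonal to every column -> zero fitted values
  yo <- residuals(lm.fit(Q, rnorm(12)))
  fito <- mnr_fit(yo, Q)
  expect_equal(fito$fitted, rep(0, 12), tolerance = 1e-10)

  # hat matrix is a symmetric projection
  expect_equal(fit$L, t(fit$L), tolerance = 1e-12)
  expect_equal(fit$L %*% fit$L, fit$L, tolerance = 1e-10)
})

test_that("rank deficiency beyond the constant aliasing is an error naming columns", {
  set.seed(12)
  Q <- cbind(a = rnorm(10), b = rnorm(10))
  Q <- cbind(Q, c = Q[, "a"] + Q[, "b"])
  expect_error(mnr_fit(rnorm(10), Q), "'c'")

  # the built-in intercept/half-constant aliasing is NOT an error
  fx <- fixture_fit(n = 20, seed = 2)
  expect_equal(fx$fit$global$rank, ncol(fx$fit$design) - 1L)
  # the aliased constant split preserves the combined constant
  eta <- fx$fit$global$eta
  hc <- attr(fx$fit$design, "half_col")
  expect_equal(eta[[1]] + 0.5 * eta[[hc]],
               fx$fit$global$eta_reduced[[1]])
})

test_that("local weighted fit matches a brute-force weighted oracle", {
  set.seed(13)
  n <- 10
  Q <- cbind(1, rnorm(n), runif(n))
  colnames(Q) <- c("i", "a", "b")
  y <- rnorm(n)
  d <- as.matrix(dist(cbind(runif(n), runif(n))))[4, ]
  w <- kernel_weights(d, 0.4, "gaussian")
  fit <- gwnr_fit_local(y, Q, w, 4L)
  W <- diag(w)
  eta_oracle <- solve(t(Q) %*% W %*% Q, t(Q) %*% W %*% y)
  g_oracle <- drop(t(Q[4, ]) %*% solve(t(Q) %*% W %*% Q, t(Q) %*% W))
  expect_equal(unname(fit$eta), unname(drop(eta_oracle)), tolerance = 1e-8)
  expect_equal(fit$g_row, unname(g_oracle), tolerance = 1e-8)
  expect_equal(fit$yhat, sum(g_oracle * y), tolerance = 1e-10)

  # all-ones weights reduce every local fit to the global one
  fx <- fixture_fit(n = 15, seed = 4)
  gfit <- fx$fit
  for (i in c(1L, 7L, 15L)) {
    loc <- gwnr_fit_local(gfit$y, gfit$design, rep(1, 15), i)
    expect_equal(loc$eta, gfit$global$eta, tolerance = 1e-8)
  }

  # constant response is reproduced exactly for any valid weights
  loc <- gwnr_fit_local(rep(4.2, 15), gfit$design,
                        kernel_weights(gfit$D[2, ], 2, "gaussian"), 2L)
  expect_equal(loc$yhat, 4.2, tolerance = 1e-10)
})

test_that("tiny compact-support bandwidths raise a local-singularity error", {
  fx <- fixture_fit(n = 25, seed = 6)
  sim <- fx$sim
  expect_error(
    suppressMessages(gwnr(sim$formula, sim$data, coords = ~ u + v,
                          kernel = "bisquare", bandwidth = 0.05,
                          knots = sim$knots)),
    "location|bandwidth|zero")
})

test_that("stacked GWNR fit agrees with looping the local fits", {
  fx <- fixture_fit(n = 15, seed = 8, amplitude = 1, bandwidth = 2)
  gfit <- fx$fit
  sse_loop <- 0
  for (i in 1:15) {
    loc <- gwnr_fit_local(gfit$y, gfit$design, gfit$W[i, ], i)
    expect_equal(gfit$G[i, ], loc$g_row, tolerance = 1e-10)
    expect_equal(gfit$eta_local[i, ], loc$eta, tolerance = 1e-10)
    sse_loop <- sse_loop + (gfit$y[i] - loc$yhat)^2
  }
  expect_equal(gfit$sse, sse_loop, tolerance = 1e-8)
  expect_equal(gfit$fitted, drop(gfit$G %*% gfit$y), tolerance = 1e-12)
  expect_equal(gfit$sse,
               drop(crossprod(gfit$y, crossprod(diag(15) - gfit$G) %*% gfit$y)),
               tolerance = 1e-8)
})

test_that("uniform weights collapse GWNR onto the global fit", {
  fx <- fixture_fit(n = 20, seed = 9, bandwidth = Inf)
  gfit <- fx$fit
  expect_lt(max(abs(gfit$G - gfit$global$L)), 1e-8)
  expect_equal(gfit$sse, gfit$global$sse, tolerance = 1e-10)
  # (I-G)'(I-G) = I - L so gamma1 = n - rank
  expect_equal(gfit$gamma1, 20 - gfit$global$rank, tolerance = 1e-8)

  # constant response -> zero SSE
  dat <- fx$sim$data; dat$y <- 2
  gfit2 <- suppressMessages(gwnr(fx$sim$formula, dat, coords = ~ u + v,
                                 bandwidth = 2, knots = fx$sim$knots))
  expect_lt(gfit2$sse, 1e-16)
})

test_that("hat-matrix rows sum to one for every kernel and bandwidth", {
  for (k in c("gaussian", "bisquare", "tricube")) {
    for (bw in c(5, 9)) {
      fx <- fixture_fit(n = 40, seed = 10, bandwidth = bw, kernel = k)
      expect_lt(max(abs(rowSums(fx$fit$G) - 1)), 1e-8)
    }
  }
  # adaptive bandwidth too
  sim <- gwnr_sim(n = 20, seed = 10)
  fit <- suppressMessages(gwnr(sim$formula, sim$data, coords = ~ u + v,
                               adaptive_k = 8, knots = sim$knots))
  expect_lt(max(abs(rowSums(fit$G) - 1)), 1e-8)
})

test_that("formula roles, coordinates and validation behave", {
  sim <- gwnr_sim(n = 20, seed = 12)
  dat <- sim$data
  expect_error(mnr(y ~ sp(x1) + fr(x1), dat), "both")
  expect_error(mnr(y ~ sp(nope), dat), "not found")
  expect_error(gwnr(y ~ sp(x1) + fr(z1), dat, coords = c("u", "missing")),
               "missing")
  dat2 <- dat; dat2$x1[3] <- NA
  expect_error(mnr(y ~ sp(x1) + fr(z1), dat2), "missing values")

  # bare names default to the spline role
  f1 <- mnr(y ~ x1 + fr(z1), dat, knots = sim$knots)
  f2 <- mnr(y ~ sp(x1) + fr(z1), dat, knots = sim$knots)
  expect_equal(coef(f1), coef(f2))

  # coords as formula, names, or matrix give the same fit
  g1 <- suppressMessages(gwnr(y ~ sp(x1) + fr(z1), dat, coords = ~ u + v,
                              bandwidth = 3, knots = sim$knots))
  g2 <- suppressMessages(gwnr(y ~ sp(x1) + fr(z1), dat,
                              coords = c("u", "v"),
                              bandwidth = 3, knots = sim$knots))
  g3 <- suppressMessages(gwnr(y ~ sp(x1) + fr(z1), dat,
                              coords = cbind(dat$u, dat$v),
                              bandwidth = 3, knots = sim$knots))
  expect_equal(g1$sse, g2$sse)
  expect_equal(g1$sse, g3$sse)
})

test_that("prediction rebuilds the training basis; new locations refused", {
  sim <- gwnr_sim(n = 25, seed = 14)
  fit <- mnr(sim$formula, sim$data, knots = sim$knots)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, sim$data[3:7, ]), fitted(fit)[3:7],
               tolerance = 1e-10)
  gfit <- fixture_fit(n = 15, seed = 14)$fit
  expect_error(predict(gfit, newdata = sim$data), "unobserved")
})
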