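test_that("sliding-window weights follow the decay law and the window clip", {
  w <- tvnet_window(delta = 2, decay = "gaussian", sigma = 1)
  expect_equal(window_weight(3, 3, w), 1)
  expect_equal(window_weight(4, 3, w), exp(-0.5))
  expect_equal(window_weight(5, 3, w), exp(-2))
  expect_equal(window_weight(6, 3, w), 0)   # beyond delta
  expect_equal(window_weight(2, 3, w), 0)   # backward: forward-only window
  offs <- window_weight(3:5, 3, w)
  expect_true(all(diff(offs) < 0))          # non-increasing with distance

  we <- tvnet_window(delta = 3, decay = "exponential", sigma = 2)
  expect_equal(window_weight(4, 3, we), exp(-0.5))
  expect_equal(window_weight(7, 3, we), 0)
})

test_that("smoothness indicators produce the hard and soft proximity matrices", {
  Mh <- smoothness_matrix(tvnet_indicator("hard", radius = 1), 4)
  expect_equal(Mh, rbind(c(0, 1, 0, 0), c(1, 0, 1, 0),
                         c(0, 1, 0, 1), c(0, 0, 1, 0)))
  Ms <- smoothness_matrix(tvnet_indicator("soft", tau = 2), 3)
  expect_equal(Ms[1, 2], exp(-1 / 2))
  expect_equal(Ms[1, 3], exp(-4 / 2))
  expect_equal(diag(Ms), rep(0, 3))
  expect_true(isSymmetric(Ms))
})

test_that("the objective matches an independent loop evaluation term by term", {
  set.seed(7)
  data <- lapply(1:3, function(i) matrix(rnorm(12), 3, 4))
  W <- lapply(1:3, function(i) matrix(rnorm(9, sd = 0.3), 3, 3))
  for (win in list(tvnet_window(delta = 0), tvnet_window(delta = 2),
                   tvnet_window(delta = 2, decay = "exponential", sigma = 0.7)))
    for (ind in list(tvnet_indicator("hard", radius = 2),
                     tvnet_indicator("soft", tau = 1.5))) {
      got <- tvnet_objective(W, data, lambda1 = 0.3, lambda2 = 0.7,
                             window = win, indicator = ind)
      want <- brute_objective(W, data, 0.3, 0.7, win, ind)
      expect_equal(got$loss, want$loss, tolerance = 1e-12)
      expect_equal(got$smoothness, want$smoothness, tolerance = 1e-12)
      expect_equal(got$sparsity, want$sparsity, tolerance = 1e-12)
      expect_equal(got$total, want$total, tolerance = 1e-12)
    }

  # all-zero series: loss is the weighted norm of the later states
  W0 <- lapply(1:3, function(i) matrix(0, 3, 3))
  got0 <- tvnet_objective(W0, data, lambda1 = 2, lambda2 = 5)
  expect_equal(got0$sparsity, 0)
  expect_equal(got0$smoothness, 0)
  expect_equal(got0$loss, brute_objective(W0, data)$loss, tolerance = 1e-12)

  # series evaluated at the generating truth, noiseless, delta = 0: zero loss
  sim <- generate_synthetic(K = 4, T = 4, density = 0.25, n_perturb = 2,
                            noise_frac = 0, n_samples = 5, seed = 2)
  ob <- tvnet_objective(sim$truth, sim$observations, 0, 0,
                        window = tvnet_window(delta = 0))
  expect_lt(abs(ob$total), 1e-10)

  # sparsity term is plain arithmetic: sum |entries| times lambda2
  W1 <- list(matrix(c(1, -0.5, 0, 2), 2), matrix(0, 2, 2))
  ob1 <- tvnet_objective(W1, list(matrix(0, 2, 3)), lambda1 = 0, lambda2 = 2)
  expect_equal(ob1$sparsity, 3.5)
  expect_equal(ob1$total, 2 * 3.5)
})

test_that("noiseless fits recover the truth and match the least-squares oracle", {
  sim <- generate_synthetic(K = 2, T = 3, density = 0.5, n_perturb = 1,
                            noise_frac = 0, n_samples = 8, seed = 21)
  fit <- tvnet(sim$observations, lambda1 = 0, lambda2 = 1e-4,
               window = tvnet_window(delta = 0))
  ols <- ols_series(sim$observations)
  for (th in seq_along(fit$W)) {
    expect_lt(sqrt(sum((fit$W[[th]] - sim$truth[[th]])^2)), 1e-2)
    expect_lt(sqrt(sum((fit$W[[th]] - ols[[th]])^2)), 1e-2)
  }
})

test_that("lambda2 above the data-derived critical value zeroes the solution", {
  sim <- generate_synthetic(K = 4, T = 4, density = 0.25, n_perturb = 2,
                            noise_frac = 0.1, n_samples = 6, seed = 5)
  for (win in list(tvnet_window(delta = 0), tvnet_window(delta = 2))) {
    lmax <- lambda_max(sim$observations, win)
    fit <- tvnet(sim$observations, lambda1 = 0.05, lambda2 = lmax * (1 + 1e-12),
                 window = win)
    expect_true(all(unlist(fit$W) == 0))
    # just below, at zero smoothness, something survives
    fit2 <- tvnet(sim$observations, lambda1 = 0, lambda2 = lmax * 0.99,
                  window = win)
    expect_gt(sum(abs(unlist(fit2$W))), 0)
  }
})

test_that("a dominant smoothness penalty equalizes the transition matrices", {
  sim <- generate_synthetic(K = 4, T = 4, density = 0.25, n_perturb = 3,
                            noise_frac = 0.1, n_samples = 10, seed = 3)
  ctrl <- tvnet_control(tol_outer = 1e-12, tol_inner = 1e-12,
                        max_cycles = 2000)
  fit <- NULL
  dists <- c()
  for (l1 in 10^(0:6)) {
    fit <- tvnet(sim$observations, l1, 0, control = ctrl,
                 init = if (is.null(fit)) NULL else fit$W)
    d <- max(vapply(1:2, function(a) max(vapply((a + 1):3, function(b)
      sqrt(sum((fit$W[[a]] - fit$W[[b]])^2)), 1)), 1))
    dists <- c(dists, d)
  }
  expect_true(all(diff(dists) <= 1e-12))
  expect_lt(dists[length(dists)], 1e-4 * sqrt(sum(unlist(fit$W)^2)))
})

test_that("the objective trace is monotone and sparsity shrinks with lambda2", {
  sim <- generate_synthetic(K = 5, T = 4, density = 0.2, n_perturb = 3,
                            noise_frac = 0.1, n_samples = 8, seed = 9)
  l1path <- vapply(c(1e-3, 1e-2, 0.1, 0.5, 1, 5), function(l2) {
    f <- tvnet(sim$observations, lambda1 = 0.01, lambda2 = l2)
    expect_true(all(diff(f$trace) <= 1e-10))
    f$objective$sparsity
  }, numeric(1))
  expect_true(all(diff(l1path) <= 1e-10))
})

test_that("block coordinate descent agrees with the exact vectorized solver", {
  ctrl <- tvnet_control(tol_outer = 1e-11, tol_inner = 1e-11)
  for (s in 1:6) {
    sim <- generate_synthetic(K = 2 + s %% 3, T = 3 + s %% 2, density = 0.3,
                              n_perturb = 2, noise_frac = 0.1,
                              n_samples = 4 + s, seed = 30 + s)
    l1 <- 10^runif(1, -3, 0); l2 <- 10^runif(1, -3, -0.5)
    fb <- tvnet(sim$observations, l1, l2, method = "bcd", control = ctrl)
    fe <- tvnet(sim$observations, l1, l2, method = "exact", control = ctrl)
    expect_lt(abs(fb$objective$total - fe$objective$total),
              1e-6 * (1 + abs(fe$objective$total)))
  }
})

test_that("the exact solver enforces its size guard and solves trivial cases", {
  big <- lapply(1:2, function(i) matrix(rnorm(50 * 4), 50, 4))
  expect_error(tvnet(big, method = "exact"), "2000")

  zero <- list(matrix(0, 3, 4))
  fz <- tvnet(zero, lambda1 = 0.1, lambda2 = 0.1, method = "exact")
  expect_true(all(unlist(fz$W) == 0))

  # lambda1 = lambda2 = 0 with delta 0: per-transition normal equations
  sim <- generate_synthetic(K = 3, T = 3, density = 0.4, n_perturb = 1,
                            noise_frac = 0.05, n_samples = 6, seed = 4)
  fe <- tvnet(sim$observations, 0, 0, window = tvnet_window(delta = 0),
              method = "exact")
  ols <- ols_series(sim$observations)
  for (th in 1:2)
    expect_equal(fe$W[[th]], ols[[th]], ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("permuting the template order permutes the fitted matrices", {
  sim <- generate_synthetic(K = 4, T = 4, density = 0.25, n_perturb = 2,
                            noise_frac = 0.1, n_samples = 8, seed = 13)
  perm <- c(3, 1, 4, 2)
  data_p <- lapply(sim$observations, function(V) V[perm, ])
  ctrl <- tvnet_control(tol_outer = 1e-11, tol_inner = 1e-11)
  f <- tvnet(sim$observations, 0.05, 0.05, control = ctrl)
  fp <- tvnet(data_p, 0.05, 0.05, control = ctrl)
  for (th in seq_along(f$W))
    expect_equal(unname(fp$W[[th]]), unname(f$W[[th]][perm, perm]),
                 tolerance = 1e-6)
})

test_that("non-convergence is reported through the flag, not an error", {
  sim <- generate_synthetic(K = 5, T = 4, density = 0.2, n_perturb = 3,
                            noise_frac = 0.1, n_samples = 8, seed = 9)
  fit <- tvnet(sim$observations, lambda1 = 10, lambda2 = 1e-3,
               control = tvnet_control(max_cycles = 2))
  expect_s3_class(fit, "tvnet")
  expect_false(fit$converged)
})
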