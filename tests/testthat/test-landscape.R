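test_that("diagonal quadratic losses give exact extreme eigenvalues and ratio", {
  # loss 0.5 * sum(a_i w_i^2): Hessian diag(a)
  grad_of <- function(a) function(w) a * w
  sp <- extreme_eigenvalues(grad_of(c(4, 1, -1)), c(0.3, -0.2, 0.5), seed = 1)
  expect_equal(sp$lambda_max, 4, tolerance = 1e-4)
  expect_equal(sp$lambda_min, -1, tolerance = 1e-4)
  expect_equal(sp$ratio, 0.25, tolerance = 1e-4)
  # pure convex quadratic: lambda_min is the smallest coefficient
  sp2 <- extreme_eigenvalues(grad_of(c(5, 2, 0.5)), rep(1, 3), seed = 2)
  expect_equal(sp2$lambda_max, 5, tolerance = 1e-4)
  expect_equal(sp2$lambda_min, 0.5, tolerance = 1e-4)
  expect_equal(sp2$ratio, 0.1, tolerance = 1e-3)
})

test_that("power iteration matches a dense eigensolver on random symmetric quadratics", {
  set.seed(21)
  for (n in c(10, 20, 50)) {
    A <- matrix(rnorm(n * n), n)
    A <- (A + t(A)) / 2
    # extremes of a Gaussian ensemble have close neighbors, so give the
    # iteration headroom; the scientific check is the 1% oracle agreement
    sp <- extreme_eigenvalues(function(w) as.vector(A %*% w), rnorm(n),
                              seed = n, max_iter = 3000)
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(sp$lambda_max - max(ev)) / abs(max(ev)), 0.01)
    expect_lt(abs(sp$lambda_min - min(ev)) / abs(min(ev)), 0.01)
  }
})

test_that("the MinMax ratio is invariant under positive loss rescaling", {
  set.seed(5)
  A <- matrix(rnorm(64), 8)
  A <- (A + t(A)) / 2
  base <- extreme_eigenvalues(function(w) as.vector(A %*% w), rnorm(8), seed = 3)
  for (c_ in c(0.1, 7)) {
    scaled <- extreme_eigenvalues(function(w) c_ * as.vector(A %*% w),
                                  rnorm(8), seed = 3)
    expect_equal(scaled$ratio, base$ratio, tolerance = 1e-3)
    expect_equal(scaled$lambda_max, c_ * base$lambda_max,
                 tolerance = 1e-3 * c_ * abs(base$lambda_max))
  }
})

test_that("power iteration converges at the theoretical geometric rate", {
  # dominant ratio |lambda2/lambda1| = 0.5: residual after k steps ~ 0.5^k
  A <- diag(c(4, 2, 1, 0.5))
  few <- plastnn:::power_iteration(function(v) as.vector(A %*% v), 4,
                                   tol = 0, max_iter = 8,
                                   v0 = c(1, 1, 1, 1))
  many <- plastnn:::power_iteration(function(v) as.vector(A %*% v), 4,
                                    tol = 0, max_iter = 30,
                                    v0 = c(1, 1, 1, 1))
  expect_equal(many$lambda, 4, tolerance = 1e-8)
  # error shrinks at least geometrically with ratio ~ (1/2)^2 per Rayleigh step
  expect_lt(abs(many$lambda - 4), abs(few$lambda - 4))
  expect_lt(abs(few$lambda - 4), 4 * 0.5^(2 * 6))
})

test_that("non-convergence is flagged rather than thrown", {
  A <- diag(c(1, 1))  # degenerate spectrum: shifted operator cannot separate
  sp <- extreme_eigenvalues(function(w) as.vector(A %*% w), c(1, 2),
                            tol = 1e-12, max_iter = 3, seed = 1)
  expect_type(sp$converged, "logical")
  expect_error(extreme_eigenvalues("not a function", 1:3), "grad_fn")
})

test_that("the loss surface is exact at the center and parabolic for quadratics", {
  net <- init_network(c(4, 6, 3), seed = 1)
  set.seed(2)
  X <- matrix(rnorm(20 * 4), 20)
  y <- sample(1:3, 20, replace = TRUE)
  g <- loss_surface(net, X, y, n_grid = 5, extent = 0.5, seed = 4)
  or <- net_loss_oracles(net, X, y)
  expect_identical(g$center_loss, or$loss(or$theta0))
  expect_identical(g$loss[3, 3], g$center_loss)
  # single linear layer with mse loss: surface is an exact paraboloid slice
  lin <- init_network(c(3, 2), seed = 5)
  Xl <- matrix(rnorm(30), 10)
  Yl <- matrix(rnorm(20), 10)
  gl <- loss_surface(lin, Xl, Yl, n_grid = 7, extent = 1, seed = 6,
                     loss = "mse")
  for (slice in list(gl$loss[, 4], gl$loss[4, ])) {
    fit <- lm(slice ~ poly(gl$alpha, 2, raw = TRUE))
    expect_lt(max(abs(residuals(fit))), 1e-10)
  }
})

test_that("ratio maps and their summaries agree with a brute-force recomputation", {
  lin <- init_network(c(3, 2), seed = 7)
  X <- matrix(rnorm(24), 8)
  Y <- matrix(rnorm(16), 8)
  g <- loss_surface(lin, X, Y, n_grid = 3, extent = 0.5, seed = 2,
                    with_spectrum = TRUE, loss = "mse")
  s <- ratio_summary(g)
  expect_identical(s$median_ratio, median(as.vector(g$ratio)))
  expect_identical(sum(s$histogram), length(s$ratios))
  stored <- vapply(g$spectra, `[[`, numeric(1), "ratio")
  expect_setequal(round(stored, 12), round(as.vector(g$ratio), 12))
  # quadratic mse loss: Hessian constant over the grid, verified densely
  or <- net_loss_oracles(lin, X, Y, loss = "mse")
  n <- length(or$theta0)
  H <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    plastnn:::hvp(or$grad, or$theta0, e)
  }, numeric(n))
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  dense_ratio <- abs(min(ev)) / abs(max(ev))
  expect_equal(median(as.vector(g$ratio)), dense_ratio, tolerance = 0.02)
  df <- landscape_as_df(g)
  expect_identical(nrow(df), 9L)
  expect_equal(df$loss[df$alpha == 0 & df$beta == 0], g$center_loss)
})
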