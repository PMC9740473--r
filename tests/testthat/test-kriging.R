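# Closed-form ordinary-kriging oracle on <= 4 points: plain solve of
# the unnormalized system, independent of the package's SVD path.
ok_oracle <- function(h_mat, h_query, vario) {
  n <- nrow(h_mat)
  G <- vario_eval(vario, h_mat)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  b <- c(ifelse(h_query < 1e-12, 0, vario_eval(vario, h_query)), 1)
  sol <- solve(A, b)
  list(w = sol[1:n], lam = sol[n + 1],
       var = sum(sol[1:n] * b[1:n]) + sol[n + 1])
}

fx_models_1d <- function(x, values, vario, range = max(x) + 0.5) {
  s <- fx_line_samples(x, values)
  suppressWarnings(fit_models(s, interaction_range = range,
                              n_regions = 1, variogram_override = vario))
}

vario_exp <- structure(list(family = "exponential", nugget = 0, psill = 3,
                            range = 1.0, region = c(0, 10)),
                       class = "mdem_variogram")

test_that("find_neighborhood matches a full sort and handles edge cases", {
  set.seed(5)
  x <- runif(200, 0, 5)
  s <- fx_line_samples(x, rnorm(200))
  q <- config(2.2, 0, 0)
  ids <- find_neighborhood(s, q, 20)
  d <- abs(x - 2.2)
  expect_equal(ids, order(d, seq_along(d))[1:20])
  expect_equal(find_neighborhood(s, q, 1000), order(d, seq_along(d)))
  expect_equal(find_neighborhood(s, config(x[7], 0, 0), 3)[1], 7L)
})

test_that("UK system: hand-checkable 2x2, symmetry, entry reconstruction", {
  s <- fx_line_samples(1.0, -5)
  tr <- fit_trend(s, "A-B", families = "constant")
  sys <- assemble_uk_system(s, 1L, tr, vario_exp, config(1.5, 0, 0))
  expect_equal(dim(sys$A), c(2, 2))
  expect_equal(sys$A, rbind(c(0, 1), c(1, 0)))
  g05 <- vario_eval(vario_exp, 0.5) / (vario_exp$nugget + vario_exp$psill)
  expect_equal(sys$b, c(g05, 1))
  sol <- solve_uk(sys)
  expect_equal(sol$weights, 1)  # single neighbor forced by constraint

  set.seed(6)
  x <- runif(12, 0.2, 4)
  s2 <- fx_line_samples(x, rnorm(12))
  s2$weight <- density_weights(s2)
  tr2 <- fit_trend(s2, "A-B")
  sys2 <- assemble_uk_system(s2, 1:12, tr2, vario_exp, config(2, 0, 0))
  expect_lt(max(abs(sys2$A - t(sys2$A))), 1e-12)
  # gamma block against direct evaluation
  Dij <- abs(outer(x, x, `-`))
  G <- vario_eval(vario_exp, Dij) / (vario_exp$nugget + vario_exp$psill)
  diag(G) <- 0
  expect_equal(sys2$A[1:12, 1:12], G, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("solve_uk equals the closed-form ordinary-kriging oracle", {
  x <- c(0.5, 1.1, 2.7)
  u <- c(-3, 1, 4)
  models <- fx_models_1d(x, u, vario_exp)
  models$trends[["A-B"]] <- structure(
    list(component = "A-B", family = "constant", theta = NA_real_,
         coef = c(mean(u), 0), r2 = 0, range = c(0, 4)),
    class = "mdem_trend")
  q <- config(1.6, 0, 0)
  r <- uk_estimate(models, q, N_pot = 3, N_var = 3)
  ids <- r$ids
  h_mat <- abs(outer(x[ids], x[ids], `-`))
  oracle <- ok_oracle(h_mat, abs(x[ids] - 1.6), vario_exp)
  expect_equal(r$weights, oracle$w, tolerance = 1e-8)
  expect_equal(sum(r$weights * u[ids]), r$components[["A-B"]],
               tolerance = 1e-10)
  # de-normalized lambda reproduces the closed-form variance
  expect_equal(r$variance[["A-B"]], oracle$var, tolerance = 1e-6)
})

test_that("exactness, unbiasedness and duplicate degeneracy", {
  set.seed(7)
  x <- runif(15, 0.2, 4.5)
  u <- sin(x) * 3
  models <- fx_models_1d(x, u, vario_exp, range = 5)
  for (i in c(1, 8, 15)) {
    r <- uk_estimate(models, config(x[i], 0, 0), N_pot = 10, N_var = 10)
    expect_lt(abs(r$components[["A-B"]] - u[i]), 1e-6)
    expect_lt(r$variance[["A-B"]], 1e-6)
    expect_lt(abs(sum(r$weights) - 1), 1e-8)
  }
  # duplicated data point: singular system still solved, constraints met
  xd <- c(x, x[1])
  models2 <- fx_models_1d(xd, c(u, u[1]), vario_exp, range = 5)
  r2 <- uk_estimate(models2, config(2.0, 0, 0), N_pot = 16, N_var = 16)
  expect_lt(abs(sum(r2$weights) - 1), 1e-6)
  expect_equal(r2$components[["A-B"]],
               uk_estimate(models, config(2, 0, 0),
                           N_pot = 15, N_var = 15)$components[["A-B"]],
               tolerance = 1e-4)
})

test_that("variance depends on geometry only; far queries hit the trend", {
  set.seed(8)
  x <- runif(12, 0.2, 3)
  u1 <- rnorm(12); u2 <- sample(u1)
  m1 <- fx_models_1d(x, u1, vario_exp, range = 8)
  m2 <- fx_models_1d(x, u2, vario_exp, range = 8)
  # force identical (constant) trends so only values differ
  trc <- structure(list(component = "A-B", family = "constant",
                        theta = NA_real_, coef = c(0, 0), r2 = 0,
                        range = c(0, 8)), class = "mdem_trend")
  m1$trends[["A-B"]] <- trc; m2$trends[["A-B"]] <- trc
  q <- config(1.7, 0, 0)
  r1 <- uk_estimate(m1, q, N_pot = 12, N_var = 12)
  r2 <- uk_estimate(m2, q, N_pot = 12, N_var = 12)
  expect_equal(r1$variance, r2$variance, tolerance = 1e-8)
  # query far beyond all correlation: estimate -> local mean, variance
  # -> sill-level plateau (gaussian model so saturation is sharp)
  # short range so all points are mutually uncorrelated: the BLUE
  # then weights every point equally and returns the local mean
  vg <- structure(list(family = "gaussian", nugget = 0, psill = 3,
                       range = 0.05, region = c(0, 10)),
                  class = "mdem_variogram")
  xg <- seq(0.3, 3.6, by = 0.3)   # mutually beyond the range
  mg <- fx_models_1d(xg, u1, vg, range = 8)
  mg$trends[["A-B"]] <- trc
  rfar <- uk_estimate(mg, config(7.5, 0, 0), N_pot = 12, N_var = 12)
  expect_equal(rfar$components[["A-B"]], mean(u1), tolerance = 1e-3)
  expect_gt(rfar$variance[["A-B"]], 0.9 * vg$psill)
  # beyond the declared interaction range: trend asymptote with warning
  expect_warning(rout <- uk_estimate(m1, config(9, 0, 0), N_pot = 5),
                 "interaction range")
  expect_equal(rout$total, 0, tolerance = 1e-9)
})
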