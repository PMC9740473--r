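fx_coeffs <- function() {
  do.call(diffusion_coefficients, hbcag_constants()$diffusion[c("Dt", "Dr")])
}

test_that("viscosity scaling: inverse proportionality and composition", {
  co <- fx_coeffs()
  s <- scale_viscosity(co, 0.1)
  expect_equal(s$Dt, co$Dt * 10)
  expect_equal(s$Dr, co$Dr * 10)
  expect_equal(s$viscosity, co$viscosity * 0.1)
  expect_equal(scale_viscosity(co, 1), co)
  two <- scale_viscosity(scale_viscosity(co, 0.5), 0.2)
  one <- scale_viscosity(co, 0.1)
  expect_equal(two$Dt, one$Dt, tolerance = 1e-12)
  expect_error(scale_viscosity(co, 0), "positive")
  expect_error(diffusion_coefficients(c(-1, 1, 1), c(1, 1, 1)), "positive")
})

test_that("zero-temperature step damps velocities toward zero", {
  st <- toy_molecule()
  state <- sim_state(st, matrix(c(5, 5, 5), 1), matrix(c(1, 0, 0, 0), 1),
                     box = rep(20, 3), temperature = 0, coeffs = fx_coeffs(),
                     vel = matrix(c(0.1, -0.2, 0.05), 1),
                     omega = matrix(c(0.3, 0, -0.1), 1))
  v0 <- sqrt(sum(state$vel^2))
  for (i in 1:20) state <- langevin_step(state, NULL, 0.1)
  expect_lt(sqrt(sum(state$vel^2)), 1e-6 * v0)
  expect_lt(sqrt(sum(state$omega^2)), 1e-6)
})

test_that("free-particle diffusion recovery within 5%", {
  set.seed(21)
  co <- fx_coeffs()
  r <- measure_free_diffusion(co, synthetic_dimer(), dt_ps = 0.1,
                              n_steps = 2e5)
  expect_equal(r$Dt, unname(co$Dt), tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(r$Dr, unname(co$Dr), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("harmonic trap equipartition (position variance = kT/k)", {
  # one axis of the integrator's exact-OU update under a linear
  # restoring force; the stationary law must be Boltzmann
  set.seed(22)
  st <- toy_molecule()
  k <- 200  # kJ/mol/nm^2 (stiff: short position relaxation time)
  co <- fx_coeffs()
  kT <- mdem:::.kB * 293
  zeta <- kT / (co$Dt * 1e-6)
  m <- sum(st$masses)
  xs <- numeric(20000)
  x <- 0; v <- 0
  oc <- mdem:::.ou_coeffs(zeta[1], m, 2, kT)
  sdv <- sqrt(oc$var_v); cv <- oc$cov_xv / sdv
  sdx <- sqrt(oc$var_x - cv^2)
  for (i in seq_along(xs)) {
    f <- -k * x
    z1 <- rnorm(1); z2 <- rnorm(1)
    x <- x + oc$cx_v * v + oc$cx_f * f + cv * z1 + sdx * z2
    v <- oc$a * v + oc$cv_f * f + sdv * z1
    xs[i] <- x
  }
  varx <- var(xs[-(1:2000)])
  # ~280 independent samples at this relaxation time: 3 sigma ~ 25%
  expect_lt(abs(varx - kT / k) / (kT / k), 0.25)
})

test_that("neighbor list matches brute force under minimum image", {
  set.seed(23)
  st <- toy_molecule()
  n <- 60
  box <- rep(15, 3)
  state <- sim_state(st, matrix(runif(3 * n, 0, 15), n, 3),
                     random_quat(n), box, 293, fx_coeffs())
  nl <- neighbor_list(state, 3, skin = 1)
  ij <- t(utils::combn(n, 2))
  d <- state$pos[ij[, 2], ] - state$pos[ij[, 1], ]
  d <- d - box[1] * round(d / box[1])
  brute <- ij[rowSums(d^2) < 16, , drop = FALSE]
  expect_equal(nl, brute)
  # pair straddling the boundary included
  st2 <- sim_state(st, rbind(c(0.5, 7, 7), c(14.5, 7, 7)),
                   random_quat(2), box, 293, fx_coeffs())
  expect_equal(nrow(neighbor_list(st2, 2, 1)), 1)
  # far-separated pair excluded
  st3 <- sim_state(st, rbind(c(1, 1, 1), c(8, 8, 8)),
                   random_quat(2), box, 293, fx_coeffs())
  expect_equal(nrow(neighbor_list(st3, 2, 1)), 0)
})

test_that("SP3 molecule count arithmetic and zero-duration runs", {
  pc <- protocol_config("SP3", concentration = 5, box = 0.2,
                        duration = 0)
  expect_equal(pc$box_nm, 200)
  st <- toy_molecule()
  set.seed(24)
  state <- mdem:::.random_state(pc, st, fx_coeffs())
  expect_equal(nrow(state$pos), 12)   # round(5e-6*NA*8e-18 L /2)
  # zero-duration run: initial frame only
  ff <- fun_field(function(cf) rep(0, nrow(cf)), r_cut = 5)
  traj <- run_protocol(pc, st, ff, fx_coeffs(), state0 = state)
  expect_length(traj$frames, 1)
  expect_equal(traj$times, 0)
})

test_that("SP1 quench on the trimer: monotone energy, wells reached", {
  set.seed(25)
  hc <- hbcag_constants()
  cap <- capsid_fixture()
  st <- cap$struct
  # trimer: a pose and two contacts from the fixture
  i0 <- cap$contacts$i[1]; j0 <- cap$contacts$j[1]
  k0 <- setdiff(c(cap$contacts$i[cap$contacts$i == i0 |
                                   cap$contacts$j == i0],
                  cap$contacts$j[cap$contacts$i == i0 |
                                   cap$contacts$j == i0]), c(i0, j0))[1]
  ids <- c(i0, j0, k0)
  pos <- cap$poses[ids, 1:3]
  quat <- cap$poses[ids, 4:7]
  ctr <- colMeans(pos)
  pos <- sweep(pos, 2, ctr) + 40
  # binding wells at the reference configurations, wide enough to pull
  binding <- hc$binding
  nb <- sum(st$backbone)
  bindf <- cbind(
    vapply(seq_len(4), function(k) mdem:::place_flat(
      st, config(binding[k, 1], binding[k, 2], binding[k, 3],
                 binding[k, 4], binding[k, 5], binding[k, 6],
                 order = cap$convention)), numeric(3 * nb)),
    vapply(seq_len(4), function(k) mdem:::place_flat(
      st, config_inverse(config(binding[k, 1], binding[k, 2],
                                binding[k, 3], binding[k, 4],
                                binding[k, 5], binding[k, 6],
                                order = cap$convention))),
      numeric(3 * nb)))
  wellfun <- function(cf) {
    vapply(seq_len(nrow(cf)), function(i) {
      v <- cf[i, ]
      f <- mdem:::place_flat(st, config(v[1], v[2], v[3], v[4], v[5],
                                        v[6]))
      dr2 <- colSums((bindf - f)^2) / nb
      -500 * sum(exp(-dr2 / (2 * 1.5^2)))
    }, numeric(1))
  }
  ff <- fun_field(wellfun, steps = c(0.05, 0.02), r_cut = 12)
  # perturb the poses slightly off the fixture
  set.seed(26)
  pos_p <- pos + matrix(rnorm(9, 0, 0.15), 3)
  quat_p <- t(vapply(1:3, function(i)
    quat_mul(mdem:::rotvec_quat(rnorm(3, 0, 0.04)), quat[i, ]),
    numeric(4)))
  state <- sim_state(st, pos_p, quat_p, box = rep(80, 3),
                     temperature = 0, coeffs = fx_coeffs())
  pc <- protocol_config("SP1", dt = 5e-12, duration = 1.5e-9,
                        save_interval = 5e-11)
  traj <- run_protocol(pc, st, ff, fx_coeffs(), state0 = state,
                       r_interaction = 12)
  # energy non-increasing (tolerance: one stencil-noise uptick per 100)
  dU <- diff(traj$potential)
  expect_lt(sum(dU > 1e-6), max(1, length(dU) / 100))
  # final relative configs within delta_r 1 nm of a binding config
  fin <- traj$frames[[length(traj$frames)]]
  for (pr in list(c(1, 2), c(1, 3))) {
    qi <- fin$quat[pr[1], ]; qj <- fin$quat[pr[2], ]
    dlab <- fin$pos[pr[2], ] - fin$pos[pr[1], ]
    trel <- as.numeric(t(quat_to_mat(qi)) %*% dlab)
    e <- quat_to_euler(quat_mul(quat_conj(qi), qj), "ZYX")
    cfg <- config(trel[1], trel[2], trel[3], e[1], e[2], e[3])
    f <- mdem:::place_flat(st, cfg)
    dr <- sqrt(min(colSums((bindf - f)^2)) / nb)
    expect_lt(dr, 1.0)
  }
})

test_that("trajectory text format round-trips", {
  set.seed(27)
  st <- toy_molecule()
  state <- sim_state(st, matrix(runif(9, 0, 10), 3), random_quat(3),
                     rep(10, 3), 293, fx_coeffs())
  ff <- fun_field(function(cf) rep(0, nrow(cf)), r_cut = 3)
  pc <- protocol_config("SP2", dt = 1e-13, duration = 2e-12,
                        save_interval = 1e-12, temperature = 293)
  traj <- run_protocol(pc, st, ff, fx_coeffs(), state0 = state)
  path <- tempfile(fileext = ".txt")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(length(back$frames), length(traj$frames))
  expect_equal(back$times, traj$times, tolerance = 1e-9)
  expect_equal(back$frames[[2]]$pos, traj$frames[[2]]$pos,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(back$box, traj$box)
})

test_that("RPY drag: isolated sphere and two-sphere closed form", {
  expect_equal(rpy_drag_ratios(matrix(0, 1, 3), 1, c(1, 0, 0)), 1.0)
  # two spheres along the motion axis: closed-form 2x2 inversion
  r <- 3; a <- 1
  ratio <- rpy_drag_ratios(rbind(c(0, 0, 0), c(r, 0, 0)), a, c(1, 0, 0))
  mu0 <- 1 / (6 * pi * a)
  mu12 <- 1 / (8 * pi * r) * (1 + 2 * a^2 / (3 * r^2) + 1 - 2 * a^2 / r^2)
  # longitudinal component: (1+2a2/3r2) + (1-2a2/r2) along rr
  f <- solve(rbind(c(mu0, mu12), c(mu12, mu0)), c(1, 1))[1]
  expect_equal(ratio, f / (6 * pi * a), tolerance = 1e-10)
  expect_error(rpy_drag_ratios(rbind(c(0, 0, 0), c(1.5, 0, 0)), 1),
               "overlap")
})

test_that("run determinism: identical seed gives identical trajectory", {
  st <- toy_molecule()
  co <- fx_coeffs()
  ff <- fun_field(function(cf) rep(0, nrow(cf)), r_cut = 3)
  pc <- protocol_config("SP3", dt = 1e-12, duration = 5e-11,
                        save_interval = 1e-11, concentration = 4981,
                        box_nm = 20, seed = 5)
  set.seed(5); t1 <- run_protocol(pc, st, ff, co)
  set.seed(5); t2 <- run_protocol(pc, st, ff, co)
  expect_identical(t1$frames, t2$frames)
})
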