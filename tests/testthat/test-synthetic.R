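test_that("sgs_field degenerate regimes", {
  xs <- seq(-2, 2, length.out = 30)
  # sill = 0: all zeros
  set.seed(1)
  expect_true(all(sgs_field(xs, xs, sill = 0, nugget = 0) == 0))
  # pure nugget: iid normals with variance = sill (KS test at 1%)
  set.seed(2)
  f <- sgs_field(xs, xs, range = 0.7, sill = 100, nugget = 100)
  ks <- stats::ks.test(as.numeric(f) / 10, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_error(sgs_field(xs, xs, sill = 1, nugget = 2), "nugget")
})

test_that("sgs_field reproduces the target spatial correlation", {
  set.seed(5)
  xs <- seq(-2, 2, length.out = 60)
  f <- sgs_field(xs, xs, range = 0.7, sill = 10000, nugget = 3000)
  # variance close to the sill
  expect_lt(abs(stats::var(as.numeric(f)) - 10000) / 10000, 0.35)
  # short-lag semivariance far below the sill (spatial continuity),
  # nugget visible as the zero-lag jump
  coords <- as.matrix(expand.grid(xs, xs))
  v <- as.numeric(f)
  set.seed(6)
  sub <- sample(length(v), 1200)
  D <- as.matrix(stats::dist(coords[sub, ]))
  pairs_near <- which(D > 0 & D < 0.12, arr.ind = TRUE)
  sv_near <- mean(0.5 * (v[sub[pairs_near[, 1]]] -
                           v[sub[pairs_near[, 2]]])^2)
  expect_lt(sv_near, 6000)
  expect_gt(sv_near, 1500)
})

test_that("2D truth field composition matches the closed form", {
  set.seed(3)
  tf <- truth_field_2d(n_grid = 50)
  # taper: 1 inside, linear midpoint 0.5, 0 outside
  expect_equal(tf$taper(c(0.2, 0.8, 1.5)), c(1, 0.5, 0))
  # far point: trend only
  expect_equal(tf$truth(2, 0), -400 * exp(-2), tolerance = 1e-9)
  expect_equal(tf$truth(1.2, 1.3), -400 * exp(-(1.2^2 + 1.3^2) / 2),
               tolerance = 1e-9)
  # at a stored grid node inside the taper: SGS value + trend
  i <- which.min(abs(tf$xs - 0.1)); j <- which.min(abs(tf$ys + 0.05))
  x <- tf$xs[i]; y <- tf$ys[j]
  dm <- sqrt(x^2 + y^2)
  expect_equal(tf$truth(x, y),
               tf$field[i, j] * tf$taper(dm) + tf$trend(dm),
               tolerance = 1e-9)
  # oracle evaluates the same surface
  expect_equal(as.numeric(tf$oracle$evaluate(cbind(x, y, 0, 0, 0, 0))),
               tf$truth(x, y))
})

test_that("toy patchy oracle: wells, decay, symmetry, noise model", {
  set.seed(4)
  or <- toy_patchy_oracle(noise_sd = 0)
  site <- matrix(c(3, 0, 0, 0, 0, 0), 1)
  v <- or$evaluate(site)
  dm <- min_distance(or$structA, or$structB, config(3, 0, 0))
  solv <- 5 * exp(-dm / 0.5)
  # at the site: well depth (other site beyond reach, repulsion zero)
  # plus the constructed roughness surface
  expect_lt(v[1, "A-B"], -20)
  expect_equal(unname(v[1, "solvent"]), solv, tolerance = 1e-9)
  # colliding configuration rejected
  expect_true(is.na(or$evaluate(matrix(c(0.05, 0, 0, 0, 0, 0), 1))[1, 1]))
  # far beyond range: ~0
  or0 <- toy_patchy_oracle(noise_sd = 0, rough_sd = 0)
  far <- matrix(c(0, 0, 6, 0, 0, 0), 1)
  expect_lt(abs(or0$evaluate(far)[1, "A-B"]), 1e-4)
  expect_equal(unname(or0$evaluate(site)[1, "A-B"]), -60, tolerance = 1e-5)
  # exact A-B symmetry under configuration inversion
  set.seed(8)
  cfg <- random_config(2.5, 4, or0$structA, or0$structB)
  inv <- config_inverse(cfg)
  expect_equal(or0$evaluate(matrix(as.numeric(cfg), 1))[1, "A-B"],
               or0$evaluate(matrix(as.numeric(inv), 1))[1, "A-B"],
               tolerance = 1e-6)
  # noise: mean of repeated evaluations near the analytic value
  or2 <- toy_patchy_oracle(noise_sd = 2, rough_sd = 0)
  set.seed(9)
  reps <- replicate(100, or2$evaluate(site)[1, "A-B"])
  expect_lt(abs(mean(reps) - (-60)), 3 * 2 / sqrt(100))
})

test_that("synthetic structures have the stated geometry", {
  st <- synthetic_dimer()
  expect_equal(gyration_radii(st), c(1.31, 1.85, 1.97), tolerance = 1e-6)
  expect_equal(sum(st$masses), 30)
  tm <- toy_molecule()
  expect_equal(nrow(tm$coords), 15)
  com <- colSums(tm$coords * tm$masses) / sum(tm$masses)
  expect_lt(max(abs(com)), 1e-9)
})

test_that("reference constants are exposed verbatim", {
  hc <- hbcag_constants()
  expect_equal(hc$binding[2, 1:3], c(x = 1.47, y = -0.91, z = -4.14))
  expect_equal(hc$binding[1, ], c(x = -2.74, y = -0.74, z = -3.10,
                                  alpha = -0.48, beta = 0.98,
                                  gamma = -0.32))
  expect_equal(hc$diffusion$Dt[["x"]], 87.69)
  expect_equal(hc$diffusion$Dr[["alpha"]], 12.05)
  expect_true(all(unlist(hc$diffusion[c("Dt", "Dr")]) > 0))
})

test_that("capsid fixture: inverse consistency and closed regular shell", {
  b <- hbcag_constants()$binding
  st <- synthetic_dimer()
  # applying transform 1 then its inverse returns to the seed
  p1 <- pose(b[1, 1:3], euler = b[1, 4:6], order = "xyz")
  back <- pose_compose(p1, pose_inverse(p1))
  expect_lt(config_distance(pose_to_config(back), config(), st), 1e-6)
  cap <- capsid_fixture()
  expect_true(cap$closed)
  expect_gte(cap$n, 20)
  deg <- tabulate(c(cap$contacts$i, cap$contacts$j), nbins = cap$n)
  expect_true(all(deg == 4))
  # connected contact graph
  parent <- seq_len(cap$n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(cap$contacts))) {
    a <- find(cap$contacts$i[r]); bb <- find(cap$contacts$j[r])
    if (a != bb) parent[a] <- bb
  }
  expect_equal(length(unique(vapply(seq_len(cap$n), find, integer(1)))), 1)
  # shell geometry: centers on a sphere
  P <- cap$poses[, 1:3]
  r <- sqrt(rowSums(sweep(P, 2, colMeans(P))^2))
  expect_lt(stats::sd(r) / mean(r), 0.05)
})
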