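fx_capsid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- capsid_fixture()
    cache
  }
})

test_that("contact classification on the capsid fixture and edge cases", {
  cap <- fx_capsid()
  frame <- list(pos = cap$poses[, 1:3], quat = cap$poses[, 4:7])
  ct <- classify_contacts(frame, cap$struct, hbcag_constants()$binding,
                          order = cap$convention)
  expect_true(all(ct$kind == "structured"))
  deg <- tabulate(c(ct$i, ct$j), nbins = cap$n)
  expect_true(all(deg == 4))
  gs <- global_stats(ct, cap$n)
  expect_equal(gs$xi_struc, 4.0)
  expect_equal(gs$xi_unstruc, 0)
  expect_equal(gs$phi_struc, 1.0)
  # two far molecules: no record
  st <- toy_molecule()
  far <- list(pos = rbind(c(0, 0, 0), c(10, 0, 0)),
              quat = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  ct2 <- classify_contacts(far, st, rbind(c(3, 0, 0, 0, 0, 0)))
  expect_equal(nrow(ct2), 0)
  # pair displaced ~0.5 nm from a binding config: structured, match 1
  near <- list(pos = rbind(c(0, 0, 0), c(3.5, 0, 0)),
               quat = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  ct3 <- classify_contacts(near, st, rbind(c(3, 0, 0, 0, 0, 0)))
  expect_equal(nrow(ct3), 1)
  expect_equal(ct3$kind, "structured")
  expect_equal(ct3$binding, 1)
  expect_equal(ct3$delta_r, 0.5, tolerance = 1e-6)
  # touching far from binding geometry: unstructured (single beads so
  # delta_m is the center distance)
  st1 <- bead_structure(matrix(0, 1, 3))
  touch <- list(pos = rbind(c(0, 0, 0), c(0, 0.25, 0)),
                quat = rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  ct4 <- classify_contacts(touch, st1, rbind(c(3, 0, 0, 0, 0, 0)))
  expect_equal(ct4$kind, "unstructured")
  # symmetric in pair order: zero contacts without inverses would
  # break this; with inverses the classification is order-independent
  gs0 <- global_stats(ct4, 2)
  expect_equal(gs0$xi_unstruc, 1.0)
  expect_true(is.na(global_stats(ct2, 2)$phi_struc))
})

test_that("find_structures: components, sizes, diameter of gyration", {
  # no contacts: singletons
  empty <- data.frame(i = integer(), j = integer(), kind = character())
  st <- find_structures(empty, 10)
  expect_equal(nrow(st), 10)
  expect_true(all(st$n_sas == 1))
  # chain a-b, b-c
  ct <- data.frame(i = c(1, 2), j = c(2, 3), kind = "structured")
  st2 <- find_structures(ct, 5)
  sizes <- sort(st2$n_sas)
  expect_equal(sizes, c(1, 1, 3))
  # sum over structures equals molecule count
  expect_equal(sum(st2$n_sas), 5)
  # random graph vs igraph components oracle
  skip_if_not_installed("igraph")
  set.seed(31)
  n <- 40
  edges <- t(replicate(30, sort(sample(n, 2))))
  ct3 <- data.frame(i = edges[, 1], j = edges[, 2], kind = "structured")
  st3 <- find_structures(ct3, n)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, n - max(edges))
  comp <- igraph::components(g)
  expect_equal(sort(st3$n_sas), sort(unname(comp$csize)))
  # min-image unwrapped diameter of gyration across the boundary
  pos <- rbind(c(0.5, 5, 5), c(9.5, 5, 5))
  ct4 <- data.frame(i = 1, j = 2, kind = "structured")
  st4 <- find_structures(ct4, 2, pos = pos, box = rep(10, 3))
  expect_equal(st4$d_gyr[st4$n_sas == 2], 1.0)  # 2 * rms(0.5) = 1
})

test_that("size classes partition the integers as stated", {
  expect_equal(size_class(c(1, 2, 5)), c(1L, 2L, 5L))
  expect_equal(size_class(c(7, 15)), c(10L, 10L))
  expect_equal(size_class(16), 20L)
  expect_equal(size_class(c(206, 500)), c(206L, 206L))
  expect_equal(size_class(205), 200L)
  # total and deterministic: classes partition 1..300
  cl <- size_class(1:300)
  expect_true(all(cl %in% c(1:5, seq(10, 200, 10), 206)))
  for (c0 in seq(10, 200, 10)) {
    expect_true(all(size_class((c0 - 4):(c0 + 5)) == c0))
  }
})

test_that("transitions: static zero, hand-computed join, normalization", {
  M <- rbind(c(1, 1, 2, 2), c(1, 1, 2, 2))
  tr0 <- transitions(M)
  expect_true(all(tr0$gross == 0))
  # one dimer joining a pair: 1->3 for it, 2->3 for the two others
  M2 <- rbind(c(1, 2, 2), c(3, 3, 3))
  tr <- transitions(M2)
  g <- tr$gross
  expect_equal(g["1", "3"], 1 / 3)
  expect_equal(g["2", "3"], 2 / 3)
  expect_equal(sum(g), 1)
  expect_equal(tr$net["1", "3"], tr$net["3", "1"])
  expect_equal(tr$signed["1", "3"], -tr$signed["3", "1"])
  # per-dimer normalization bound: row sums <= frames - 1
  set.seed(32)
  M3 <- matrix(sample(c(1, 2, 3, 10), 50, TRUE), 5, 10)
  tr3 <- transitions(M3)
  expect_lte(max(rowSums(tr3$gross)), nrow(M3) - 1)
})

test_that("lifetimes: persistence, windows, merge identity", {
  # structure persisting the whole run: censored, t_life = duration
  spf <- list(
    data.frame(structure = 1, n_sas = 3, d_gyr = NA)
  )
  spf[[1]]$members <- list(1:3)
  frames <- lapply(1:5, function(f) spf[[1]])
  lt <- lifetimes(frames, times = seq(0, 4))
  expect_equal(nrow(lt), 1)
  expect_equal(lt$t_life, 4)
  expect_true(lt$censored)
  # structure existing frames 3-7 of 10: t_life = 4 * interval
  singleton <- data.frame(structure = 1:3, n_sas = 1, d_gyr = NA)
  singleton$members <- list(1L, 2L, 3L)
  trio <- data.frame(structure = 1, n_sas = 3, d_gyr = NA)
  trio$members <- list(1:3)
  frames2 <- c(rep(list(singleton), 2), rep(list(trio), 5),
               rep(list(singleton), 3))
  lt2 <- lifetimes(frames2, times = 0:9)
  big <- lt2[lt2$max_size == 3, ]
  expect_equal(big$t_life, 4)
  expect_false(big$censored)
  # merge: the larger parent's identity continues
  ab <- data.frame(structure = 1:2, n_sas = c(3, 2), d_gyr = NA)
  ab$members <- list(1:3, 4:5)
  merged <- data.frame(structure = 1, n_sas = 5, d_gyr = NA)
  merged$members <- list(1:5)
  frames3 <- list(ab, ab, merged, merged)
  lt3 <- lifetimes(frames3, times = 0:3)
  # the size-3 parent lives to the end; the size-2 one dies at t=1
  expect_equal(sort(lt3$death), c(1, 3))
  expect_equal(lt3$death[lt3$max_size == 5], 3)
})

test_that("kinetics fit: exact recovery, degenerate, noisy", {
  t <- seq(0, 5, by = 0.1)
  truth <- 100 + (1 - 100) * exp(-t / 0.5)
  fit <- fit_kinetics(t, truth)
  expect_equal(fit$s, 100, tolerance = 1e-6)
  expect_equal(fit$r, 0.5, tolerance = 1e-6)
  # constant series: s = c, r unconstrained sentinel
  fitc <- fit_kinetics(t, rep(7, length(t)))
  expect_equal(fitc$s, 7)
  expect_true(is.na(fitc$r))
  expect_error(fit_kinetics(c(0, 1), c(1, 2)), "3 time points")
  # noisy synthetic study: parameters recovered within stated bands
  set.seed(33)
  sv <- numeric(0); rv <- numeric(0)
  for (i in 1:6) {
    y <- 100 + (1 - 100) * exp(-t / 0.5) + rnorm(length(t), 0, 2)
    f <- fit_kinetics(t, y, N0 = 1)
    sv <- c(sv, f$s); rv <- c(rv, f$r)
  }
  expect_lt(abs(mean(sv) - 100) / 100, 0.05)
  expect_lt(abs(mean(rv) - 0.5) / 0.5, 0.15)
})

test_that("stability objective: reference, dissociated, partial", {
  cap <- fx_capsid()
  frame <- list(pos = cap$poses[, 1:3], quat = cap$poses[, 4:7])
  o1 <- stability_objective(frame, cap)
  expect_equal(o1$o_stab, 1.0)
  expect_equal(o1$definition, "surrogate")
  # fully dissociated: scatter the poses far apart
  set.seed(34)
  frame2 <- list(pos = frame$pos * 10, quat = frame$quat)
  o0 <- stability_objective(frame2, cap)
  expect_equal(o0$o_stab, 0.0)
  # removing 10% of molecules removes their contacts
  keep <- seq_len(cap$n)
  drop <- sample(cap$n, 6)
  frame3 <- list(pos = frame$pos, quat = frame$quat)
  frame3$pos[drop, ] <- frame3$pos[drop, ] * 50
  o3 <- stability_objective(frame3, cap)
  lost <- sum(cap$contacts$i %in% drop | cap$contacts$j %in% drop)
  expect_equal(o3$o_stab, 1 - lost / nrow(cap$contacts), tolerance = 1e-9)
})
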