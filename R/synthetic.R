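# Synthetic fixtures and oracles standing in for the production MD
# parameterization: a 2D geostatistical benchmark field (sequential
# Gaussian simulation + distance taper + Gaussian trend), a 6D
# patchy-particle oracle with designed binding wells, a deterministic
# stand-in dimer structure, and the capsid pose fixture generated by
# closure of the four reference binding transformations.

#' Reference binding configurations and diffusion coefficients
#'
#' The four inter-dimer binding locations of the reference capsid
#' (positions in nm, angles in rad, molecule B in A's body frame) and
#' the anisotropic translational (um^2/s) and rotational (Mrad^2/s)
#' diffusion coefficients of the dimer at 293 K, 150 mM NaCl.
#'
#' @return list with \code{binding} (4 x 6 matrix) and \code{diffusion}
#'   (named list \code{Dt}, \code{Dr}, \code{temperature},
#'   \code{viscosity} in Pa s).
#' @export
hbcag_constants <- function() {
  binding <- matrix(c(
    -2.74, -0.74, -3.10, -0.48,  0.98, -0.32,
     1.47, -0.91, -4.14, -0.88, -1.05,  0.67,
    -3.01, -0.70, -3.08, -2.72, -1.05,  3.03,
    -0.65, -0.77,  4.25,  2.72,  0.92,  2.76), nrow = 4, byrow = TRUE)
  colnames(binding) <- c("x", "y", "z", "alpha", "beta", "gamma")
  list(binding = binding,
       diffusion = list(Dt = c(x = 87.69, y = 72.27, z = 71.48),
                        Dr = c(alpha = 12.05, beta = 7.46, gamma = 7.00),
                        temperature = 293, viscosity = 1.0074e-3))
}

#' Deterministic stand-in dimer structure (synthetic)
#'
#' An ellipsoidal bead shell whose per-axis gyration radii match the
#' reference dimer (1.31, 1.85, 1.97 nm about x, y, z). This is a
#' synthetic geometric stand-in, not a structural model. The default
#' total mass is deliberately small (30 amu) so that the momentum
#' relaxation time is far below the integration step and the dynamics
#' are configurationally diffusive (see the methods vignette).
#'
#' @param n_beads number of shell beads.
#' @param mass_total total mass in amu.
#' @return a canonicalized \code{mdem_structure}.
#' @export
synthetic_dimer <- function(n_beads = 20, mass_total = 30) {
  X <- .fibonacci_sphere(n_beads)
  X <- X %*% diag(c(2.90, 1.81, 1.37))
  st <- bead_structure(X, TRUE, mass_total / n_beads, name = "dimer-synthetic")
  st <- canonicalize_frame(st)$structure
  # rescale coordinates so the about-axis gyration radii match exactly
  g <- c(1.31, 1.85, 1.97)
  m <- st$masses / sum(st$masses)
  ms <- colSums(st$coords^2 * m)
  tgt <- c((g[2]^2 + g[3]^2 - g[1]^2) / 2,
           (g[1]^2 + g[3]^2 - g[2]^2) / 2,
           (g[1]^2 + g[2]^2 - g[3]^2) / 2)
  st$coords <- sweep(st$coords, 2, sqrt(tgt / ms), `*`)
  canonicalize_frame(st)$structure
}

#' Compact toy molecule for patchy-particle worlds
#'
#' A spherical bead shell of the given radius plus a center bead.
#'
#' @param n_beads shell beads.
#' @param radius shell radius in nm.
#' @param mass_total total mass in amu.
#' @return a canonicalized \code{mdem_structure}.
#' @export
toy_molecule <- function(n_beads = 14, radius = 1.2, mass_total = 30) {
  X <- rbind(.fibonacci_sphere(n_beads) * radius, c(0, 0, 0))
  st <- bead_structure(X, TRUE, mass_total / (n_beads + 1), name = "toy")
  canonicalize_frame(st)$structure
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

# ---------------------------------------------------------------------------
# Sequential Gaussian simulation and the 2D benchmark truth field

#' Sequential Gaussian simulation of a 2D random field
#'
#' Zero-mean Gaussian random field on a regular grid with spatial
#' correlation from a Gaussian variogram model
#' \code{gamma(h) = nugget + (sill - nugget) (1 - exp(-(h/range)^2))}.
#' Nodes are visited along a random path and simulated from the
#' simple-kriging conditional given previously simulated neighbors
#' (neighborhood capped); the nugget is added as independent noise.
#' Consumes the R RNG stream.
#'
#' @param xs,ys node coordinate vectors.
#' @param range variogram range.
#' @param sill total sill.
#' @param nugget nugget variance.
#' @param maxneigh neighborhood cap, default 24.
#' @param cutoff neighbor search radius, default \code{3 * range}.
#' @return matrix \code{length(xs) x length(ys)} of field values.
#' @export
sgs_field <- function(xs, ys, range = 0.7, sill = 10000, nugget = 3000,
                      maxneigh = 24, cutoff = 3 * range) {
  if (nugget < 0 || sill < nugget) stop("need 0 <= nugget <= sill")
  coords <- as.matrix(expand.grid(x = xs, y = ys))
  n <- nrow(coords)
  psill <- sill - nugget
  path <- sample.int(n)
  z <- stats::rnorm(n)
  vals <- if (psill > 0) {
    as.numeric(cpp_sgs(coords, path, psill, range, z, maxneigh, cutoff))
  } else numeric(n)
  if (nugget > 0) vals <- vals + stats::rnorm(n, 0, sqrt(nugget))
  matrix(vals, nrow = length(xs))
}

#' Binned empirical variogram of a gridded 2D field
#'
#' Subsamples grid nodes (consuming the RNG), bins the pairwise
#' semivariances over distance and returns bins suitable for
#' \code{\link{fit_variogram}}.
#'
#' @param field value matrix.
#' @param xs,ys node coordinates.
#' @param n_sub node subsample size (default 2500).
#' @param bin_width,cutoff binning parameters.
#' @return data.frame with center, gamma, sd, n.
#' @export
grid_variogram <- function(field, xs, ys, n_sub = 2500, bin_width = 0.1,
                           cutoff = 2) {
  coords <- as.matrix(expand.grid(xs, ys))
  v <- as.numeric(field)
  sub <- sample(length(v), min(n_sub, length(v)))
  n <- length(sub)
  h <- as.numeric(stats::dist(coords[sub, ]))
  ii <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  jj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  keep <- h <= cutoff
  sv <- 0.5 * (v[sub[ii[keep]]] - v[sub[jj[keep]]])^2
  bin <- floor(h[keep] / bin_width)
  out <- data.frame(
    center = (as.numeric(names(tapply(sv, bin, mean))) + 0.5) * bin_width,
    gamma = as.numeric(tapply(sv, bin, mean)),
    sd = as.numeric(tapply(sv, bin, stats::sd)),
    n = as.numeric(tapply(sv, bin, length)))
  out[order(out$center), , drop = FALSE]
}

#' The 2D benchmark truth field and its oracle
#'
#' Truth value at (x, y):
#' \code{SGS(x, y) * taper(dm) + A * exp(-dm^2 / (2 r_t^2))} with
#' \code{dm = hypot(x, y)}; the taper is 1 up to \code{taper[1]},
#' falls linearly to 0 at \code{taper[2]} and is 0 beyond, so the
#' stochastic residual lives only at short minimum distances. Defaults:
#' SGS range 0.7, nugget 3000, sill 10000; taper over [0.4, 1.2];
#' trend amplitude -400 with range 1.0. The returned oracle evaluates
#' the stored field by bilinear interpolation and adds no extra noise.
#'
#' @param n_grid nodes per axis.
#' @param domain axis limits \code{c(min, max)}.
#' @param range,sill,nugget SGS parameters.
#' @param taper taper bounds \code{c(inner, outer)} in minimum distance.
#' @param trend_amp,trend_range Gaussian trend parameters.
#' @return list with the field matrix, axes, parameters, a vectorized
#'   \code{truth(x, y)} function, and an \code{mdem_oracle}.
#' @export
truth_field_2d <- function(n_grid = 100, domain = c(-2, 2), range = 0.7,
                           sill = 10000, nugget = 3000,
                           taper = c(0.4, 1.2), trend_amp = -400,
                           trend_range = 1.0) {
  xs <- seq(domain[1], domain[2], length.out = n_grid)
  ys <- xs
  res <- sgs_field(xs, ys, range, sill, nugget)
  taper_fun <- function(dm) {
    pmax(0, pmin(1, (taper[2] - dm) / (taper[2] - taper[1])))
  }
  trend_fun <- function(dm) trend_amp * exp(-dm^2 / (2 * trend_range^2))
  interp <- function(x, y) .bilinear(res, xs, ys, x, y)
  truth <- function(x, y) {
    dm <- sqrt(x^2 + y^2)
    interp(x, y) * taper_fun(dm) + trend_fun(dm)
  }
  bead <- bead_structure(matrix(0, 1, 3), TRUE, 1, name = "atom2d")
  oracle <- make_oracle(
    evaluate = function(configs) {
      cbind(`A-B` = truth(configs[, 1], configs[, 2]))
    },
    components = "A-B",
    interaction_range = 2,
    d_coll = 0,
    structA = bead, structB = bead,
    symmetric = FALSE,
    draw = function(n) {
      cbind(stats::runif(n, domain[1], domain[2]),
            stats::runif(n, domain[1], domain[2]), 0, 0, 0, 0)
    })
  list(field = res, xs = xs, ys = ys,
       params = list(range = range, sill = sill, nugget = nugget,
                     taper = taper, trend_amp = trend_amp,
                     trend_range = trend_range, domain = domain),
       taper = taper_fun, trend = trend_fun, truth = truth,
       oracle = oracle)
}

.bilinear <- function(M, xs, ys, x, y) {
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  u <- pmin(pmax((x - xs[1]) / dx, 0), length(xs) - 1 - 1e-12)
  v <- pmin(pmax((y - ys[1]) / dy, 0), length(ys) - 1 - 1e-12)
  i <- floor(u); j <- floor(v)
  fu <- u - i; fv <- v - j
  i <- i + 1; j <- j + 1
  M[cbind(i, j)] * (1 - fu) * (1 - fv) +
    M[cbind(i + 1, j)] * fu * (1 - fv) +
    M[cbind(i, j + 1)] * (1 - fu) * fv +
    M[cbind(i + 1, j + 1)] * fu * fv
}

# ---------------------------------------------------------------------------
# Toy patchy oracle

#' Patchy-particle oracle with designed binding wells
#'
#' Desk-scale stand-in for pairwise MD sampling. The "A-B" component is
#' a sum of Gaussian wells in delta_r around the binding sites plus a
#' short-ranged soft overlap repulsion that vanishes beyond
#' \code{rep_range} in delta_m; the "solvent" component is a small
#' positive exponentially decaying trend in delta_m. Gaussian noise of
#' standard deviation \code{noise_sd} is added per evaluation (seed the
#' R RNG for determinism). Configurations with an all-bead minimum
#' distance below \code{d_coll} are rejected (NA rows).
#'
#' @param struct molecule structure (identical species A = B).
#' @param sites list of binding configurations; defaults to two
#'   opposite patches along the x axis (mutually inverse, so the
#'   oracle is exactly symmetric under A-B exchange).
#' @param depths well depths (kJ/mol, negative), recycled over sites.
#' @param well_width Gaussian well width in delta_r (nm).
#' @param repulsion overlap repulsion amplitude (kJ/mol).
#' @param rep_range repulsion reach in delta_m (nm).
#' @param solvent_amp solvent trend amplitude (kJ/mol).
#' @param noise_sd evaluation noise (kJ/mol).
#' @param rough_sd,rough_width,n_rough smooth correlated roughness of
#'   the A-B surface: \code{n_rough} Gaussian bumps of standard
#'   deviation \code{rough_sd} and delta_r width \code{rough_width}
#'   are scattered over the interaction shell at construction time
#'   (consumes the RNG), giving the component a structured variogram
#'   as molecular interaction data have.
#' @param d_coll rejection threshold (nm).
#' @param interaction_range declared delta_m interaction range (nm).
#' @return an \code{mdem_oracle}.
#' @export
toy_patchy_oracle <- function(struct = toy_molecule(),
                              sites = list(config(3, 0, 0),
                                           config(-3, 0, 0)),
                              depths = -60, well_width = 1.0,
                              repulsion = 200, rep_range = 0.5,
                              solvent_amp = 5, noise_sd = 1,
                              rough_sd = 8, rough_width = 0.8,
                              n_rough = 40,
                              d_coll = 0.4, interaction_range = 2) {
  depths <- rep_len(depths, length(sites))
  if (any(depths >= 0)) stop("well depths must be negative")
  site_flat <- vapply(sites, function(sc) place_flat(struct, sc),
                      numeric(3 * sum(struct$backbone)))
  nb <- sum(struct$backbone)
  r_ext <- max(sqrt(rowSums(struct$coords^2)))
  rough_flat <- NULL; rough_amp <- numeric(0)
  if (n_rough > 0 && rough_sd > 0) {
    rough_flat <- vapply(seq_len(n_rough), function(i)
      place_flat(struct, random_config(2 * r_ext * 0.7,
                                       2 * r_ext + interaction_range,
                                       struct, struct, d_coll = 0)),
      numeric(3 * nb))
    rough_amp <- stats::rnorm(n_rough, 0, rough_sd)
  }
  evaluate <- function(configs) {
    n <- nrow(configs)
    out <- matrix(NA_real_, n, 2,
                  dimnames = list(NULL, c("A-B", "solvent")))
    for (i in seq_len(n)) {
      v <- configs[i, ]
      cfg <- config(v[1], v[2], v[3], v[4], v[5], v[6])
      if (min_distance(struct, struct, cfg, backbone_only = FALSE) < d_coll) {
        next
      }
      dm <- min_distance(struct, struct, cfg)
      # the smooth A-B surface is evaluated as the average over the
      # configuration and its pose inverse, making the oracle exactly
      # symmetric under A-B exchange (delta_r itself is not)
      surf <- function(c1) {
        f <- place_flat(struct, c1)
        dr <- sqrt(colSums((site_flat - f)^2) / nb)
        w <- sum(depths * exp(-dr^2 / (2 * well_width^2)))
        if (!is.null(rough_flat)) {
          drr <- sqrt(colSums((rough_flat - f)^2) / nb)
          w <- w + sum(rough_amp * exp(-drr^2 / (2 * rough_width^2)))
        }
        w
      }
      wells <- (surf(cfg) + surf(config_inverse(cfg))) / 2
      rep_u <- repulsion * max(0, 1 - dm / rep_range)^2
      out[i, "A-B"] <- wells + rep_u + stats::rnorm(1, 0, noise_sd)
      out[i, "solvent"] <- solvent_amp * exp(-dm / 0.5)
    }
    out
  }
  make_oracle(
    evaluate = evaluate, components = c("A-B", "solvent"),
    interaction_range = interaction_range, d_coll = d_coll,
    structA = struct, structB = struct, symmetric = TRUE,
    draw = function(n) {
      t(vapply(seq_len(n), function(i) {
        as.numeric(random_config(2 * r_ext * 0.8,
                                 2 * r_ext + interaction_range,
                                 struct, struct, d_coll,
                                 radial_policy = "radial"))
      }, numeric(6)))
    },
    sites = sites)
}

# ---------------------------------------------------------------------------
# Capsid fixture by closure of the binding transformations

#' Generate a capsid pose fixture by closure of binding transforms
#'
#' Breadth-first propagation of the binding transformations (and their
#' inverses) from a seed pose, merging poses closer than
#' \code{dedup_tol} in delta_r. The Euler convention of the table is
#' not given, so a candidate set is tried; conventions are ranked by
#' how closely the individual transforms close their own symmetry
#' cycles (\code{T^n} back to the identity).
#'
#' The printed reference table averages quasi-equivalent contacts and
#' is rounded, so the four transforms are not exactly
#' group-consistent: direct breadth-first closure diverges. When that
#' happens the generator falls back to a documented strict-symmetry
#' projection: the transforms with tight cycles (here the 5-fold and
#' 3-fold contacts) are projected onto the nearest exact icosahedral
#' operations about a jointly fitted capsid center, and closure is run
#' with the projected generators, giving an exactly closed 60-pose
#' shell whose contacts remain within the projection residual
#' (about 0.35 nm delta_r) of the table. See the methods vignette.
#'
#' @param binding 4 x 6 matrix of binding configurations (default the
#'   built-in reference table).
#' @param struct structure used for delta_r deduplication (default the
#'   synthetic stand-in dimer).
#' @param dedup_tol pose merge tolerance in delta_r (nm), default 0.5;
#'   also the cycle-error threshold for calling a transform strict.
#' @param conventions candidate Euler conventions.
#' @param budget maximum pose count before a convention is declared
#'   non-closing.
#' @param contact_tol delta_r tolerance for the contact list (nm).
#' @return an \code{mdem_capsid}: poses (n x 7 matrix: position +
#'   quaternion), contact data.frame, chosen convention, method
#'   (\code{"direct"} or \code{"strict_projection"}), per-convention
#'   diagnostics.
#' @export
capsid_fixture <- function(binding = hbcag_constants()$binding,
                           struct = synthetic_dimer(),
                           dedup_tol = 0.5,
                           conventions = c("ZYX", "XYZ", "ZYZ",
                                           "zyx", "xyz", "zyz",
                                           "YXZ", "yxz", "XZY", "xzy"),
                           budget = 150, contact_tol = 1.0) {
  counts <- stats::setNames(integer(length(conventions)), conventions)
  cyc_err <- stats::setNames(numeric(length(conventions)), conventions)
  cycles <- list()
  direct <- NULL
  for (cv in conventions) {
    res <- .capsid_closure(binding, struct, dedup_tol, cv, budget)
    counts[cv] <- res$n
    if (res$closed && res$n > 1 && is.null(direct)) {
      direct <- list(res = res, cv = cv)
    }
    cy <- .transform_cycles(binding, struct, cv)
    cycles[[cv]] <- cy
    cyc_err[cv] <- sum(cy$err)
  }
  if (!is.null(direct)) {
    contacts <- .capsid_contacts(direct$res, binding, struct, direct$cv,
                                 contact_tol)
    return(structure(list(poses = direct$res$poses, n = direct$res$n,
                          convention = direct$cv, method = "direct",
                          closed = TRUE, contacts = contacts,
                          counts = counts, dedup_tol = dedup_tol,
                          struct = struct),
                     class = "mdem_capsid"))
  }
  # strict-symmetry projection fallback
  ranked <- names(sort(cyc_err))
  for (cv in ranked) {
    cy <- cycles[[cv]]
    strict <- which(cy$err < dedup_tol)
    ords <- cy$order[strict]
    if (!(5 %in% ords && 3 %in% ords)) next
    k5 <- strict[match(5, ords)]
    k3 <- strict[match(3, ords)]
    prj <- .ico_project(binding, struct, cv, k5, k3)
    if (is.null(prj)) next
    res <- .pose_closure(list(prj$g5, prj$g3), struct, dedup_tol, budget)
    if (!res$closed || res$n < 10) next
    contacts <- .capsid_contacts(res, binding, struct, cv, contact_tol)
    return(structure(list(poses = res$poses, n = res$n, convention = cv,
                          method = "strict_projection", closed = TRUE,
                          contacts = contacts, counts = counts,
                          projection = list(generators = c(k5, k3),
                                            residual = prj$residual,
                                            center = prj$center),
                          dedup_tol = dedup_tol, struct = struct),
                     class = "mdem_capsid"))
  }
  stop("no Euler convention closes the binding transforms into a ",
       "finite shell; per-convention pose counts: ",
       paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
}

# Smallest n in 2..6 with T^n close to the identity, per transform.
.transform_cycles <- function(binding, struct, convention) {
  idc <- config()
  ords <- integer(nrow(binding)); errs <- numeric(nrow(binding))
  for (k in seq_len(nrow(binding))) {
    pk <- pose(binding[k, 1:3], euler = binding[k, 4:6],
               order = convention)
    e <- vapply(2:6, function(n) {
      p <- pose()
      for (i in seq_len(n)) p <- pose_compose(p, pk)
      config_distance(pose_to_config(p), idc, struct)
    }, numeric(1))
    ords[k] <- which.min(e) + 1L
    errs[k] <- min(e)
  }
  list(order = ords, err = errs)
}

# Fit exact icosahedral 5-fold / 3-fold operations (common center,
# axes at the exact icosahedral angle) minimizing the worst delta_r
# distance to the two strict transforms. Deterministic multi-start
# Nelder-Mead over center, 5-fold axis direction and 3-fold azimuth,
# with both rotation-sense branches.
.ico_project <- function(binding, struct, convention, k5, k3) {
  nb <- sum(struct$backbone)
  pf <- function(p) as.numeric(place_beads(struct, p, struct$backbone))
  T5 <- pose(binding[k5, 1:3], euler = binding[k5, 4:6],
             order = convention)
  T3 <- pose(binding[k3, 1:3], euler = binding[k3, 4:6],
             order = convention)
  f5 <- pf(T5); f3 <- pf(T3)
  th53 <- acos(sqrt((5 + 2 * sqrt(5)) / 15))
  rotpose <- function(n, th, c0) {
    q <- c(cos(th / 2), sin(th / 2) * n)
    R <- quat_to_mat(q)
    pose(as.numeric((diag(3) - R) %*% c0), quat = q)
  }
  mk <- function(par, s5, s3) {
    c0 <- par[1:3]
    n5 <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]),
            cos(par[4]))
    a <- if (abs(n5[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- a - sum(a * n5) * n5; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n5[2] * e1[3] - n5[3] * e1[2],
            n5[3] * e1[1] - n5[1] * e1[3],
            n5[1] * e1[2] - n5[2] * e1[1])
    n3 <- cos(th53) * n5 + sin(th53) * (cos(par[6]) * e1 +
                                          sin(par[6]) * e2)
    list(g5 = rotpose(n5, s5 * 72 * pi / 180, c0),
         g3 = rotpose(n3, s3 * 120 * pi / 180, c0))
  }
  obj <- function(par, s5, s3) {
    g <- mk(par, s5, s3)
    max(sqrt(sum((pf(g$g5) - f5)^2) / nb),
        sqrt(sum((pf(g$g3) - f3)^2) / nb))
  }
  # initial center guess: fixed point of the 5-fold screw
  sc <- tryCatch({
    q <- T5$q; s <- sqrt(sum(q[2:4]^2))
    n <- q[2:4] / s
    A <- diag(3) - quat_to_mat(q)
    as.numeric(qr.solve(A + outer(n, n), T5$t - sum(T5$t * n) * n))
  }, error = function(e) c(0, -10, 0))
  starts <- as.matrix(expand.grid(
    thi = c(pi / 6, pi / 3, pi / 2, 2 * pi / 3, 5 * pi / 6),
    phi = seq(-pi, pi / 2, by = pi / 2),
    az = c(-pi / 2, 0, pi / 2, pi)))
  best <- NULL
  for (s5 in c(1, -1)) for (s3 in c(1, -1)) {
    v0 <- apply(starts, 1, function(st)
      obj(c(sc, st), s5 = s5, s3 = s3))
    top <- order(v0)[1:6]
    for (r in top) {
      o <- stats::optim(c(sc, starts[r, ]), obj, s5 = s5, s3 = s3,
                        method = "Nelder-Mead",
                        control = list(maxit = 1500, reltol = 1e-10))
      if (is.null(best) || o$value < best$value) {
        best <- o; best$s <- c(s5, s3)
      }
    }
  }
  if (is.null(best) || best$value > 1.0) return(NULL)
  g <- mk(best$par, best$s[1], best$s[2])
  list(g5 = g$g5, g3 = g$g3, residual = best$value,
       center = best$par[1:3])
}

# Generic breadth-first closure with a list of generator poses.
.pose_closure <- function(gens, struct, tol, budget) {
  tf <- c(gens, lapply(gens, pose_inverse))
  nb <- sum(struct$backbone)
  poseflat <- function(p) as.numeric(place_beads(struct, p,
                                                 struct$backbone))
  poses <- list(pose())
  flats <- matrix(poseflat(poses[[1]]), nrow = 1)
  queue <- 1L
  while (length(queue) && length(poses) <= budget) {
    i <- queue[1]; queue <- queue[-1]
    for (t in tf) {
      cand <- pose_compose(poses[[i]], t)
      f <- poseflat(cand)
      d2 <- colSums((t(flats) - f)^2) / nb
      if (min(d2) >= tol^2) {
        poses[[length(poses) + 1L]] <- cand
        flats <- rbind(flats, f)
        queue <- c(queue, length(poses))
      }
      if (length(poses) > budget) break
    }
  }
  closed <- length(queue) == 0 && length(poses) <= budget
  pm <- t(vapply(poses, function(p) c(p$t, p$q), numeric(7)))
  colnames(pm) <- c("x", "y", "z", "qw", "qx", "qy", "qz")
  list(poses = pm, n = nrow(pm), closed = closed, flats = flats)
}

#' @export
print.mdem_capsid <- function(x, ...) {
  cat(sprintf(
    "<mdem_capsid: %d poses (convention %s), %d contacts>\n",
    x$n, x$convention, nrow(x$contacts)))
  invisible(x)
}

.capsid_closure <- function(binding, struct, tol, convention, budget) {
  gens <- lapply(seq_len(nrow(binding)), function(k)
    pose(binding[k, 1:3], euler = binding[k, 4:6], order = convention))
  .pose_closure(gens, struct, tol, budget)
}

.capsid_contacts <- function(res, binding, struct, convention, tol) {
  n <- res$n
  nb <- sum(struct$backbone)
  bind_flat <- vapply(seq_len(nrow(binding)), function(k) {
    cfg <- config(binding[k, 1], binding[k, 2], binding[k, 3],
                  binding[k, 4], binding[k, 5], binding[k, 6],
                  order = convention)
    place_flat(struct, cfg)
  }, numeric(3 * nb))
  # include both orderings
  inv_flat <- vapply(seq_len(nrow(binding)), function(k) {
    cfg <- config(binding[k, 1], binding[k, 2], binding[k, 3],
                  binding[k, 4], binding[k, 5], binding[k, 6],
                  order = convention)
    place_flat(struct, config_inverse(cfg))
  }, numeric(3 * nb))
  bf <- cbind(bind_flat, inv_flat)
  poses <- lapply(seq_len(n), function(i)
    pose(res$poses[i, 1:3], quat = res$poses[i, 4:7]))
  out <- list()
  centers <- res$poses[, 1:3, drop = FALSE]
  reach <- max(sqrt(rowSums(binding[, 1:3, drop = FALSE]^2)), 5) + 2
  for (i in seq_len(n - 1)) {
    dc <- sqrt(colSums((t(centers[(i + 1):n, , drop = FALSE]) -
                          centers[i, ])^2))
    for (jj in which(dc < reach)) {
      j <- i + jj
      rel <- pose_compose(pose_inverse(poses[[i]]), poses[[j]])
      f <- as.numeric(place_beads(struct, rel, struct$backbone))
      dr <- sqrt(colSums((bf - f)^2) / nb)
      k <- which.min(dr)
      if (dr[k] <= tol) {
        out[[length(out) + 1L]] <-
          data.frame(i = i, j = j, binding = ((k - 1) %% nrow(binding)) + 1,
                     delta_r = dr[k])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), binding = integer(),
                      delta_r = numeric()))
  }
  do.call(rbind, out)
}
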