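# Anisotropic Langevin rigid-body dynamics with periodic boundary
# conditions, Verlet neighbor lists, the SP1-SP3 protocols and the
# Rotne-Prager-Yamakawa drag utility.
#
# Internal unit system: nm, ps, amu, kJ/mol (1 kJ/mol = 1 amu nm^2/ps^2).
# Diffusion coefficients enter in um^2/s and Mrad^2/s (both convert by
# 1e-6 to nm^2/ps and rad^2/ps). Friction per body axis follows the
# Einstein relation zeta_i = kB T_ref / D_i; the stochastic update is
# the exact Ornstein-Uhlenbeck propagator per body axis (constant
# force over a step), which recovers configurational diffusion at any
# ratio of momentum relaxation time to time step.

#' Anisotropic diffusion coefficients
#'
#' @param Dt translational coefficients along the body axes (um^2/s).
#' @param Dr rotational coefficients about the body axes (Mrad^2/s).
#' @param temperature reference temperature (K).
#' @param viscosity reference dynamic viscosity (Pa s).
#' @return an \code{mdem_diffusion} object.
#' @export
diffusion_coefficients <- function(Dt, Dr, temperature = 293,
                                   viscosity = 1.0074e-3) {
  if (any(c(Dt, Dr) <= 0)) stop("diffusion coefficients must be positive")
  structure(list(Dt = Dt, Dr = Dr, temperature = temperature,
                 viscosity = viscosity),
            class = "mdem_diffusion")
}

#' Scale the effective viscosity
#'
#' Stokes-Einstein inverse proportionality: a viscosity factor f
#' multiplies all diffusion coefficients by 1/f (e.g. the reduced
#' effective viscosity of 10% used to emulate hydrodynamic shielding
#' multiplies D by 10).
#'
#' @param coeffs an \code{mdem_diffusion}.
#' @param factor viscosity scale factor (> 0).
#' @return scaled coefficients.
#' @export
scale_viscosity <- function(coeffs, factor) {
  if (factor <= 0) stop("viscosity factor must be positive")
  coeffs$Dt <- coeffs$Dt / factor
  coeffs$Dr <- coeffs$Dr / factor
  coeffs$viscosity <- coeffs$viscosity * factor
  coeffs
}

# Principal moments of inertia (amu nm^2) of a canonicalized structure.
inertia_principal <- function(struct) {
  X <- struct$coords; m <- struct$masses
  c(sum(m * (X[, 2]^2 + X[, 3]^2)),
    sum(m * (X[, 1]^2 + X[, 3]^2)),
    sum(m * (X[, 1]^2 + X[, 2]^2)))
}

# Exact OU propagator coefficients for one axis.
# zeta in amu/ps, m in amu, dt in ps, kT in kJ/mol.
.ou_coeffs <- function(zeta, m, dt, kT) {
  tau <- m / zeta
  a <- exp(-dt / tau)
  vv <- (1 - a^2)
  xx <- tau^2 * (2 * dt / tau - 3 + 4 * a - a^2)
  xv <- tau * (1 - a)^2
  list(a = a, tau = tau, zeta = zeta,
       cx_v = tau * (1 - a),              # dx from initial velocity
       cx_f = (dt - tau * (1 - a)) / zeta,  # dx from constant force
       cv_f = (1 - a) / zeta,             # dv from constant force
       var_v = kT / m * vv, var_x = kT / m * xx, cov_xv = kT / m * xv)
}

# Draw correlated (dx, dv) noise for n molecules x 3 axes.
# oc: list of per-axis coefficient lists. Returns list(dx, dv) n x 3.
.ou_noise <- function(oc, n) {
  dx <- matrix(0, n, 3); dv <- matrix(0, n, 3)
  for (d in 1:3) {
    c1 <- oc[[d]]
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    sdv <- sqrt(max(c1$var_v, 0))
    if (sdv > 0) {
      cv <- c1$cov_xv / sdv
      sdx <- sqrt(max(c1$var_x - cv^2, 0))
      dv[, d] <- sdv * z1
      dx[, d] <- cv * z1 + sdx * z2
    }
  }
  list(dx = dx, dv = dv)
}

#' Simulation state
#'
#' @param struct molecule structure (single species).
#' @param pos n x 3 positions (nm).
#' @param quat n x 4 orientations (body to lab).
#' @param box periodic box edge lengths (nm), length 3.
#' @param temperature simulation temperature (K).
#' @param coeffs \code{\link{diffusion_coefficients}}.
#' @param viscosity_scale effective viscosity factor.
#' @param vel,omega optional initial body-frame velocities (nm/ps) and
#'   angular velocities (rad/ps); default thermal at
#'   \code{temperature} (zero at 0 K).
#' @return an \code{mdem_state}.
#' @export
sim_state <- function(struct, pos, quat, box, temperature, coeffs,
                      viscosity_scale = 1, vel = NULL, omega = NULL) {
  pos <- matrix(pos, ncol = 3)
  quat <- matrix(quat, ncol = 4)
  n <- nrow(pos)
  m <- sum(struct$masses)
  kT <- .kB * temperature
  if (is.null(vel)) {
    vel <- matrix(stats::rnorm(3 * n, 0, sqrt(kT / m)), n, 3)
  }
  inert <- inertia_principal(struct)
  if (is.null(omega)) {
    omega <- vapply(1:3, function(d)
      stats::rnorm(n, 0, sqrt(kT / inert[d])), numeric(n))
    omega <- matrix(omega, n, 3)
  }
  cs <- if (viscosity_scale != 1) scale_viscosity(coeffs, viscosity_scale)
        else coeffs
  structure(list(struct = struct, pos = pos, quat = quat,
                 vel = vel, omega = omega, box = box, time = 0,
                 temperature = temperature, coeffs = cs,
                 viscosity_scale = viscosity_scale, mass = m,
                 inertia = inert),
            class = "mdem_state")
}

# Minimum-image displacement matrix (rows j - i, wrapped).
.min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Verlet neighbor list
#'
#' All pairs with minimum-image center distance below
#' \code{r_interaction + skin}.
#'
#' @param state an \code{mdem_state}.
#' @param r_interaction interaction radius (nm).
#' @param skin Verlet skin (nm).
#' @return 2-column matrix of pair indices (i < j).
#' @export
neighbor_list <- function(state, r_interaction, skin = 1) {
  n <- nrow(state$pos)
  if (n < 2) return(matrix(integer(0), 0, 2))
  rc <- r_interaction + skin
  ij <- t(utils::combn(n, 2))
  d <- .min_image(state$pos[ij[, 2], , drop = FALSE] -
                    state$pos[ij[, 1], , drop = FALSE], state$box)
  keep <- rowSums(d^2) < rc^2
  ij[keep, , drop = FALSE]
}

# Pairwise body-frame forces/torques from the field for the pair list.
# Returns accumulated force (body frame, n x 3), torque (n x 3) and
# the total pair potential.
.pair_forces <- function(state, field, pairs) {
  n <- nrow(state$pos)
  Fb <- matrix(0, n, 3); Tb <- matrix(0, n, 3)
  U <- 0
  if (!nrow(pairs)) return(list(F = Fb, M = Tb, U = 0))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dlab <- .min_image(matrix(state$pos[j, ] - state$pos[i, ], 1),
                       state$box)[1, ]
    qi <- state$quat[i, ]; qj <- state$quat[j, ]
    Ri <- quat_to_mat(qi)
    qrel <- quat_mul(quat_conj(qi), qj)
    trel <- as.numeric(t(Ri) %*% dlab)
    e <- quat_to_euler(qrel, "ZYX")
    cfg <- c(trel, e)
    ft <- force_torque(field, cfg)
    Rrel <- quat_to_mat(qrel)
    Fb[i, ] <- Fb[i, ] + ft$F_A
    Tb[i, ] <- Tb[i, ] + ft$M_A
    Fb[j, ] <- Fb[j, ] + as.numeric(t(Rrel) %*% ft$F_B)
    Tb[j, ] <- Tb[j, ] + as.numeric(t(Rrel) %*% ft$M_B)
    U <- U + ft$U
  }
  list(F = Fb, M = Tb, U = U)
}

#' One Langevin integration step
#'
#' Per molecule and body axis: deterministic pair force/torque,
#' friction from the Einstein relation at the reference temperature,
#' and Gaussian noise satisfying fluctuation-dissipation at the
#' current temperature, integrated with the exact constant-force
#' Ornstein-Uhlenbeck propagator; then the periodic wrap.
#'
#' @param state an \code{mdem_state}.
#' @param field potential field (grid or function backed); NULL for
#'   free diffusion.
#' @param dt_ps time step in ps.
#' @param pairs neighbor pair list.
#' @param max_disp displacement guard (nm): error when any molecule
#'   moves farther in one step.
#' @return updated state (element \code{last_U} carries the pair
#'   potential before the step, \code{max_step_disp} the displacement).
#' @export
langevin_step <- function(state, field, dt_ps, pairs = NULL,
                          max_disp = Inf) {
  n <- nrow(state$pos)
  kT_ref <- .kB * state$coeffs$temperature
  kT <- .kB * state$temperature
  Dt <- state$coeffs$Dt * 1e-6   # nm^2/ps
  Dr <- state$coeffs$Dr * 1e-6   # rad^2/ps
  zt <- kT_ref / Dt
  zr <- kT_ref / Dr
  oct_ <- lapply(1:3, function(d)
    .ou_coeffs(zt[d], state$mass, dt_ps, kT))
  ocr <- lapply(1:3, function(d)
    .ou_coeffs(zr[d], state$inertia[d], dt_ps, kT))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  ff <- if (is.null(field)) list(F = matrix(0, n, 3), M = matrix(0, n, 3),
                                 U = 0)
        else .pair_forces(state, field, pairs)
  nz_t <- .ou_noise(oct_, n)
  nz_r <- .ou_noise(ocr, n)
  dxb <- matrix(0, n, 3); dphib <- matrix(0, n, 3)
  for (d in 1:3) {
    ct <- oct_[[d]]; cr <- ocr[[d]]
    dxb[, d] <- ct$cx_v * state$vel[, d] + ct$cx_f * ff$F[, d] +
      nz_t$dx[, d]
    state$vel[, d] <- ct$a * state$vel[, d] + ct$cv_f * ff$F[, d] +
      nz_t$dv[, d]
    dphib[, d] <- cr$cx_v * state$omega[, d] + cr$cx_f * ff$M[, d] +
      nz_r$dx[, d]
    state$omega[, d] <- cr$a * state$omega[, d] + cr$cv_f * ff$M[, d] +
      nz_r$dv[, d]
  }
  disp <- sqrt(rowSums(dxb^2))
  if (any(disp > max_disp)) {
    stop(sprintf(
      "step displacement %.3g nm exceeds the guard %.3g nm; reduce dt",
      max(disp), max_disp))
  }
  for (i in seq_len(n)) {
    R <- quat_to_mat(state$quat[i, ])
    state$pos[i, ] <- state$pos[i, ] + as.numeric(R %*% dxb[i, ])
    state$quat[i, ] <- quat_normalize(
      quat_mul(state$quat[i, ], rotvec_quat(dphib[i, ])))
  }
  state$pos <- state$pos - floor(state$pos / rep(state$box, each = n)) *
    rep(state$box, each = n)
  state$time <- state$time + dt_ps * 1e-3   # ns
  state$last_U <- ff$U
  state$max_step_disp <- max(disp)
  state
}

#' Free-molecule diffusion measurement
#'
#' Simulates one interaction-free molecule with the same per-axis
#' Ornstein-Uhlenbeck update as \code{\link{langevin_step}} (vectorized
#' over steps) and estimates the diffusion coefficients from the
#' per-step body-frame displacement increments,
#' \code{D = mean(dx^2) / (2 dt)}.
#'
#' @param coeffs \code{\link{diffusion_coefficients}}.
#' @param struct molecule structure (mass and inertia).
#' @param dt_ps time step (ps), default 0.1 (1e-13 s).
#' @param n_steps number of steps, default 1e6.
#' @param temperature simulation temperature (K).
#' @return list \code{Dt} (um^2/s) and \code{Dr} (Mrad^2/s) estimates
#'   per body axis.
#' @export
measure_free_diffusion <- function(coeffs, struct = synthetic_dimer(),
                                   dt_ps = 0.1, n_steps = 1e6,
                                   temperature = coeffs$temperature) {
  kT_ref <- .kB * coeffs$temperature
  kT <- .kB * temperature
  m <- sum(struct$masses)
  inert <- inertia_principal(struct)
  est_axis <- function(zeta, mm) {
    oc <- .ou_coeffs(zeta, mm, dt_ps, kT)
    z1 <- stats::rnorm(n_steps); z2 <- stats::rnorm(n_steps)
    sdv <- sqrt(oc$var_v)
    cv <- oc$cov_xv / sdv
    sdx <- sqrt(max(oc$var_x - cv^2, 0))
    xiv <- sdv * z1
    xix <- cv * z1 + sdx * z2
    v0 <- stats::rnorm(1, 0, sqrt(kT / mm))
    v <- stats::filter(xiv, oc$a, method = "recursive", init = v0)
    vprev <- c(v0, v[-n_steps])
    dx <- oc$cx_v * vprev + xix
    mean(dx^2) / (2 * dt_ps)
  }
  Dt <- vapply(1:3, function(d)
    est_axis(kT_ref / (coeffs$Dt[d] * 1e-6), m), numeric(1))
  Dr <- vapply(1:3, function(d)
    est_axis(kT_ref / (coeffs$Dr[d] * 1e-6), inert[d]), numeric(1))
  list(Dt = Dt * 1e6, Dr = Dr * 1e6)
}

#' Protocol configuration
#'
#' SP1: zero-temperature damped quench (friction retained, random
#' force exactly zero). SP2: thermal run from a given initial state.
#' SP3: self-assembly from random placement at a given concentration;
#' the molecule count is \code{N = round(c NA V / 2)} (the protein
#' concentration counts monomers, the simulated particles are dimers;
#' set \code{monomer_concentration = FALSE} to count particles
#' directly).
#'
#' @param protocol "SP1", "SP2", "SP3" or "custom".
#' @param dt time step in seconds (default 1e-13; SP3 production used
#'   1e-12).
#' @param duration run time in seconds.
#' @param save_interval frame saving interval in seconds.
#' @param temperature K.
#' @param viscosity_scale effective viscosity factor.
#' @param concentration protein concentration in uM (SP3).
#' @param box box edge in um (SP3) or nm via \code{box_nm}.
#' @param box_nm box edge in nm (overrides \code{box}).
#' @param seed RNG seed recorded in the trajectory metadata (the
#'   caller seeds the RNG).
#' @param monomer_concentration see above.
#' @return a protocol config list.
#' @export
protocol_config <- function(protocol = c("SP1", "SP2", "SP3", "custom"),
                            dt = 1e-13, duration = 1e-9,
                            save_interval = 1e-10, temperature = 293,
                            viscosity_scale = 1, concentration = NULL,
                            box = NULL, box_nm = NULL, seed = NULL,
                            monomer_concentration = TRUE) {
  protocol <- match.arg(protocol)
  if (dt <= 0) stop("dt must be positive")
  if (duration < 0) stop("duration must be >= 0")
  if (protocol == "SP1") temperature <- 0
  if (is.null(box_nm) && !is.null(box)) box_nm <- box * 1e3
  list(protocol = protocol, dt = dt, duration = duration,
       save_interval = save_interval, temperature = temperature,
       viscosity_scale = viscosity_scale, concentration = concentration,
       box_nm = box_nm, seed = seed,
       monomer_concentration = monomer_concentration)
}

#' Run a simulation protocol
#'
#' @param pc a \code{\link{protocol_config}}.
#' @param struct molecule structure.
#' @param field potential field (grid or function backed).
#' @param coeffs diffusion coefficients.
#' @param state0 initial \code{mdem_state} (SP1/SP2/custom); SP3
#'   builds one by random placement.
#' @param r_interaction interaction radius for the neighbor list (nm);
#'   default from the field metadata.
#' @param skin Verlet skin (nm).
#' @return an \code{mdem_trajectory}: times (ns), frames (pos/quat),
#'   per-frame potential, box and metadata.
#' @export
run_protocol <- function(pc, struct, field, coeffs, state0 = NULL,
                         r_interaction = NULL, skin = 1.5) {
  dt_ps <- pc$dt * 1e12
  n_steps <- if (pc$duration == 0) 0 else max(1, round(pc$duration / pc$dt))
  save_every <- max(1, round(pc$save_interval / pc$dt))
  if (is.null(r_interaction)) {
    r_interaction <- .field_reach(field, struct)
  }
  if (is.null(state0)) {
    if (pc$protocol != "SP3") stop("SP1/SP2 need an initial state")
    state0 <- .random_state(pc, struct, coeffs)
  }
  state <- state0
  state$temperature <- pc$temperature
  if (pc$temperature == 0) {
    state$vel[] <- 0; state$omega[] <- 0
  }
  pairs <- neighbor_list(state, r_interaction, skin)
  ref_pos <- state$pos
  times <- numeric(0); frames <- list(); pot <- numeric(0)
  snap <- function(st, U) {
    times <<- c(times, st$time)
    frames[[length(frames) + 1]] <<- list(pos = st$pos, quat = st$quat)
    pot <<- c(pot, U)
  }
  U0 <- .pair_forces(state, field, pairs)$U
  snap(state, U0)
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      state <- langevin_step(state, field, dt_ps, pairs,
                             max_disp = skin / 2)
      drift <- sqrt(max(rowSums(
        .min_image(state$pos - ref_pos, state$box)^2)))
      if (drift > skin / 2) {
        pairs <- neighbor_list(state, r_interaction, skin)
        ref_pos <- state$pos
      }
      if (k %% save_every == 0 || k == n_steps) {
        snap(state, .pair_forces(state, field, pairs)$U)
      }
    }
  }
  structure(list(times = times, frames = frames, potential = pot,
                 box = state$box,
                 meta = list(protocol = pc$protocol, dt = pc$dt,
                             temperature = pc$temperature,
                             seed = pc$seed,
                             n_molecules = nrow(state$pos))),
            class = "mdem_trajectory")
}

#' @export
print.mdem_trajectory <- function(x, ...) {
  cat(sprintf("<mdem_trajectory %s: %d molecules, %d frames, %.3f ns>\n",
              x$meta$protocol, x$meta$n_molecules, length(x$frames),
              utils::tail(x$times, 1)))
  invisible(x)
}

.field_reach <- function(field, struct) {
  if (inherits(field, "mdem_grid")) {
    mx <- vapply(field$axes[1:3], function(a) a$min + a$step * (a$n - 1),
                 numeric(1))
    max(abs(c(mx, vapply(field$axes[1:3], `[[`, numeric(1), "min"))))
  } else {
    field$meta$r_cut %||% 10
  }
}

.random_state <- function(pc, struct, coeffs, max_tries = 2000) {
  if (is.null(pc$concentration) || is.null(pc$box_nm)) {
    stop("SP3 needs concentration and box")
  }
  V_m3 <- (pc$box_nm * 1e-9)^3
  monomers <- pc$concentration * 1e-6 * 1e3 * 6.02214076e23 * V_m3
  n <- if (pc$monomer_concentration) round(monomers / 2) else round(monomers)
  if (n < 1) stop("concentration/box give zero molecules")
  box <- rep(pc$box_nm, 3)
  r_ext <- max(sqrt(rowSums(struct$coords^2)))
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3, 0, box)
      if (i == 1) { pos[i, ] <- p; placed <- TRUE; break }
      d <- .min_image(sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p,
                            `-`), box)
      if (min(rowSums(d^2)) > (2 * r_ext)^2) {
        pos[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) stop("random placement failed; box too crowded")
  }
  quat <- random_quat(n)
  sim_state(struct, pos, quat, box, pc$temperature, coeffs,
            viscosity_scale = pc$viscosity_scale)
}

#' Write a trajectory as text with a JSON sidecar
#'
#' One block per frame: a header line \code{t=<ns>} followed by one
#' line per molecule: id, x, y, z (nm), qw, qx, qy, qz.
#'
#' @param traj an \code{mdem_trajectory}.
#' @param path output path (sidecar at \code{<path>.json}).
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(traj$frames)) {
    writeLines(sprintf("t=%.9g", traj$times[k]), con)
    f <- traj$frames[[k]]
    writeLines(sprintf("%d %.6f %.6f %.6f %.9f %.9f %.9f %.9f",
                       seq_len(nrow(f$pos)),
                       f$pos[, 1], f$pos[, 2], f$pos[, 3],
                       f$quat[, 1], f$quat[, 2], f$quat[, 3],
                       f$quat[, 4]), con)
  }
  jsonlite::write_json(
    c(traj$meta, list(box = traj$box, n_frames = length(traj$frames))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  heads <- grep("^t=", lines)
  times <- as.numeric(sub("^t=", "", lines[heads]))
  bounds <- c(heads, length(lines) + 1)
  frames <- lapply(seq_along(heads), function(k) {
    rec <- lines[(bounds[k] + 1):(bounds[k + 1] - 1)]
    m <- do.call(rbind, lapply(strsplit(rec, " "), as.numeric))
    list(pos = m[, 2:4, drop = FALSE], quat = m[, 5:8, drop = FALSE])
  })
  meta <- NULL
  box <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    box <- meta$box
  }
  structure(list(times = times, frames = frames, potential = NULL,
                 box = box, meta = meta),
            class = "mdem_trajectory")
}

# ---------------------------------------------------------------------------
# Rotne-Prager-Yamakawa drag

#' Hydrodynamic drag ratio from the RPY mobility tensor
#'
#' Builds the 3N x 3N Rotne-Prager-Yamakawa mobility matrix for equal
#' spheres, inverts it to the friction matrix, imposes identical unit
#' velocity on all spheres along \code{axis} and returns the force on
#' \code{which_sphere} along that axis divided by its isolated Stokes
#' drag 6 pi eta R.
#'
#' @param positions N x 3 sphere centers (same length unit as
#'   \code{radius}).
#' @param radius sphere radius.
#' @param axis motion direction (length-3 vector, normalized
#'   internally).
#' @param which_sphere index of the probed sphere, default 1.
#' @return drag ratio (dimensionless; 1 for an isolated sphere).
#' @export
rpy_drag_ratios <- function(positions, radius, axis = c(1, 0, 0),
                            which_sphere = 1) {
  P <- matrix(positions, ncol = 3)
  n <- nrow(P)
  axis <- axis / sqrt(sum(axis^2))
  eta <- 1
  mu0 <- 1 / (6 * pi * eta * radius)
  M <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    ii <- (i - 1) * 3 + 1:3
    M[ii, ii] <- diag(3) * mu0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- P[j, ] - P[i, ]
      rn <- sqrt(sum(r^2))
      if (rn < 2 * radius) {
        stop("overlapping spheres: regularized RPY not supported")
      }
      rh <- r / rn
      rr <- outer(rh, rh)
      a2 <- radius^2 / rn^2
      Mij <- 1 / (8 * pi * eta * rn) *
        ((1 + 2 * a2 / 3) * diag(3) + (1 - 2 * a2) * rr)
      M[ii, (j - 1) * 3 + 1:3] <- Mij
    }
  }
  Z <- solve(M)
  V <- rep(axis, n)
  F <- Z %*% V
  ii <- (which_sphere - 1) * 3 + 1:3
  sum(F[ii] * axis) / (6 * pi * eta * radius)
}
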