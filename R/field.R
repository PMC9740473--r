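# 6D potential grids: construction from kriging, collision
# augmentation, empirical binding insertion, multilinear lookup, and
# gradient forces/torques by central differences.

#' Grid axis specifications
#'
#' \code{grid_axis} defines a linear axis by bounds and step;
#' \code{angular_axis} defines a periodic angle axis with \code{n}
#' nodes covering (-pi, pi]. \code{grid_axes} assembles the six axis
#' specs (x, y, z, alpha, beta, gamma); singleton axes (one node)
#' freeze a dimension, which is how the 2D benchmark runs through the
#' same machinery.
#'
#' @param min,max axis bounds (nm).
#' @param step node spacing (nm or rad).
#' @param n node count.
#' @return axis spec / list of six axis specs.
#' @export
grid_axis <- function(min, max, step) {
  if (max < min) stop("axis max < min")
  n <- if (max == min) 1L else as.integer(round((max - min) / step)) + 1L
  list(min = min, step = if (n > 1) (max - min) / (n - 1) else 1,
       n = n, periodic = FALSE)
}

#' @rdname grid_axis
#' @export
angular_axis <- function(n) {
  n <- as.integer(n)
  if (n < 1) stop("angular axis needs >= 1 node")
  if (n == 1) return(list(min = 0, step = 1, n = 1L, periodic = FALSE))
  list(min = -pi, step = 2 * pi / n, n = n, periodic = TRUE)
}

#' @rdname grid_axis
#' @param x,y,z spatial axis specs.
#' @param alpha,beta,gamma angular axis specs.
#' @export
grid_axes <- function(x, y = x, z = x, alpha = angular_axis(1),
                      beta = alpha, gamma = alpha) {
  list(x = x, y = y, z = z, alpha = alpha, beta = beta, gamma = gamma)
}

axis_nodes <- function(ax) ax$min + ax$step * (seq_len(ax$n) - 1)

#' Node configurations of a grid
#'
#' @param grid an \code{mdem_grid}.
#' @param idx node indices (default all), in array order (x fastest).
#' @return matrix of 6D configurations.
#' @export
grid_node_configs <- function(grid, idx = NULL) {
  nodes <- lapply(grid$axes, axis_nodes)
  cf <- as.matrix(do.call(expand.grid, nodes))
  colnames(cf) <- c("x", "y", "z", "alpha", "beta", "gamma")
  if (is.null(idx)) cf else cf[idx, , drop = FALSE]
}

#' Collision model parameters
#'
#' @param k_coll potential increase per colliding bead pair (kJ/mol).
#' @param d_flex flexibility distance (nm): the penalty ramps linearly
#'   from 0 at delta_r_nearest = 0 (configuration backed by data,
#'   flexibility fully trusted) to full at \code{d_flex}.
#' @param threshold collision distance (nm), default 0.4.
#' @return a parameter list.
#' @export
collision_params <- function(k_coll = 50, d_flex = 0.5, threshold = 0.4) {
  if (k_coll < 0 || d_flex <= 0) stop("invalid collision parameters")
  list(k_coll = k_coll, d_flex = d_flex, threshold = threshold)
}

#' Collision penalty for one configuration
#'
#' \code{dU = k_coll * n_coll * ramp(delta_r_nearest / d_flex)} with a
#' linear ramp clamped to [0, 1]; \code{n_coll} counts all-bead pairs
#' closer than the threshold and \code{delta_r_nearest} is the
#' distance to the closest data point.
#'
#' @param structA,structB structures.
#' @param cfg configuration.
#' @param samples sample set (for the nearest-data distance); NULL
#'   treats the configuration as unbacked (full penalty).
#' @param cp \code{\link{collision_params}}.
#' @return non-negative potential increase (kJ/mol).
#' @export
collision_penalty <- function(structA, structB, cfg, samples, cp) {
  ncol_ <- count_collisions(structA, structB, cfg, cp$threshold,
                            backbone_only = FALSE)
  if (ncol_ == 0) return(0)
  ramp <- if (is.null(samples)) 1 else {
    drn <- min(delta_r_to(samples, cfg))
    max(0, min(1, drn / cp$d_flex))
  }
  cp$k_coll * ncol_ * ramp
}

#' Build a potential grid by kriging
#'
#' Estimates potential and estimation variance at every grid node.
#' Nodes beyond the interaction range are set to zero and masked
#' gradient-free; colliding nodes receive the collision penalty.
#'
#' @param models an \code{mdem_models} bundle.
#' @param axes six axis specs from \code{\link{grid_axes}}.
#' @param N_pot,N_var kriging neighborhood sizes.
#' @param collision optional \code{\link{collision_params}}.
#' @param compute_variance build the variance array (default TRUE).
#' @param max_nodes allocation guard.
#' @return an \code{mdem_grid}.
#' @export
build_grid <- function(models, axes, N_pot = 100, N_var = 100,
                       collision = NULL, compute_variance = TRUE,
                       max_nodes = 2e6) {
  dims <- vapply(axes, `[[`, numeric(1), "n")
  ntot <- prod(dims)
  if (ntot > max_nodes) {
    stop(sprintf("grid of %g nodes exceeds the cap of %g", ntot, max_nodes))
  }
  s <- models$samples
  cf <- NULL
  dm <- .grid_delta_m(s$structA, s$structB, axes)
  value <- numeric(ntot)
  variance <- if (compute_variance) numeric(ntot) else NULL
  mask <- dm > models$interaction_range
  todo <- which(!mask)
  if (length(todo)) {
    cf <- grid_node_configs(structure(list(axes = axes), class = "mdem_grid"),
                            todo)
    est <- uk_estimate_batch(models, cf, N_pot, N_var, compute_variance)
    value[todo] <- est$estimate
    if (compute_variance) variance[todo] <- est$variance
    if (!is.null(collision)) {
      coll_idx <- todo[dm[todo] < collision$threshold]
      for (i in coll_idx) {
        v <- grid_node_configs(
          structure(list(axes = axes), class = "mdem_grid"), i)[1, ]
        cfg <- config(v[1], v[2], v[3], v[4], v[5], v[6], order = s$order)
        value[i] <- value[i] +
          collision_penalty(s$structA, s$structB, cfg, s, collision)
      }
    }
  }
  structure(list(axes = axes, value = value, variance = variance,
                 mask = mask, delta_m = dm,
                 meta = list(species = c(s$structA$name, s$structB$name),
                             components = models$components,
                             order = s$order,
                             interaction_range = models$interaction_range)),
            class = "mdem_grid")
}

# delta_m at every node, grouped by orientation for speed.
.grid_delta_m <- function(structA, structB, axes) {
  A <- structA$coords[structA$backbone, , drop = FALSE]
  B <- structB$coords[structB$backbone, , drop = FALSE]
  sp <- as.matrix(do.call(expand.grid, lapply(axes[1:3], axis_nodes)))
  ang <- as.matrix(do.call(expand.grid, lapply(axes[4:6], axis_nodes)))
  nspat <- nrow(sp)
  out <- numeric(nspat * nrow(ang))
  for (o in seq_len(nrow(ang))) {
    q <- euler_to_quat(ang[o, ], order = "ZYX")
    Brot <- B %*% t(quat_to_mat(q))
    out[(o - 1) * nspat + seq_len(nspat)] <-
      as.numeric(cpp_min_dist_many(A, Brot, sp))
  }
  out
}

#' @export
print.mdem_grid <- function(x, ...) {
  dims <- vapply(x$axes, `[[`, numeric(1), "n")
  cat(sprintf("<mdem_grid %s: %d nodes, %.0f%% masked>\n",
              paste(dims, collapse = "x"), length(x$value),
              100 * mean(x$mask)))
  invisible(x)
}

#' Interpolated potential at configurations
#'
#' Multilinear interpolation over the 6D cell with periodic wrap on
#' angle axes; queries outside the spatial extent return 0.
#'
#' @param field an \code{mdem_grid} or \code{mdem_funfield}.
#' @param configs one configuration or an n x 6 matrix.
#' @param ... unused.
#' @return potential values (kJ/mol).
#' @export
value_at <- function(field, configs, ...) UseMethod("value_at")

#' @export
value_at.mdem_grid <- function(field, configs, ...) {
  q <- if (is.matrix(configs)) configs else matrix(as.numeric(configs), 1)
  q[, 4:6] <- wrap_angle(q[, 4:6])
  cpp_interp6(field$value,
              as.integer(vapply(field$axes, `[[`, numeric(1), "n")),
              vapply(field$axes, `[[`, numeric(1), "min"),
              vapply(field$axes, `[[`, numeric(1), "step"),
              vapply(field$axes, `[[`, logical(1), "periodic"),
              q)
}

#' Function-backed potential field
#'
#' Wraps an analytic potential \code{fun(configs) -> values} in the
#' field interface so dynamics and quench protocols can run on exact
#' potentials (useful for verification and for sub-grid-width wells).
#'
#' @param fun vectorized potential function over n x 6 configuration
#'   matrices.
#' @param steps central-difference steps \code{c(dx, dangle)} used by
#'   \code{\link{force_torque}}.
#' @param r_cut interaction radius for neighbor lists (nm).
#' @return an \code{mdem_funfield}.
#' @export
fun_field <- function(fun, steps = c(0.05, 0.02), r_cut = 10) {
  structure(list(fun = fun, steps = steps,
                 meta = list(r_cut = r_cut)),
            class = "mdem_funfield")
}

#' @export
value_at.mdem_funfield <- function(field, configs, ...) {
  q <- if (is.matrix(configs)) configs else matrix(as.numeric(configs), 1)
  field$fun(q)
}

field_steps <- function(field) {
  if (inherits(field, "mdem_funfield")) {
    c(rep(field$steps[1], 3), rep(field$steps[2], 3))
  } else {
    vapply(field$axes, `[[`, numeric(1), "step")
  }
}

#' Forces and torques from the potential field
#'
#' Central differences of the interpolated potential: translational
#' gradient over x, y, z with the axis step, rotational gradient with
#' respect to small rotations of B about A's body axes
#' (quaternion-composed perturbations of the angular step, not raw
#' Euler rates). Returns the force/torque on A and the reaction on B,
#' all in A's body frame; the reaction satisfies zero total force and
#' torque balance about the pair midpoint within stencil tolerance.
#'
#' @param field an \code{mdem_grid} or \code{mdem_funfield}.
#' @param cfg configuration of B in A's body frame.
#' @return list \code{F_A}, \code{M_A}, \code{F_B}, \code{M_B}
#'   (kJ/mol/nm and kJ/mol/rad, A's body frame) and the potential
#'   \code{U}.
#' @export
force_torque <- function(field, cfg) {
  v <- as.numeric(cfg)
  st <- field_steps(field)
  if (inherits(field, "mdem_grid")) {
    # masked region: zero force
    idx <- .grid_cell_index(field, v)
    if (!is.na(idx) && field$mask[idx]) {
      z <- c(0, 0, 0)
      return(list(F_A = z, M_A = z, F_B = z, M_B = z,
                  U = value_at(field, v)))
    }
  }
  qB <- euler_to_quat(v[4:6], order = "ZYX")
  pts <- matrix(rep(v, 13), ncol = 6, byrow = TRUE)
  r <- 1
  for (d in 1:3) {
    pts[r + 1, d] <- v[d] + st[d]
    pts[r + 2, d] <- v[d] - st[d]
    r <- r + 2
  }
  for (d in 1:3) {
    ax <- c(0, 0, 0); ax[d] <- 1
    qp <- quat_mul(rotvec_quat(ax * st[3 + d]), qB)
    qm <- quat_mul(rotvec_quat(-ax * st[3 + d]), qB)
    pts[r + 1, 4:6] <- quat_to_euler(qp, "ZYX")
    pts[r + 2, 4:6] <- quat_to_euler(qm, "ZYX")
    r <- r + 2
  }
  u <- value_at(field, pts)
  gx <- unname((u[c(2, 4, 6)] - u[c(3, 5, 7)]) / (2 * st[1:3]))
  gphi <- unname((u[c(8, 10, 12)] - u[c(9, 11, 13)]) / (2 * st[4:6]))
  F_B <- -gx                 # force on B, A's body frame
  F_A <- gx
  M_B <- -gphi               # torque on B about its center, A's frame
  x <- v[1:3]
  M_A <- -M_B + .cross3(x, F_A)
  list(F_A = F_A, M_A = M_A, F_B = F_B, M_B = M_B, U = u[1])
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Nearest-node flat index for a configuration (NA outside the grid).
.grid_cell_index <- function(grid, v) {
  idx <- 0L; stridev <- 1L
  for (d in 1:6) {
    ax <- grid$axes[[d]]
    u <- (v[d] - ax$min) / ax$step
    if (ax$periodic) {
      i <- as.integer(round(u)) %% ax$n
    } else {
      i <- as.integer(round(u))
      if (ax$n == 1) i <- 0L
      if (i < 0 || i >= ax$n) return(NA_integer_)
    }
    idx <- idx + i * stridev
    stridev <- stridev * ax$n
  }
  idx + 1L
}

# ---------------------------------------------------------------------------
# Empirical binding insertion

#' Empirical binding specification
#'
#' @param configs list of binding configurations (or a k x 6 matrix).
#' @param U_center potential at the binding center (kJ/mol).
#' @param U_outer potential at the well rim (kJ/mol).
#' @param r_bind well range in delta_r (nm).
#' @param max_extra_collisions backbone-collision budget for virtual
#'   points, default 10.
#' @return a binding spec list.
#' @export
binding_spec <- function(configs, U_center = -1400, U_outer = -1000,
                         r_bind = 1.0, max_extra_collisions = 10) {
  if (is.matrix(configs)) {
    configs <- lapply(seq_len(nrow(configs)), function(i) {
      v <- configs[i, ]
      config(v[1], v[2], v[3], v[4], v[5], v[6])
    })
  }
  if (!(U_center <= U_outer && U_outer <= 0)) {
    stop("need U_center <= U_outer <= 0")
  }
  if (r_bind <= 0) stop("r_bind must be positive")
  list(configs = configs, U_center = U_center, U_outer = U_outer,
       r_bind = r_bind, max_extra_collisions = max_extra_collisions)
}

# Gaussian well profile from U_center to U_outer over delta_r.
.well_value <- function(dr, bspec) {
  bspec$U_outer + (bspec$U_center - bspec$U_outer) *
    exp(-dr^2 / (2 * (bspec$r_bind / 2)^2))
}

#' Insert virtual binding data points
#'
#' Two point sets per binding configuration: set 1 at constant
#' \code{U_center} at the center and axis-aligned +/-0.1 nm offsets
#' (rotational equivalent via \code{dangle = 0.1 nm / R_char}); set 2
#' following a Gaussian well from \code{U_center} to \code{U_outer}
#' over delta_r at offsets of -0.4, -0.2, 0.2, 0.4 nm per axis.
#' Points farther than \code{r_bind} in delta_r or adding more than
#' the allowed extra backbone collisions are dropped. Binding
#' configurations overlapping at the bead level are first moved to the
#' nearest overlap-free configuration by a +/-5-step search of 0.2 nm
#' / 10 degrees per axis.
#'
#' The inserted value is a target for the total potential: the kriged
#' component receives the target minus the trend values of all other
#' components, so exact interpolation reproduces the target.
#'
#' @param s sample set to augment.
#' @param bspec a \code{\link{binding_spec}}.
#' @param models fitted \code{mdem_models} (for the non-kriged trends);
#'   NULL assigns the full value to \code{component}.
#' @param component kriged component receiving the well, default the
#'   first column.
#' @param d_coll overlap threshold for the correction search (nm).
#' @return the augmented sample set; attribute \code{"insert_log"}
#'   records dropped offsets.
#' @export
insert_empirical <- function(s, bspec, models = NULL,
                             component = colnames(s$pot)[1],
                             d_coll = 0.4) {
  structA <- s$structA; structB <- s$structB
  R_char <- max(gyration_radii(structB))
  dang1 <- 0.1 / R_char
  log <- list()
  all_cf <- NULL; all_pot <- NULL
  other <- setdiff(colnames(s$pot), component)
  target_minus_trends <- function(target, dm) {
    val <- rep(0, length(colnames(s$pot)))
    names(val) <- colnames(s$pot)
    val[component] <- target
    if (!is.null(models)) {
      for (cp in other) {
        tv <- trend_eval(models$trends[[cp]], dm)
        val[cp] <- tv
        val[component] <- val[component] - tv
      }
    }
    val
  }
  for (bi in seq_along(bspec$configs)) {
    base <- bspec$configs[[bi]]
    if (count_collisions(structA, structB, base, d_coll) > 0) {
      base <- .overlap_correct(structA, structB, base, d_coll)
    }
    base_ncoll <- count_collisions(structA, structB, base, d_coll,
                                   backbone_only = TRUE)
    if (is.null(base)) {
      stop(sprintf("binding configuration %d cannot be made overlap-free",
                   bi))
    }
    offsets1 <- .axis_offsets(base, c(-0.1, 0.1), dang1, structB)
    offsets2 <- .axis_offsets(base, c(-0.4, -0.2, 0.2, 0.4),
                              c(-0.4, -0.2, 0.2, 0.4) / R_char, structB)
    cand <- c(list(list(cfg = base, dr = 0)), offsets1, offsets2)
    for (k in seq_along(cand)) {
      cfg <- cand[[k]]$cfg
      dr <- cand[[k]]$dr
      if (dr > bspec$r_bind) {
        log[[length(log) + 1]] <- sprintf(
          "binding %d offset %d dropped: delta_r %.2f > r_bind", bi, k, dr)
        next
      }
      nc <- count_collisions(structA, structB, cfg, d_coll,
                             backbone_only = TRUE)
      if (nc - base_ncoll > bspec$max_extra_collisions) {
        if (k == 1) {
          stop(sprintf(
            "binding configuration %d violates the collision budget", bi))
        }
        log[[length(log) + 1]] <- sprintf(
          "binding %d offset %d dropped: %d extra backbone collisions",
          bi, k, nc - base_ncoll)
        next
      }
      target <- if (k == 1 || dr <= 0.1 + 1e-9) bspec$U_center
                else .well_value(dr, bspec)
      dm <- min_distance(structA, structB, cfg)
      all_cf <- rbind(all_cf, as.numeric(cfg))
      all_pot <- rbind(all_pot, target_minus_trends(target, dm))
    }
  }
  if (is.null(all_cf)) return(s)
  add <- sample_set(all_cf, all_pot, structA, structB,
                    provenance = "virtual", order = s$order)
  out <- append_samples(s, add)
  attr(out, "insert_log") <- unlist(log)
  out
}

# Axis-aligned offsets around a configuration; returns configs with
# their delta_r to the base placement.
.axis_offsets <- function(base, dxs, dangs, structB) {
  v <- as.numeric(base)
  qB <- euler_to_quat(v[4:6], "ZYX")
  out <- list()
  for (d in 1:3) {
    for (dx in dxs) {
      w <- v; w[d] <- w[d] + dx
      cfg <- config(w[1], w[2], w[3], w[4], w[5], w[6])
      out[[length(out) + 1]] <- list(cfg = cfg,
                                     dr = config_distance(base, cfg, structB))
    }
  }
  for (d in 1:3) {
    for (da in dangs) {
      ax <- c(0, 0, 0); ax[d] <- 1
      q2 <- quat_mul(rotvec_quat(ax * da), qB)
      e <- quat_to_euler(q2, "ZYX")
      cfg <- config(v[1], v[2], v[3], e[1], e[2], e[3])
      out[[length(out) + 1]] <- list(cfg = cfg,
                                     dr = config_distance(base, cfg, structB))
    }
  }
  out
}

# Greedy +/-5-step per-axis search (0.2 nm / 10 deg) for the nearest
# overlap-free configuration by delta_r.
.overlap_correct <- function(structA, structB, base, d_coll,
                             max_rounds = 3) {
  cur <- base
  for (round in seq_len(max_rounds)) {
    if (count_collisions(structA, structB, cur, d_coll) == 0) return(cur)
    v <- as.numeric(cur)
    qB <- euler_to_quat(v[4:6], "ZYX")
    best <- NULL; best_dr <- Inf
    for (d in 1:3) {
      for (stp in setdiff(-5:5, 0) * 0.2) {
        w <- v; w[d] <- w[d] + stp
        cfg <- config(w[1], w[2], w[3], w[4], w[5], w[6])
        if (count_collisions(structA, structB, cfg, d_coll) == 0) {
          dr <- config_distance(base, cfg, structB)
          if (dr < best_dr) { best <- cfg; best_dr <- dr }
        }
      }
    }
    for (d in 1:3) {
      for (stp in setdiff(-5:5, 0) * (10 * pi / 180)) {
        ax <- c(0, 0, 0); ax[d] <- 1
        q2 <- quat_mul(rotvec_quat(ax * stp), qB)
        e <- quat_to_euler(q2, "ZYX")
        cfg <- config(v[1], v[2], v[3], e[1], e[2], e[3])
        if (count_collisions(structA, structB, cfg, d_coll) == 0) {
          dr <- config_distance(base, cfg, structB)
          if (dr < best_dr) { best <- cfg; best_dr <- dr }
        }
      }
    }
    if (!is.null(best)) return(best)
    # no single-axis fix found: nudge outward along the translation
    v[1:3] <- v[1:3] * (1 + 0.1 * round)
    cur <- config(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  NULL
}

# ---------------------------------------------------------------------------
# Binary field format
# magic "MDEMFLD1"; little-endian; header: version uint32, species pair
# (length-prefixed UTF-8 x2), component count + names, 6 x axis spec
# (float64 min, max, step; uint8 periodic), uint8 flags for variance
# and mask; payload: value float32 (x fastest), optional variance
# float32, mask packed bits.

#' Save / load a potential grid in the binary field format
#'
#' @param grid an \code{mdem_grid}.
#' @param path file path.
#' @return \code{load_field} returns the grid; values round-trip at
#'   float32 precision bit-exactly.
#' @export
save_field <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MDEMFLD1"), con)
  writeBin(1L, con, size = 4, endian = "little")
  wstr <- function(x) {
    r <- charToRaw(enc2utf8(x))
    writeBin(length(r), con, size = 4, endian = "little")
    writeBin(r, con)
  }
  species <- grid$meta$species %||% c("A", "B")
  wstr(species[1]); wstr(species[2])
  comps <- grid$meta$components %||% "A-B"
  writeBin(length(comps), con, size = 4, endian = "little")
  for (cp in comps) wstr(cp)
  for (ax in grid$axes) {
    writeBin(as.numeric(c(ax$min, ax$min + ax$step * (ax$n - 1), ax$step)),
             con, size = 8, endian = "little")
    writeBin(as.integer(ax$periodic), con, size = 1)
  }
  writeBin(as.integer(!is.null(grid$variance)), con, size = 1)
  writeBin(1L, con, size = 1)   # mask present
  writeBin(as.numeric(grid$value), con, size = 4, endian = "little")
  if (!is.null(grid$variance)) {
    writeBin(as.numeric(grid$variance), con, size = 4, endian = "little")
  }
  writeBin(packBits(as.integer(
    c(grid$mask, rep(0, (-length(grid$mask)) %% 8))), type = "raw"), con)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, "MDEMFLD1")) stop("bad magic: not a field file")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (version != 1) stop("unsupported field format version: ", version)
  rstr <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  species <- c(rstr(), rstr())
  ncomp <- readBin(con, "integer", 1, size = 4, endian = "little")
  comps <- vapply(seq_len(ncomp), function(i) rstr(), "")
  axes <- lapply(1:6, function(d) {
    v <- readBin(con, "numeric", 3, size = 8, endian = "little")
    p <- readBin(con, "integer", 1, size = 1)
    n <- if (v[2] == v[1]) 1L else as.integer(round((v[2] - v[1]) / v[3])) + 1L
    list(min = v[1], step = v[3], n = n, periodic = as.logical(p))
  })
  names(axes) <- c("x", "y", "z", "alpha", "beta", "gamma")
  has_var <- readBin(con, "integer", 1, size = 1) == 1
  has_mask <- readBin(con, "integer", 1, size = 1) == 1
  ntot <- prod(vapply(axes, `[[`, numeric(1), "n"))
  value <- readBin(con, "numeric", ntot, size = 4, endian = "little")
  if (length(value) < ntot) stop("truncated field file")
  variance <- NULL
  if (has_var) {
    variance <- readBin(con, "numeric", ntot, size = 4, endian = "little")
    if (length(variance) < ntot) stop("truncated field file")
  }
  mask <- rep(FALSE, ntot)
  if (has_mask) {
    nbytes <- ceiling(ntot / 8)
    raw <- readBin(con, "raw", nbytes)
    if (length(raw) < nbytes) stop("truncated field file")
    mask <- as.logical(rawToBits(raw))[seq_len(ntot)]
  }
  structure(list(axes = axes, value = value, variance = variance,
                 mask = mask,
                 meta = list(species = species, components = comps)),
            class = "mdem_grid")
}

#' Read only the header of a field file
#'
#' @param path field file.
#' @return list with version, species and components (payload not
#'   loaded).
#' @export
field_info <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, "MDEMFLD1")) stop("bad magic: not a field file")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  rstr <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  species <- c(rstr(), rstr())
  ncomp <- readBin(con, "integer", 1, size = 4, endian = "little")
  comps <- vapply(seq_len(ncomp), function(i) rstr(), "")
  list(version = version, species = species, components = comps)
}
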