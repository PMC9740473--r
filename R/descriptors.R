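# Spatial descriptors of pair configurations: the minimum backbone
# distance delta_m (trend coordinate), the configuration RMSD delta_r
# (metric for neighborhoods, variograms and binding proximity),
# collision counting and data-point symmetrization.

#' Minimum backbone distance between two placed molecules
#'
#' @param structA,structB canonicalized bead structures.
#' @param cfg configuration of B in A's body frame.
#' @param backbone_only use backbone beads only (the delta_m
#'   definition); set \code{FALSE} for the all-atom placement filter.
#' @return minimum pair distance in nm.
#' @export
min_distance <- function(structA, structB, cfg, backbone_only = TRUE) {
  p <- config_to_pose(cfg)
  selA <- if (backbone_only) structA$backbone else NULL
  selB <- if (backbone_only) structB$backbone else NULL
  A <- if (is.null(selA)) structA$coords else structA$coords[selA, , drop = FALSE]
  B <- place_beads(structB, p, selB)
  cpp_min_dist(A, B)
}

# Flattened backbone placement of B at cfg: numeric length 3k. delta_r
# between two configurations is the Euclidean distance of these vectors
# divided by sqrt(k), which makes it a true metric.
place_flat <- function(structB, cfg) {
  as.numeric(place_beads(structB, config_to_pose(cfg), structB$backbone))
}

#' Configuration distance delta_r
#'
#' RMSD of molecule B's backbone beads placed at \code{c1} versus
#' placed at \code{c2}.
#'
#' @param c1,c2 configurations.
#' @param structB canonicalized structure of molecule B.
#' @return delta_r in nm (symmetric, satisfies the triangle inequality).
#' @export
config_distance <- function(c1, c2, structB) {
  k <- sum(structB$backbone)
  sqrt(sum((place_flat(structB, c1) - place_flat(structB, c2))^2) / k)
}

#' Count colliding bead pairs
#'
#' @inheritParams min_distance
#' @param threshold collision distance, default 0.4 nm.
#' @return number of (A, B) bead pairs closer than \code{threshold}.
#' @export
count_collisions <- function(structA, structB, cfg, threshold = 0.4,
                             backbone_only = FALSE) {
  p <- config_to_pose(cfg)
  selA <- if (backbone_only) structA$backbone else NULL
  selB <- if (backbone_only) structB$backbone else NULL
  A <- if (is.null(selA)) structA$coords else structA$coords[selA, , drop = FALSE]
  B <- place_beads(structB, p, selB)
  cpp_count_within(A, B, threshold)
}

#' Mirror configuration (A-B to B-A)
#'
#' The pose-algebra inverse of a configuration: the same physical pair
#' seen from the other molecule.
#'
#' @param cfg configuration.
#' @return the inverse configuration (same Euler convention).
#' @export
config_inverse <- function(cfg) {
  pose_to_config(pose_inverse(config_to_pose(cfg)), order = config_order(cfg))
}

#' Draw a random non-colliding configuration
#'
#' Position uniform within a radial shell, orientation uniform over
#' SO(3); draws are rejected until the all-bead minimum distance is at
#' least \code{d_coll}. Consumes the R RNG stream.
#'
#' @param r_min,r_max radial bounds for the center-center distance (nm).
#' @param structA,structB canonicalized structures.
#' @param d_coll minimum allowed bead-bead distance (nm), default 0.4.
#' @param max_tries rejection budget.
#' @param order Euler convention of the result.
#' @param radial_policy \code{"volume"} (uniform in the shell volume)
#'   or \code{"radial"} (uniform in center distance, giving more even
#'   coverage of short minimum distances).
#' @return an \code{mdem_config}.
#' @export
random_config <- function(r_min, r_max, structA, structB, d_coll = 0.4,
                          max_tries = 1000, order = "ZYX",
                          radial_policy = c("volume", "radial")) {
  radial_policy <- match.arg(radial_policy)
  for (i in seq_len(max_tries)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u * u))
    r <- if (radial_policy == "volume") {
      (stats::runif(1, r_min^3, r_max^3))^(1 / 3)
    } else stats::runif(1, r_min, r_max)
    q <- as.numeric(random_quat(1))
    p <- pose(translation = r * u, quat = q)
    cfg <- pose_to_config(p, order = order)
    if (min_distance(structA, structB, cfg, backbone_only = FALSE) >= d_coll) {
      return(cfg)
    }
  }
  stop(sprintf(
    "random_config: no non-colliding placement in [%g, %g] nm after %d tries",
    r_min, r_max, max_tries))
}

# ---------------------------------------------------------------------------
# Sample sets

#' Build a sample set from configurations and oracle potentials
#'
#' A sample set carries the 6D configurations, the per-component
#' potential values, the descriptors delta_m, cached backbone
#' placements (for fast delta_r), density weights, residuals and
#' provenance.
#'
#' @param configs n x 6 matrix (or list of configs).
#' @param potentials n x P matrix with component names as columns.
#' @param structA,structB canonicalized structures.
#' @param provenance per-point provenance, \code{"oracle"} or
#'   \code{"virtual"}.
#' @param order Euler convention of the configuration angles.
#' @return object of class \code{mdem_samples}.
#' @export
sample_set <- function(configs, potentials, structA, structB,
                       provenance = "oracle", order = "ZYX") {
  if (is.list(configs) && !is.matrix(configs)) {
    configs <- do.call(rbind, lapply(configs, as.numeric))
  }
  configs <- matrix(as.numeric(configs), ncol = 6)
  colnames(configs) <- c("x", "y", "z", "alpha", "beta", "gamma")
  potentials <- as.matrix(potentials)
  n <- nrow(configs)
  if (nrow(potentials) != n) stop("configs/potentials row mismatch")
  placed <- t(apply(configs, 1, function(v)
    place_flat(structB, config(v[1], v[2], v[3], v[4], v[5], v[6],
                               order = order))))
  delta_m <- vapply(seq_len(n), function(i)
    min_distance(structA, structB,
                 config(configs[i, 1], configs[i, 2], configs[i, 3],
                        configs[i, 4], configs[i, 5], configs[i, 6],
                        order = order)), numeric(1))
  structure(list(
    config = configs, pot = potentials, res = NULL,
    delta_m = delta_m, weight = rep(1, n),
    provenance = rep_len(provenance, n), placed = placed,
    structA = structA, structB = structB, order = order,
    nb = sum(structB$backbone)
  ), class = "mdem_samples")
}

#' @export
print.mdem_samples <- function(x, ...) {
  cat(sprintf("<mdem_samples: %d points, components: %s>\n",
              nrow(x$config), paste(colnames(x$pot), collapse = ", ")))
  invisible(x)
}

n_samples <- function(s) nrow(s$config)

get_config <- function(s, i) {
  v <- s$config[i, ]
  config(v[1], v[2], v[3], v[4], v[5], v[6], order = s$order)
}

# delta_r between a query configuration and every point of the set.
delta_r_to <- function(s, cfg) {
  f <- place_flat(s$structB, cfg)
  sqrt(colSums((t(s$placed) - f)^2) / s$nb)
}

# Row-subset of a sample set.
.subset_samples <- function(s, idx) {
  s$config <- s$config[idx, , drop = FALSE]
  s$pot <- s$pot[idx, , drop = FALSE]
  s$delta_m <- s$delta_m[idx]
  s$weight <- s$weight[idx]
  s$provenance <- s$provenance[idx]
  s$placed <- s$placed[idx, , drop = FALSE]
  if (!is.null(s$res)) s$res <- s$res[idx, , drop = FALSE]
  s
}

# Append points to a sample set (same structures/order assumed).
append_samples <- function(s, s2) {
  s$config <- rbind(s$config, s2$config)
  s$pot <- rbind(s$pot, s2$pot)
  s$delta_m <- c(s$delta_m, s2$delta_m)
  s$weight <- c(s$weight, s2$weight)
  s$provenance <- c(s$provenance, s2$provenance)
  s$placed <- rbind(s$placed, s2$placed)
  s$res <- NULL   # residuals stale after growth
  s
}

#' Symmetrize a data point
#'
#' For identical species the relative configuration seen from molecule
#' B carries the same potential values, so each evaluation yields two
#' data points. Hetero pairs are returned unchanged.
#'
#' @param cfg configuration of the evaluated point.
#' @param potentials named potential values.
#' @param identical_species logical.
#' @return list of one or two \code{list(config, potentials)} entries.
#' @export
symmetrize <- function(cfg, potentials, identical_species = TRUE) {
  if (!identical_species) return(list(list(config = cfg, potentials = potentials)))
  list(list(config = cfg, potentials = potentials),
       list(config = config_inverse(cfg), potentials = potentials))
}

#' Write / read a sample set as CSV
#'
#' Columns: id, x, y, z, alpha, beta, gamma, delta_m, one column per
#' potential component, provenance.
#'
#' @param s an \code{mdem_samples}.
#' @param path file path.
#' @export
write_samples_csv <- function(s, path) {
  df <- data.frame(id = seq_len(n_samples(s)), s$config,
                   delta_m = s$delta_m, check.names = FALSE)
  pot <- as.data.frame(s$pot)
  names(pot) <- colnames(s$pot)
  df <- cbind(df, pot, provenance = s$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @param structA,structB structures to attach on read.
#' @param order Euler convention of the stored angles.
#' @export
read_samples_csv <- function(path, structA, structB, order = "ZYX") {
  df <- utils::read.csv(path, check.names = FALSE)
  fixed <- c("id", "x", "y", "z", "alpha", "beta", "gamma", "delta_m",
             "provenance")
  comp <- setdiff(names(df), fixed)
  sample_set(as.matrix(df[, c("x", "y", "z", "alpha", "beta", "gamma")]),
             as.matrix(df[, comp, drop = FALSE]),
             structA, structB, provenance = df$provenance, order = order)
}
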