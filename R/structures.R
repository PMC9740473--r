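# Molecular reference structures, body frames, poses and their algebra.
#
# A bead structure is the rigid reference of one molecule species: bead
# coordinates (nm), a backbone mask selecting the beads used by the
# spatial descriptors, and bead masses (amu). After canonicalization
# the mass-weighted center sits at the origin and the coordinate
# covariance is diagonal with descending eigenvalues, so the body frame
# is the principal-axes frame.

#' Create a bead structure
#'
#' @param coords numeric n x 3 matrix of bead coordinates in nm.
#' @param backbone logical vector (recycled) marking backbone beads.
#' @param masses bead masses in amu (default 1).
#' @param name species label.
#' @return an object of class \code{mdem_structure}.
#' @export
bead_structure <- function(coords, backbone = TRUE, masses = 1,
                           name = "mol") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n < 1) stop("structure needs at least one bead")
  stopifnot_finite(coords, "bead coordinates")
  backbone <- rep_len(as.logical(backbone), n)
  if (!any(backbone)) stop("backbone mask must select at least one bead")
  masses <- rep_len(as.numeric(masses), n)
  if (any(masses <= 0)) stop("bead masses must be positive")
  structure(list(name = name, coords = coords, backbone = backbone,
                 masses = masses),
            class = "mdem_structure")
}

#' @export
print.mdem_structure <- function(x, ...) {
  cat(sprintf("<mdem_structure '%s': %d beads (%d backbone), mass %.1f amu>\n",
              x$name, nrow(x$coords), sum(x$backbone), sum(x$masses)))
  invisible(x)
}

#' Canonicalize a structure into its principal-axes body frame
#'
#' Moves the mass-weighted center of mass to the origin and rotates the
#' beads so the mass-weighted coordinate covariance is diagonal with
#' descending eigenvalues and a right-handed axis set. Sign convention:
#' on the first two axes the coordinate of largest magnitude is made
#' positive; the third axis is the cross product of the first two.
#'
#' @param struct an \code{mdem_structure}.
#' @return list with elements \code{structure} (canonicalized) and
#'   \code{transform} (list \code{R}, \code{t} applied as
#'   \code{coords_new = (coords - t) \%*\% R}).
#' @export
canonicalize_frame <- function(struct) {
  X <- struct$coords
  m <- struct$masses
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  C <- crossprod(Xc * m, Xc) / sum(m)
  e <- eigen(C, symmetric = TRUE)   # descending eigenvalues
  V <- e$vectors
  Y <- Xc %*% V
  for (k in 1:2) {
    i <- which.max(abs(Y[, k]))
    if (Y[i, k] < 0) { V[, k] <- -V[, k]; Y[, k] <- -Y[, k] }
  }
  v3 <- c(V[2, 1] * V[3, 2] - V[3, 1] * V[2, 2],
          V[3, 1] * V[1, 2] - V[1, 1] * V[3, 2],
          V[1, 1] * V[2, 2] - V[2, 1] * V[1, 2])
  V[, 3] <- v3
  Y <- Xc %*% V
  out <- struct
  out$coords <- Y
  list(structure = out, transform = list(R = V, t = com))
}

#' Per-axis radii of gyration
#'
#' The gyradius about each body axis: mass-weighted RMS of the two
#' perpendicular coordinate components, so the smallest value belongs
#' to the longest principal axis.
#'
#' @param struct a canonicalized \code{mdem_structure}.
#' @return numeric length 3 (nm), about x, y, z.
#' @export
gyration_radii <- function(struct) {
  X <- struct$coords
  m <- struct$masses / sum(struct$masses)
  r2 <- colSums((X^2) * m)   # weighted mean square per coordinate
  sqrt(c(r2[2] + r2[3], r2[1] + r2[3], r2[1] + r2[2]))
}

# ---------------------------------------------------------------------------
# Poses and configurations

#' Rigid-body pose
#'
#' @param translation numeric length 3, nm.
#' @param quat unit quaternion; alternatively supply \code{euler} plus
#'   \code{order}.
#' @param euler Euler angles (rad) used when \code{quat} is missing.
#' @param order Euler convention (see \code{\link{euler_to_quat}}).
#' @return object of class \code{mdem_pose}.
#' @export
pose <- function(translation = c(0, 0, 0), quat = NULL, euler = NULL,
                 order = "ZYX") {
  if (is.null(quat)) {
    quat <- if (is.null(euler)) c(1, 0, 0, 0) else euler_to_quat(euler, order)
  }
  quat <- quat_normalize(quat)
  structure(list(t = as.numeric(translation), q = quat), class = "mdem_pose")
}

#' @export
print.mdem_pose <- function(x, ...) {
  cat(sprintf("<mdem_pose t=(%.3f, %.3f, %.3f) q=(%.3f, %.3f, %.3f, %.3f)>\n",
              x$t[1], x$t[2], x$t[3], x$q[1], x$q[2], x$q[3], x$q[4]))
  invisible(x)
}

#' Pose algebra
#'
#' \code{pose_compose(p1, p2)} applies \code{p2} in the frame of
#' \code{p1}; \code{pose_inverse} inverts a pose so that
#' \code{pose_compose(pose_inverse(p), p)} is the identity.
#'
#' @param p1,p2,p poses.
#' @return a pose.
#' @export
pose_compose <- function(p1, p2) {
  pose(translation = p1$t + as.numeric(quat_to_mat(p1$q) %*% p2$t),
       quat = quat_mul(p1$q, p2$q))
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(p) {
  qi <- quat_conj(p$q)
  pose(translation = -as.numeric(quat_to_mat(qi) %*% p$t), quat = qi)
}

#' 6D configuration of molecule B in molecule A's body frame
#'
#' @param x,y,z relative position (nm).
#' @param alpha,beta,gamma relative orientation Euler angles (rad).
#' @param order Euler convention the angles are expressed in.
#' @return named numeric length 6 of class \code{mdem_config} with the
#'   convention stored in attribute \code{"order"}.
#' @export
config <- function(x = 0, y = 0, z = 0, alpha = 0, beta = 0, gamma = 0,
                   order = "ZYX") {
  v <- c(x = x, y = y, z = z,
         alpha = wrap_angle(alpha), beta = wrap_angle(beta),
         gamma = wrap_angle(gamma))
  stopifnot_finite(v, "configuration")
  structure(v, class = "mdem_config", order = order)
}

config_order <- function(cfg) attr(cfg, "order") %||% "ZYX"

#' @rdname config
#' @param cfg an \code{mdem_config}.
#' @return \code{config_to_pose}: the pose of B in A's body frame.
#' @export
config_to_pose <- function(cfg) {
  pose(translation = cfg[1:3], euler = cfg[4:6], order = config_order(cfg))
}

#' @rdname config
#' @param p pose of B relative to A.
#' @export
pose_to_config <- function(p, order = "ZYX") {
  e <- quat_to_euler(p$q, order)
  config(p$t[1], p$t[2], p$t[3], e[1], e[2], e[3], order = order)
}

#' Relative configuration of B in A's body frame
#'
#' @param poseA,poseB lab-frame poses of the two molecules.
#' @param order Euler convention of the result.
#' @return an \code{mdem_config}.
#' @export
relative_config <- function(poseA, poseB, order = "ZYX") {
  pose_to_config(pose_compose(pose_inverse(poseA), poseB), order = order)
}

# Place structure beads (subset sel) at a pose/config; returns k x 3 matrix.
place_beads <- function(struct, p, sel = NULL) {
  X <- struct$coords
  if (!is.null(sel)) X <- X[sel, , drop = FALSE]
  sweep(X %*% t(quat_to_mat(p$q)), 2, p$t, `+`)
}

# ---------------------------------------------------------------------------
# File I/O: XYZ and minimal PDB (first model, ATOM/HETATM records)

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, FE = 55.845, ZN = 65.38)

#' Read a bead structure from XYZ or PDB
#'
#' PDB reading is deliberately minimal: ATOM/HETATM coordinates of the
#' first model, with a name-based backbone selection. XYZ files carry
#' element symbols; masses default to 1 amu for unknown elements.
#'
#' @param path file path.
#' @param format \code{"xyz"}, \code{"pdb"} or \code{"auto"} (by
#'   extension).
#' @param selection backbone policy: \code{"CA"} (alpha carbons, PDB),
#'   \code{"backbone"} (N, CA, C, O) or \code{"all"}.
#' @return an \code{mdem_structure} in file order (not canonicalized).
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb"),
                           selection = "all") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "xyz") .read_xyz(path, selection) else .read_pdb(path, selection)
}

.read_xyz <- function(path, selection) {
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("XYZ parse error at line 1: expected atom count")
  rec <- lines[seq(3, length.out = n)]
  toks <- strsplit(trimws(rec), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 4)
  if (length(bad)) stop("XYZ parse error at line ", bad[1] + 2)
  el <- toupper(vapply(toks, `[`, "", 1))
  xyz <- t(vapply(toks, function(t)
    suppressWarnings(as.numeric(t[2:4])), numeric(3)))
  if (any(!is.finite(xyz))) {
    stop("XYZ parse error at line ",
         which(!is.finite(rowSums(xyz)))[1] + 2, ": bad coordinate")
  }
  masses <- .element_masses[el]
  masses[is.na(masses)] <- 1
  backbone <- if (identical(selection, "all")) rep(TRUE, n)
              else el %in% toupper(selection)
  if (!any(backbone)) stop("empty backbone selection")
  bead_structure(xyz, backbone, masses,
                 name = sub("\\.[^.]*$", "", basename(path)))
}

.read_pdb <- function(path, selection) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  keep <- grep("^(ATOM  |HETATM)", lines)
  if (!length(keep)) stop("PDB parse error: no ATOM/HETATM records")
  at <- lines[keep]
  name <- toupper(trimws(substr(at, 13, 16)))
  xyz <- cbind(suppressWarnings(as.numeric(substr(at, 31, 38))),
               suppressWarnings(as.numeric(substr(at, 39, 46))),
               suppressWarnings(as.numeric(substr(at, 47, 54)))) / 10  # A -> nm
  bad <- which(!is.finite(rowSums(xyz)))
  if (length(bad)) stop("PDB parse error at line ", keep[bad[1]])
  el <- toupper(trimws(substr(at, 77, 78)))
  el[el == ""] <- substr(name[el == ""], 1, 1)
  masses <- .element_masses[el]
  masses[is.na(masses)] <- 1
  backbone <- switch(selection,
                     all = rep(TRUE, length(at)),
                     CA = name == "CA",
                     backbone = name %in% c("N", "CA", "C", "O"),
                     name %in% toupper(selection))
  if (!any(backbone)) stop("empty backbone selection")
  bead_structure(xyz, backbone, masses,
                 name = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_structure
#' @param struct structure to write.
#' @param comment second-line comment.
#' @export
write_xyz <- function(struct, path, comment = struct$name) {
  el <- rep("C", nrow(struct$coords))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(struct$coords)), comment), con)
  writeLines(sprintf("%s %.9f %.9f %.9f", el,
                     struct$coords[, 1], struct$coords[, 2],
                     struct$coords[, 3]), con)
  invisible(path)
}
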