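# Assembly postprocessing: contact classification, structure
# detection, global statistics, size classes, transitions, lifetimes,
# kinetics fitting and the capsid stability surrogate.

#' Classify pair contacts in a frame
#'
#' Structured contacts lie within delta_r <= 1 nm of a known binding
#' configuration; unstructured contacts touch (delta_m <= 0.3 nm) away
#' from binding geometry. The supplied binding configurations should
#' include both orderings (see \code{\link{symmetrize}}); the built-in
#' helper adds the inverses automatically.
#'
#' @param frame list with \code{pos} (n x 3, nm) and \code{quat}
#'   (n x 4).
#' @param struct molecule structure.
#' @param binding list of binding configurations or a k x 6 matrix.
#' @param box periodic box (nm) or NULL for open boundaries.
#' @param dr_structured delta_r threshold (nm), default 1.
#' @param dm_touch delta_m threshold (nm), default 0.3.
#' @param add_inverses also match the inverse configurations (default
#'   TRUE).
#' @param order Euler convention of the binding angles.
#' @return data.frame: i, j, kind, binding (best-match index),
#'   delta_r, delta_m.
#' @export
classify_contacts <- function(frame, struct, binding, box = NULL,
                              dr_structured = 1, dm_touch = 0.3,
                              add_inverses = TRUE, order = "ZYX") {
  cfgs <- .as_config_list(binding, order)
  if (add_inverses) cfgs <- c(cfgs, lapply(cfgs, config_inverse))
  nb <- sum(struct$backbone)
  bf <- vapply(cfgs, function(c0) place_flat(struct, c0), numeric(3 * nb))
  nbind <- length(cfgs) / (if (add_inverses) 2 else 1)
  n <- nrow(frame$pos)
  r_ext <- max(sqrt(rowSums(struct$coords^2)))
  reach <- max(sqrt(colSums(bf[1:3, , drop = FALSE]^0)), 0) # placeholder
  reach <- max(vapply(cfgs, function(c0) sqrt(sum(c0[1:3]^2)), numeric(1)))
  cutoff <- max(reach + dr_structured, 2 * r_ext + dm_touch) + 0.5
  out <- list()
  if (n >= 2) {
    ij <- t(utils::combn(n, 2))
    d <- frame$pos[ij[, 2], , drop = FALSE] -
      frame$pos[ij[, 1], , drop = FALSE]
    if (!is.null(box)) d <- .min_image(d, box)
    keep <- rowSums(d^2) < cutoff^2
    ij <- ij[keep, , drop = FALSE]
    d <- d[keep, , drop = FALSE]
    for (p in seq_len(nrow(ij))) {
      i <- ij[p, 1]; j <- ij[p, 2]
      qi <- frame$quat[i, ]; qj <- frame$quat[j, ]
      qrel <- quat_mul(quat_conj(qi), qj)
      trel <- as.numeric(t(quat_to_mat(qi)) %*% d[p, ])
      e <- quat_to_euler(qrel, "ZYX")
      cfg <- config(trel[1], trel[2], trel[3], e[1], e[2], e[3])
      f <- place_flat(struct, cfg)
      dr <- sqrt(colSums((bf - f)^2) / nb)
      k <- which.min(dr)
      best_dr <- dr[k]
      kbind <- ((k - 1) %% nbind) + 1
      if (best_dr <= dr_structured) {
        out[[length(out) + 1]] <- data.frame(
          i = i, j = j, kind = "structured", binding = kbind,
          delta_r = best_dr,
          delta_m = min_distance(struct, struct, cfg))
      } else {
        dm <- min_distance(struct, struct, cfg)
        if (dm <= dm_touch) {
          out[[length(out) + 1]] <- data.frame(
            i = i, j = j, kind = "unstructured", binding = NA_integer_,
            delta_r = best_dr, delta_m = dm)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), kind = character(),
                      binding = integer(), delta_r = numeric(),
                      delta_m = numeric()))
  }
  do.call(rbind, out)
}

.as_config_list <- function(binding, order = "ZYX") {
  if (is.matrix(binding)) {
    lapply(seq_len(nrow(binding)), function(i) {
      v <- binding[i, ]
      config(v[1], v[2], v[3], v[4], v[5], v[6], order = order)
    })
  } else binding
}

#' Detect self-assembled structures
#'
#' Connected components over the union of structured and unstructured
#' contacts; each component is one self-assembled structure (SAS) with
#' size N_SAS and diameter of gyration d_SAS,gyr = 2 x RMS distance of
#' member centers from the component centroid (minimum-image
#' unwrapped).
#'
#' @param contacts data.frame from \code{\link{classify_contacts}}.
#' @param n_molecules total molecule count.
#' @param pos n x 3 positions (for d_SAS,gyr; optional).
#' @param box periodic box or NULL.
#' @return data.frame: structure id, n_sas, d_gyr, members (list
#'   column).
#' @export
find_structures <- function(contacts, n_molecules, pos = NULL,
                            box = NULL) {
  parent <- seq_len(n_molecules)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    as.integer(x)
  }
  if (nrow(contacts)) {
    for (p in seq_len(nrow(contacts))) {
      a <- find(contacts$i[p]); b <- find(contacts$j[p])
      if (a != b) parent[a] <- b
    }
  }
  comp <- vapply(seq_len(n_molecules), find, integer(1))
  ids <- split(seq_len(n_molecules), comp)
  res <- lapply(seq_along(ids), function(k) {
    mem <- ids[[k]]
    dg <- NA_real_
    if (!is.null(pos)) {
      X <- .unwrap_component(pos, mem, contacts, box)
      ctr <- colMeans(X)
      dg <- 2 * sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
    }
    data.frame(structure = k, n_sas = length(mem), d_gyr = dg)
  })
  out <- do.call(rbind, res)
  out$members <- unname(ids)
  out
}

# Unwrap member positions across the periodic boundary by BFS over the
# component's contact edges.
.unwrap_component <- function(pos, members, contacts, box) {
  X <- pos[members, , drop = FALSE]
  if (is.null(box) || length(members) == 1) return(X)
  loc <- match(seq_len(nrow(pos)), members)
  adj <- lapply(seq_along(members), function(i) integer(0))
  if (nrow(contacts)) {
    for (p in seq_len(nrow(contacts))) {
      a <- loc[contacts$i[p]]; b <- loc[contacts$j[p]]
      if (!is.na(a) && !is.na(b)) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  seen <- rep(FALSE, length(members))
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in adj[[i]]) {
      if (!seen[j]) {
        d <- .min_image(matrix(X[j, ] - X[i, ], 1), box)[1, ]
        X[j, ] <- X[i, ] + d
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  X
}

#' Global assembly statistics
#'
#' xi = 2 x (contact count) / n per kind (average connections per
#' molecule) and the structured fraction
#' Phi = xi_struc / (xi_struc + xi_unstruc).
#'
#' @param contacts classified contacts.
#' @param n_molecules molecule count.
#' @return list: xi_struc, xi_unstruc, phi_struc (NA with no contacts).
#' @export
global_stats <- function(contacts, n_molecules) {
  ns <- sum(contacts$kind == "structured")
  nu <- sum(contacts$kind == "unstructured")
  xi_s <- 2 * ns / n_molecules
  xi_u <- 2 * nu / n_molecules
  phi <- if (ns + nu > 0) xi_s / (xi_s + xi_u) else NA_real_
  list(xi_struc = xi_s, xi_unstruc = xi_u, phi_struc = phi)
}

#' Size class of a structure
#'
#' Sizes 1-5 are their own class; larger sizes map to the decade
#' classes 10, 20, ..., 200 covering c-4 to c+5; sizes of 206 and
#' above fall in class 206.
#'
#' @param N structure sizes (>= 1).
#' @return integer class labels.
#' @export
size_class <- function(N) {
  vapply(N, function(n) {
    if (n <= 5) return(as.integer(n))
    if (n >= 206) return(206L)
    # decade class c covers c-4 .. c+5
    as.integer(((n + 4) %/% 10) * 10)
  }, integer(1))
}

#' Per-dimer size-class transitions
#'
#' For each molecule and consecutive frame pair, one count from its
#' old size class to its new one (diagonal excluded). The gross matrix
#' is normalized by the molecule count; the net matrix sums both
#' directions; the signed difference is also returned.
#'
#' @param class_per_frame list (one per frame) of per-molecule class
#'   labels, or a matrix frames x molecules.
#' @return list: gross, net, signed (matrices with class-labelled
#'   dimnames), classes.
#' @export
transitions <- function(class_per_frame) {
  M <- if (is.matrix(class_per_frame)) class_per_frame
       else do.call(rbind, class_per_frame)
  if (nrow(M) < 2) stop("need at least two frames")
  n_mol <- ncol(M)
  classes <- sort(unique(as.integer(M)))
  k <- length(classes)
  G <- matrix(0, k, k, dimnames = list(classes, classes))
  for (f in seq_len(nrow(M) - 1)) {
    from <- match(M[f, ], classes)
    to <- match(M[f + 1, ], classes)
    ch <- which(from != to)
    for (i in ch) G[from[i], to[i]] <- G[from[i], to[i]] + 1
  }
  G <- G / n_mol
  list(gross = G, net = G + t(G), signed = G - t(G), classes = classes)
}

#' Structure lifetimes across frames
#'
#' Structure identity is propagated by maximum member overlap (> 50%);
#' under a merge the larger parent's identity continues. Lifetime is
#' death minus birth, censored at the end of the trajectory.
#'
#' @param structures_per_frame list (per frame) of
#'   \code{\link{find_structures}} outputs.
#' @param times frame times (ns).
#' @return data.frame: id, birth, death, t_life, censored, max_size.
#' @export
lifetimes <- function(structures_per_frame, times) {
  next_id <- 0L
  live <- list()    # id -> members
  recs <- list()    # id -> list(birth, last, max_size)
  for (f in seq_along(structures_per_frame)) {
    st <- structures_per_frame[[f]]
    new_live <- list()
    used <- character(0)
    ord <- order(-st$n_sas)
    for (r in ord) {
      mem <- st$members[[r]]
      best <- NULL; best_ov <- 0
      for (id in setdiff(names(live), used)) {
        # symmetric overlap: a shrinking fragment does not inherit the
        # parent's identity, the majority part does
        ov <- length(intersect(live[[id]], mem)) /
          max(length(live[[id]]), length(mem))
        if (ov > 0.5 && ov > best_ov) { best <- id; best_ov <- ov }
      }
      if (is.null(best)) {
        next_id <- next_id + 1L
        best <- as.character(next_id)
        recs[[best]] <- list(birth = times[f], last = times[f],
                             max_size = length(mem))
      } else {
        used <- c(used, best)
        recs[[best]]$last <- times[f]
        recs[[best]]$max_size <- max(recs[[best]]$max_size, length(mem))
      }
      new_live[[best]] <- mem
    }
    live <- new_live
  }
  t_end <- times[length(times)]
  do.call(rbind, lapply(names(recs), function(id) {
    r <- recs[[id]]
    censored <- id %in% names(live) || r$last >= t_end
    data.frame(id = as.integer(id), birth = r$birth, death = r$last,
               t_life = r$last - r$birth, censored = censored,
               max_size = r$max_size)
  }))
}

#' Fit asymptotic-exponential assembly kinetics
#'
#' Least squares of \code{N(t) = s + (N0 - s) exp(-t / r)} with N0
#' fixed at the first observation; s is the asymptotic structure size
#' and r the time constant.
#'
#' @param times time points.
#' @param n_sas mean structure size per time point.
#' @param N0 fixed initial value (default the first observation).
#' @return list: s, r, N0, residual (RMS).
#' @export
fit_kinetics <- function(times, n_sas, N0 = n_sas[1]) {
  if (length(times) < 3) stop("need >= 3 time points")
  if (stats::sd(n_sas) < 1e-12) {
    return(list(s = n_sas[1], r = NA_real_, N0 = N0, residual = 0))
  }
  t0 <- times - times[1]
  obj <- function(lr) {
    e <- exp(-t0 / exp(lr))
    # profile s: N = s (1 - e) + N0 e  ->  linear in s
    y <- n_sas - N0 * e
    x <- 1 - e
    s <- sum(x * y) / max(sum(x * x), 1e-300)
    sum((n_sas - (s + (N0 - s) * e))^2)
  }
  span <- max(t0[t0 > 0])
  opt <- stats::optimize(obj, log(c(span * 1e-4, span * 100)))
  r <- exp(opt$minimum)
  e <- exp(-t0 / r)
  y <- n_sas - N0 * e
  x <- 1 - e
  s <- sum(x * y) / max(sum(x * x), 1e-300)
  res <- sqrt(opt$objective / length(t0))
  if (!is.finite(s)) stop("kinetics fit did not converge")
  list(s = s, r = r, N0 = N0, residual = res)
}

#' Capsid stability surrogate
#'
#' Fraction of the reference capsid's structured contacts retained in
#' a frame; a declared surrogate for the production stability
#' objective, bounded in [0, 1].
#'
#' @param frame current frame (pos/quat).
#' @param capsid reference \code{mdem_capsid} fixture.
#' @param box periodic box or NULL.
#' @param binding binding configurations (default the fixture's).
#' @return list: o_stab, retained, reference, definition = "surrogate".
#' @export
stability_objective <- function(frame, capsid,
                                binding = hbcag_constants()$binding,
                                box = NULL) {
  ref_ct <- capsid$contacts
  n_ref <- nrow(ref_ct)
  ct <- classify_contacts(frame, capsid$struct, binding, box = box,
                          order = capsid$convention)
  ct <- ct[ct$kind == "structured", , drop = FALSE]
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  retained <- length(intersect(key(ref_ct), key(ct)))
  list(o_stab = min(1, retained / max(n_ref, 1)), retained = retained,
       reference = n_ref, definition = "surrogate")
}

#' Analyze a trajectory
#'
#' Runs contact classification, structure detection and global
#' statistics on every frame and fits the assembly kinetics.
#'
#' @param traj an \code{mdem_trajectory}.
#' @param struct molecule structure.
#' @param binding binding configurations.
#' @param order Euler convention of the binding table.
#' @return list: per_frame (data.frame), contacts (last frame),
#'   structures (last frame), kinetics, transitions.
#' @export
analyze_trajectory <- function(traj, struct, binding, order = "ZYX") {
  n <- traj$meta$n_molecules %||% nrow(traj$frames[[1]]$pos)
  per <- list()
  class_mat <- NULL
  st_all <- list()
  last_ct <- NULL; last_st <- NULL
  for (f in seq_along(traj$frames)) {
    fr <- traj$frames[[f]]
    ct <- classify_contacts(fr, struct, binding, box = traj$box,
                            order = order)
    st <- find_structures(ct, n, pos = fr$pos, box = traj$box)
    gs <- global_stats(ct, n)
    sizes <- integer(n)
    for (r in seq_len(nrow(st))) sizes[st$members[[r]]] <- st$n_sas[r]
    class_mat <- rbind(class_mat, size_class(sizes))
    st_all[[f]] <- st
    per[[f]] <- data.frame(time = traj$times[f],
                           mean_n_sas = mean(st$n_sas[
                             rep(seq_len(nrow(st)), st$n_sas)]),
                           xi_struc = gs$xi_struc,
                           xi_unstruc = gs$xi_unstruc,
                           phi_struc = gs$phi_struc)
    last_ct <- ct; last_st <- st
  }
  per <- do.call(rbind, per)
  kin <- if (nrow(per) >= 3 && stats::sd(per$mean_n_sas) > 0) {
    tryCatch(fit_kinetics(per$time, per$mean_n_sas),
             error = function(e) NULL)
  } else NULL
  tr <- if (nrow(class_mat) >= 2) transitions(class_mat) else NULL
  list(per_frame = per, contacts = last_ct, structures = last_st,
       kinetics = kin, transitions = tr,
       lifetimes = lifetimes(st_all, traj$times))
}
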