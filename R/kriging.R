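# Universal Kriging of per-component potentials at arbitrary 6D
# configurations: neighborhood search in delta_r, assembly of the UK
# system (variogram block, unbiasedness row, trend-basis rows),
# SVD-regularised solve, and the estimation variance.

#' Fit the full model bundle for a sample set
#'
#' Computes density weights, fits the delta_m trend per component,
#' fills residuals, partitions the interaction range into regions and
#' fits sectional variograms. A component is flagged "kriged" when its
#' residual shows usable spatial correlation (structured sill above
#' \code{min_structure} of the total sill in at least one region);
#' other components fall back to trend-only estimates.
#'
#' @param s an \code{mdem_samples}.
#' @param interaction_range delta_m interaction range (nm).
#' @param n_regions number of variogram sections, default 5.
#' @param kernel_width density-weight kernel width (nm), default 2.
#' @param bin_width,cutoff empirical-variogram binning (nm).
#' @param kriged optional logical named vector overriding the
#'   correlation criterion.
#' @param variogram_override optional \code{mdem_variogram} (or list per
#'   component) used for every region instead of per-region fits; used
#'   by the 2D benchmark where the variogram is determined from the
#'   truth field.
#' @param min_structure structured-sill fraction for the kriged flag.
#' @return an \code{mdem_models} bundle.
#' @export
fit_models <- function(s, interaction_range, n_regions = 5,
                       kernel_width = 2, bin_width = 0.1, cutoff = 4,
                       kriged = NULL, variogram_override = NULL,
                       min_structure = 0.05) {
  s$weight <- density_weights(s, kernel_width)
  comps <- colnames(s$pot)
  # trend/variogram models are generated from oracle data only;
  # inserted virtual points enter the kriging data set but must not
  # distort the statistical models
  oracle_idx <- which(s$provenance == "oracle")
  if (!length(oracle_idx)) oracle_idx <- seq_len(n_samples(s))
  s_fit <- .subset_samples(s, oracle_idx)
  s_fit$weight <- density_weights(s_fit, kernel_width)
  trends <- lapply(comps, function(cp) fit_trend(s_fit, cp))
  names(trends) <- comps
  s <- fill_residuals(s, trends)
  s_fit <- fill_residuals(s_fit, trends)
  regions <- partition_regions(s_fit, n_regions, interaction_range)
  variograms <- list()
  kr <- logical(length(comps))
  names(kr) <- comps
  for (cp in comps) {
    if (!is.null(variogram_override)) {
      vo <- if (inherits(variogram_override, "mdem_variogram"))
        variogram_override else variogram_override[[cp]] %||%
          variogram_override
      if (inherits(vo, "mdem_variogram")) vo <- rep(list(vo), n_regions)
      if (length(vo) != n_regions) {
        stop("variogram override must give one model or one per region")
      }
      variograms[[cp]] <- vo
      kr[cp] <- any(vapply(vo, function(v) v$psill > 0, logical(1)))
      next
    }
    vl <- vector("list", n_regions)
    for (i in seq_len(n_regions)) {
      idx <- regions$selectors[[i]]
      vl[[i]] <- tryCatch({
        bins <- empirical_variogram(s_fit, cp, idx, bin_width, cutoff)
        fit_variogram(bins, region = regions$bounds[i, ])
      }, error = function(e) {
        warning(sprintf("variogram %s region %d: %s; nugget fallback",
                        cp, i, conditionMessage(e)))
        rv <- stats::var(s_fit$res[idx, cp])
        if (!is.finite(rv)) rv <- stats::var(s_fit$res[, cp])
        structure(list(family = "nugget", nugget = rv, psill = 0,
                       range = 1, sse = NA_real_,
                       region = regions$bounds[i, ]),
                  class = "mdem_variogram")
      })
    }
    variograms[[cp]] <- vl
    frac <- vapply(vl, function(v) v$psill / max(v$nugget + v$psill, 1e-300),
                   numeric(1))
    kr[cp] <- any(frac > min_structure)
  }
  if (!is.null(kriged)) kr[names(kriged)] <- kriged
  structure(list(samples = s, components = comps, trends = trends,
                 variograms = variograms, regions = regions,
                 kriged = kr, interaction_range = interaction_range),
            class = "mdem_models")
}

#' Nearest data points in delta_r
#'
#' @param s an \code{mdem_samples}.
#' @param cfg query configuration.
#' @param N neighborhood size; the whole set if fewer points exist.
#' @param candidates optional index subset to search within.
#' @return integer ids ordered by ascending delta_r (ties by id).
#' @export
find_neighborhood <- function(s, cfg, N, candidates = NULL) {
  if (n_samples(s) < 1) stop("empty sample set")
  d <- delta_r_to(s, cfg)
  if (!is.null(candidates)) {
    o <- candidates[order(d[candidates], candidates)]
    return(o[seq_len(min(N, length(o)))])
  }
  order(d, seq_along(d))[seq_len(min(N, length(d)))]
}

#' Assemble the Universal Kriging system
#'
#' Builds the (N+M+1) square system: variogram block, unbiasedness
#' ones row/column, trend-basis rows/columns and a zero lower-right
#' block. Variogram entries are normalized by the sill and basis
#' entries by their maximum magnitude over the neighborhood, which
#' keeps all matrix blocks at order one.
#'
#' @param s sample set.
#' @param ids neighborhood indices.
#' @param trend component trend model (supplies the basis functions).
#' @param vario region variogram model.
#' @param cfg query configuration.
#' @param dm_query query delta_m (computed if missing).
#' @return list with the matrix \code{A}, right-hand side \code{b} and
#'   the normalization scales.
#' @export
assemble_uk_system <- function(s, ids, trend, vario, cfg,
                               dm_query = NULL) {
  n <- length(ids)
  if (n < 1) stop("empty neighborhood")
  if (is.null(dm_query)) {
    dm_query <- min_distance(s$structA, s$structB, cfg)
  }
  P <- s$placed[ids, , drop = FALSE]
  Dij <- as.matrix(stats::dist(P)) / sqrt(s$nb)
  dq <- delta_r_to(s, cfg)[ids]
  sill <- vario$nugget + vario$psill
  sc_g <- if (sill > 1e-300) sill else 1
  G <- vario_eval(vario, Dij) / sc_g
  diag(G) <- 0                       # exact zeros on self-distances
  gq <- ifelse(dq < 1e-12, 0, vario_eval(vario, dq)) / sc_g
  basis <- NULL
  sc_f <- numeric(0)
  if (trend$family != "constant") {
    g <- .trend_families[[trend$family]]$g
    fvals <- g(s$delta_m[ids], trend$theta)
    # no basis extrapolation beyond the neighborhood's delta_m support:
    # an exploding basis value at an unsampled delta_m would force
    # explosive weights through the universality constraint
    fq <- min(max(g(dm_query, trend$theta), min(fvals)), max(fvals))
    sc_f <- max(abs(c(fvals, fq)), 1e-300)
    basis <- rbind(fvals / sc_f)
    fq <- fq / sc_f
  } else fq <- numeric(0)
  m <- nrow(basis %||% matrix(nrow = 0, ncol = 0))
  A <- matrix(0, n + m + 1, n + m + 1)
  A[1:n, 1:n] <- G
  A[1:n, n + 1] <- 1
  A[n + 1, 1:n] <- 1
  if (m > 0) {
    A[1:n, (n + 2):(n + 1 + m)] <- t(basis)
    A[(n + 2):(n + 1 + m), 1:n] <- basis
  }
  b <- c(gq, 1, fq)
  list(A = A, b = b, n = n, m = m, sc_g = sc_g, sc_f = sc_f)
}

#' Solve a UK system by SVD with condition cutoff
#'
#' Singular values below \code{max(sv)/1e6} are discarded
#' (double-precision pseudo-inverse), which resolves the
#' ill-conditioning of Gaussian variograms near zero lag. Lagrange
#' multipliers are de-normalized so the estimation variance can be
#' evaluated with the raw variogram and basis functions.
#'
#' @param sys system from \code{\link{assemble_uk_system}}.
#' @param sv_ratio singular-value cutoff ratio, default 1e6.
#' @return list \code{weights} (sum to one), \code{lambda}
#'   (de-normalized multipliers, constant first).
#' @export
solve_uk <- function(sys, sv_ratio = 1e6) {
  sv <- svd(sys$A)
  keep <- sv$d > max(sv$d) / sv_ratio
  if (!any(keep)) stop("UK system numerically zero: all singular values cut")
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], sys$b)) / sv$d[keep])
  w <- x[seq_len(sys$n)]
  lam <- x[-seq_len(sys$n)]
  # de-normalize: gamma was scaled by 1/sc_g, basis rows by 1/sc_f
  lam[1] <- lam[1] * sys$sc_g
  if (sys$m > 0) {
    lam[-1] <- lam[-1] * sys$sc_g / sys$sc_f
  }
  list(weights = as.numeric(w), lambda = as.numeric(lam))
}

#' Universal Kriging estimate at a configuration
#'
#' Per-component best linear unbiased estimate and estimation variance.
#' Kriged components use the UK weights over the \code{N_pot}
#' neighborhood (estimate) and the \code{N_var} neighborhood
#' (variance); components without usable spatial correlation use the
#' trend value. The total is the superposition of all components.
#'
#' @param models an \code{mdem_models} bundle.
#' @param cfg query configuration.
#' @param N_pot neighborhood size for the potential estimate
#'   (production default 500; desk-scale problems use less).
#' @param N_var neighborhood size for the variance (default 100).
#' @param compute_variance set \code{FALSE} to skip the variance solve.
#' @return an \code{mdem_kriging_result}: per-component estimates,
#'   variances, total, weights, multipliers and neighborhood ids.
#' @export
uk_estimate <- function(models, cfg, N_pot = 100, N_var = 100,
                        compute_variance = TRUE) {
  s <- models$samples
  dmq <- min_distance(s$structA, s$structB, cfg)
  if (dmq > models$interaction_range) {
    warning("query beyond interaction range; trend asymptote used")
    est <- vapply(models$components, function(cp)
      trend_eval(models$trends[[cp]], dmq), numeric(1))
    return(structure(list(
      components = est, total = sum(est),
      variance = stats::setNames(rep(0, length(est)), models$components),
      weights = NULL, lambda = NULL, ids = integer(0), delta_m = dmq),
      class = "mdem_kriging_result"))
  }
  reg <- region_of(models$regions, dmq)
  # sectional stationarity: the neighborhood is drawn from the query's
  # delta_m region and its adjacent regions, the domain on which the
  # region's variogram was fitted
  nb_reg <- nrow(models$regions$bounds)
  lo <- models$regions$bounds[max(1, reg - 1), "lo"]
  hi <- models$regions$bounds[min(nb_reg, reg + 1), "hi"]
  cand <- which(s$delta_m >= lo &
                  (s$delta_m <= hi | reg >= nb_reg - 1))
  if (length(cand) < 2) cand <- NULL
  ids <- find_neighborhood(s, cfg, N_pot, candidates = cand)
  est <- numeric(length(models$components))
  names(est) <- models$components
  varc <- est
  w_out <- NULL; lam_out <- NULL
  for (cp in models$components) {
    tr <- models$trends[[cp]]
    if (!models$kriged[[cp]]) {
      est[cp] <- trend_eval(tr, dmq)
      varc[cp] <- 0
      next
    }
    vr <- models$variograms[[cp]][[reg]]
    sys <- assemble_uk_system(s, ids, tr, vr, cfg, dm_query = dmq)
    sol <- solve_uk(sys)
    est[cp] <- sum(sol$weights * s$pot[ids, cp])
    w_out <- sol$weights; lam_out <- sol$lambda
    if (compute_variance) {
      if (N_var == N_pot) {
        idv <- ids; sysv <- sys; solv <- sol
      } else {
        idv <- find_neighborhood(s, cfg, N_var, candidates = cand)
        sysv <- assemble_uk_system(s, idv, tr, vr, cfg, dm_query = dmq)
        solv <- solve_uk(sysv)
      }
      dq <- delta_r_to(s, cfg)[idv]
      gq <- ifelse(dq < 1e-12, 0, vario_eval(vr, dq))
      fq <- 1
      if (tr$family != "constant") {
        fq <- c(1, .trend_families[[tr$family]]$g(dmq, tr$theta))
      }
      v <- sum(solv$weights * gq) + sum(solv$lambda * fq)
      varc[cp] <- max(v, 0)   # numerical noise floored at zero
    }
  }
  structure(list(components = est, total = sum(est), variance = varc,
                 weights = w_out, lambda = lam_out, ids = ids,
                 delta_m = dmq),
            class = "mdem_kriging_result")
}

#' @export
print.mdem_kriging_result <- function(x, ...) {
  cat(sprintf("<kriging estimate: total %.3f kJ/mol (delta_m %.3f nm)>\n",
              x$total, x$delta_m))
  invisible(x)
}

# Batch estimation over a configuration matrix; returns estimate and
# variance vectors (totals). Used by grid construction.
uk_estimate_batch <- function(models, configs, N_pot = 100, N_var = 100,
                              compute_variance = TRUE) {
  n <- nrow(configs)
  est <- numeric(n); va <- numeric(n)
  for (i in seq_len(n)) {
    v <- configs[i, ]
    cfg <- config(v[1], v[2], v[3], v[4], v[5], v[6],
                  order = models$samples$order)
    r <- suppressWarnings(
      uk_estimate(models, cfg, N_pot, N_var, compute_variance))
    est[i] <- r$total
    va[i] <- sum(r$variance)
  }
  list(estimate = est, variance = va)
}
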