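# Trend models over the minimum distance delta_m and sectional residual
# variograms over the configuration distance delta_r.
#
# The interaction potential of each component is decomposed into a
# systematic trend mu(delta_m) -- a linear combination of a constant
# and one decaying basic function chosen by weighted R^2 -- plus a
# spatially correlated residual whose continuity is modeled by
# variograms fitted separately in delta_m regions (sections), because
# the residual process is only approximately stationary within a
# section.

# --- trend basis families ---------------------------------------------------
# Each family contributes one basic function g(delta_m; theta) used as
# mu = b0 + b1 * g. theta is profiled by 1D optimization.

.trend_families <- list(
  constant    = list(np = 0, g = function(dm, th) NULL),
  gaussian    = list(np = 1, g = function(dm, th) exp(-dm^2 / (2 * th^2)),
                     lo = 0.05, hi = 10),
  exponential = list(np = 1, g = function(dm, th) exp(-dm / th),
                     lo = 0.05, hi = 10),
  power1      = list(np = 1, g = function(dm, th) 1 / (dm + th),
                     lo = 0.01, hi = 5),
  power6      = list(np = 1, g = function(dm, th) 1 / (dm + th)^6,
                     lo = 0.05, hi = 5),
  power12     = list(np = 1, g = function(dm, th) 1 / (dm + th)^12,
                     lo = 0.1, hi = 5)
)

#' Density weights against sampling heterogeneity
#'
#' Inverse Gaussian-kernel density in delta_r:
#' \code{w_i = 1 / sum_j exp(-delta_r(i,j)^2 / (2 h^2))} (the self term
#' contributes 1), so points in densely sampled regions are
#' down-weighted in trend fitting.
#'
#' @param s an \code{mdem_samples} (or a precomputed delta_r matrix).
#' @param kernel_width kernel width h in nm, default 2.
#' @return positive weights, one per point.
#' @export
density_weights <- function(s, kernel_width = 2) {
  if (kernel_width <= 0) stop("kernel_width must be positive")
  D <- if (is.matrix(s)) s else delta_r_matrix(s)
  1 / rowSums(exp(-D^2 / (2 * kernel_width^2)))
}

# Full pairwise delta_r matrix via the flattened-placement embedding.
delta_r_matrix <- function(s, idx = NULL) {
  P <- if (is.null(idx)) s$placed else s$placed[idx, , drop = FALSE]
  as.matrix(stats::dist(P)) / sqrt(s$nb)
}

#' Fit a delta_m trend model for one potential component
#'
#' Weighted least squares of \code{U = b0 + b1 g(delta_m; theta)} for
#' each candidate basis family; the family with the best weighted R^2
#' wins. The constant basis is always included.
#'
#' @param s an \code{mdem_samples} with \code{weight} set (see
#'   \code{\link{density_weights}}).
#' @param component column name in \code{s$pot}.
#' @param families candidate family names (see Details in the package
#'   vignette); default all.
#' @return an \code{mdem_trend}: family, theta, coefficients, R^2 and
#'   the valid delta_m range.
#' @export
fit_trend <- function(s, component, families = names(.trend_families)) {
  dm <- s$delta_m
  u <- s$pot[, component]
  w <- s$weight
  rng <- c(0, max(dm))
  wls <- function(X) {
    fit <- stats::lm.wfit(X, u, w)
    sse <- sum(w * fit$residuals^2)
    list(coef = fit$coefficients, sse = sse)
  }
  wmean <- sum(w * u) / sum(w)
  sst <- sum(w * (u - wmean)^2)
  best <- list(family = "constant", theta = NA_real_,
               coef = c(b0 = wmean, b1 = 0),
               sse = sst)
  for (fam in setdiff(families, "constant")) {
    f <- .trend_families[[fam]]
    if (is.null(f)) stop("unknown trend family: ", fam)
    obj <- function(lth) {
      g <- f$g(dm, exp(lth))
      X <- cbind(1, g)
      if (qr(X)$rank < 2) return(sst * 2)
      wls(X)$sse
    }
    opt <- tryCatch(stats::optimize(obj, log(c(f$lo, f$hi))),
                    error = function(e) NULL)
    if (is.null(opt)) next
    # polish the profiled scale parameter on a narrow bracket
    opt2 <- tryCatch(stats::optimize(obj, opt$minimum + c(-0.3, 0.3),
                                     tol = 1e-12),
                     error = function(e) opt)
    if (opt2$objective <= opt$objective) opt <- opt2
    th <- exp(opt$minimum)
    X <- cbind(1, f$g(dm, th))
    if (qr(X)$rank < 2) next
    ft <- wls(X)
    if (ft$sse < best$sse) {
      best <- list(family = fam, theta = th,
                   coef = c(b0 = ft$coef[1], b1 = ft$coef[2]), sse = ft$sse)
    }
  }
  r2 <- if (sst < 1e-12) {
    if (best$sse < 1e-9) 1 else 0
  } else 1 - best$sse / sst
  structure(list(component = component, family = best$family,
                 theta = best$theta, coef = unname(best$coef), r2 = r2,
                 range = rng),
            class = "mdem_trend")
}

#' Evaluate a trend model
#'
#' @param trend an \code{mdem_trend}.
#' @param dm minimum distances (nm); beyond the fitted range the
#'   decaying basis provides the asymptote.
#' @return trend values mu(delta_m) in kJ/mol.
#' @export
trend_eval <- function(trend, dm) {
  if (trend$family == "constant") return(rep(trend$coef[1], length(dm)))
  g <- .trend_families[[trend$family]]$g(dm, trend$theta)
  trend$coef[1] + trend$coef[2] * g
}

#' Fill per-component residuals
#'
#' Stores \code{R_i = U_i - mu(delta_m_i)} for each fitted component.
#'
#' @param s an \code{mdem_samples}.
#' @param trends named list of \code{mdem_trend} (one per component).
#' @return the sample set with \code{res} populated.
#' @export
fill_residuals <- function(s, trends) {
  res <- s$pot
  for (comp in colnames(s$pot)) {
    tr <- trends[[comp]]
    if (is.null(tr)) next
    res[, comp] <- s$pot[, comp] - trend_eval(tr, s$delta_m)
  }
  s$res <- res
  s
}

#' Partition the interaction range into delta_m regions
#'
#' Contiguous equal-width intervals over [0, interaction range]; the
#' per-region sample selector also includes the adjacent regions, which
#' restores approximate stationarity at region boundaries.
#'
#' @param s an \code{mdem_samples}.
#' @param n_regions number of regions, default 5.
#' @param interaction_range upper delta_m bound (nm); default the
#'   sample maximum.
#' @return an \code{mdem_regions}: bounds matrix and selector indices.
#' @export
partition_regions <- function(s, n_regions = 5,
                              interaction_range = max(s$delta_m)) {
  if (n_regions < 1) stop("n_regions must be >= 1")
  edges <- seq(0, interaction_range, length.out = n_regions + 1)
  bounds <- cbind(lo = edges[-(n_regions + 1)], hi = edges[-1])
  sel <- vector("list", n_regions)
  for (i in seq_len(n_regions)) {
    lo <- bounds[max(1, i - 1), "lo"]
    hi <- bounds[min(n_regions, i + 1), "hi"]
    inc <- which(s$delta_m >= lo & s$delta_m <= hi)
    own <- which(s$delta_m >= bounds[i, "lo"] & s$delta_m <= bounds[i, "hi"])
    if (!length(own)) {
      warning(sprintf("region %d [%0.2f, %0.2f] nm empty; selector widened",
                      i, bounds[i, "lo"], bounds[i, "hi"]))
    }
    sel[[i]] <- inc
  }
  structure(list(bounds = bounds, selectors = sel,
                 interaction_range = interaction_range),
            class = "mdem_regions")
}

# Region index for a query delta_m: containing interval; outside the
# interaction range, the nearest region (center rule).
region_of <- function(regions, dm) {
  b <- regions$bounds
  i <- findInterval(dm, c(b[, "lo"], b[nrow(b), "hi"]),
                    rightmost.closed = TRUE)
  pmin(pmax(i, 1L), nrow(b))
}

#' Binned empirical variogram of residuals
#'
#' Semivariance \code{0.5 (R_i - R_j)^2} of all point pairs in the
#' selector, binned over delta_r.
#'
#' @param s an \code{mdem_samples} with residuals filled.
#' @param component component name.
#' @param idx point indices (a region selector); default all points.
#' @param bin_width delta_r bin width (nm), default 0.1.
#' @param cutoff maximum pair distance (nm), default 4.
#' @return data.frame with bin \code{center}, \code{gamma} (kJ^2/mol^2),
#'   \code{sd} and pair count \code{n}; empty bins dropped.
#' @export
empirical_variogram <- function(s, component, idx = NULL, bin_width = 0.1,
                                cutoff = 4) {
  if (is.null(s$res)) stop("residuals not filled; call fill_residuals()")
  if (is.null(idx)) idx <- seq_len(n_samples(s))
  if (length(idx) < 2) stop("need at least two points for a variogram")
  D <- stats::dist(s$placed[idx, , drop = FALSE]) / sqrt(s$nb)
  r <- s$res[idx, component]
  n <- length(idx)
  ii <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  jj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  h <- as.numeric(D)
  keep <- h <= cutoff
  h <- h[keep]
  sv <- 0.5 * (r[ii[keep]] - r[jj[keep]])^2
  bin <- pmin(floor(h / bin_width), ceiling(cutoff / bin_width) - 1)
  agg_m <- tapply(sv, bin, mean)
  agg_s <- tapply(sv, bin, stats::sd)
  agg_n <- tapply(sv, bin, length)
  centers <- (as.numeric(names(agg_m)) + 0.5) * bin_width
  out <- data.frame(center = centers, gamma = as.numeric(agg_m),
                    sd = as.numeric(agg_s), n = as.numeric(agg_n))
  out$sd[is.na(out$sd)] <- out$gamma[is.na(out$sd)]
  out[order(out$center), , drop = FALSE]
}

# --- variogram families -----------------------------------------------------
# gamma(h) = nugget + psill * f(h/range), with f the unit structure:
#   nugget:      f = 0 (pure noise)
#   spherical:   f = 1.5u - 0.5u^3 for u < 1, else 1
#   exponential: f = 1 - exp(-u)
#   gaussian:    f = 1 - exp(-u^2)
# gamma(0) is the nugget by right-limit convention; the kriging system
# places exact zeros on self-distances.

.vario_unit <- function(family, u) {
  switch(family,
         nugget = u * 0,
         spherical = ifelse(u < 1, 1.5 * u - 0.5 * u^3, 1),
         exponential = 1 - exp(-u),
         gaussian = 1 - exp(-u^2),
         stop("unknown variogram family: ", family))
}

#' Evaluate a variogram model
#'
#' @param v an \code{mdem_variogram}.
#' @param h delta_r lags (nm); \code{gamma(0)} returns the nugget
#'   (right limit).
#' @return semivariances (kJ^2/mol^2).
#' @export
vario_eval <- function(v, h) {
  v$nugget + v$psill * .vario_unit(v$family, h / v$range)
}

#' Fit a variogram model to binned semivariances
#'
#' Weighted least squares with per-bin weights \code{1/sd^2} (the bin
#' standard deviation is the uncertainty); the best family by weighted
#' SSE wins. If every parametric fit fails, a pure-nugget model at the
#' empirical variance is returned with a warning.
#'
#' @param bins output of \code{\link{empirical_variogram}}.
#' @param families candidate families, default nugget, spherical,
#'   exponential, gaussian.
#' @param region optional delta_m bounds stored on the model.
#' @return an \code{mdem_variogram}: family, nugget, psill (sill minus
#'   nugget), range.
#' @export
fit_variogram <- function(bins,
                          families = c("nugget", "spherical",
                                       "exponential", "gaussian"),
                          region = c(0, Inf)) {
  if (nrow(bins) < 3) stop("need >= 3 non-empty bins to fit a variogram")
  h <- bins$center
  g <- bins$gamma
  n <- if (!is.null(bins$n)) bins$n else rep(1, nrow(bins))
  # uncertainty of the bin mean: sd / sqrt(n), floored so sparse or
  # accidentally tight bins cannot dominate the fit
  sdv <- pmax(bins$sd, 0.05 * max(g, 1e-12), 1e-300)
  w <- n / sdv^2
  best <- NULL
  for (fam in families) {
    if (fam == "nugget") {
      n0 <- sum(w * g) / sum(w)
      sse <- sum(w * (g - n0)^2)
      cand <- list(family = "nugget", nugget = max(n0, 0), psill = 0,
                   range = 1, sse = sse)
    } else {
      obj <- function(p) {
        nug <- exp(p[1]); ps <- exp(p[2]); rg <- exp(p[3])
        sum(w * (g - (nug + ps * .vario_unit(fam, h / rg)))^2)
      }
      gmax <- max(g); g0 <- max(g[1], 1e-8 * gmax)
      starts <- list(
        log(c(max(g0 / 2, 1e-8 * gmax), max(gmax - g0 / 2, 1e-6 * gmax),
              max(h) / 3)),
        log(c(1e-6 * gmax, gmax, max(h) / 6)))
      fits <- lapply(starts, function(s0)
        tryCatch(stats::optim(s0, obj, method = "Nelder-Mead",
                              control = list(maxit = 2000, reltol = 1e-12)),
                 error = function(e) NULL))
      fits <- Filter(Negate(is.null), fits)
      if (!length(fits)) next
      ft <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
      p <- exp(ft$par)
      cand <- list(family = fam, nugget = p[1], psill = p[2], range = p[3],
                   sse = ft$value)
    }
    if (is.null(best) || cand$sse < best$sse) best <- cand
  }
  if (is.null(best)) {
    warning("all variogram fits failed; pure-nugget fallback")
    best <- list(family = "nugget", nugget = stats::var(g), psill = 0,
                 range = 1, sse = NA_real_)
  }
  structure(c(best, list(region = region)), class = "mdem_variogram")
}

#' @export
print.mdem_variogram <- function(x, ...) {
  cat(sprintf("<mdem_variogram %s: nugget=%.3g sill=%.3g range=%.3g nm>\n",
              x$family, x$nugget, x$nugget + x$psill, x$range))
  invisible(x)
}

#' Serialize trend and variogram models to JSON
#'
#' @param models a model bundle from \code{\link{fit_models}}.
#' @param path output path.
#' @export
write_models_json <- function(models, path) {
  strip <- function(x) lapply(unclass(x), function(e)
    if (is.function(e)) NULL else e)
  out <- list(
    components = models$components, kriged = models$kriged,
    interaction_range = models$interaction_range,
    regions = models$regions$bounds,
    trends = lapply(models$trends, strip),
    variograms = lapply(models$variograms, function(vr) lapply(vr, strip)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
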