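# Oracle contract, initial random sampling, and the supervised
# iterative-refinement loop with convergence tracking.

#' Construct a sampling oracle
#'
#' An oracle is the stand-in for pairwise MD production runs: it
#' evaluates per-component potentials (kJ/mol) at 6D configurations,
#' rejecting colliding ones (NA rows), and declares its component list,
#' interaction range and collision rule. \code{draw(n)} proposes
#' admissible configurations for the systematic random strategy.
#'
#' @param evaluate function(configs matrix) -> n x P matrix (NA rows
#'   mark rejections).
#' @param components component names.
#' @param interaction_range declared delta_m range (nm).
#' @param d_coll collision threshold (nm).
#' @param structA,structB canonicalized structures.
#' @param symmetric TRUE when A and B are the same species (each
#'   evaluation yields two data points by symmetrization).
#' @param draw function(n) -> n x 6 configuration matrix.
#' @param ... extra fields stored on the oracle.
#' @return an \code{mdem_oracle}.
#' @export
make_oracle <- function(evaluate, components, interaction_range, d_coll,
                        structA, structB, symmetric, draw, ...) {
  structure(list(evaluate = evaluate, components = components,
                 interaction_range = interaction_range, d_coll = d_coll,
                 structA = structA, structB = structB,
                 symmetric = symmetric, draw = draw, ...),
            class = "mdem_oracle")
}

#' Initial systematic random sampling
#'
#' Draws admissible configurations, evaluates the oracle (rejections
#' are retried), and symmetrizes for identical species so each
#' evaluation yields two data points.
#'
#' @param oracle an \code{mdem_oracle}.
#' @param n number of oracle evaluations.
#' @param max_reject_rounds retry budget for rejected draws.
#' @return an \code{mdem_samples}.
#' @export
initial_sample <- function(oracle, n, max_reject_rounds = 100) {
  configs <- NULL
  pots <- NULL
  tried <- 0
  rounds <- 0
  need <- n
  while (need > 0) {
    rounds <- rounds + 1
    if (rounds > max_reject_rounds) {
      stop("oracle acceptance rate too low; widen the sampling bounds")
    }
    cf <- oracle$draw(need)
    pv <- oracle$evaluate(cf)
    ok <- stats::complete.cases(pv)
    tried <- tried + need
    configs <- rbind(configs, cf[ok, , drop = FALSE])
    pots <- rbind(pots, pv[ok, , drop = FALSE])
    need <- n - nrow(configs)
    if (tried > 100 * n && nrow(configs) < 0.01 * tried) {
      stop("oracle acceptance rate below 1%; widen the sampling bounds")
    }
  }
  if (oracle$symmetric) {
    inv <- t(apply(configs, 1, function(v)
      as.numeric(config_inverse(config(v[1], v[2], v[3], v[4], v[5], v[6])))))
    configs <- rbind(configs, inv)
    pots <- rbind(pots, pots)
  }
  sample_set(configs, pots, oracle$structA, oracle$structB)
}

#' Refinement configuration
#'
#' @param iterations number of refinement iterations.
#' @param per_iteration oracle evaluations per iteration.
#' @param criteria criterion schedule, recycled over iterations:
#'   \code{"variance"}, \code{"normalized_variance"} or
#'   \code{"extrema"}. The default phases variance-type criteria first
#'   and extrema last.
#' @param spacing minimum delta_r between new samples (nm).
#' @return a \code{mdem_refine_config}.
#' @export
refinement_config <- function(iterations = 8, per_iteration = 10,
                              criteria = NULL, spacing = 0.2) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (per_iteration < 1) stop("per_iteration must be >= 1")
  if (is.null(criteria)) {
    n_var <- ceiling(iterations * 2 / 3)
    criteria <- c(rep("normalized_variance", n_var),
                  rep("extrema", iterations - n_var))
  }
  criteria <- rep_len(criteria, max(iterations, 1))
  structure(list(iterations = iterations, per_iteration = per_iteration,
                 criteria = criteria, spacing = spacing),
            class = "mdem_refine_config")
}

#' Score grid cells for resampling
#'
#' Ranks candidate grid nodes under one of the three resampling
#' criteria: estimation variance, normalized estimation variance
#' (sigma^2 / (|U| + eps)), or extrema (union of local minima/maxima
#' of U and maxima of |grad U|, ranked by magnitude). Selected nodes
#' are mutually at least \code{spacing} apart in delta_r; with a flat
#' criterion the selection falls back to uniform random cells.
#'
#' @param grid an \code{mdem_grid} with value and variance arrays.
#' @param criterion \code{"variance"}, \code{"normalized_variance"} or
#'   \code{"extrema"}.
#' @param k number of configurations to select.
#' @param spacing minimum mutual delta_r (nm).
#' @param structB structure used for the delta_r spacing metric.
#' @param eps normalization floor (kJ/mol).
#' @return matrix of k (or fewer, with a warning) configurations.
#' @export
score_resampling <- function(grid, criterion, k, spacing = 0.2,
                             structB = NULL, eps = 1) {
  cand <- which(!grid$mask)
  if (!length(cand)) stop("no unmasked grid cells to score")
  U <- grid$value[cand]
  V <- if (is.null(grid$variance)) rep(0, length(cand)) else grid$variance[cand]
  score <- switch(criterion,
    variance = V,
    normalized_variance = V / (abs(U) + eps),
    extrema = {
      ex <- .grid_extrema(grid)
      s <- rep(0, length(grid$value))
      s[ex$idx] <- ex$score
      s[cand]
    },
    stop("unknown criterion: ", criterion))
  if (max(score) - min(score) < 1e-12) {
    ord <- sample(length(cand))   # flat criterion: uniform fallback
  } else {
    ord <- order(score, decreasing = TRUE)
  }
  configs <- grid_node_configs(grid, cand[ord])
  nb <- if (is.null(structB)) 1 else sum(structB$backbone)
  chosen <- matrix(numeric(0), 0, 6)
  chosen_flat <- NULL
  for (i in seq_len(nrow(configs))) {
    v <- configs[i, ]
    f <- if (is.null(structB)) v[1:3] else
      place_flat(structB, config(v[1], v[2], v[3], v[4], v[5], v[6]))
    if (!is.null(chosen_flat)) {
      d <- sqrt(colSums((t(chosen_flat) - f)^2) / nb)
      if (min(d) < spacing) next
    }
    chosen <- rbind(chosen, v)
    chosen_flat <- rbind(chosen_flat, f)
    if (nrow(chosen) == k) break
  }
  if (nrow(chosen) < k) {
    warning(sprintf("only %d of %d candidates satisfy the spacing",
                    nrow(chosen), k))
  }
  unname(chosen)
}

# Local extrema of U and maxima of |grad U| on the grid, with a
# magnitude score. Axis-wise neighbor comparison.
.grid_extrema <- function(grid) {
  dims <- vapply(grid$axes, `[[`, numeric(1), "n")
  U <- array(grid$value, dim = dims)
  nd <- length(dims)
  idx_all <- integer(0); score_all <- numeric(0)
  gmax <- array(0, dim = dims)
  is_min <- array(TRUE, dim = dims)
  is_max <- array(TRUE, dim = dims)
  for (d in which(dims > 1)) {
    lo <- .shift_array(U, d, -1L, grid$axes[[d]]$periodic)
    hi <- .shift_array(U, d, +1L, grid$axes[[d]]$periodic)
    is_min <- is_min & (U <= lo) & (U <= hi)
    is_max <- is_max & (U >= lo) & (U >= hi)
    g <- abs(hi - lo) / (2 * grid$axes[[d]]$step)
    gmax <- pmax(gmax, g)
  }
  gm_peak <- array(TRUE, dim = dims)
  for (d in which(dims > 1)) {
    lo <- .shift_array(gmax, d, -1L, grid$axes[[d]]$periodic)
    hi <- .shift_array(gmax, d, +1L, grid$axes[[d]]$periodic)
    gm_peak <- gm_peak & (gmax >= lo) & (gmax >= hi)
  }
  sel <- which((is_min | is_max | gm_peak) & !array(grid$mask, dim = dims))
  sc <- pmax(abs(U[sel]), gmax[sel])
  list(idx = sel, score = sc)
}

# Shift an array along dimension d; replicate edges unless periodic.
.shift_array <- function(A, d, by, periodic = FALSE) {
  n <- dim(A)[d]
  i <- seq_len(n) + by
  if (periodic) i <- ((i - 1) %% n) + 1 else i <- pmin(pmax(i, 1), n)
  idx <- rep(list(quote(expr = )), length(dim(A)))
  idx[[d]] <- i
  do.call(`[`, c(list(A), idx, list(drop = FALSE)))
}

#' Supervised iterative refinement
#'
#' Each iteration re-fits the trend (and, unless a variogram override
#' is supplied, the sectional variograms), rebuilds the potential and
#' variance grids, scores the scheduled criterion, evaluates the
#' oracle at the selected configurations and appends the (symmetrized)
#' points. The trace records per-iteration potential change and
#' variance summaries over unmasked cells.
#'
#' @param oracle an \code{mdem_oracle}.
#' @param samples initial \code{mdem_samples}.
#' @param rc a \code{\link{refinement_config}}.
#' @param axes grid axis specs (see \code{\link{grid_axes}}).
#' @param N_pot,N_var kriging neighborhood sizes.
#' @param variogram_override fixed variogram model (see
#'   \code{\link{fit_models}}).
#' @param n_regions variogram sections.
#' @return list \code{samples}, \code{grid}, \code{models},
#'   \code{trace} (data.frame).
#' @export
refine <- function(oracle, samples, rc, axes, N_pot = 100, N_var = 100,
                   variogram_override = NULL, n_regions = 5) {
  build <- function(s) {
    models <- fit_models(s, oracle$interaction_range,
                         n_regions = n_regions,
                         variogram_override = variogram_override)
    grid <- build_grid(models, axes, N_pot = N_pot, N_var = N_var)
    list(models = models, grid = grid)
  }
  cur <- build(samples)
  trace <- NULL
  if (rc$iterations > 0) {
    for (it in seq_len(rc$iterations)) {
      crit <- rc$criteria[it]
      # keep the oracle's collision rule out of the candidate set
      gscore <- cur$grid
      if (!is.null(gscore$delta_m) && oracle$d_coll > 0) {
        gscore$mask <- gscore$mask | (gscore$delta_m < oracle$d_coll)
      }
      new_cf <- score_resampling(gscore, crit, rc$per_iteration,
                                 spacing = rc$spacing,
                                 structB = samples$structB)
      pv <- oracle$evaluate(new_cf)
      ok <- stats::complete.cases(pv)
      if (!all(ok)) {
        warning(sprintf("iteration %d: %d selected configs rejected",
                        it, sum(!ok)))
      }
      new_cf <- new_cf[ok, , drop = FALSE]
      pv <- pv[ok, , drop = FALSE]
      if (nrow(new_cf)) {
        if (oracle$symmetric) {
          inv <- t(apply(new_cf, 1, function(v) as.numeric(
            config_inverse(config(v[1], v[2], v[3], v[4], v[5], v[6])))))
          new_cf <- rbind(new_cf, inv)
          pv <- rbind(pv, pv)
        }
        add <- sample_set(new_cf, pv, oracle$structA, oracle$structB)
        samples <- append_samples(samples, add)
      }
      nxt <- tryCatch(build(samples), error = function(e) {
        warning("iteration ", it, " aborted: ", conditionMessage(e))
        NULL
      })
      if (is.null(nxt)) break
      cm <- convergence_metrics(nxt$grid, cur$grid)
      trace <- rbind(trace, data.frame(
        iteration = it, criterion = crit, n_samples = n_samples(samples),
        du_rms = cm["du_rms"], du_max = cm["du_max"],
        var_rms = cm["var_rms"], var_max = cm["var_max"],
        row.names = NULL))
      cur <- nxt
    }
  }
  list(samples = samples, grid = cur$grid, models = cur$models,
       trace = trace)
}

#' Convergence metrics between successive field iterates
#'
#' RMS and maximum of the potential change and of the estimation
#' variance over cells inside the interaction cutoff (unmasked in both
#' grids).
#'
#' @param grid_i,grid_prev grids on the same axes.
#' @return named numeric: du_rms, du_max, var_rms, var_max.
#' @export
convergence_metrics <- function(grid_i, grid_prev) {
  if (!identical(lapply(grid_i$axes, `[`, c("min", "step", "n")),
                 lapply(grid_prev$axes, `[`, c("min", "step", "n")))) {
    stop("grids have mismatched axes")
  }
  ok <- !(grid_i$mask | grid_prev$mask)
  du <- grid_i$value[ok] - grid_prev$value[ok]
  v <- if (is.null(grid_i$variance)) 0 else grid_i$variance[ok]
  c(du_rms = sqrt(mean(du^2)), du_max = max(abs(du)),
    var_rms = sqrt(mean(v^2)), var_max = max(v))
}

#' Write a convergence trace as CSV
#'
#' @param trace trace data.frame from \code{\link{refine}}.
#' @param path output path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
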