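# Two-iteration coordinate grid search for the DIF parameters, maximising
# the DIF model evidence. Parameters are optimised in pairs on full
# resolution^2 grids; in iteration 1 the not-yet-optimised parameters sit at
# the centres of their intervals, in iteration 2 at the iteration-1 optima.
#
# The weight constraint alpha_L + alpha_S + alpha_Delta = 1 leaves two free
# weights: (alpha_S, alpha_Delta) are gridded and alpha_L is derived, with
# the published alpha_L range enforced as a feasibility filter.

#' Search space for the DIF grid search
#'
#' Default ranges follow the published search table: `alpha_L` 0.5..0.9
#' (applied as a feasibility filter on the derived weight), `tau1` 10..100,
#' `tau2` 0.1..1, `beta_S` 1..10, `alpha_Delta` 0.001..0.1, `gamma_Delta2`
#' 0.5..1, each sampled linearly at `resolution` values. The gridded
#' `alpha_S` range is the mirror image `1 - alpha_L range = 0.1..0.5`. The
#' default pair order `(beta_S, alpha_S)`, `(tau1, tau2)`,
#' `(gamma_Delta2, alpha_Delta)` is configuration, since coordinate search
#' optima can depend on it.
#'
#' @param resolution Grid points per parameter (>= 2; the published search
#'   used 100).
#' @param iterations Number of coordinate sweeps (published: 2).
#' @param ranges Named list of `c(min, max)` per parameter.
#' @param pairs List of character pairs defining the simultaneous grids.
#' @param alpha_L_range Feasibility interval for the derived weight.
#' @return A list of class `search_space`.
#' @export
search_space <- function(resolution = 100, iterations = 2,
                         ranges = list(
                           beta_S = c(1, 10), alpha_S = c(0.1, 0.5),
                           tau1 = c(10, 100), tau2 = c(0.1, 1),
                           gamma_Delta2 = c(0.5, 1), alpha_Delta = c(0.001, 0.1)
                         ),
                         pairs = list(c("beta_S", "alpha_S"),
                                      c("tau1", "tau2"),
                                      c("gamma_Delta2", "alpha_Delta")),
                         alpha_L_range = c(0.5, 0.9)) {
  if (resolution < 2) stop("`resolution` must be >= 2.")
  for (nm in names(ranges)) {
    if (ranges[[nm]][1] >= ranges[[nm]][2]) {
      stop(sprintf("Range for %s must have min < max.", nm))
    }
  }
  free <- unlist(pairs)
  if (anyDuplicated(free) || !setequal(free, names(ranges))) {
    stop("Every free parameter must appear in exactly one pair.")
  }
  structure(list(resolution = as.integer(resolution),
                 iterations = as.integer(iterations),
                 ranges = ranges, pairs = pairs,
                 alpha_L_range = alpha_L_range),
            class = "search_space")
}

#' Evaluation budget of a search space
#'
#' Number of evidence evaluations implied by a [search_space()]: each pair
#' contributes `resolution^2` grid points per iteration, so the default
#' space costs 3 x 100^2 = 30,000 evaluations per iteration and 60,000 over
#' its two iterations.
#'
#' @param space A [search_space()].
#' @return A one-row tibble with `per_iteration` and `total`.
#' @export
search_budget <- function(space = search_space()) {
  per <- length(space$pairs) * space$resolution^2
  tibble::tibble(per_iteration = per, total = per * space$iterations)
}

grid_values <- function(space, name) {
  r <- space$ranges[[name]]
  seq(r[1], r[2], length.out = space$resolution)
}

centre <- function(space, name) mean(space$ranges[[name]])

params_from_point <- function(point, space) {
  alpha_L <- 1 - point[["alpha_S"]] - point[["alpha_Delta"]]
  rng <- space$alpha_L_range
  if (alpha_L < max(rng[1], 0) - 1e-12 || alpha_L > min(rng[2], 1) + 1e-12) {
    return(NULL)  # infeasible weight combination
  }
  dif_params(
    alpha_L = alpha_L, alpha_S = point[["alpha_S"]],
    alpha_Delta = point[["alpha_Delta"]],
    tau1 = point[["tau1"]], tau2 = point[["tau2"]],
    beta_S = point[["beta_S"]], gamma_Delta2 = point[["gamma_Delta2"]]
  )
}

#' Coordinate grid search for the DIF parameters
#'
#' Maximises the DIF log evidence over the [search_space()], two parameters
#' at a time. Each pair is evaluated on its full `resolution^2` grid (3
#' pairs x 100^2 = 30,000 combinations per iteration, 60,000 over the
#' default two iterations). Evidence failures at single grid points are
#' recorded as missing and the search continues. Ties are broken by the
#' first-encountered grid point in row-major order, making the search fully
#' deterministic.
#'
#' @param amplitudes Amplitude tibble (`participant`, `trial`, `Y`) as in
#'   [build_design()].
#' @param sequences List of `p3_sequence` objects, one per probability
#'   category, concatenated in trial order.
#' @param space A [search_space()].
#' @param control A [peb_control()] used for every evidence evaluation.
#' @param start Optional named vector of starting values for the free
#'   parameters; by default the not-yet-optimised parameters of iteration 1
#'   sit at the centres of their intervals (the published procedure).
#' @param verbose Print per-pair progress.
#' @return A list of class `dif_search`: `best_params` ([dif_params()]),
#'   `best_F`, `surfaces` (tibble `iteration, pair, par1, par2, value1,
#'   value2, F`), `optima` (per-iteration best points), `n_evaluated`,
#'   `n_failed`.
#' @export
coordinate_grid_search <- function(amplitudes, sequences, space = search_space(),
                                   control = peb_control(), start = NULL,
                                   verbose = FALSE) {
  stopifnot(inherits(space, "search_space"))
  if (!is.list(sequences) || !all(vapply(sequences, inherits, logical(1), "p3_sequence"))) {
    stop("`sequences` must be a list of p3_sequence objects.")
  }
  free <- unlist(space$pairs)
  current <- vapply(free, function(nm) centre(space, nm), numeric(1))
  if (!is.null(start)) current[names(start)] <- start

  # per-participant amplitude matrix (participants share the trial grid)
  amplitudes <- dplyr::arrange(tibble::as_tibble(amplitudes), participant, trial)
  L <- length(unique(amplitudes$participant))
  n_trials <- nrow(amplitudes) / L
  if (n_trials != round(n_trials)) stop("Ragged participant trial counts.")
  if (n_trials != sum(vapply(sequences, seq_N, integer(1)))) {
    stop("Sequences and amplitudes disagree on the trial count.")
  }
  Ymat <- matrix(amplitudes$Y, n_trials, L)
  comp <- lapply(sequences, dif_grid_components)

  # evidence of the DIF regressor assembled from cached filter outputs
  evaluate <- function(point) {
    prm <- params_from_point(point, space)
    if (is.null(prm)) return(NA_real_)
    tryCatch({
      x <- unlist(lapply(comp, function(cm) {
        dif_surprise_from_components(cm, prm)
      }))
      peb_evidence_shared(Ymat, x, control)
    }, error = function(e) NA_real_)
  }

  surfaces <- list()
  optima <- list()
  n_eval <- 0L
  n_failed <- 0L
  best_F <- -Inf
  best_point <- current
  for (iter in seq_len(space$iterations)) {
    for (pair in space$pairs) {
      v1 <- grid_values(space, pair[1])
      v2 <- grid_values(space, pair[2])
      Fmat <- matrix(NA_real_, length(v1), length(v2))
      for (i in seq_along(v1)) {
        point <- current
        point[pair[1]] <- v1[i]
        for (j in seq_along(v2)) {
          point[pair[2]] <- v2[j]
          Fmat[i, j] <- evaluate(point)
        }
      }
      n_eval <- n_eval + length(Fmat)
      n_failed <- n_failed + sum(is.na(Fmat))
      if (all(is.na(Fmat))) {
        stop(sprintf("All grid points failed for pair (%s, %s).",
                     pair[1], pair[2]))
      }
      # row-major first-encountered argmax
      idx <- which(Fmat == max(Fmat, na.rm = TRUE))
      rows <- (idx - 1L) %% length(v1) + 1L
      cols <- (idx - 1L) %/% length(v1) + 1L
      ord <- order(rows, cols)
      i_best <- rows[ord[1]]; j_best <- cols[ord[1]]
      current[pair[1]] <- v1[i_best]
      current[pair[2]] <- v2[j_best]
      pair_F <- Fmat[i_best, j_best]
      if (pair_F > best_F) {
        best_F <- pair_F
        best_point <- current
      }
      surfaces[[length(surfaces) + 1L]] <- tibble::tibble(
        iteration = iter, pair = paste(pair, collapse = ":"),
        par1 = pair[1], par2 = pair[2],
        value1 = rep(v1, times = length(v2)),
        value2 = rep(v2, each = length(v1)),
        F = as.vector(Fmat)
      )
      if (verbose) {
        message(sprintf("iter %d pair (%s, %s): best F = %.3f at (%.4g, %.4g)",
                        iter, pair[1], pair[2], pair_F,
                        v1[i_best], v2[j_best]))
      }
    }
    optima[[iter]] <- tibble::as_tibble(as.list(c(current, F = best_F)))
  }
  best_params <- params_from_point(best_point, space)
  structure(list(
    best_params = best_params, best_F = best_F,
    best_point = best_point,
    surfaces = dplyr::bind_rows(surfaces),
    optima = dplyr::bind_rows(optima, .id = "iteration"),
    n_evaluated = n_eval, n_failed = n_failed,
    space = space
  ), class = "dif_search")
}

#' @export
print.dif_search <- function(x, ...) {
  cat(sprintf("<dif_search> best F = %.3f over %d evaluations (%d failed)\n",
              x$best_F, x$n_evaluated, x$n_failed))
  pt <- x$best_point
  cat("  optimum:", paste(sprintf("%s=%.4g", names(pt), pt), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the evidence surfaces of a grid search
#'
#' @param x A `dif_search`.
#' @param ... Unused.
#' @return The long surface tibble (one row per evaluated grid point).
#' @export
tidy.dif_search <- function(x, ...) x$surfaces

#' @export
glance.dif_search <- function(x, ...) {
  tibble::tibble(best_F = x$best_F, n_evaluated = x$n_evaluated,
                 n_failed = x$n_failed,
                 flat_top_share = flat_top_share(x))
}

# Share of evaluated grid points within 3 nats of the maximum (the
# "relatively flat top" diagnostic; reported, not asserted).
flat_top_share <- function(x, window = 3) {
  f <- x$surfaces$F
  mean(f >= max(f, na.rm = TRUE) - window, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Lean numeric DIF machinery for the inner search loop. The results are
# identical to the tibble-based dif_probability() route (asserted in the
# tests); only container overhead is avoided, plus memoisation of filter
# outputs that do not depend on the pair currently being swept.

dif_grid_components <- function(seq) {
  ev <- seq_events(seq); K <- seq_K(seq); N <- seq_N(seq)
  g <- vapply(seq_len(K), function(k) as.numeric(ev == k), numeric(N))
  env <- new.env(parent = emptyenv())
  list(ev = ev, K = K, N = N, g = g, cache = env)
}

# first-order recursion over an N x K indicator matrix; gammas has length N
fast_iir <- function(g, K, gammas) {
  N <- nrow(g)
  out <- matrix(0, N, K)
  prev_c <- rep(1 / K, K)
  prev_g <- rep(1 / K, K)
  for (n in seq_len(N)) {
    prev_c <- (1 - gammas[n]) * prev_g + gammas[n] * prev_c
    out[n, ] <- prev_c
    prev_g <- g[n, ]
  }
  out
}

fast_fir <- function(g, K, taps, C_Delta) {
  N <- nrow(g)
  gp <- rbind(matrix(1 / K, 4, K), g)
  out <- matrix(0, N, K)
  for (lag in 1:4) {
    out <- out + taps[lag] * gp[seq_len(N) + 4L - lag, , drop = FALSE]
  }
  out / C_Delta
}

cached <- function(cm, key, fn) {
  if (is.null(cm$cache[[key]])) cm$cache[[key]] <- fn()
  cm$cache[[key]]
}

dif_surprise_from_components <- function(cm, prm) {
  cS <- cached(cm, paste0("S", prm$beta_S), function() {
    fast_iir(cm$g, cm$K, rep(prm$gamma_S, cm$N))
  })
  cL <- cached(cm, paste0("L", prm$tau1, "_", prm$tau2), function() {
    sched <- long_term_schedule(prm$tau1, prm$tau2, cm$N)$gamma_L
    fast_iir(cm$g, cm$K, c(sched[1], sched)[seq_len(cm$N)])
  })
  cD <- cached(cm, paste0("D", prm$gamma_Delta2), function() {
    fast_fir(cm$g, cm$K, prm$taps, prm$C_Delta)
  })
  D <- sum(prm$taps) / prm$C_Delta
  inv_C <- prm$alpha_Delta * (1 - D) / cm$K
  P <- prm$alpha_L * cL + prm$alpha_S * cS + prm$alpha_Delta * cD + inv_C
  P <- P / rowSums(P)
  P <- pmin(pmax(P, CLAMP_EPS), 1)
  -log2(P[cbind(seq_len(cm$N), cm$ev)])
}
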