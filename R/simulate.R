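# Synthetic multi-participant P300 amplitude data with the statistical
# structure the hierarchical analysis assumes: per-participant intercepts
# and slopes scattered around group values, amplitudes linear in the
# observer's surprise, Gaussian trial noise averaged over repeated
# presentations of an identical sequence per probability category.

# derive a sub-seed that stays inside 32-bit integer range
derive_seed <- function(seed, mult, offset) {
  as.integer((as.numeric(seed) * mult + offset) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the serial two-choice design:
#' 16 participants, two probability categories (`[0.5, 0.5]` and
#' `[0.3, 0.7]`) of 192 trials each with a single randomisation per
#' category shared by all participants, six identical-sequence repetitions
#' averaged per category, and amplitudes generated as
#' `Y = theta_l + vartheta_l * I(n) + noise`.
#'
#' The group parameters `theta2 = 3.5` uV and `vartheta2 = 1.0` uV/bit are
#' configuration choices placing mean amplitudes in the 2-5 uV range typical
#' of parietal P300 measurements; they are not published values. The default
#' single-trial noise `lambda1 = 10` uV^2 (SD about 3.2 uV) reflects the
#' notoriously low signal-to-noise ratio of single-trial EEG; averaging over
#' `reps = 6` repetitions leaves an effective trial variance of
#' `lambda1/reps`. `lambda2 = 0.5` scatters participant intercepts and
#' slopes around the group values.
#'
#' @param L Number of participants.
#' @param N Trials per block (per category).
#' @param categories List of probability vectors, one per category.
#' @param reps Identical-sequence repetitions averaged per category.
#' @param model Generating observer (`"DIF"`, `"MAR"` or `"SQU"`).
#' @param params Parameters of the generating observer (defaults to
#'   [dif_params()] for DIF).
#' @param theta2,vartheta2 Group intercept (uV) and slope (uV/bit).
#' @param lambda1 Single-trial (per repetition) noise variance, uV^2.
#' @param lambda2 Between-participant variance of intercept and slope.
#' @param error_rate Probability that a trial is flagged (e.g. as a wrong
#'   response) and dropped from the repetition average; 0 by default.
#' @param seed Integer seed controlling sequences, participant parameters
#'   and noise.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 16, N = 192,
                       categories = list(c(0.5, 0.5), c(0.3, 0.7)),
                       reps = 6, model = "DIF", params = NULL,
                       theta2 = 3.5, vartheta2 = 1.0,
                       lambda1 = 10, lambda2 = 0.5,
                       error_rate = 0, seed = 1) {
  if (lambda1 < 0 || lambda2 < 0) stop("Variances must be nonnegative.")
  if (reps < 1) stop("`reps` must be >= 1.")
  if (error_rate < 0 || error_rate >= 1) stop("`error_rate` must lie in [0, 1).")
  structure(list(
    L = as.integer(L), N = as.integer(N), categories = categories,
    reps = as.integer(reps), model = model, params = params,
    theta2 = theta2, vartheta2 = vartheta2,
    lambda1 = lambda1, lambda2 = lambda2,
    error_rate = error_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a multi-participant trial-by-trial P300 dataset
#'
#' One stimulus sequence is randomised per probability category and shared
#' by all participants. Per participant, intercept and slope are drawn as
#' Gaussian deviations from the group parameters (one pair per participant,
#' spanning both categories); per repetition, amplitudes are the linear
#' model plus trial noise, and the returned trace is the repetition
#' average. The observer-model traces used for generation are returned so
#' that fitting can reuse the identical regressors (no recomputation
#' drift).
#'
#' @param config A [sim_config()].
#' @return A list of class `p3_sim` with elements `sequences` (one
#'   `p3_sequence` per category), `traces` (one `p3_trace` per category),
#'   `amplitudes` (tibble `participant, category, trial, Y`), `regressor`
#'   (surprise/expectancy concatenated over categories, shared by
#'   participants), `truth` (all latent draws) and `config`.
#' @examples
#' sim <- simulate_p300(sim_config(L = 2, N = 16, reps = 2, seed = 42))
#' head(sim$amplitudes)
#' @export
simulate_p300 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n_cat <- length(config$categories)
  sequences <- vector("list", n_cat)
  traces <- vector("list", n_cat)
  for (j in seq_len(n_cat)) {
    sequences[[j]] <- generate_sequence(
      K = length(config$categories[[j]]), N = config$N,
      probs = config$categories[[j]],
      seed = derive_seed(config$seed, 1000, j)
    )
    prm <- config$params
    if (identical(config$model, "SQU") && is.null(prm)) {
      prm <- squ_params(config$categories[[j]])
    }
    traces[[j]] <- model_trace(sequences[[j]], config$model, prm)
  }
  regressor <- unlist(lapply(traces, trace_regressor))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  L <- config$L
  theta_l <- config$theta2 + stats::rnorm(L, 0, sqrt(config$lambda2))
  vartheta_l <- config$vartheta2 + stats::rnorm(L, 0, sqrt(config$lambda2))
  n_per <- n_cat * config$N
  amp <- vector("list", L)
  for (l in seq_len(L)) {
    mu <- theta_l[l] + vartheta_l[l] * regressor
    reps_mat <- matrix(mu, n_per, config$reps) +
      matrix(stats::rnorm(n_per * config$reps, 0, sqrt(config$lambda1)),
             n_per, config$reps)
    if (config$error_rate > 0) {
      flagged <- matrix(stats::runif(n_per * config$reps) < config$error_rate,
                        n_per, config$reps)
      reps_mat[flagged] <- NA_real_
      Yl <- rowMeans(reps_mat, na.rm = TRUE)
      Yl[is.nan(Yl)] <- mu[is.nan(Yl)]  # all reps flagged: fall back to mean
    } else {
      Yl <- rowMeans(reps_mat)
    }
    amp[[l]] <- tibble::tibble(
      participant = l,
      category = rep(seq_len(n_cat), each = config$N),
      trial = seq_len(n_per),
      Y = Yl
    )
  }
  amplitudes <- dplyr::bind_rows(amp)
  structure(list(
    sequences = sequences, traces = traces, amplitudes = amplitudes,
    regressor = regressor,
    truth = list(theta2 = config$theta2, vartheta2 = config$vartheta2,
                 theta_l = theta_l, vartheta_l = vartheta_l,
                 lambda1 = config$lambda1, lambda2 = config$lambda2,
                 regressor_fingerprint = rlang::hash(regressor)),
    config = config
  ), class = "p3_sim")
}

#' @export
print.p3_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<p3_sim> %d participants x %d categories x %d trials (%s generator, seed %d)\n",
    cfg$L, length(cfg$categories), cfg$N, cfg$model, cfg$seed
  ))
  invisible(x)
}

#' Fit an observer model to a simulated (or real) dataset
#'
#' Convenience wrapper: computes the requested observer's trace on the
#' dataset's sequences, builds the hierarchical design and fits it by PEB.
#' For the generating model of a simulation the stored traces are reused
#' verbatim.
#'
#' @param sim A `p3_sim` (or a list with `sequences` and `amplitudes`).
#' @param model Observer to fit (`"DIF"`, `"MAR"`, `"SQU"`).
#' @param params Optional observer parameters.
#' @param control A [peb_control()].
#' @return A `peb_fit` (with the model name attached).
#' @export
fit_observer <- function(sim, model = "DIF", params = NULL,
                         control = peb_control()) {
  reuse <- inherits(sim, "p3_sim") && identical(model, sim$config$model) &&
    is.null(params)
  traces <- if (reuse) {
    sim$traces
  } else {
    lapply(sim$sequences, function(s) {
      prm <- params
      if (identical(model, "SQU") && is.null(prm)) {
        prm <- squ_params(attr(s, "probs"))
      }
      model_trace(s, model, prm)
    })
  }
  regressor <- unlist(lapply(traces, trace_regressor))
  design <- build_design(sim$amplitudes, regressor)
  attr(design, "model") <- model
  fit <- peb_fit(design, control)
  fit$model <- model
  fit$trace_fingerprints <- vapply(traces, attr, character(1), "fingerprint")
  fit
}

#' Score parameter recovery of a fit against simulation truth
#'
#' Reports bias and interval coverage for the group parameters and the
#' participant parameters: whether each 95% posterior interval (and each
#' 3-posterior-SD interval) contains the generating value.
#'
#' @param fit A `peb_fit` computed on the simulated dataset.
#' @param truth The `truth` element of a [simulate_p300()] result (or a
#'   `p3_sim`).
#' @return A tibble with one row per parameter: `level`, `term`,
#'   `participant`, `truth`, `estimate`, `sd`, `bias`, `in95`, `in3sd`.
#' @export
recovery_score <- function(fit, truth) {
  stopifnot(inherits(fit, "peb_fit"))
  if (inherits(truth, "p3_sim")) truth <- truth$truth
  tt <- tidy(fit)
  true_vals <- c(
    truth$theta2, truth$vartheta2,
    as.vector(rbind(truth$theta_l, truth$vartheta_l))
  )
  tt$truth <- true_vals
  tt$bias <- tt$estimate - tt$truth
  tt$in95 <- abs(tt$bias) <= stats::qnorm(0.975) * tt$std.error
  tt$in3sd <- abs(tt$bias) <= 3 * tt$std.error
  dplyr::select(tt, level, participant, term, truth, estimate,
                sd = std.error, bias, in95, in3sd)
}
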