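# Stimulus sequences and their indicator/input signals.
#
# Trials are 1-based: trial n = 1 is the first stimulus of a block. Event
# codes are 1..K (1-based, matching the usual notation for K-ary designs).
# Padding samples of the model-exciting signal carry indices nu <= 0 and the
# uniform value 1/K.

#' Construct a stimulus sequence object
#'
#' Wraps an integer vector of event codes into a `p3_sequence`: a tibble with
#' columns `trial` and `event` carrying the alphabet size `K`, the true block
#' probabilities and an optional category label as attributes.
#'
#' @param events Integer vector of event codes, each in `1..K`.
#' @param K Alphabet size (defaults to `max(events)`, at least 2).
#' @param probs Optional probability vector of length `K` (the true block
#'   probabilities, e.g. `c(0.3, 0.7)`).
#' @param category Optional label for the probability category (defaults to a
#'   compact rendering of `probs`).
#' @param seed Optional integer recording the seed used to generate the
#'   sequence (absent for read-in data).
#' @return A `p3_sequence` tibble with columns `trial` and `event`.
#' @examples
#' as_p3_sequence(c(1, 1, 2, 1), K = 2)
#' @export
as_p3_sequence <- function(events, K = max(events), probs = NULL,
                           category = NULL, seed = NULL) {
  events <- as.integer(events)
  if (length(events) < 1L) stop("`events` must contain at least one trial.")
  if (!is.numeric(K) || K < 2L) {
    stop("`K` must be at least 2: a single-event alphabet carries no surprise.")
  }
  K <- as.integer(K)
  if (anyNA(events) || any(events < 1L | events > K)) {
    stop("All event codes must lie in 1..K.")
  }
  if (!is.null(probs)) {
    if (length(probs) != K) stop("`probs` must have length K.")
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
      stop("`probs` must be nonnegative and sum to 1.")
    }
  }
  if (is.null(category) && !is.null(probs)) {
    category <- paste0("[", paste(format(probs, trim = TRUE), collapse = ","), "]")
  }
  out <- tibble::tibble(trial = seq_along(events), event = events)
  structure(out,
    class = c("p3_sequence", class(out)),
    K = K, probs = probs, category = category, seed = seed
  )
}

#' @export
print.p3_sequence <- function(x, ...) {
  cat(sprintf(
    "<p3_sequence> N = %d trials, K = %d%s%s\n",
    nrow(x), attr(x, "K"),
    if (!is.null(attr(x, "category"))) paste0(", category ", attr(x, "category")) else "",
    if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else ""
  ))
  NextMethod()
}

seq_events <- function(seq) seq[["event"]]
seq_K <- function(seq) attr(seq, "K")
seq_N <- function(seq) nrow(seq)

#' Generate a random stimulus sequence
#'
#' Draws `N` i.i.d. events from a categorical distribution, emulating a block
#' of a serial two-choice task in which each of `K` stimuli occurs with fixed
#' probability (e.g. `c(0.5, 0.5)` or `c(0.3, 0.7)`).
#'
#' @param K Alphabet size (>= 2).
#' @param N Number of trials in the block.
#' @param probs Probability vector of length `K`, summing to 1.
#' @param seed Integer seed; identical seeds give identical sequences. The
#'   draw uses a local RNG state and does not disturb the caller's stream.
#' @param category Optional category label (defaults to rendering of `probs`).
#' @return A [as_p3_sequence()] object.
#' @examples
#' generate_sequence(2, 10, c(0.3, 0.7), seed = 1)
#' @export
generate_sequence <- function(K = 2, N = 192, probs = rep(1 / K, K), seed,
                              category = NULL) {
  if (!is.numeric(N) || N < 1) stop("`N` must be at least 1.")
  if (!is.numeric(K) || K < 2) stop("`K` must be at least 2.")
  if (length(probs) != K) stop("`probs` must have length K.")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    stop("`probs` must be nonnegative and sum to 1 (tolerance 1e-9).")
  }
  if (missing(seed) || is.null(seed)) stop("`seed` is required for reproducibility.")
  events <- local_seed_sample(seed, as.integer(N), probs)
  as_p3_sequence(events, K = as.integer(K), probs = probs,
                 category = category, seed = as.integer(seed))
}

# Seeded categorical draw that restores the caller's RNG state.
local_seed_sample <- function(seed, N, probs) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(length(probs), N, replace = TRUE, prob = probs)
}

#' Indicator signal of one event
#'
#' `indicator_d()` returns the per-trial indicator d_k(nu): 1 on the trials
#' where the sequence realised event `k`, 0 elsewhere (defined for nu >= 1).
#'
#' @param seq A [as_p3_sequence()] object.
#' @param k Event code in `1..K`.
#' @return A tibble with columns `nu` and `value`, plus attributes `kind`
#'   (`"d"`) and `k`.
#' @examples
#' indicator_d(as_p3_sequence(c(1, 1, 2)), 1)
#' @export
indicator_d <- function(seq, k) {
  check_event_code(seq, k)
  out <- tibble::tibble(nu = seq[["trial"]], value = as.numeric(seq[["event"]] == k))
  structure(out, class = c("p3_signal", class(out)), kind = "d", k = as.integer(k),
            K = seq_K(seq))
}

#' Model-exciting input signal g
#'
#' `input_signal_g()` materialises the input signal g_k(nu) shared by all
#' filters of the DIF observer: a uniform prior value 1/K on every sample
#' nu <= 0 (the conceptually infinite pre-block history) and the realised
#' indicator d_k(nu) from trial 1 on. The recursive filters absorb the
#' infinite prefix into their initialisation, so `pad = 0` is the working
#' default; positive `pad` materialises that many nu <= 0 samples for
#' direct-sum computations.
#'
#' @inheritParams indicator_d
#' @param pad Number of materialised padding samples with nu <= 0 (>= 0).
#' @return A tibble with columns `nu` (from `1 - pad`) and `value`, plus
#'   attributes `kind` (`"g"`) and `k`.
#' @examples
#' input_signal_g(as_p3_sequence(c(2, 1), K = 2), k = 1, pad = 3)
#' @export
input_signal_g <- function(seq, k, pad = 0) {
  check_event_code(seq, k)
  if (!is.numeric(pad) || pad < 0) stop("`pad` must be >= 0.")
  pad <- as.integer(pad)
  K <- seq_K(seq)
  nu <- seq.int(1L - pad, seq_N(seq))
  value <- c(rep(1 / K, pad), as.numeric(seq[["event"]] == k))
  out <- tibble::tibble(nu = nu, value = value)
  structure(out, class = c("p3_signal", class(out)), kind = "g", k = as.integer(k),
            K = K)
}

check_event_code <- function(seq, k) {
  if (!inherits(seq, "p3_sequence")) stop("`seq` must be a p3_sequence.")
  if (length(k) != 1L || !is.numeric(k) || k < 1 || k > seq_K(seq)) {
    stop(sprintf("`k` must be a single event code in 1..%d.", seq_K(seq)))
  }
  invisible(TRUE)
}

#' Write / read a sequence as CSV with a JSON sidecar
#'
#' The CSV holds columns `trial,event` (1-based trial index, integer event
#' codes 1..K). A JSON sidecar `<path>.json` records `K`, `probs`, `seed` and
#' `category` so a read-in sequence round-trips exactly.
#'
#' @param seq A `p3_sequence`.
#' @param path CSV file path.
#' @return `write_sequence_csv()` returns `path` invisibly;
#'   `read_sequence_csv()` returns a `p3_sequence`.
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "p3_sequence"))
  utils::write.csv(as.data.frame(seq), path, row.names = FALSE, quote = FALSE)
  meta <- list(K = seq_K(seq), probs = attr(seq, "probs"),
               seed = attr(seq, "seed"), category = attr(seq, "category"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  df <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  as_p3_sequence(df$event,
    K = if (!is.null(meta$K)) meta$K else max(df$event),
    probs = meta$probs, category = meta$category, seed = meta$seed
  )
}
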