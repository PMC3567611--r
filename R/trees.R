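# Sequence-history ("tree") averaging of trial-by-trial amplitudes.
#
# Amplitudes are conditioned on the pattern of the 0..3 preceding stimuli
# relative to the current one. In the equiprobable category the analysis is
# collapsed across the two stimuli: symbol `a` denotes the current event and
# `b` the other one, so every pattern ends in `a`. In the biased category
# `a` is anchored to the rare stimulus and `b` to the frequent one, and
# separate trees are reported for rare-final and frequent-final trials.

#' History pattern labels
#'
#' Patterns are written oldest-first, e.g. `baaa` means the event three
#' trials back differed from the current event and the two intermediate
#' events matched it; the final symbol is the eliciting trial.
#'
#' @param order History depth 0..3.
#' @param mode `"collapsed"` (patterns relative to the current event, all
#'   ending in `a`) or `"anchored"` (`a` = rare, `b` = frequent; patterns
#'   ending in either symbol).
#' @return Character vector of labels: `2^order` in collapsed mode,
#'   `2^(order+1)` in anchored mode.
#' @examples
#' sequence_labels(1, "collapsed")  # "aa" "ba"
#' sequence_labels(3, "collapsed")
#' @export
sequence_labels <- function(order, mode = c("collapsed", "anchored")) {
  mode <- match.arg(mode)
  if (!is.numeric(order) || order < 0 || order > 3) {
    stop("`order` must be between 0 and 3 (the analysed history depth).")
  }
  order <- as.integer(order)
  finals <- if (mode == "collapsed") "a" else c("a", "b")
  out <- character(0)
  for (fin in finals) {
    if (order == 0L) {
      out <- c(out, fin)
    } else {
      hist <- expand.grid(rep(list(c("a", "b")), order), stringsAsFactors = FALSE)
      # order histories by recency: vary the most recent predecessor fastest,
      # giving aa..., ba..., ab..., bb... style ordering oldest-first labels
      labs <- apply(hist, 1, function(r) paste0(paste(rev(r), collapse = ""), fin))
      out <- c(out, labs)
    }
  }
  out
}

#' Average amplitudes by stimulus-history pattern
#'
#' Labels every eligible trial (those with at least `order` predecessors)
#' with its history pattern and returns per-pattern means and counts. In
#' collapsed mode symbols are relative to the current event; in anchored
#' mode `a` is the rare event (`rare` argument) and trees are split by the
#' final symbol.
#'
#' Empty pattern cells are reported with count 0 and a missing mean rather
#' than dropped.
#'
#' @param amplitudes Numeric vector of per-trial amplitudes aligned with
#'   `seq`.
#' @param seq A `p3_sequence` (K = 2).
#' @param order History depth 0..3.
#' @param mode `"collapsed"` or `"anchored"`.
#' @param rare Event code treated as `a` in anchored mode (defaults to the
#'   least probable event of the sequence's category).
#' @return A tibble with columns `order`, `pattern`, `mean`, `count`.
#' @examples
#' s <- as_p3_sequence(c(1, 1, 2, 1), K = 2)
#' average_by_sequence(c(3, 3.2, 4.1, 3.9), s, order = 1)
#' @export
average_by_sequence <- function(amplitudes, seq, order,
                                mode = c("collapsed", "anchored"),
                                rare = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "p3_sequence"))
  if (seq_K(seq) != 2L) stop("Tree averaging is defined for binary sequences.")
  if (length(amplitudes) != seq_N(seq)) {
    stop("`amplitudes` must be aligned with the sequence (one value per trial).")
  }
  if (!is.numeric(order) || order < 0 || order > 3) {
    stop("`order` must be between 0 and 3.")
  }
  order <- as.integer(order)
  ev <- seq_events(seq)
  N <- length(ev)
  if (mode == "anchored" && is.null(rare)) {
    probs <- attr(seq, "probs")
    rare <- if (!is.null(probs)) which.min(probs) else 1L
  }
  eligible <- seq_len(N)[seq_len(N) > order]
  labels <- vapply(eligible, function(n) {
    window <- ev[(n - order):n]
    if (mode == "collapsed") {
      symbols <- ifelse(window == ev[n], "a", "b")
    } else {
      symbols <- ifelse(window == rare, "a", "b")
    }
    paste(symbols, collapse = "")
  }, character(1))
  all_labels <- sequence_labels(order, mode)
  df <- tibble::tibble(pattern = factor(labels, levels = all_labels),
                       Y = amplitudes[eligible])
  out <- df |>
    dplyr::group_by(pattern, .drop = FALSE) |>
    dplyr::summarise(mean = mean(Y), count = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(order = order, .before = 1) |>
    dplyr::mutate(pattern = as.character(pattern),
                  mean = ifelse(count == 0, NA_real_, mean))
  out
}

#' Full tree table over orders 0..3
#'
#' Computes [average_by_sequence()] for each requested order, optionally per
#' participant with equal-weight grand averaging across participants (the
#' ERP convention), or pooled over all trials.
#'
#' @param amplitudes Tibble with columns `participant`, `trial`, `Y` (or a
#'   bare numeric vector for a single trace).
#' @param seq The `p3_sequence` the trials follow.
#' @param orders Integer vector of history depths.
#' @param mode,rare Passed to [average_by_sequence()].
#' @param average `"participants"` (grand average of per-participant
#'   pattern means) or `"pooled"` (all trials pooled).
#' @return A tibble with columns `order`, `pattern`, `mean`, `count` (counts
#'   are summed over participants).
#' @export
tree_table <- function(amplitudes, seq, orders = 0:3,
                       mode = c("collapsed", "anchored"), rare = NULL,
                       average = c("participants", "pooled")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  if (is.numeric(amplitudes)) {
    amplitudes <- tibble::tibble(participant = 1L,
                                 trial = seq_along(amplitudes),
                                 Y = amplitudes)
  }
  per_part <- amplitudes |>
    dplyr::group_by(participant) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, trial)
      purrr::map_dfr(orders, function(o) {
        average_by_sequence(d$Y, seq, o, mode = mode, rare = rare)
      })
    }) |>
    dplyr::ungroup()
  if (average == "pooled") {
    # pooling is equivalent to count-weighted means across participants
    out <- per_part |>
      dplyr::group_by(order, pattern) |>
      dplyr::summarise(
        mean = ifelse(sum(count) == 0, NA_real_,
                      sum(mean * count, na.rm = TRUE) / sum(count)),
        count = sum(count), .groups = "drop"
      )
  } else {
    out <- per_part |>
      dplyr::group_by(order, pattern) |>
      dplyr::summarise(mean = mean(mean, na.rm = TRUE),
                       count = sum(count), .groups = "drop")
    out$mean[out$count == 0] <- NA_real_
  }
  dplyr::arrange(out, order, pattern)
}
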