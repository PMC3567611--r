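.onLoad <- function(libname, pkgname) {
  # the default FIR sign pattern must give a high-pass response
  prm <- dif_params()
  f <- c(0, 1 / 3)
  mag <- amplitude_response("alternation", f, fs = 2 / 3, params = prm)$magnitude
  if (!(mag[2] > mag[1])) {
    stop("Default alternation taps do not yield a high-pass response.")
  }
  invisible()
}

utils::globalVariables(c(
  "participant", "trial", "Y", "pattern", "count", "pair", "value1", "value2",
  "F", "event", "event_k", "value", "level", "term", "std.error", "Yhat",
  "order_parent", "order_child", "mean_parent", "mean_child", "parent",
  "magnitude", "measured", "fitted", "filter", "estimate", "bias",
  "in95", "in3sd"
))
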