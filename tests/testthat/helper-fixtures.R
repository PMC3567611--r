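# Shared fixtures built in code.

seq_from <- function(events, K = 2, probs = NULL) {
  as_p3_sequence(events, K = K, probs = probs)
}

# planted parameter set on the resolution-20 grid, near the published optimum
planted_point <- function(space = search_space(resolution = 20)) {
  gv <- function(nm) seq(space$ranges[[nm]][1], space$ranges[[nm]][2],
                         length.out = space$resolution)
  c(beta_S = gv("beta_S")[3], alpha_S = gv("alpha_S")[2],
    tau1 = gv("tau1")[6], tau2 = gv("tau2")[5],
    gamma_Delta2 = gv("gamma_Delta2")[18], alpha_Delta = gv("alpha_Delta")[10])
}

params_from_named <- function(pt) {
  dif_params(
    alpha_L = 1 - pt[["alpha_S"]] - pt[["alpha_Delta"]],
    alpha_S = pt[["alpha_S"]], alpha_Delta = pt[["alpha_Delta"]],
    tau1 = pt[["tau1"]], tau2 = pt[["tau2"]],
    beta_S = pt[["beta_S"]], gamma_Delta2 = pt[["gamma_Delta2"]]
  )
}

grid_steps <- function(space = search_space(resolution = 20)) {
  vapply(names(space$ranges), function(nm) {
    diff(space$ranges[[nm]]) / (space$resolution - 1)
  }, numeric(1))
}

# Table-1 grid values of the published long-term constants (print as 33.6, 0.27)
TAU1_STAR <- 10 + 90 * 26 / 99
TAU2_STAR <- 0.1 + 0.9 * 19 / 99
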