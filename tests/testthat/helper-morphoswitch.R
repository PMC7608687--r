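# Shared helpers for the test suite.  Everything is generated in code; no
# stored fixtures.

p_solid <- default_params()                    # lawn context (gamma_fp = 0.1/h)
p_liquid <- default_params(phase = "liquid")   # exponential culture (0.7/h)

terminal_state <- function(env, params, t_end = 48) {
  tr <- integrate_circuit(rep(0, 6), env, params, t_end = t_end,
                          dt_out = t_end)
  tr$states[nrow(tr$states), ]
}

n_stable <- function(env, params, ...) {
  eq <- find_equilibria(env, params, ...)
  sum(vapply(eq, function(e) e$stability == "stable", logical(1)))
}

# Small condition grids reused by the inference tests
receiver_grid <- rbind(
  expand.grid(c6 = c(0, 15, 40, 75, 150, 400, 1000), c12 = 0),
  expand.grid(c6 = 0, c12 = c(25, 60, 120, 250, 600, 1500)))
exclusive_grid <- expand.grid(c6 = c(0, 20, 60, 180, 540),
                              c12 = c(0, 40, 120, 360, 1080))

make_receiver_params <- function(p = p_liquid) {
  p$variant <- "receiver"
  p
}
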