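# Parameter vectors with the multiplier chain frozen to constants, so the
# simulator reduces to the two-channel diffusion model with external rate
# p and internal rate q (all switches off, delta normalized to 1).
bass_params <- function(p, q, cr0 = 0, N = 1e7) {
  gp_parameters(alpha = p, mu = q, beta0 = 1, g0 = 1, gamma_min = 1,
                cr0 = cr0, N = N)
}

# closed-form two-channel diffusion fraction, F(0) = 0
bass_fraction <- function(t, p, q) {
  (1 - exp(-(p + q) * t)) / (1 + (q / p) * exp(-(p + q) * t))
}

# initial state matching gp_simulate()'s initialization
initial_state <- function(params) {
  C0 <- params$cr0 * params$N
  gp_state(params$horizon[1], params$N - C0, C0,
           max(params$gp_floor, C0 / params$panel_size))
}

all_on_scenario <- function(idr = NA_real_) {
  gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, jtp = 1, ii = 1,
              idr = idr, name = "mixed7")
}
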