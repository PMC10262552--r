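# Shared fixtures, built in code.

# literature-typical two-compartment parameter set used across tests
test_pk <- function(clearance = 2, central_volume = 12,
                    intercompartmental_clearance = 8,
                    peripheral_volume = 18) {
  pk_parameters(clearance, central_volume, intercompartmental_clearance,
                peripheral_volume)
}

# independent numerical oracle: trapezoid integration of the
# concentration curve on a fine grid
trapz_auc <- function(params, doses, t0, t1, step = 0.01) {
  tt <- seq(t0, t1, by = step)
  cc <- concentration_at(params, doses, tt)
  sum((cc[-1] + cc[-length(cc)]) / 2) * step
}

# random but physiologic parameter sets for property loops
random_pk <- function() {
  pk_parameters(clearance = exp(rnorm(1, log(2), 0.5)),
                central_volume = exp(rnorm(1, log(12), 0.3)),
                intercompartmental_clearance = exp(rnorm(1, log(8), 0.4)),
                peripheral_volume = exp(rnorm(1, log(18), 0.3)))
}
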