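# Shared fixtures: parameter sets and small synthetic curve tables built in
# code. The Yeoh constants (3.54, 38.21, -14.6 kPa) are the reference matrix
# set used throughout the recovery tests.

table1_yeoh <- function() yeoh(3.54, 38.21, -14.6, allow_nonphysical = TRUE)

desk_fiber <- function(e_f_kpa = 100, phi = 0.2, k = 3) {
  fiber_model(table1_yeoh(), e_f = e_f_kpa, phi = phi, k = k,
              e_f_unit = "kPa")
}

clean_curves <- function(params, n = 1, by = 0.01) {
  generate_curves(synthetic_spec(params, strain_grid = seq(0, 0.5, by = by),
                                 noise = "none", n_specimens = n))
}

all_model_params <- function() {
  list(
    neo_hookean = neo_hookean(2),
    yeoh = table1_yeoh(),
    ogden = ogden(4.3, 8),
    goh = goh(6.91, 184, 0.9, 0.3),
    fiber = fiber_model(table1_yeoh(), e_f = 230, phi = 0.2, k = 2.02)
  )
}
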