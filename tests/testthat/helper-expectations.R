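# Comparison against values printed at a fixed number of decimals.
# The band is half a unit in the last printed place, plus an optional
# slack for input-precision propagation: the fixture's responses are
# themselves printed at 2 decimals (+-0.005), and the l1 norm of the OLS
# estimator weights on this design is bounded by 2.5, so statistics
# recomputed from the printed table can drift from the study's
# full-precision values by up to ~0.0125 on the coefficient scale.
expect_printed <- function(computed, printed, decimals, slack = 0) {
  band <- 0.5 * 10^(-decimals) + slack + 1e-9
  expect_true(all(abs(computed - printed) <= band),
              label = sprintf("max |computed - printed| = %.3g within %.3g",
                              max(abs(computed - printed)), band))
}

# input-rounding propagation slack on the coefficient scale
COEF_SLACK <- 0.0125

fixture_fits <- function() {
  fx <- spirulina_fixture()
  list(
    fx = fx,
    pigment = fit_quadratic(fx$design, fx$responses$pigment_mg_per_g,
                            "full", response_name = "pigment"),
    abts = fit_quadratic(fx$design, fx$responses$abts_mg_TRE_per_g,
                         "no-interactions", response_name = "abts"),
    tpc = fit_quadratic(fx$design, fx$responses$tpc_mg_GAE_per_g,
                        "full", response_name = "tpc")
  )
}
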