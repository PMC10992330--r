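#' The 15-run Spirulina extraction study
#'
#' The built-in design/response fixture for the ultrasound-assisted
#' NADES extraction study of Spirulina platensis: the 15-run, 3-factor
#' Box-Behnken design (temperature 50-70 degC, extraction-cycle time
#' 20-40 min, solvent-to-biomass ratio 50-70 mL/mg; three centre
#' replicates) and the three observed responses per run (total pigment
#' yield, ABTS antioxidant capacity as Trolox equivalents, and total
#' phenolic content as gallic-acid equivalents, all per g dry matter).
#'
#' The published design table lists runs 3 and 4 with a natural
#' extraction time of 30 min alongside coded level +1; the coded column
#' is internally consistent with the canonical Box-Behnken layout and
#' with the fitted models, so the default fixture corrects the natural
#' time of those runs to 40 min.  `verbatim = TRUE` returns the table
#' exactly as published (which then fails [validate_design()] at runs
#' 3 and 4).
#'
#' @param verbatim Keep the published (uncorrected) natural times for
#'   runs 3 and 4.
#' @return List with `design` (a `bbd_design`) and `responses` (data
#'   frame: `run_id`, `pigment_mg_per_g`, `abts_mg_TRE_per_g`,
#'   `tpc_mg_GAE_per_g`).
#' @examples
#' fx <- spirulina_fixture()
#' fx$responses[11, ]
#' @export
spirulina_fixture <- function(verbatim = FALSE) {
  design <- build_bbd(uae_factors(), n_center = 3)
  if (verbatim) design$time_min[3:4] <- 30
  responses <- data.frame(
    run_id = 1:15,
    pigment_mg_per_g = c(65.88, 63.37, 66.77, 39.84, 30.08, 18.50, 57.35,
                         39.92, 64.81, 106.31, 161.04, 83.87, 94.95, 25.10,
                         60.57),
    abts_mg_TRE_per_g = c(27.41, 35.36, 26.93, 30.48, 21.27, 28.92, 27.67,
                          34.49, 21.73, 25.82, 34.40, 35.05, 27.14, 29.93,
                          31.25),
    tpc_mg_GAE_per_g = c(23.15, 7.17, 23.70, 21.98, 14.60, 12.35, 5.73,
                         4.72, 22.39, 39.99, 43.49, 41.82, 27.97, 31.14,
                         29.49)
  )
  list(design = design, responses = responses)
}

#' Map fixture response columns to short response names
#' @keywords internal
.response_names <- c(pigment_mg_per_g = "pigment",
                     abts_mg_TRE_per_g = "abts",
                     tpc_mg_GAE_per_g = "tpc")

#' Define a known quadratic truth for simulation
#'
#' @param coefficients Named list of full 10-term coefficient vectors
#'   (canonical term order; missing terms are taken as 0), one entry per
#'   response.
#' @param noise_sd Named non-negative noise standard deviation per
#'   response (homoscedastic Gaussian).
#' @return Object of class `surface_truth`.
#' @export
surface_truth <- function(coefficients, noise_sd) {
  stopifnot(is.list(coefficients), length(coefficients) >= 1L,
            !is.null(names(coefficients)))
  coefficients <- lapply(coefficients, function(b) {
    full <- stats::setNames(rep(0, length(.canonical_terms)), .canonical_terms)
    if (is.null(names(b))) {
      stopifnot(length(b) == length(.canonical_terms))
      full[] <- b
    } else {
      stopifnot(all(names(b) %in% .canonical_terms))
      full[names(b)] <- b
    }
    full
  })
  stopifnot(all(names(coefficients) %in% names(noise_sd)) ||
              length(noise_sd) == length(coefficients))
  if (is.null(names(noise_sd))) names(noise_sd) <- names(coefficients)
  noise_sd <- noise_sd[names(coefficients)]
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0)) {
    stop("noise_sd must be finite and non-negative", call. = FALSE)
  }
  structure(list(coefficients = coefficients, noise_sd = noise_sd),
            class = "surface_truth")
}

#' Reference truth: the refitted study surfaces
#'
#' The default generative truth for [simulate_experiment()]: the three
#' coefficient vectors obtained by refitting the study fixture (full
#' quadratic models for pigment and TPC, the reduced no-interaction
#' model for ABTS), with per-response noise standard deviations set to
#' the pure-error standard deviation of the fixture's centre replicates.
#' Everything is recomputed from the fixture at call time.
#'
#' @return A [surface_truth()].
#' @export
reference_truth <- function() {
  fx <- spirulina_fixture()
  resp <- fx$responses
  term_choice <- c(pigment = "full", abts = "no-interactions", tpc = "full")
  coefs <- list(); sds <- numeric(0)
  for (col in names(.response_names)) {
    nm <- .response_names[[col]]
    fit <- fit_quadratic(fx$design, resp[[col]], term_choice[[nm]],
                         response_name = nm)
    coefs[[nm]] <- fit$coefficients
    sds[nm] <- stats::sd(resp[[col]][13:15])
  }
  surface_truth(coefs, sds)
}

#' Simulate a Box-Behnken experiment with known truth
#'
#' Builds the canonical design, evaluates the true quadratic surfaces on
#' it and adds independent homoscedastic Gaussian noise per run and
#' response.  A single integer seed governs all draws: per-response
#' sub-seeds are split from it so that adding a response never perturbs
#' the noise stream of an earlier one.
#'
#' @param truth A [surface_truth()]; defaults to [reference_truth()].
#' @param n_center Number of centre replicates (default 3).
#' @param seed Integer seed.
#' @param factors Factor definitions (default [uae_factors()]).
#' @return Object of class `synthetic_experiment`: `design`, `responses`
#'   (data frame, one column per response), `truth`, `seed`.
#' @examples
#' sim <- simulate_experiment(seed = 1)
#' head(sim$responses)
#' @export
simulate_experiment <- function(truth = reference_truth(), n_center = 3,
                                seed = 1, factors = uae_factors()) {
  stopifnot(inherits(truth, "surface_truth"))
  design <- build_bbd(factors, n_center = n_center)
  X <- build_model_matrix(design, "full")
  resp <- names(truth$coefficients)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(resp))
  responses <- data.frame(run_id = design$run_id)
  for (j in seq_along(resp)) {
    mu <- unname(drop(X %*% truth$coefficients[[j]]))
    set.seed(sub_seeds[j])
    responses[[resp[j]]] <- mu + stats::rnorm(nrow(X), sd = truth$noise_sd[j])
  }
  structure(list(design = design, responses = responses,
                 truth = truth, seed = seed),
            class = "synthetic_experiment")
}

#' Simulate absorbances that realize target pigment concentrations
#'
#' Inverts the pigment equations: given target chlorophyll a+b and
#' carotenoid concentrations (ug/mL) and a phycocyanin concentration
#' (mg/mL), returns a five-channel [spectral_reading()] such that the
#' forward equations reproduce the targets exactly.  The inverse system
#' is underdetermined, so the absorbances at 652 and 663.6 nm are fixed
#' by a seeded uniform draw on `[0.2, 0.8]` (or by `base_draws`) and the
#' remaining three channels are solved for.
#'
#' @param chl_ab Target chlorophyll a+b concentration, ug/mL.
#' @param carotenoids Target carotenoid concentration, ug/mL.
#' @param phycocyanin Target phycocyanin concentration, mg/mL.
#' @param seed Integer seed for the free draws.
#' @param base_draws Optional length-2 numeric `(A652, A663.6)`
#'   overriding the random draws.
#' @return A [spectral_reading()] at 440, 620, 646.6, 652 and 663.6 nm.
#' @export
simulate_absorbances <- function(chl_ab = 0, carotenoids = 0, phycocyanin = 0,
                                 seed = 1, base_draws = NULL) {
  stopifnot(is.finite(chl_ab), is.finite(carotenoids), is.finite(phycocyanin))
  if (is.null(base_draws)) {
    set.seed(seed)
    base_draws <- stats::runif(2, 0.2, 0.8)
  }
  stopifnot(length(base_draws) == 2L, all(is.finite(base_draws)))
  a652 <- base_draws[1L]; a663 <- base_draws[2L]
  a646 <- (chl_ab + 7.34 * a663) / 17.76
  a440 <- (carotenoids + 0.267 * chl_ab) / 4.69
  a620 <- phycocyanin * 5.34 + 0.474 * a652
  spectral_reading(c(440, 620, 646.6, 652, 663.6),
                   c(a440, a620, a646, a652, a663))
}
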