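#' Write / read a design table as CSV
#'
#' Columns: `run_id`, the three natural-unit factor columns
#' (`temperature_C`, `time_min`, `ratio_mL_per_mg` for the default
#' factors), then the coded `x1`, `x2`, `x3`.  Full double precision is
#' preserved on the round trip.
#'
#' @param design A `bbd_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `bbd_design`.
#' @export
write_design_csv <- function(design, path) {
  cols <- c("run_id", vapply(.design_factors(design),
                             function(f) f$name, character(1)),
            "x1", "x2", "x3")
  utils::write.csv(as.data.frame(design)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param factors Factor definitions used to interpret the natural
#'   columns (default [uae_factors()]).
#' @export
read_design_csv <- function(path, factors = uae_factors()) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("run_id", vapply(factors, function(f) f$name, character(1)),
            "x1", "x2", "x3")
  if (!all(need %in% names(df))) {
    stop("design CSV must carry columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_center <- sum(df$x1 == 0 & df$x2 == 0 & df$x3 == 0)
  structure(df[, need], factors = factors, n_center = n_center,
            class = c("bbd_design", "data.frame"))
}

#' Write / read a response table as CSV
#'
#' Columns: `run_id` followed by one numeric column per response
#' (`pigment_mg_per_g`, `abts_mg_TRE_per_g`, `tpc_mg_GAE_per_g` for the
#' built-in study).
#'
#' @param responses Data frame with `run_id` plus response columns.
#' @param path File path.
#' @export
write_responses_csv <- function(responses, path) {
  stopifnot("run_id" %in% names(responses))
  utils::write.csv(responses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"run_id" %in% names(df)) {
    stop("responses CSV must carry a run_id column", call. = FALSE)
  }
  df
}

#' Export a prediction grid over two factors
#'
#' Evaluates a fitted surface on a `resolution x resolution` coded grid
#' over the chosen factor pair while holding the remaining factor at a
#' fixed coded level (the centre by default) — the numeric analogue of a
#' response-surface / contour plot panel.
#'
#' @param model An `rsm_fit`.
#' @param factor_pair Integer pair selecting the varying factors, e.g.
#'   `c(2, 3)` for time vs ratio.
#' @param fixed_level Coded level of the remaining factor (default 0).
#' @param resolution Grid levels per axis (>= 2).
#' @return Data frame: coded and natural coordinates of the two varying
#'   factors, the fixed factor's level, and `predicted`.
#' @export
export_surface_grid <- function(model, factor_pair, fixed_level = 0,
                                resolution = 21) {
  stopifnot(inherits(model, "rsm_fit"), length(factor_pair) == 2L,
            all(factor_pair %in% 1:3), factor_pair[1L] != factor_pair[2L])
  lv <- .grid_levels(resolution)
  other <- setdiff(1:3, factor_pair)
  g <- expand.grid(a = lv, b = lv)
  grid <- matrix(fixed_level, nrow = nrow(g), ncol = 3L,
                 dimnames = list(NULL, c("x1", "x2", "x3")))
  grid[, factor_pair[1L]] <- g$a
  grid[, factor_pair[2L]] <- g$b
  factors <- model$factors
  nat <- decode_point(factors, grid)
  fa <- factors[[factor_pair[1L]]]; fb <- factors[[factor_pair[2L]]]
  fo <- factors[[other]]
  out <- data.frame(g$a, g$b, nat[, factor_pair[1L]], nat[, factor_pair[2L]],
                    fixed_level, nat[, other],
                    predicted = predict(model, grid))
  names(out) <- c(paste0("coded_", fa$name), paste0("coded_", fb$name),
                  fa$name, fb$name,
                  paste0("coded_", fo$name, "_fixed"),
                  paste0(fo$name, "_fixed"), "predicted")
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration over a design/response table: fit a
#' second-order model per response (fixed term sets or automatic
#' selection), compute ANOVA with lack of fit, pairwise Pearson
#' correlations between responses, the run-wise desirability table with
#' its optimum, a grid-refined optimum, per-factor desirability
#' profiles, and the three surface grids per response.  The computation
#' is fully deterministic; running twice on the same inputs yields
#' identical numbers.
#'
#' With no inputs the built-in study fixture is analysed with its
#' published term sets (full quadratic for pigment and TPC, reduced
#' no-interaction model for ABTS), so `run_pipeline()` reproduces the
#' study end-to-end.
#'
#' @param design A `bbd_design`; default the fixture design.
#' @param responses Data frame `run_id` + response columns; default the
#'   fixture responses.  Fixture-style column names are shortened to
#'   `pigment` / `abts` / `tpc` in reports.
#' @param terms `"study"` (the embedded study's term sets), `"auto"`
#'   (per-response [select_model()] over its default candidates), a
#'   single preset name for all responses, or a named list/vector
#'   mapping response names to presets or [term_set()]s.
#' @param weights Optional named per-response desirability weights.
#' @param resolution Grid resolution for [grid_optimize()],
#'   [desirability_profiles()] and [export_surface_grid()].
#' @param validation Optional data frame with columns `response`,
#'   `experimental_mean` and optionally `experimental_sd`, holding
#'   confirmation measurements at the optimum.
#' @param out_dir Optional directory; when given, the bundle is written
#'   out (models JSON, ANOVA CSV laid out like the study's ANOVA table,
#'   desirability CSV, optimum JSON, profile and surface-grid CSVs,
#'   validation CSV, decision log).
#' @return A list bundle: `design`, `responses`, `models`, `anovas`,
#'   `selection` (when `terms = "auto"`), `correlations`, `desirability`,
#'   `grid_optimum`, `profiles`, `surface_grids`, `validation`, `log`.
#' @examples
#' bundle <- run_pipeline(resolution = 5)
#' bundle$desirability$optimum$natural
#' @export
run_pipeline <- function(design = NULL, responses = NULL, terms = "study",
                         weights = NULL, resolution = 21, validation = NULL,
                         out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.null(design) || is.null(responses)) {
    fx <- spirulina_fixture()
    if (is.null(design)) design <- fx$design
    if (is.null(responses)) responses <- fx$responses
    note("inputs: built-in study fixture (runs 3-4 natural time corrected to 40 min)")
  }
  findings <- validate_design(design)
  for (f in findings) note("design finding: %s", f)

  resp_cols <- setdiff(names(responses), "run_id")
  short <- ifelse(resp_cols %in% names(.response_names),
                  .response_names[resp_cols], resp_cols)
  names(resp_cols) <- short

  study_terms <- c(pigment = "full", abts = "no-interactions", tpc = "full")
  models <- list(); anovas <- list(); selection <- list()
  for (nm in short) {
    y <- responses[[resp_cols[[nm]]]]
    if (identical(terms, "auto")) {
      sel <- select_model(design, y, response_name = nm)
      models[[nm]] <- sel$model
      anovas[[nm]] <- sel$anova
      selection[[nm]] <- sel$scores
      note("term selection (auto): %s", sel$rationale)
    } else {
      tm <- if (identical(terms, "study")) {
        if (nm %in% names(study_terms)) study_terms[[nm]] else "full"
      } else if (is.list(terms) || (is.character(terms) && !is.null(names(terms)))) {
        if (!nm %in% names(terms)) {
          stop("no term set given for response '", nm, "'", call. = FALSE)
        }
        terms[[nm]]
      } else {
        terms
      }
      models[[nm]] <- fit_quadratic(design, y, tm, response_name = nm)
      anovas[[nm]] <- anova(models[[nm]])
      note("term set for %s: %s (%d terms)", nm,
           if (is.character(tm) && length(tm) == 1L) tm else "custom",
           length(models[[nm]]$coefficients))
    }
  }

  correlations <- list()
  if (length(short) >= 2L) {
    for (i in seq_len(length(short) - 1L)) for (j in seq(i + 1L, length(short))) {
      key <- paste(short[i], short[j], sep = "~")
      correlations[[key]] <- pearson_cor(responses[[resp_cols[[short[i]]]]],
                                         responses[[resp_cols[[short[j]]]]])
    }
  }

  des <- desirability_table(models, design, weights = weights)
  for (nm in rownames(des$bounds)) {
    note("desirability bounds for %s: predicted [%.4f, %.4f] over design runs",
         nm, des$bounds[nm, 1L], des$bounds[nm, 2L])
  }
  note("run-wise optimum: run %d, D = %.4f", des$optimum$run_id, des$optimum$D)
  gopt <- grid_optimize(models, design, resolution = resolution,
                        weights = weights)
  profiles <- lapply(1:3, function(k) {
    desirability_profiles(models, design, k, resolution = resolution,
                          weights = weights)
  })
  pairs <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  surface_grids <- lapply(models, function(m) {
    lapply(pairs, function(pr) export_surface_grid(m, pr, 0, resolution))
  })

  validation_out <- NULL
  if (!is.null(validation)) {
    stopifnot(all(c("response", "experimental_mean") %in% names(validation)))
    rows <- lapply(seq_len(nrow(validation)), function(i) {
      nm <- validation$response[i]
      v <- validate_optimum(
        predicted = des$optimum$predicted[[nm]],
        experimental_mean = validation$experimental_mean[i],
        experimental_sd = if ("experimental_sd" %in% names(validation)) {
          validation$experimental_sd[i]
        } else NA_real_,
        response_name = nm)
      data.frame(response = nm, predicted = v$predicted,
                 experimental_mean = v$experimental_mean,
                 experimental_sd = v$experimental_sd,
                 relative_error = v$relative_error)
    })
    validation_out <- do.call(rbind, rows)
    note("validation: %d confirmation rows compared against the optimum predictions",
         nrow(validation_out))
  }

  bundle <- list(design = design, responses = responses, models = models,
                 anovas = anovas,
                 selection = if (length(selection)) selection else NULL,
                 correlations = correlations, desirability = des,
                 grid_optimum = gopt, profiles = profiles,
                 surface_grids = surface_grids,
                 validation = validation_out, log = log)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a pipeline bundle to disk
#'
#' Files are written at full double precision; display rounding is left
#' to the reader.
#'
#' @param bundle A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(bundle$design, file.path(out_dir, "design.csv"))
  write_responses_csv(bundle$responses, file.path(out_dir, "responses.csv"))

  models_json <- lapply(bundle$models, function(m) {
    list(response = m$response_name,
         terms = as.character(m$terms),
         coefficients = as.list(m$coefficients),
         se = as.list(m$se),
         n_obs = m$n_obs, residual_df = m$residual_df, sigma = m$sigma)
  })
  jsonlite::write_json(models_json, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # ANOVA table: terms as rows, responses as columns (per-term p-values),
  # summary statistics appended as extra rows
  terms_all <- .canonical_terms
  an_tab <- data.frame(term = c(terms_all, "R2", "adj_R2", "F_value",
                                "lack_of_fit_p"))
  for (nm in names(bundle$anovas)) {
    an <- bundle$anovas[[nm]]
    pv <- stats::setNames(rep(NA_real_, length(terms_all)), terms_all)
    pv[names(an$p_values)] <- an$p_values
    an_tab[[nm]] <- c(unname(pv), an$r_squared, an$adj_r_squared,
                      an$f_value, an$lack_of_fit_p)
  }
  utils::write.csv(an_tab, file.path(out_dir, "anova.csv"), row.names = FALSE)

  utils::write.csv(bundle$desirability$table,
                   file.path(out_dir, "desirability.csv"), row.names = FALSE)
  opt <- bundle$desirability$optimum
  jsonlite::write_json(
    list(run_id = opt$run_id, coded = as.list(opt$coded),
         natural = as.list(opt$natural), D = opt$D,
         predicted = as.list(opt$predicted),
         bounds = apply(bundle$desirability$bounds, 1L, as.list),
         grid_refined = list(coded = as.list(bundle$grid_optimum$coded),
                             natural = as.list(bundle$grid_optimum$natural),
                             D = bundle$grid_optimum$D)),
    file.path(out_dir, "optimum.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  for (k in seq_along(bundle$profiles)) {
    utils::write.csv(bundle$profiles[[k]],
                     file.path(out_dir, sprintf("profile_factor%d.csv", k)),
                     row.names = FALSE)
  }
  for (nm in names(bundle$surface_grids)) {
    grids <- bundle$surface_grids[[nm]]
    for (k in seq_along(grids)) {
      utils::write.csv(grids[[k]],
                       file.path(out_dir, sprintf("surface_%s_pair%d.csv", nm, k)),
                       row.names = FALSE)
    }
  }
  if (!is.null(bundle$validation)) {
    utils::write.csv(bundle$validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
  }
  writeLines(bundle$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(out_dir)
}
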