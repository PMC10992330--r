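#' @keywords internal
.canonical_terms <- c("(Intercept)", "x1", "x2", "x3",
                      "x1:x2", "x1:x3", "x2:x3",
                      "x1^2", "x2^2", "x3^2")

#' Choose the terms of a second-order model
#'
#' The full second-order polynomial in three coded factors has ten terms
#' in the canonical order intercept, linear (`x1`, `x2`, `x3`),
#' two-factor interactions (`x1:x2`, `x1:x3`, `x2:x3`) and pure
#' quadratics (`x1^2`, `x2^2`, `x3^2`).  The intercept is always
#' included.
#'
#' @param preset One of `"full"` (10 terms), `"no-interactions"`
#'   (intercept + linear + quadratic, 7 terms), `"linear"` (4 terms) or
#'   `"intercept-only"`.
#' @return Character vector of term names (class `term_set`).
#' @export
term_set <- function(preset = c("full", "no-interactions", "linear",
                                "intercept-only")) {
  if (is.character(preset) && length(preset) > 1L &&
      all(preset %in% .canonical_terms)) {
    # explicit term selection; force canonical order and the intercept
    terms <- .canonical_terms[.canonical_terms %in% unique(c("(Intercept)", preset))]
    return(structure(terms, class = "term_set"))
  }
  preset <- match.arg(preset)
  terms <- switch(preset,
    "full"             = .canonical_terms,
    "no-interactions"  = .canonical_terms[c(1:4, 8:10)],
    "linear"           = .canonical_terms[1:4],
    "intercept-only"   = .canonical_terms[1L]
  )
  structure(terms, class = "term_set")
}

.as_term_set <- function(terms) {
  if (inherits(terms, "term_set")) return(terms)
  if (is.character(terms) && length(terms) == 1L &&
      !terms %in% .canonical_terms) return(term_set(terms))
  if (is.character(terms)) {
    if (!all(terms %in% .canonical_terms)) {
      stop("unknown model terms: ",
           paste(setdiff(terms, .canonical_terms), collapse = ", "),
           call. = FALSE)
    }
    return(structure(.canonical_terms[.canonical_terms %in%
                                        unique(c("(Intercept)", terms))],
                     class = "term_set"))
  }
  stop("terms must be a term_set, a preset name, or term names", call. = FALSE)
}

#' Build the model matrix for a second-order fit
#'
#' Interaction columns are elementwise products of the coded factors and
#' quadratic columns their elementwise squares, laid out in canonical
#' term order.
#'
#' @param design A `bbd_design`, coded matrix, or 3-vector of coded
#'   coordinates (see [coded_matrix()]).
#' @param terms A [term_set()] or preset name.
#' @return Numeric matrix, one row per design point, one column per term.
#' @export
build_model_matrix <- function(design, terms = "full") {
  terms <- .as_term_set(terms)
  cm <- coded_matrix(design)
  if (nrow(cm) == 0L) stop("empty design", call. = FALSE)
  x1 <- cm[, "x1"]; x2 <- cm[, "x2"]; x3 <- cm[, "x3"]
  full <- cbind("(Intercept)" = rep(1, nrow(cm)),
                "x1" = x1, "x2" = x2, "x3" = x3,
                "x1:x2" = x1 * x2, "x1:x3" = x1 * x3, "x2:x3" = x2 * x3,
                "x1^2" = x1^2, "x2^2" = x2^2, "x3^2" = x3^2)
  full[, terms, drop = FALSE]
}

#' Fit a second-order response-surface model by least squares
#'
#' Ordinary least squares on the coded model matrix, solved via the QR
#' decomposition (through [stats::lm()]).  Coefficient standard errors
#' come from the residual variance; the fit is fully deterministic.
#'
#' @param design A `bbd_design` (or coded matrix).
#' @param y Response vector, aligned with the design rows.
#' @param terms A [term_set()] or preset name (default full quadratic).
#' @param response_name Label used in reports.
#' @return Object of class `rsm_fit`: coefficients, standard errors,
#'   t statistics and two-sided p-values per term, plus residual
#'   information and the design context needed by [anova.rsm_fit()].
#' @examples
#' fx <- spirulina_fixture()
#' fit_quadratic(fx$design, fx$responses$pigment_mg_per_g, "full", "pigment")
#' @export
fit_quadratic <- function(design, y, terms = "full",
                          response_name = deparse(substitute(y))) {
  terms <- .as_term_set(terms)
  X <- build_model_matrix(design, terms)
  stopifnot(is.numeric(y), length(y) == nrow(X))
  if (!all(is.finite(y))) stop("responses must be finite", call. = FALSE)
  p <- ncol(X)
  if (length(y) <= p) {
    stop("need more observations than model terms", call. = FALSE)
  }
  if (qr(X)$rank < p) {
    stop("singular fit: model matrix is rank deficient", call. = FALSE)
  }
  fit <- stats::lm(y ~ 0 + X)
  # summary.lm warns on numerically perfect fits; noiseless synthetic
  # surfaces are a designed use here, so silence that specific nag
  smry <- suppressWarnings(summary(fit))$coefficients
  rownames(smry) <- sub("^X", "", rownames(smry))
  cm <- coded_matrix(design)
  structure(
    list(
      coefficients  = stats::setNames(smry[, 1L], rownames(smry)),
      se            = stats::setNames(smry[, 2L], rownames(smry)),
      t_value       = stats::setNames(smry[, 3L], rownames(smry)),
      p_value       = stats::setNames(smry[, 4L], rownames(smry)),
      terms         = terms,
      n_obs         = length(y),
      residual_df   = fit$df.residual,
      sigma         = suppressWarnings(summary(fit))$sigma,
      fitted_values = unname(stats::fitted(fit)),
      residuals     = unname(stats::resid(fit)),
      y             = y,
      coded         = cm,
      n_center      = .n_center_of(design),
      factors       = .design_factors(design),
      response_name = response_name
    ),
    class = "rsm_fit"
  )
}

#' @export
print.rsm_fit <- function(x, digits = 4, ...) {
  co <- x$coefficients
  eq <- paste0(
    format(co[1L], digits = digits),
    paste0(sprintf(" %s %s*%s",
                   ifelse(co[-1L] < 0, "-", "+"),
                   format(abs(co[-1L]), digits = digits),
                   names(co)[-1L]),
           collapse = "")
  )
  cat(sprintf("Second-order model for %s (n = %d, residual df = %d)\n",
              x$response_name, x$n_obs, x$residual_df))
  cat("  y-hat =", eq, "\n")
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' @param object An `rsm_fit`.
#' @param newdata Coded coordinates: a `bbd_design`, a matrix/data frame
#'   with `x1`, `x2`, `x3` columns, or a single 3-vector.  Defaults to
#'   the fitted design points.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_values)
  X <- build_model_matrix(coded_matrix(newdata), object$terms)
  unname(drop(X %*% object$coefficients))
}

#' ANOVA with centre-point lack-of-fit for a response-surface model
#'
#' Produces the summary used for model assessment: per-term two-sided
#' t-test p-values, `R^2 = 1 - SSE/SST`, adjusted
#' `R^2 = 1 - (SSE/df_res)/(SST/(n-1))`, the overall regression F
#' statistic `(SSR/(p-1)) / (SSE/df_res)` with its p-value, and the
#' lack-of-fit test that splits the residual sum of squares into pure
#' error from the replicated centre runs (`df_PE = n_center - 1`) and
#' lack of fit (`df_LOF = df_res - df_PE`):
#' `F_LOF = (SS_LOF/df_LOF) / (SS_PE/df_PE)`.  With fewer than two
#' centre replicates the lack-of-fit entries are `NA`.
#'
#' @param object An [fit_quadratic()] result.
#' @param ... Unused.
#' @return Object of class `rsm_anova`.
#' @export
anova.rsm_fit <- function(object, ...) {
  y <- object$y
  n <- object$n_obs
  p <- length(object$coefficients)
  sse <- sum(object$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  df_res <- object$residual_df
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (sse / df_res) / (sst / (n - 1))
  f_value <- (ssr / (p - 1)) / (sse / df_res)
  f_p <- stats::pf(f_value, p - 1, df_res, lower.tail = FALSE)

  nc <- object$n_center
  if (nc >= 2L) {
    center <- rowSums(abs(object$coded)) == 0
    yc <- y[center]
    ss_pe <- sum((yc - mean(yc))^2)
    df_pe <- nc - 1L
    df_lof <- df_res - df_pe
    ss_lof <- sse - ss_pe
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    lof_p <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    ss_pe <- NA_real_; df_pe <- NA_integer_
    ss_lof <- NA_real_; df_lof <- NA_integer_
    f_lof <- NA_real_; lof_p <- NA_real_
  }

  structure(
    list(
      response_name = object$response_name,
      p_values = object$p_value,
      r_squared = r2, adj_r_squared = adj_r2,
      f_value = f_value, f_p_value = f_p,
      sse = sse, ssr = ssr, sst = sst,
      residual_df = df_res,
      ss_pure_error = ss_pe, pure_error_df = df_pe,
      ss_lack_of_fit = ss_lof, lof_df = df_lof,
      lof_f = f_lof, lack_of_fit_p = lof_p
    ),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("ANOVA for %s\n", x$response_name))
  star <- ifelse(x$p_values < 0.05, "*", "")
  tab <- data.frame(term = names(x$p_values),
                    p_value = signif(x$p_values, digits),
                    sig = star)
  print(tab, row.names = FALSE)
  cat(sprintf("  R^2 = %.4f   adj R^2 = %.4f   F = %.4g (p = %.4g)\n",
              x$r_squared, x$adj_r_squared, x$f_value, x$f_p_value))
  if (is.finite(x$lack_of_fit_p)) {
    cat(sprintf("  lack of fit: F = %.4g on (%d, %d) df, p = %.4g\n",
                x$lof_f, x$lof_df, x$pure_error_df, x$lack_of_fit_p))
  } else {
    cat("  lack of fit: undefined (fewer than 2 center replicates)\n")
  }
  invisible(x)
}

#' Terms significant at a given level
#'
#' @param an An `rsm_anova`.
#' @param alpha Significance level (default 0.05).
#' @param include_intercept Whether to report the intercept.
#' @return Character vector of significant term names.
#' @export
significant_terms <- function(an, alpha = 0.05, include_intercept = FALSE) {
  stopifnot(inherits(an, "rsm_anova"))
  p <- an$p_values
  if (!include_intercept) p <- p[names(p) != "(Intercept)"]
  names(p)[p < alpha]
}

#' Select among candidate term sets
#'
#' Fits every candidate and ranks by adjusted R-squared (higher better),
#' then by least-significant lack of fit (larger p preferred), with ties
#' broken in favour of fewer terms.  Singular candidates are dropped
#' with a note; if every candidate is singular an error is raised.
#'
#' The default candidate set holds the two second-order shapes compared
#' in the underlying study — the full quadratic and the no-interaction
#' (intercept + linear + quadratic) model.  A first-order model can be
#' entertained by passing it explicitly; note that on strongly linear
#' responses it can out-rank both second-order shapes on adjusted
#' R-squared, which is the rule working as stated.
#'
#' @param design A `bbd_design`.
#' @param y Response vector.
#' @param candidates Named list of [term_set()]s (or preset names);
#'   defaults to full / no-interactions.
#' @param response_name Label for reports.
#' @return List with elements `model` (the winning `rsm_fit`), `anova`,
#'   `scores` (per-candidate data frame) and `rationale`.
#' @export
select_model <- function(design, y,
                         candidates = list(
                           "full" = term_set("full"),
                           "no-interactions" = term_set("no-interactions")),
                         response_name = deparse(substitute(y))) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  fits <- list(); rows <- list()
  for (nm in names(candidates)) {
    fit <- tryCatch(
      fit_quadratic(design, y, candidates[[nm]], response_name = response_name),
      error = function(e) NULL)
    if (is.null(fit)) next
    an <- anova(fit)
    fits[[nm]] <- list(fit = fit, anova = an)
    rows[[nm]] <- data.frame(
      candidate = nm, n_terms = length(fit$coefficients),
      r_squared = an$r_squared, adj_r_squared = an$adj_r_squared,
      lack_of_fit_p = an$lack_of_fit_p, stringsAsFactors = FALSE)
  }
  if (!length(fits)) stop("all candidate term sets are singular", call. = FALSE)
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  ord <- order(-scores$adj_r_squared,
               -ifelse(is.na(scores$lack_of_fit_p), -Inf, scores$lack_of_fit_p),
               scores$n_terms)
  scores <- scores[ord, , drop = FALSE]
  winner <- scores$candidate[1L]
  rationale <- sprintf(
    "selected '%s' for %s: adj R^2 = %.4f (ranked by adjusted R^2, then lack-of-fit p, then parsimony)",
    winner, response_name, scores$adj_r_squared[1L])
  list(model = fits[[winner]]$fit, anova = fits[[winner]]$anova,
       scores = scores, rationale = rationale)
}

#' Pearson correlation between two responses
#'
#' Sample Pearson correlation with the usual two-sided t-based test,
#' via [stats::cor.test()].
#'
#' @param a,b Numeric vectors of equal length >= 3, non-constant.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_cor <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant input: Pearson correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
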