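#' Define an experimental factor for a coded design
#'
#' A factor is described by its natural-unit low, centre and high levels.
#' Coding maps natural values onto the dimensionless scale used by the
#' response-surface model via `(value - center) / half_range`, where
#' `half_range = (high - low) / 2`, so the three design levels land on
#' -1, 0 and +1.
#'
#' @param name Column name used for the factor in design tables
#'   (e.g. `"temperature_C"`).
#' @param low,high Natural-unit extremes of the investigated range.
#' @param center Natural-unit centre level. Defaults to the midpoint of
#'   `low` and `high`; an off-midpoint centre is accepted (coding still
#'   uses `(value - center)/half_range`) but triggers a warning because
#'   the three levels are then asymmetric.
#' @param units Free-text unit label, for reporting only.
#' @return An object of class `factor_def`.
#' @examples
#' factor_def("temperature_C", 50, 70, units = "degC")
#' @export
factor_def <- function(name, low, high, center = (low + high) / 2, units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  vals <- c(low = low, center = center, high = high)
  if (!all(is.finite(vals))) {
    stop("invalid factor '", name, "': levels must be finite", call. = FALSE)
  }
  if (!(low < center && center < high)) {
    stop("invalid factor '", name, "': need low < center < high", call. = FALSE)
  }
  if (abs(center - (low + high) / 2) > 1e-8 * (high - low)) {
    warning("factor '", name, "': center is not the midpoint of [low, high]; ",
            "coded levels will be asymmetric", call. = FALSE)
  }
  structure(
    list(name = name, low = low, center = center, high = high, units = units),
    class = "factor_def"
  )
}

#' @export
print.factor_def <- function(x, ...) {
  cat(sprintf("factor %s: %g / %g / %g %s\n",
              x$name, x$low, x$center, x$high, x$units))
  invisible(x)
}

#' The three ultrasound-assisted extraction factors
#'
#' Default factor definitions for the Spirulina extraction study:
#' bath temperature 50-70 degC, extraction-cycle time 20-40 min, and
#' solvent-to-biomass ratio 50-70 mL/mg (the ratio unit label is carried
#' as published; it is not converted).
#'
#' @return A list of three [factor_def()] objects.
#' @export
uae_factors <- function() {
  list(
    factor_def("temperature_C",   50, 70, units = "degC"),
    factor_def("time_min",        20, 40, units = "min"),
    factor_def("ratio_mL_per_mg", 50, 70, units = "mL/mg")
  )
}

.half_range <- function(f) (f$high - f$low) / 2

.check_factors <- function(factors) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  for (f in factors) {
    if (!inherits(f, "factor_def")) {
      stop("factors must be a list of factor_def objects", call. = FALSE)
    }
    if (.half_range(f) <= 0) {
      stop("degenerate factor '", f$name, "': zero half-range", call. = FALSE)
    }
  }
  invisible(factors)
}

#' Convert natural factor values to coded levels
#'
#' @param factors List of [factor_def()] objects (one per coordinate).
#' @param natural Numeric vector of length `length(factors)`, or a matrix
#'   with that many columns (rows are points).
#' @return Coded values, same shape as `natural`.
#' @examples
#' code_point(uae_factors(), c(70, 20, 60))  # (1, -1, 0)
#' @export
code_point <- function(factors, natural) {
  .check_factors(factors)
  ctr  <- vapply(factors, function(f) f$center, numeric(1))
  half <- vapply(factors, function(f) .half_range(f), numeric(1))
  if (is.matrix(natural) || is.data.frame(natural)) {
    m <- as.matrix(natural)
    stopifnot(ncol(m) == length(factors))
    sweep(sweep(m, 2L, ctr, "-"), 2L, half, "/")
  } else {
    stopifnot(length(natural) == length(factors))
    (natural - ctr) / half
  }
}

#' Convert coded levels back to natural factor values
#'
#' Exact inverse of [code_point()].
#'
#' @inheritParams code_point
#' @param coded Coded values, vector or matrix.
#' @examples
#' decode_point(uae_factors(), c(-1, 0, 1))  # (50, 30, 70)
#' @export
decode_point <- function(factors, coded) {
  .check_factors(factors)
  ctr  <- vapply(factors, function(f) f$center, numeric(1))
  half <- vapply(factors, function(f) .half_range(f), numeric(1))
  if (is.matrix(coded) || is.data.frame(coded)) {
    m <- as.matrix(coded)
    stopifnot(ncol(m) == length(factors))
    sweep(sweep(m, 2L, half, "*"), 2L, ctr, "+")
  } else {
    stopifnot(length(coded) == length(factors))
    coded * half + ctr
  }
}

#' Build a three-factor Box-Behnken design
#'
#' Constructs the canonical 3-factor, 3-level Box-Behnken design: the 12
#' edge midpoints of the coded cube (all sign combinations of two factors
#' at +-1 with the third at 0, in blocks `(x1,x2)`, `(x1,x3)`, `(x2,x3)`)
#' followed by `n_center` replicate centre runs at `(0,0,0)`.  Runs are
#' returned in this fixed canonical order; no run-order randomization is
#' applied (pass the table through [shuffle_runs()] for that).
#'
#' @param factors List of exactly 3 [factor_def()] objects.
#' @param n_center Number of replicate centre points (>= 1).
#' @return A `bbd_design`: a data frame with columns `run_id`, the three
#'   natural-unit factor columns (named after the factors), and coded
#'   columns `x1`, `x2`, `x3`; attributes `factors` and `n_center`.
#' @examples
#' build_bbd(uae_factors(), n_center = 3)
#' @export
build_bbd <- function(factors, n_center = 3) {
  .check_factors(factors)
  if (length(factors) != 3L) {
    stop("only the 3-factor Box-Behnken construction is supported", call. = FALSE)
  }
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1 ||
      n_center != round(n_center)) {
    stop("n_center must be a positive integer", call. = FALSE)
  }
  n_center <- as.integer(n_center)
  pm <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))[, c("a", "b")]
  blocks <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  coded <- do.call(rbind, lapply(blocks, function(pair) {
    m <- matrix(0, nrow = 4L, ncol = 3L)
    m[, pair] <- pm
    m
  }))
  coded <- rbind(coded, matrix(0, nrow = n_center, ncol = 3L))
  colnames(coded) <- c("x1", "x2", "x3")
  natural <- decode_point(factors, coded)
  colnames(natural) <- vapply(factors, function(f) f$name, character(1))
  out <- data.frame(run_id = seq_len(nrow(coded)), natural, coded,
                    check.names = FALSE)
  structure(out,
            factors = factors, n_center = n_center,
            class = c("bbd_design", "data.frame"))
}

#' Randomize the run order of a design
#'
#' @param design A `bbd_design`.
#' @param seed Integer seed; the permutation is fully determined by it.
#' @return The design with rows permuted; `run_id` is renumbered to the
#'   new execution order and the original id retained as `std_order`.
#' @export
shuffle_runs <- function(design, seed) {
  stopifnot(inherits(design, "bbd_design"))
  set.seed(seed)
  idx <- sample.int(nrow(design))
  out <- design[idx, , drop = FALSE]
  out$std_order <- out$run_id
  out$run_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attributes(out)[c("factors", "n_center")] <-
    attributes(design)[c("factors", "n_center")]
  class(out) <- class(design)
  out
}

#' Extract the coded design matrix
#'
#' @param design A `bbd_design`, or any data frame / matrix carrying
#'   columns `x1`, `x2`, `x3`.
#' @return Numeric matrix with columns `x1`, `x2`, `x3`.
#' @export
coded_matrix <- function(design) {
  if (is.matrix(design)) {
    if (!is.null(colnames(design)) && all(c("x1", "x2", "x3") %in% colnames(design))) {
      return(design[, c("x1", "x2", "x3"), drop = FALSE])
    }
    stopifnot(ncol(design) == 3L)
    colnames(design) <- c("x1", "x2", "x3")
    return(design)
  }
  if (is.data.frame(design)) {
    stopifnot(all(c("x1", "x2", "x3") %in% names(design)))
    m <- as.matrix(design[, c("x1", "x2", "x3")])
    rownames(m) <- NULL
    return(m)
  }
  stopifnot(is.numeric(design), length(design) == 3L)
  matrix(design, nrow = 1L, dimnames = list(NULL, c("x1", "x2", "x3")))
}

.design_factors <- function(design, default = uae_factors()) {
  f <- attr(design, "factors", exact = TRUE)
  if (is.null(f)) default else f
}

.n_center_of <- function(design) {
  nc <- attr(design, "n_center", exact = TRUE)
  if (!is.null(nc)) return(nc)
  sum(rowSums(abs(coded_matrix(design))) == 0)
}

#' Check a design table against the Box-Behnken invariants
#'
#' Returns findings rather than raising conditions, so a partially broken
#' table can still be inspected.  Checks: total run count (12 edge
#' midpoints + `n_center` centres), coded levels restricted to
#' \{-1, 0, +1\}, exactly one zero coordinate on every non-centre run,
#' zero column sums, the number of all-zero rows matching `n_center`, and
#' agreement between the natural columns and the decoded coded columns.
#'
#' @param design A `bbd_design` (or compatible data frame with attributes).
#' @return Character vector of findings; empty for a canonical design.
#' @export
validate_design <- function(design) {
  findings <- character(0)
  cm <- coded_matrix(design)
  n_center <- .n_center_of(design)
  factors <- .design_factors(design)

  if (nrow(cm) != 12L + n_center) {
    findings <- c(findings, sprintf(
      "run-count mismatch: %d runs, expected %d (12 + %d center)",
      nrow(cm), 12L + n_center, n_center))
  }
  if (!all(cm %in% c(-1, 0, 1))) {
    findings <- c(findings, "coded levels outside {-1, 0, +1}")
  }
  zero_per_row <- rowSums(cm == 0)
  is_center <- zero_per_row == 3L
  if (sum(is_center) != n_center) {
    findings <- c(findings, sprintf(
      "center-count mismatch: %d all-zero runs, expected %d",
      sum(is_center), n_center))
  }
  if (any(zero_per_row[!is_center] != 1L)) {
    findings <- c(findings,
                  "non-center run without exactly one zero coded component")
  }
  cs <- colSums(cm)
  if (any(cs != 0)) {
    findings <- c(findings, sprintf(
      "non-zero coded column sums: (%s)", paste(cs, collapse = ", ")))
  }
  nat_cols <- vapply(factors, function(f) f$name, character(1))
  if (is.data.frame(design) && all(nat_cols %in% names(design))) {
    nat <- as.matrix(design[, nat_cols])
    expected <- decode_point(factors, cm)
    bad <- which(rowSums(abs(nat - expected) > 1e-8) > 0)
    if (length(bad)) {
      findings <- c(findings, sprintf(
        "coded/natural mismatch at runs %s", paste(bad, collapse = ",")))
    }
  }
  findings
}

#' @export
print.bbd_design <- function(x, ...) {
  cat(sprintf("Box-Behnken design: %d runs (%d center)\n",
              nrow(x), .n_center_of(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
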