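#' DIF shift patterns for the four simulated kinds of DIF
#'
#' Builds the per-threshold shifts added to the focal group's item locations.
#' Four kinds of differential item functioning are distinguished:
#'
#' * **uniform**: every threshold shifted by the same amount `size`; the item
#'   characteristic curves of the two groups are parallel and the item is
#'   uniformly harder in the focal group.
#' * **balanced non-uniform** (`balanced_gentle`, `balanced_very_gentle`,
#'   `balanced_steep`): shifts differ across thresholds but sum to zero, so
#'   the overall item difficulty is unchanged and the two characteristic
#'   curves cross at the centre of the item.  The gentle pattern spreads the
#'   focal thresholds (flatter curve), the steep pattern compresses them
#'   (steeper curve); "very gentle" is the gentle pattern at `size = 2`.
#' * **unbalanced non-uniform** (`unbalanced_small`, `unbalanced_large`):
#'   shifts differ across thresholds and sum to a positive value, so the item
#'   is harder overall in the focal group.
#'
#' The balanced patterns use the antisymmetric ladder
#' \eqn{(\,\dots, -1.5\Delta, -0.5\Delta, +0.5\Delta, +1.5\Delta)} (for
#' `K = 4`), which satisfies the sum-zero constraint and makes the curves
#' cross at the latent-trait value equal to the item's mean location.  The
#' unbalanced patterns are perturbations of a unit uniform shift: "small"
#' adds the gentle ladder at 0.5, "large" adds the positive half of the
#' gentle ladder at 1 (so its total shift is larger).  Both can be replaced
#' via `deltas`.
#'
#' @param kind one of `"none"`, `"uniform"`, `"balanced_gentle"`,
#'   `"balanced_very_gentle"`, `"balanced_steep"`, `"unbalanced_small"`,
#'   `"unbalanced_large"`.
#' @param size DIF effect size \eqn{\Delta} in logits (uniform and balanced
#'   kinds; the study grid uses 0.25, 0.5 and 1, and 2 for the very gentle
#'   slope).  Ignored for unbalanced kinds unless `deltas` is given.
#' @param K number of thresholds per item (categories minus one).
#' @param deltas optional explicit shift vector overriding the built-in
#'   pattern (checked against the kind's sum constraint).
#' @return An object of class `dif_spec`: list with `kind`, `size`, `deltas`.
#' @examples
#' make_dif_deltas("uniform", 0.5)           # (0.5, 0.5, 0.5, 0.5)
#' make_dif_deltas("balanced_gentle", 1)     # sums to zero
#' make_dif_deltas("unbalanced_small")       # sums to a positive value
#' @export
make_dif_deltas <- function(kind, size = NULL, K = 4L, deltas = NULL) {
  kinds <- c("none", "uniform", "balanced_gentle", "balanced_very_gentle",
             "balanced_steep", "unbalanced_small", "unbalanced_large")
  kind <- match.arg(kind, kinds)
  if (K < 1L) stop("`K` must be at least 1")
  ladder <- function(d) (seq_len(K) - (K + 1) / 2) * d  # antisymmetric, sum 0
  if (kind %in% c("uniform", "balanced_gentle", "balanced_steep")) {
    if (is.null(size) || !is.finite(size) || size <= 0)
      stop("`size` must be a positive effect size in logits for kind '",
           kind, "'")
    if (!size %in% c(0.25, 0.5, 1))
      warning("effect size ", size, " is outside the usual grid {0.25, 0.5, 1}")
  }
  if (kind == "balanced_very_gentle") {
    if (is.null(size)) size <- 2
    if (!isTRUE(all.equal(size, 2)))
      warning("the very gentle slope is defined at size 2; got ", size)
  }
  if (is.null(deltas)) {
    deltas <- switch(kind,
      none                 = rep(0, K),
      uniform              = rep(size, K),
      balanced_gentle      = ladder(size),
      balanced_very_gentle = ladder(size),
      balanced_steep       = -ladder(size),
      unbalanced_small     = rep(1, K) + ladder(0.5),
      unbalanced_large     = rep(1, K) + pmax(0, ladder(1)))
  } else {
    if (length(deltas) != K) stop("`deltas` must have length K = ", K)
  }
  if (is.null(size)) size <- NA_real_
  spec <- structure(list(kind = kind, size = size, deltas = as.numeric(deltas)),
                    class = "dif_spec")
  validate_dif_spec(spec)
  spec
}

validate_dif_spec <- function(spec) {
  d <- spec$deltas
  s <- sum(d)
  ok <- switch(spec$kind,
    none    = all(d == 0),
    uniform = all(abs(d - spec$size) < 1e-12),
    balanced_gentle      = ,
    balanced_very_gentle = ,
    balanced_steep       = abs(s) < 1e-12,
    unbalanced_small     = ,
    unbalanced_large     = s > 0)
  if (!ok) stop("shift pattern violates the '", spec$kind, "' sum constraint")
  invisible(spec)
}

#' @export
print.dif_spec <- function(x, ...) {
  cat("DIF pattern:", x$kind,
      if (is.finite(x$size)) paste0("(size ", x$size, " logit)"), "\n")
  cat("  threshold shifts:", paste(format(x$deltas, digits = 3),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Apply a DIF pattern to item parameters
#'
#' Returns the focal-group version of an item or item bank: the threshold
#' shifts of `spec` are added elementwise to the reference locations.  The
#' reference object is not modified.
#'
#' @param x an [item_bank()] or a numeric vector of threshold locations.
#' @param spec a [make_dif_deltas()] specification.
#' @param items for a bank, integer indices (or item ids) of the rows that
#'   receive the DIF; defaults to all items.
#' @return An object of the same shape as `x` with shifted locations.
#' @export
apply_dif <- function(x, spec, items = NULL) {
  stopifnot(inherits(spec, "dif_spec"))
  if (is.numeric(x)) {
    if (length(x) != length(spec$deltas))
      stop("length mismatch between item locations and DIF shifts")
    return(x + spec$deltas)
  }
  m <- bank_matrix(x)
  if (ncol(m) != length(spec$deltas))
    stop("length mismatch between item thresholds and DIF shifts")
  if (is.null(items)) items <- seq_len(nrow(m))
  if (is.character(items)) items <- match(items, x$item_id)
  if (anyNA(items) || any(items < 1L | items > nrow(m)))
    stop("`items` must index rows of the bank")
  m[items, ] <- sweep(m[items, , drop = FALSE], 2L, spec$deltas, "+")
  item_bank(m, item_id = x$item_id)
}

#' Classify an observed DIF pattern
#'
#' Compares focal against reference threshold locations of one item and
#' labels the difference as no DIF, uniform DIF, balanced non-uniform DIF
#' (shifts sum to about zero) or unbalanced non-uniform DIF.  The effect-size
#' summary reports per-threshold differences and their mean, the overall
#' group difference in item location — the recommended DIF effect-size
#' measure.
#'
#' @param reference,focal numeric vectors of threshold locations (same K).
#' @param tol classification tolerance in logits.  The default 0.05 is an
#'   order of magnitude below the smallest meaningful effect size (0.25
#'   logit), so estimation noise around zero is not over-interpreted.
#' @return list with `kind` (one of `"none"`, `"uniform"`,
#'   `"balanced_nonuniform"`, `"unbalanced_nonuniform"`), `deltas`,
#'   `overall` (mean delta), `max_abs` (largest absolute per-threshold
#'   delta) and `sum`.
#' @examples
#' classify_dif(c(-1, 0, 1), c(-0.5, 0.5, 1.5))  # uniform, overall 0.5
#' @export
classify_dif <- function(reference, focal, tol = 0.05) {
  if (length(reference) != length(focal))
    stop("`reference` and `focal` must have the same number of thresholds")
  classify_dif_deltas(focal - reference, tol = tol)
}

#' @rdname classify_dif
#' @param deltas per-threshold group differences (focal minus reference).
#' @export
classify_dif_deltas <- function(deltas, tol = 0.05) {
  if (!is.numeric(tol) || tol < 0) stop("`tol` must be non-negative")
  if (!all(is.finite(deltas))) stop("`deltas` must be finite")
  K <- length(deltas)
  kind <- if (max(abs(deltas)) <= tol) "none"
    else if (max(deltas) - min(deltas) <= tol) "uniform"
    else if (abs(sum(deltas)) <= K * tol) "balanced_nonuniform"
    else "unbalanced_nonuniform"
  list(kind = kind, deltas = deltas, overall = mean(deltas),
       max_abs = max(abs(deltas)), sum = sum(deltas))
}
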