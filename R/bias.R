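#' Run replications of one scenario
#'
#' Repeats the simulate-then-fit cycle: draw a dataset from `config`, fit
#' the latent-regression partial credit model that ignores DIF, and record
#' the estimated group difference.  The measurement bias of each
#' replication is `delta = gamma_hat - true_diff` (estimated minus true
#' reference-minus-focal difference), so DIF that makes focal items harder
#' yields positive deltas.  Replication seeds come from [derive_seed()], so
#' any record can be regenerated in isolation; per-replication fit failures
#' are recorded (`converged = FALSE`, `delta = NA`) rather than raised.
#'
#' @param config a [scenario_config()] or one row of a [scenario_grid()].
#' @param n_reps number of replications (>= 1).
#' @param master_seed master seed for [derive_seed()].
#' @param cell scenario cell index used in seed derivation.
#' @param quadrature Gauss-Hermite nodes for the fits.
#' @return Data frame with one row per replication: the scenario factors,
#'   `rep`, `seed`, `gamma_hat`, `sigma_hat`, `delta`, `converged`.
#' @export
run_scenario <- function(config, n_reps, master_seed = 1L, cell = 0L,
                         quadrature = 31L) {
  if (n_reps < 1L) stop("`n_reps` must be at least 1")
  if (is.data.frame(config)) config <- config_from_row(config[1L, ])
  stopifnot(inherits(config, "scenario_config"))
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    seed <- derive_seed(master_seed, cell, r)
    d <- simulate_dataset(config, seed = seed)
    fit <- tryCatch(
      suppressWarnings(fit_latent_regression_pcm(d, quadrature = quadrature,
                                                 se = FALSE)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$convergence$converged && is.finite(fit$gamma)
    rows[[r]] <- data.frame(
      cell = cell, rep = r, seed = seed,
      n_items = config$n_items, group_size = config$group_size,
      true_diff = config$true_diff, dif_kind = config$dif_kind,
      dif_size = if (is.null(config$dif_size)) NA_real_ else config$dif_size,
      dif_proportion = config$dif_proportion,
      dif_position = config$dif_position,
      gamma_hat = if (is.null(fit)) NA_real_ else fit$gamma,
      sigma_hat = if (is.null(fit)) NA_real_ else fit$sigma,
      delta = if (ok) fit$gamma - config$true_diff else NA_real_,
      converged = ok, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run a whole factorial study
#'
#' Applies [run_scenario()] to every cell of a [scenario_grid()] (or a
#' user-supplied subset of one) and stacks the replication records,
#' carrying along the grid's `size_label` used for reference coding in
#' [anova_bias()].
#'
#' @param study study name passed to [scenario_grid()]; ignored when `grid`
#'   is given.
#' @param n_reps replications per cell (scalar, or vector with one entry
#'   per grid row for precision-driven allocations).
#' @param master_seed master seed.
#' @param grid optional grid data frame (rows of a [scenario_grid()]).
#' @param quadrature Gauss-Hermite nodes.
#' @param progress print a line per cell to stderr.
#' @return Data frame of replication records across all cells.
#' @export
run_study <- function(study = NULL, n_reps = 30L, master_seed = 1L,
                      grid = NULL, quadrature = 31L, progress = FALSE) {
  if (is.null(grid)) grid <- scenario_grid(study)
  reps <- rep_len(n_reps, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    rec <- run_scenario(config_from_row(row), reps[i],
                        master_seed = master_seed, cell = row$cell,
                        quadrature = quadrature)
    rec$size_label <- row$size_label
    out[[i]] <- rec
    if (progress)
      message(sprintf("cell %d/%d: mean delta %.4f (%d/%d converged)",
                      i, nrow(grid), mean(rec$delta, na.rm = TRUE),
                      sum(rec$converged), reps[i]))
  }
  do.call(rbind, out)
}

#' Measurement bias of a set of replication records
#'
#' The mean of `delta` (estimated minus true group difference) over
#' converged replications, with its Monte-Carlo standard error.
#'
#' @param records data frame from [run_scenario()] / [run_study()].
#' @return List with `bias`, `mc_se`, `n_converged`, `n_total`.
#' @export
measurement_bias <- function(records) {
  ok <- records$converged & is.finite(records$delta)
  if (!any(ok)) stop("no converged replications")
  d <- records$delta[ok]
  list(bias = mean(d), mc_se = sd(d) / sqrt(length(d)),
       n_converged = length(d), n_total = nrow(records))
}

#' Random-error benchmark from the no-DIF scenarios
#'
#' Runs the 12 no-DIF cells (scale length x group size x true difference)
#' and returns the maximum absolute mean delta across them.  With no DIF in
#' the generating model this delta is pure random error; its maximum is the
#' benchmark against which DIF-induced measurement bias is judged.
#'
#' @inheritParams run_study
#' @return List with `benchmark` (max |mean delta|), `cells` (per-cell
#'   bias table with Monte-Carlo SEs) and `records`.
#' @export
random_error_benchmark <- function(n_reps = 100L, master_seed = 1L,
                                   quadrature = 31L, progress = FALSE) {
  grid <- scenario_grid("no_dif_benchmark")
  records <- run_study(grid = grid, n_reps = n_reps, master_seed = master_seed,
                       quadrature = quadrature, progress = progress)
  cells <- do.call(rbind, lapply(split(records, records$cell), function(r) {
    b <- measurement_bias(r)
    data.frame(cell = r$cell[1L], n_items = r$n_items[1L],
               group_size = r$group_size[1L], true_diff = r$true_diff[1L],
               bias = b$bias, mc_se = b$mc_se, n_converged = b$n_converged)
  }))
  rownames(cells) <- NULL
  list(benchmark = max(abs(cells$bias)), cells = cells, records = records)
}

#' ANOVA of measurement bias on the DIF design factors
#'
#' Ordinary least squares of the per-replication delta on reference-coded
#' factor indicators: DIF effect size (reference: smallest size, or the
#' balanced pattern for the unbalanced study), proportion of DIF items
#' (reference 25%), DIF position (reference "Unif"), and the effect-size by
#' proportion interaction.  Any non-DIF factor that varies in the records
#' (scale length, group size, true difference) enters as an additional
#' reference-coded covariate with its smallest level as reference.
#'
#' With `interactions = "auto"` the interaction block is kept only when at
#' least one of its coefficients is statistically significant at 5% with
#' absolute estimate above 0.1 logit; otherwise the model is refitted
#' without it.
#'
#' Coefficients are classified by magnitude alone: `negligible` when the
#' absolute estimate is at most 0.015 logit (the scale of the random-error
#' benchmark), `major` when above 0.1 logit (half of a small effect size),
#' `small` in between.  P-values are reported but play no part in the
#' classification.
#'
#' @param records replication records from [run_study()] (must span at
#'   least two levels of each modelled factor).
#' @param interactions `"auto"`, `"always"` or `"never"`.
#' @return Object of class `bias_anova`: a data frame with one row per
#'   coefficient (`term`, `factor`, `category`, `estimate`, `se`,
#'   `p_value`, `classification`), with the `lm` fit in attribute
#'   `"model"`.
#' @export
anova_bias <- function(records, interactions = c("auto", "always", "never")) {
  interactions <- match.arg(interactions)
  ok <- records$converged & is.finite(records$delta)
  d <- records[ok, , drop = FALSE]
  if (!nrow(d)) stop("no converged replications")
  size_levels <- unique(records$size_label)
  ref_first <- c("0.25", "balanced (1)", "none")
  size_levels <- c(intersect(ref_first, size_levels),
                   setdiff(size_levels, ref_first))
  df <- data.frame(
    delta = d$delta,
    size = factor(d$size_label, levels = size_levels),
    prop = factor(sprintf("%d%%", round(100 * d$dif_proportion)),
                  levels = c("25%", "50%", "75%")),
    position = factor(d$dif_position,
                      levels = c("Unif", "Mean", "Extreme", "High", "Low")))
  df <- droplevels(df)
  rhs <- c()
  if (nlevels(df$size) > 1L) rhs <- c(rhs, "size")
  if (nlevels(df$prop) > 1L) rhs <- c(rhs, "prop")
  if (nlevels(df$position) > 1L) rhs <- c(rhs, "position")
  covmap <- c(n_items = "items", group_size = "gsize", true_diff = "tdiff")
  for (col in names(covmap)) {
    vals <- d[[col]]
    if (length(unique(vals)) > 1L) {
      df[[covmap[[col]]]] <- factor(vals, levels = sort(unique(vals)))
      rhs <- c(rhs, covmap[[col]])
    }
  }
  want_int <- interactions != "never" &&
    all(c("size", "prop") %in% rhs) &&
    nlevels(droplevels(interaction(df$size, df$prop))) ==
      nlevels(df$size) * nlevels(df$prop)
  form <- function(with_int) {
    terms <- rhs
    if (with_int) terms <- c(terms, "size:prop")
    stats::as.formula(paste("delta ~", paste(terms, collapse = " + ")))
  }
  fit <- lm(form(want_int), data = df)
  if (want_int && interactions == "auto") {
    tab <- summary(fit)$coefficients
    int <- grepl(":", rownames(tab))
    keep <- any(tab[int, 4L] < 0.05 & abs(tab[int, 1L]) > 0.1)
    if (!keep) fit <- lm(form(FALSE), data = df)
  }
  tidy_anova(fit)
}

tidy_anova <- function(fit) {
  tab <- summary(fit)$coefficients
  asg <- attr(model.matrix(fit), "assign")
  labs <- attr(terms(fit), "term.labels")
  fmap <- c(size = "effect_size", prop = "proportion", position = "position",
            items = "n_items", gsize = "group_size", tdiff = "true_diff",
            "size:prop" = "interaction")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- rownames(tab)[i]
    if (asg[i] == 0L) {
      fac <- "constant"; cat_ <- ""
    } else {
      lab <- labs[asg[i]]
      fac <- unname(fmap[lab])
      cat_ <- nm
      for (v in strsplit(lab, ":", fixed = TRUE)[[1L]])
        cat_ <- sub(v, "", cat_, fixed = TRUE)
      cat_ <- gsub(":", "*", cat_, fixed = TRUE)
    }
    data.frame(term = nm, factor = fac, category = cat_,
               estimate = tab[i, 1L], se = tab[i, 2L], p_value = tab[i, 4L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$classification <- classify_effect(out$estimate)
  rownames(out) <- NULL
  attr(out, "model") <- fit
  class(out) <- c("bias_anova", "data.frame")
  out
}

#' Classify ANOVA effect magnitudes
#'
#' The negligible/small/major grading applied to bias ANOVA coefficients:
#' at most 0.015 logit (the random-error scale) is `negligible`, above 0.1
#' logit (half of a small effect size) is `major`, in between is `small`.
#'
#' @param estimate numeric vector of coefficients in logits.
#' @param negligible,major the two thresholds.
#' @return Character vector of classifications.
#' @export
classify_effect <- function(estimate, negligible = 0.015, major = 0.1) {
  ifelse(abs(estimate) <= negligible, "negligible",
         ifelse(abs(estimate) <= major, "small", "major"))
}

#' Look up a bias ANOVA coefficient
#'
#' @param anova a `bias_anova` table.
#' @param factor factor name (`"effect_size"`, `"proportion"`,
#'   `"position"`, `"interaction"`, `"true_diff"`, ..., or `"constant"`).
#' @param category category label (e.g. `"0.5"`, `"75%"`, `"0.5*50%"`);
#'   ignored for the constant.
#' @return The coefficient row (single-row data frame).
#' @export
anova_coef <- function(anova, factor, category = "") {
  hit <- anova$factor == factor & (factor == "constant" |
                                     anova$category == category)
  if (sum(hit) != 1L)
    stop("no unique coefficient for ", factor, " / ", category)
  anova[hit, , drop = FALSE]
}

#' @export
print.bias_anova <- function(x, ...) {
  cat("Measurement-bias ANOVA (", nrow(x), "coefficients )\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
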