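#' Build the study item bank
#'
#' Item mean locations \eqn{\beta_j} are placed at the `j/(n_items+1)`
#' quantiles of the standard normal distribution, so the scale covers the
#' latent continuum the traits are drawn from.  Threshold locations are the
#' item mean plus a zero-mean ladder `(-1.5, -0.5, 0.5, 1.5) * step` (for 5
#' response categories), so each item's mean threshold equals \eqn{\beta_j}.
#'
#' @param n_items number of items (at least 2).
#' @param n_categories number of response categories per item (at least 2);
#'   the study design uses 5.
#' @param step spacing of the threshold ladder in logits (default 0.5,
#'   giving thresholds spanning \eqn{\pm 0.75} around the item location).
#' @return An [item_bank()] with attribute `beta` (the item mean locations).
#' @examples
#' build_item_bank(4)   # items at the 0.2, 0.4, 0.6, 0.8 normal quantiles
#' @export
build_item_bank <- function(n_items, n_categories = 5L, step = 0.5) {
  if (n_items < 2L) stop("`n_items` must be at least 2")
  if (n_categories < 2L) stop("`n_categories` must be at least 2")
  K <- n_categories - 1L
  beta <- qnorm(seq_len(n_items) / (n_items + 1L))
  spread <- (seq_len(K) - (K + 1) / 2) * step
  bank <- item_bank(outer(beta, spread, "+"))
  attr(bank, "beta") <- beta
  bank
}

#' Select which items receive DIF
#'
#' Deterministically picks `n_dif` items according to the position of their
#' mean location along the latent continuum:
#' `"Unif"` spreads the DIF items evenly over the difficulty order (centred
#' systematic sampling), `"Mean"` takes the items closest to the mean
#' difficulty, `"Extreme"` alternates hardest/easiest, `"High"` takes the
#' hardest and `"Low"` the easiest items.
#'
#' @param position one of `"Unif"`, `"Mean"`, `"Extreme"`, `"High"`, `"Low"`.
#' @param n_dif number of items to select (1..`length(beta)`).
#' @param beta item mean locations, or an [item_bank()] built by
#'   [build_item_bank()].
#' @return Integer vector of item indices (in bank order).
#' @export
select_dif_items <- function(position, n_dif, beta) {
  position <- match.arg(position, c("Unif", "Mean", "Extreme", "High", "Low"))
  if (inherits(beta, "item_bank")) beta <- rowMeans(bank_matrix(beta))
  n <- length(beta)
  if (n_dif < 1L || n_dif > n) stop("`n_dif` must be between 1 and ", n)
  asc <- order(beta)                      # easiest first
  idx <- switch(position,
    Unif = asc[ceiling((seq_len(n_dif) - 0.5) * n / n_dif)],
    Mean = order(abs(beta - mean(beta)))[seq_len(n_dif)],
    Extreme = {
      desc <- rev(asc)
      take <- integer(n_dif)
      hi <- 1L; lo <- 1L
      for (i in seq_len(n_dif)) {
        if (i %% 2L == 1L) { take[i] <- desc[hi]; hi <- hi + 1L }
        else               { take[i] <- asc[lo];  lo <- lo + 1L }
      }
      take
    },
    High = rev(asc)[seq_len(n_dif)],
    Low  = asc[seq_len(n_dif)])
  sort(idx)
}

#' Define one simulation scenario
#'
#' One cell of the factorial design: scale length, group size, true latent
#' difference, and the DIF kind/size/proportion/position.  Latent traits are
#' standard normal in the reference group and `N(-true_diff, 1)` in the
#' focal group, so `true_diff` is the reference-minus-focal mean difference
#' and the focal group is the lower-scoring one when it is positive.
#'
#' @param n_items number of items (the design uses 4 or 8).
#' @param group_size persons per group (equal groups; the design uses 100 or
#'   200).
#' @param true_diff true latent mean difference in logits, reference minus
#'   focal (0 to 0.5 in the design).
#' @param dif_kind DIF kind, see [make_dif_deltas()].
#' @param dif_size DIF effect size in logits.
#' @param dif_proportion proportion of items affected (0.25, 0.5, 0.75);
#'   the affected count is `round(dif_proportion * n_items)`, at least 1
#'   when `dif_kind != "none"`.
#' @param dif_position placement of DIF items, see [select_dif_items()].
#' @param n_categories response categories per item (design value 5).
#' @param step threshold ladder spacing, see [build_item_bank()].
#' @param dif_deltas optional explicit shift pattern override.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_items = 8L, group_size = 200L, true_diff = 0.1,
                            dif_kind = "none", dif_size = NULL,
                            dif_proportion = 0, dif_position = "Unif",
                            n_categories = 5L, step = 0.5,
                            dif_deltas = NULL) {
  if (n_items < 2L) stop("`n_items` must be at least 2")
  if (group_size < 2L) stop("`group_size` must be at least 2")
  if (!is.finite(true_diff)) stop("`true_diff` must be finite")
  if (dif_proportion < 0 || dif_proportion > 1)
    stop("`dif_proportion` must be in [0, 1]")
  n_dif <- if (dif_kind == "none") 0L
           else max(1L, as.integer(round(dif_proportion * n_items)))
  cfg <- structure(list(
    n_items = as.integer(n_items), group_size = as.integer(group_size),
    true_diff = true_diff, dif_kind = dif_kind, dif_size = dif_size,
    dif_proportion = dif_proportion, dif_position = dif_position,
    n_categories = as.integer(n_categories), step = step,
    n_dif = n_dif, dif_deltas = dif_deltas), class = "scenario_config")
  # fail early on invalid DIF parameters
  invisible(make_dif_deltas(cfg$dif_kind, cfg$dif_size,
                            K = cfg$n_categories - 1L, deltas = cfg$dif_deltas))
  if (dif_kind != "none") match.arg(dif_position,
                                    c("Unif", "Mean", "Extreme", "High", "Low"))
  cfg
}

#' Simulate one two-group response dataset
#'
#' Draws latent traits (`N(0, 1)` reference, `N(-true_diff, 1)` focal) and
#' samples each response from the partial credit model, using the reference
#' item bank for the reference group and the DIF-shifted bank for the focal
#' group.  Reproducible given `seed`.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `pcm_dataset`: list with `responses` (persons
#'   x items integer matrix, categories `0..K`), `group` (factor,
#'   `reference`/`focal`), `bank`, `focal_bank`, `dif_items`, `dif_spec`,
#'   `config`, `seed`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  K <- config$n_categories - 1L
  bank <- build_item_bank(config$n_items, config$n_categories, config$step)
  spec <- make_dif_deltas(config$dif_kind, config$dif_size, K = K,
                          deltas = config$dif_deltas)
  dif_items <- integer(0)
  focal_bank <- bank
  if (config$dif_kind != "none") {
    dif_items <- select_dif_items(config$dif_position, config$n_dif,
                                  attr(bank, "beta"))
    focal_bank <- apply_dif(bank, spec, items = dif_items)
  }
  n <- config$group_size
  theta <- c(rnorm(n, 0, 1), rnorm(n, -config$true_diff, 1))
  group <- factor(rep(c("reference", "focal"), each = n),
                  levels = c("reference", "focal"))
  mref <- bank_matrix(bank)
  mfoc <- bank_matrix(focal_bank)
  resp <- matrix(NA_integer_, 2L * n, config$n_items,
                 dimnames = list(NULL, bank$item_id))
  ref_rows <- seq_len(n)
  for (j in seq_len(config$n_items)) {
    resp[ref_rows, j]  <- sample_pcm(theta[ref_rows], mref[j, ])
    resp[-ref_rows, j] <- sample_pcm(theta[-ref_rows], mfoc[j, ])
  }
  structure(list(responses = resp, group = group, theta = theta,
                 bank = bank, focal_bank = focal_bank,
                 dif_items = dif_items, dif_spec = spec,
                 config = config, seed = seed),
            class = "pcm_dataset")
}

# draw PCM responses for a vector of traits and one item
sample_pcm <- function(theta, locations) {
  p <- pcm_category_probs(theta, locations)
  K <- ncol(p) - 1L
  cum <- p %*% upper.tri(diag(K + 1L), diag = TRUE)   # row cumulative sums
  as.integer(rowSums(runif(length(theta)) > cum[, seq_len(K), drop = FALSE]))
}

#' @export
print.pcm_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "PCM dataset: %d x 2 persons, %d items (%d categories), true diff %.2f\n",
    cfg$group_size, cfg$n_items, cfg$n_categories, cfg$true_diff))
  if (cfg$dif_kind != "none")
    cat(sprintf("  DIF: %s on %d item(s) [%s], position %s\n", cfg$dif_kind,
                length(x$dif_items), paste(x$dif_items, collapse = ","),
                cfg$dif_position))
  invisible(x)
}

#' Scenario grids of the factorial simulation studies
#'
#' Returns the cells of a study as a data frame (one row per scenario).
#' The `uniform` study crosses scale length \{4, 8\}, group size \{100, 200\},
#' true difference \{0, 0.1, 0.2, 0.5\}, effect size \{0.25, 0.5, 1\},
#' proportion \{25, 50, 75\%\} and five DIF positions (720 cells).  The
#' non-uniform studies fix 8 items, 200 per group and a 0.1-logit true
#' difference and cross their effect sizes with proportion and position
#' (`balanced_gentle` adds the very gentle slope, size 2; `unbalanced`
#' includes the balanced size-1 pattern as reference level).  The
#' `no_dif_benchmark` study crosses the three non-DIF factors with DIF absent
#' (12 cells, true difference \{0, 0.1, 0.2\}).
#'
#' @param study one of `"uniform"`, `"balanced_gentle"`, `"balanced_steep"`,
#'   `"unbalanced"`, `"no_dif_benchmark"`.
#' @return A data frame with the factor columns, a human-readable
#'   `size_label` used as the effect-size factor in the bias ANOVA, and a
#'   `cell` index.
#' @export
scenario_grid <- function(study = c("uniform", "balanced_gentle",
                                    "balanced_steep", "unbalanced",
                                    "no_dif_benchmark")) {
  study <- match.arg(study)
  pos <- c("Unif", "Mean", "Extreme", "High", "Low")
  grid <- switch(study,
    uniform = {
      g <- expand.grid(dif_position = pos, dif_proportion = c(0.25, 0.5, 0.75),
                       dif_size = c(0.25, 0.5, 1), true_diff = c(0, 0.1, 0.2, 0.5),
                       group_size = c(100L, 200L), n_items = c(4L, 8L),
                       stringsAsFactors = FALSE)
      g$dif_kind <- "uniform"
      g$size_label <- as.character(g$dif_size)
      g
    },
    balanced_gentle = {
      sizes <- data.frame(dif_kind = c(rep("balanced_gentle", 3L),
                                       "balanced_very_gentle"),
                          dif_size = c(0.25, 0.5, 1, 2),
                          size_label = c("0.25", "0.5", "1", "2 (very gentle)"),
                          stringsAsFactors = FALSE)
      cross_dif(sizes, pos)
    },
    balanced_steep = {
      sizes <- data.frame(dif_kind = "balanced_steep",
                          dif_size = c(0.25, 0.5, 1),
                          size_label = c("0.25", "0.5", "1"),
                          stringsAsFactors = FALSE)
      cross_dif(sizes, pos)
    },
    unbalanced = {
      sizes <- data.frame(dif_kind = c("balanced_gentle", "unbalanced_small",
                                       "unbalanced_large"),
                          dif_size = c(1, NA, NA),
                          size_label = c("balanced (1)", "small imbalance",
                                         "large imbalance"),
                          stringsAsFactors = FALSE)
      cross_dif(sizes, pos)
    },
    no_dif_benchmark = {
      g <- expand.grid(true_diff = c(0, 0.1, 0.2), group_size = c(100L, 200L),
                       n_items = c(4L, 8L), stringsAsFactors = FALSE)
      g$dif_kind <- "none"
      g$dif_size <- NA_real_
      g$dif_proportion <- 0
      g$dif_position <- "Unif"
      g$size_label <- "none"
      g
    })
  if (is.null(grid$n_items)) {
    grid$n_items <- 8L
    grid$group_size <- 200L
    grid$true_diff <- 0.1
  }
  cols <- c("n_items", "group_size", "true_diff", "dif_kind", "dif_size",
            "size_label", "dif_proportion", "dif_position")
  grid <- grid[cols]
  grid$cell <- seq_len(nrow(grid))
  attr(grid, "study") <- study
  grid
}

cross_dif <- function(sizes, pos) {
  g <- expand.grid(dif_position = pos, dif_proportion = c(0.25, 0.5, 0.75),
                   row = seq_len(nrow(sizes)), stringsAsFactors = FALSE)
  out <- cbind(sizes[g$row, , drop = FALSE], g[c("dif_proportion",
                                                 "dif_position")])
  rownames(out) <- NULL
  out
}

# one grid row -> scenario_config
config_from_row <- function(row, ...) {
  scenario_config(n_items = row$n_items, group_size = row$group_size,
                  true_diff = row$true_diff, dif_kind = row$dif_kind,
                  dif_size = if (is.na(row$dif_size)) NULL else row$dif_size,
                  dif_proportion = row$dif_proportion,
                  dif_position = row$dif_position, ...)
}

#' Replication seeds derived from a master seed
#'
#' Every (cell, replication) pair gets its own 31-bit seed from a Lehmer-style
#' integer hash of the master seed, so any cell or replication can be
#' regenerated in isolation.
#'
#' @param master_seed integer master seed.
#' @param cell scenario cell index.
#' @param rep replication index.
#' @return Integer seed in `1..2^31-2`.
#' @export
derive_seed <- function(master_seed, cell, rep) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (v in c(cell, rep)) h <- (h * 48271 + as.numeric(v) + 1) %% m
  as.integer(h + 1)
}

#' Long-format response tables
#'
#' `as_response_df` flattens a dataset to the long CSV layout
#' (`person_id, group, item_id, response`); `responses_from_df` rebuilds the
#' wide response matrix and group factor from such a table (as read by
#' [read_response_csv()]).
#'
#' @param dataset a `pcm_dataset`.
#' @return `as_response_df`: a long data frame; `responses_from_df`: list
#'   with `responses` and `group` ready for [fit_latent_regression_pcm()].
#' @export
as_response_df <- function(dataset) {
  resp <- dataset$responses
  data.frame(
    person_id = rep(seq_len(nrow(resp)), ncol(resp)),
    group = rep(as.character(dataset$group), ncol(resp)),
    item_id = rep(colnames(resp), each = nrow(resp)),
    response = as.vector(resp),
    stringsAsFactors = FALSE)
}

#' @rdname as_response_df
#' @param df long data frame with columns `person_id`, `group`, `item_id`,
#'   `response`.
#' @export
responses_from_df <- function(df) {
  need <- c("person_id", "group", "item_id", "response")
  if (!all(need %in% names(df)))
    stop("long table must have columns ", paste(need, collapse = ", "))
  persons <- unique(df$person_id)
  items <- unique(df$item_id)
  resp <- matrix(NA_integer_, length(persons), length(items),
                 dimnames = list(NULL, items))
  resp[cbind(match(df$person_id, persons), match(df$item_id, items))] <-
    as.integer(df$response)
  grp <- df$group[match(persons, df$person_id)]
  lev <- if (all(unique(grp) %in% c("reference", "focal")))
    c("reference", "focal") else unique(grp)
  if (length(lev) != 2L) stop("expected exactly two groups")
  list(responses = resp, group = factor(grp, levels = lev))
}

#' @rdname as_response_df
#' @param path CSV file path.
#' @export
write_response_csv <- function(dataset, path) {
  write.csv(as_response_df(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname as_response_df
#' @export
read_response_csv <- function(path) {
  responses_from_df(read.csv(path, stringsAsFactors = FALSE))
}
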