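#' Category probabilities of the partial credit model
#'
#' For an item with `K + 1` ordered response categories `0..K` and threshold
#' (item location) parameters `locations` = \eqn{\delta_1, \dots, \delta_K},
#' the partial credit model gives
#' \deqn{P(X = k \mid \theta) \propto \exp\{\sum_{i \le k} (\theta - \delta_i)\},}
#' with an empty sum for `k = 0`.  Computation subtracts the maximum of the
#' cumulative sums before exponentiating, so probabilities are stable for any
#' finite `theta`.
#'
#' @param theta numeric vector of latent trait values, in logits.
#' @param locations numeric vector of K threshold parameters, in logits.
#' @return A `length(theta)` x `(K + 1)` matrix of category probabilities;
#'   rows sum to one.
#' @examples
#' pcm_category_probs(0, c(0, 0, 0, 0))     # uniform over 5 categories
#' pcm_category_probs(c(-1, 0, 1), c(-0.5, 0.5))
#' @export
pcm_category_probs <- function(theta, locations) {
  if (!is.numeric(theta) || length(theta) < 1L || !all(is.finite(theta)))
    stop("`theta` must be a non-empty vector of finite values")
  if (!is.numeric(locations) || length(locations) < 1L ||
      !all(is.finite(locations)))
    stop("`locations` must be a non-empty vector of finite values")
  K <- length(locations)
  cum <- c(0, cumsum(locations))
  v <- outer(theta, 0:K) - matrix(cum, length(theta), K + 1L, byrow = TRUE)
  v <- v - apply(v, 1L, max)
  e <- exp(v)
  p <- e / rowSums(e)
  colnames(p) <- as.character(0:K)
  p
}

#' Expected item score under the partial credit model
#'
#' The item characteristic curve \eqn{E(X \mid \theta) = \sum_k k P(X = k \mid
#' \theta)}, a strictly increasing function of the latent trait with range
#' `(0, K)`.
#'
#' @inheritParams pcm_category_probs
#' @return Numeric vector of expected scores, one per `theta`.
#' @export
pcm_expected_score <- function(theta, locations) {
  p <- pcm_category_probs(theta, locations)
  drop(p %*% seq_len(ncol(p)) - 1)
}

#' Assemble an item bank
#'
#' An item bank is a data frame with a character `item_id` column and numeric
#' threshold columns `delta_1..delta_K` (the serialisation format used for
#' CSV round trips).
#'
#' @param locations numeric matrix (items x thresholds) or vector for a
#'   single item.
#' @param item_id character vector of unique item labels.
#' @return A `data.frame` of class `item_bank`.
#' @export
item_bank <- function(locations, item_id = NULL) {
  if (is.vector(locations)) locations <- matrix(locations, nrow = 1L)
  locations <- as.matrix(locations)
  if (!all(is.finite(locations))) stop("item locations must be finite")
  if (is.null(item_id))
    item_id <- sprintf("item%02d", seq_len(nrow(locations)))
  if (anyDuplicated(item_id)) stop("item ids must be unique")
  if (length(item_id) != nrow(locations))
    stop("`item_id` length must match the number of items")
  bank <- data.frame(item_id = as.character(item_id), locations,
                     stringsAsFactors = FALSE)
  names(bank) <- c("item_id", paste0("delta_", seq_len(ncol(locations))))
  rownames(bank) <- NULL
  class(bank) <- c("item_bank", "data.frame")
  bank
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x), "items,", ncol(x) - 1L, "thresholds each\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

# threshold matrix (items x K) from a bank
bank_matrix <- function(bank) {
  m <- as.matrix(bank[grep("^delta_", names(bank))])
  rownames(m) <- bank$item_id
  storage.mode(m) <- "double"
  m
}

#' Read or write an item bank as CSV
#'
#' @param bank an [item_bank()] data frame.
#' @param path file path.
#' @return `read_item_bank` returns an `item_bank`; `write_item_bank`
#'   invisibly returns `path`.
#' @export
write_item_bank <- function(bank, path) {
  write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  item_bank(as.matrix(d[grep("^delta_", names(d))]), item_id = d$item_id)
}
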