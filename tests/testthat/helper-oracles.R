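# Brute-force marginal log-likelihood by dense trapezoid integration over the
# latent trait; independent of the quadrature code path.
trap_marginal_loglik <- function(gamma, sigma, bank, responses, group,
                                 lo = -8, hi = 8, npts = 4001) {
  m <- if (inherits(bank, "item_bank")) {
    as.matrix(bank[grep("^delta_", names(bank))])
  } else as.matrix(bank)
  th <- seq(lo, hi, length.out = npts)
  lp <- lapply(seq_len(nrow(m)), function(j)
    log(pcm_category_probs(th, as.numeric(m[j, ]))))
  mu <- ifelse(as.character(group) == "focal", -gamma, 0)
  vapply(seq_len(nrow(responses)), function(p) {
    lj <- numeric(length(th))
    for (j in seq_len(ncol(responses))) {
      x <- responses[p, j]
      if (!is.na(x)) lj <- lj + lp[[j]][, x + 1L]
    }
    log(pracma::trapz(th, exp(lj) * stats::dnorm(th, mu[p], sigma)))
  }, numeric(1))
}

# fabricate replication records with exact deltas for deterministic ANOVA tests
fake_records <- function(size_label, prop, position, delta,
                         n_items = 8L, group_size = 200L, true_diff = 0.1) {
  data.frame(cell = seq_along(delta), rep = 1L, seed = 0L,
             n_items = n_items, group_size = group_size,
             true_diff = true_diff, dif_kind = "uniform",
             dif_size = suppressWarnings(as.numeric(size_label)),
             dif_proportion = prop, dif_position = position,
             gamma_hat = true_diff + delta, sigma_hat = 1,
             delta = delta, converged = TRUE,
             size_label = size_label, stringsAsFactors = FALSE)
}
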