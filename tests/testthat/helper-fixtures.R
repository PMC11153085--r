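# Shared helpers: quick anonymous profiles and randomized profile pairs.

prof <- function(...) {
  community_profile(c(...))
}

# Random normalized profile over a shared alphabet; sparsity via zeroed taxa.
random_profile <- function(n_taxa = 8, alphabet = paste0("t", 1:12),
                           sparsity = 0.3) {
  taxa <- sample(alphabet, n_taxa)
  w <- stats::rexp(n_taxa)
  w[stats::runif(n_taxa) < sparsity] <- 0
  if (all(w == 0)) w[1] <- 1
  community_profile(stats::setNames(w, taxa))
}

# Small balanced assay table with exact cell means and optional noise.
toy_assays <- function(means, n_rep = 3, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (iso in rownames(means)) {
    for (lvl in colnames(means)) {
      od <- means[iso, lvl] + stats::rnorm(n_rep, 0, noise)
      rows[[length(rows) + 1L]] <- data.frame(
        isolate = iso, nacl_pct = as.numeric(lvl),
        replicate = seq_len(n_rep), od600 = pmax(od, 0))
    }
  }
  do.call(rbind, rows)
}
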