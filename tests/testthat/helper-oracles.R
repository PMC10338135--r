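# Independent brute-force oracles and fixture generators. The oracles work
# on substrings only (no base-4 arithmetic, no shared code with the package
# internals) so they can arbitrate the fast implementations.

BASES <- c("A", "C", "G", "T")

# All mers of length k in lexicographic (= code) order.
oracle_all_mers <- function(k) {
  if (k == 0) return("")
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  out <- do.call(paste0, g)
  sort(out)
}

# Conditional (m,n)-mer frequencies by direct window tallying of
# (context string, suffix string) pairs.
oracle_mn <- function(seq, m, n) {
  k <- m + n
  seq <- toupper(seq)
  L <- nchar(seq)
  ctxs <- oracle_all_mers(m)
  sufs <- oracle_all_mers(n)
  tally <- matrix(0, nrow = length(ctxs), ncol = length(sufs),
                  dimnames = list(ctxs, sufs))
  if (L >= k) {
    for (i in 1:(L - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      ctx <- substr(w, 1, m)
      suf <- substr(w, m + 1, k)
      tally[if (m == 0) 1 else ctx, suf] <- tally[if (m == 0) 1 else ctx, suf] + 1
    }
  }
  if (m == 0) {
    tot <- sum(tally)
    vals <- if (tot > 0) tally[1, ] / tot else tally[1, ] * 0
    return(as.numeric(vals))
  }
  rows <- rowSums(tally)
  out <- tally / ifelse(rows > 0, rows, 1)
  out[rows == 0, ] <- 0
  as.numeric(t(out))
}

# Random sequence over ACGT plus a sprinkling of N.
random_seq <- function(len, n_frac = 0) {
  ch <- sample(BASES, len, replace = TRUE)
  if (n_frac > 0) {
    nn <- rbinom(1, len, n_frac)
    if (nn > 0) ch[sample(len, nn)] <- "N"
  }
  paste(ch, collapse = "")
}

# Benchmark preset: two order-`order` chains separated by epsilon, simulated
# and converted into feature matrices for a list of specs.
make_preset_matrices <- function(seed, specs, n_per_class = 100, length = 300,
                                 order = 2, epsilon = 0.15) {
  model_a <- random_transition_model(order, seed = derive_test_seed(seed, 101))
  model_b <- perturb_model(model_a, epsilon, seed = derive_test_seed(seed, 202))
  recs <- make_two_class_dataset(model_a, model_b, n_per_class, length,
                                 seed = seed)
  lapply(specs, function(sp) build_feature_matrix(recs, sp))
}

derive_test_seed <- function(seed, i) (seed + 1000003 * i) %% 2147483629 + 1
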