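# Shared fixtures and independent oracles, built in code at test time.

toy_vocab <- function() {
  state_vocabulary(c("Tx", "Enh", "Het", "Quies"), name = "toy")
}

five_vocab <- function() roadmap_reduction(5)$target_vocab

# A track of uniform-length segments from a vector of per-segment states.
grid_track <- function(sample_id, states, vocab, chrom = "chr1",
                       seg = 200) {
  n <- length(states)
  state_track(sample_id, rep(chrom, n), seq(0, by = seg, length.out = n),
              seq(seg, by = seg, length.out = n), states, vocab)
}

# Independent MI oracle: literal double sum over the joint count table.
mi_oracle <- function(profile, groups, undefined = "undefined") {
  keep <- profile != undefined
  s <- profile[keep]; g <- groups[keep]
  total <- length(s)
  if (total < 2) return(0)
  mi <- 0
  for (gk in unique(g)) {
    for (sl in unique(s)) {
      pjoint <- sum(g == gk & s == sl) / total
      if (pjoint == 0) next
      pg <- sum(g == gk) / total
      ps <- sum(s == sl) / total
      mi <- mi + pjoint * log2(pjoint / (pg * ps))
    }
  }
  mi
}

# Brute-force step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord]
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# All permutations of 1..n (n <= 7), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Exact permutation p-value by full enumeration of profile arrangements.
exact_perm_p <- function(profile, groups, undefined = "undefined") {
  n <- length(profile)
  perms <- all_perms(n)
  obs <- mi_oracle(profile, groups, undefined)
  hits <- vapply(seq_len(nrow(perms)), function(i) {
    mi_oracle(profile[perms[i, ]], groups, undefined) >= obs - 1e-12
  }, logical(1))
  mean(hits)
}

# Hypergeometric upper-tail oracle via direct choose() summation.
hyper_tail_oracle <- function(k, K, n, N) {
  kmax <- min(K, n)
  if (k > kmax) return(0)
  sum(vapply(k:kmax, function(x) {
    choose(n, x) * choose(N - n, K - x) / choose(N, K)
  }, numeric(1)))
}

# Small synthetic dataset with planted group-aligned windows; used by the
# scan/pattern/annotation tests. Kept small so the suite stays fast.
small_planted_dataset <- function(seed = 7, n_planted = 4,
                                  strength = 1.0, undefined_rate = 0,
                                  samples_per_group = c(A = 10, B = 10),
                                  chrom_len = 2e5, window = 5000) {
  vocab <- five_vocab()
  layout <- genome_layout("chr1", chrom_len)
  grid <- make_windows(layout, windowing_params(window, window))
  set.seed(seed + 1000)
  pick <- sort(sample(nrow(grid), n_planted))
  planted <- grid[pick, ]
  planted$strength <- strength
  for (g in names(samples_per_group)) planted[[g]] <- NA_character_
  planted[[names(samples_per_group)[1]]] <- "transcription"
  planted[[names(samples_per_group)[2]]] <- "heterochromatin"
  spec <- synthetic_spec(layout, samples_per_group, vocab, planted,
                         undefined_rate = undefined_rate, seed = seed)
  c(simulate_tracks(spec), list(spec = spec, layout = layout,
                                vocab = vocab))
}
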