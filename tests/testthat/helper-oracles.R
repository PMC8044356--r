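# Independent brute-force oracles the implementation is checked against.
# These deliberately share no code with the package internals.

# sort-based median, mid-mean-of-two convention
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_scaled_mad <- function(x) {
  1.4826 * oracle_median(abs(x - oracle_median(x)))
}

oracle_math <- function(x) 100 * oracle_scaled_mad(x) / oracle_median(x)

# pair-counting AUC with half credit for ties
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# two-sided Fisher p by full enumeration of tables with the observed margins
oracle_fisher <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  ks <- seq(max(0, cs[1] - rs[2]), min(rs[1], cs[1]))
  probs <- vapply(ks, function(k) {
    choose(rs[1], k) * choose(rs[2], cs[1] - k) / choose(n, cs[1])
  }, 0)
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive Youden sweep over a fine grid of candidate thresholds
oracle_max_j <- function(scores, labels, positive, negative) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9, scores)))
  max(vapply(cand, function(t) {
    mean(scores[labels == negative] < t) +
      mean(scores[labels == positive] >= t) - 1
  }, 0))
}

# quick variant-call factory with scoring-relevant fields exposed
make_call <- function(vaf, effect = "nonsynonymous_snv", hotspot = FALSE,
                      pop_freq_max = 0, gene = "TP53", sample_id = "S1") {
  variant_calls(sample_id = sample_id, gene = gene, chrom = "1",
                pos = 1000L, ref = "A", alt = "G", vaf = vaf,
                pop_freq_max = pop_freq_max, effect = effect,
                hotspot = hotspot)
}

make_calls_df <- function(vafs, effect = "nonsynonymous_snv",
                          hotspot = FALSE, pop_freq_max = 0,
                          gene = "TP53", sample_id = "S1") {
  n <- length(vafs)
  variant_calls(sample_id = rep_len(sample_id, n),
                gene = rep_len(gene, n), chrom = "1",
                pos = seq_len(n) + 999L, ref = "A", alt = "G",
                vaf = vafs, pop_freq_max = rep_len(pop_freq_max, n),
                effect = rep_len(effect, n),
                hotspot = rep_len(hotspot, n))
}
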