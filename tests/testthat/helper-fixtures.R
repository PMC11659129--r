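# Shared fixtures: the standard protocol (120 frames at 2 s, TR 2.8 ms,
# VFA flips 5/10/15 deg) and a population AIF on its grid.
std_protocol <- acquisition_protocol()
std_t <- protocol_times(std_protocol)
std_aif <- population_aif(std_t, bolus_arrival_s = 10)

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Brute-force pair-counting AUC: P(lesion > normal) + 0.5 P(tie).
pair_count_auc <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# First-principles Spearman rho with average ranks.
spearman_brute <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
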