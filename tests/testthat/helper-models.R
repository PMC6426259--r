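# canonical model parameterizations used across tests: risk allele depletes
# a protective bacterium, common disease
canon_a <- function(...) causal_model("a", beta = -0.3, omegaB = -0.5,
                                      prevalence = 0.3, ...)
canon_b <- function(...) causal_model("b", beta = -0.3, omegaG = 0.5,
                                      prevalence = 0.3, ...)
canon_c <- function(...) causal_model("c", omegaB = -0.5, omegaG = 0.5,
                                      prevalence = 0.3, ...)
canon_d <- function(...) causal_model("d", gamma = -0.3, omegaG = 0.5,
                                      prevalence = 0.3, ...)

# case-only minus population OLS slope on full-sample standardized views:
# the brute-force oracle for the moment-based bias formula
delta_brute <- function(pop) {
  s <- standardize(pop$b, pop$g, pop$d)
  cases <- pop$d == 1
  slope <- function(y, x) {
    mean((x - mean(x)) * (y - mean(y))) / mean((x - mean(x))^2)
  }
  slope(s$B[cases], s$G[cases]) - slope(s$B, s$G)
}
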