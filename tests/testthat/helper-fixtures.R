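# Shared fixtures and independent test oracles.

star_net <- function() load_edge_list(c("H A", "H B", "H C"))
triangle_net <- function() load_edge_list(c("A B", "B C", "C A"))
path_net <- function() load_edge_list(c("A H", "H B"))
cycle4_net <- function() load_edge_list(c("A B", "B C", "C D", "D A"))

# Independent hypergeometric oracle for the 2x2 exact test, written from the
# counting definition with choose() only (no d/phyper).
enum_fisher_oracle <- function(a, b, c, d, sided = "one") {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- choose(c1, support) * choose(n - c1, r1 - support) / choose(n, r1)
  if (sided == "one") sum(prob[support >= a])
  else sum(prob[prob <= prob[support == a] * (1 + 1e-7)])
}

# Small two-module synthetic study shared by pipeline tests (kept light).
tiny_study <- function(seed = 7) {
  base <- gen_network(200, 6, "ER", seed = seed)
  truth <- plant_modules(base, k_modules = 2, module_size = 8,
                         p_intra = 0.9, seed = seed)
  cohort <- gen_cohort(truth, n_samples = 10, drivers_per_sample = 3,
                       passengers_per_sample = 6, seed = seed)
  c(truth, list(cohort = cohort))
}
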