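# small deterministic fixtures used across test files

one_species <- function(mu_max = 1, K_N = 0.5, K_O = 0.2, m = 0.2,
                        c_N = 7, c_O = 25, id = "a") {
  species_pool(id, mu_max, K_N, K_O, m, c_N, c_O)
}

# two species with crossing ZNGIs and a stable coexistence wedge:
# 'ngl' is the better ammonia competitor (lower K_N), 'ogl' the better
# oxygen competitor; each consumes relatively more of the resource it is
# worse at acquiring.
stable_pair <- function(m = 0.2) {
  species_pool(c("ngl", "ogl"), mu_max = 1,
               K_N = c(0.5, 2), K_O = c(0.8, 0.2), m = m,
               c_N = c(5, 10), c_O = c(30, 12))
}

# independent brute-force Raup-Crick oracle: direct summation of the
# hypergeometric pmf written from choose(), not via phyper/dhyper
src_brute <- function(n_a, n_b, pool, shared) {
  pmf <- function(k) choose(n_a, k) * choose(pool - n_a, n_b - k) /
    choose(pool, n_b)
  below <- if (shared > 0) sum(vapply(0:(shared - 1), pmf, numeric(1))) else 0
  below + 0.5 * pmf(shared)
}
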