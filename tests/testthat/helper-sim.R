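# Cached simulations shared across test files (generation is deterministic,
# so caching only saves time).
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(n_sites, seed, ...) {
  key <- paste(n_sites, seed, ..., sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_phosphoproteome(
      sim_config(n_sites = n_sites, ...), seed = seed)
  }
  .sim_cache[[key]]
}

# Hand-built 10-site inhibitor-screen table with one replicate per arm:
# 5 regulated (|insulin log2| = 2), of which 3 are PI3K-dependent
# (LY reversal 0.6) and 2 of those also Akt-dependent (MK reversal 0.6).
toy_dependence_sites <- function() {
  ins <- c(2, 2, 2, 2, -2, 0.1, 0.1, -0.1, 0.1, 0.1)
  ly <- c(0.8, 0.8, 0.8, 2, -2, 0.1, 0.1, -0.1, 0.1, 0.1)
  mk <- c(0.8, 0.8, 2, 2, -2, 0.1, 0.1, -0.1, 0.1, 0.1)
  tibble::tibble(
    site_id = sprintf("t%02d", 1:10),
    protein_id = "P1", gene_name = "G1", position = 1:10,
    residue = "S", localization_prob = 0.99, multiplicity = 1L,
    sequence_window = strrep("A", 6) |> paste0("S", strrep("A", 6)),
    ins_1 = ins, mk_1 = mk, ly_1 = ly
  )
}

# Brute-force O(n^2) non-dominated sorting oracle over (score, delta).
pareto_brute_force <- function(score, delta) {
  n <- length(score)
  front <- integer(n)
  remaining <- seq_len(n)
  f <- 0L
  while (length(remaining) > 0) {
    f <- f + 1L
    dominated <- vapply(remaining, function(i) {
      any(vapply(remaining, function(j) {
        j != i && score[j] >= score[i] && delta[j] >= delta[i] &&
          (score[j] > score[i] || delta[j] > delta[i])
      }, logical(1)))
    }, logical(1))
    front[remaining[!dominated]] <- f
    remaining <- remaining[dominated]
  }
  front
}
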