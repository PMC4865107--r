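# Shared fixtures, built once per test run. Everything is generated in
# code from fixed seeds; no data files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Small circular genome used throughout the unit tests.
small_genome <- function(len = 100000, oriC = 10000, dif = 60000) {
  genome_spec(len, oriC = oriC, dif = dif)
}

# Canonical noise-free cleavage site at the center of a 100 kb genome.
canonical_experiment <- function() {
  cached("canonical", function() {
    g <- small_genome()
    plant_norflip_experiment(g, planted_sites(50000, fold = 10),
                             depth = 5, noise = FALSE)
  })
}

# One noisy mid-size NorflIP experiment with well-separated planted sites.
noisy_norflip <- function() {
  cached("noisy_norflip", function() {
    g <- genome_spec(1000000, oriC = 100000, dif = 600000)
    centers <- seq(50000, 950000, by = 75000)
    list(genome = g, centers = centers,
         exp = plant_norflip_experiment(g, planted_sites(centers, fold = 8),
                                        depth = 5, seed = 42))
  })
}

# Nearest-truth distance for each called site.
nearest_truth <- function(called, truth_centers, genome_length) {
  vapply(called, function(c0) {
    min(circ_dist(c0, truth_centers, genome_length))
  }, numeric(1))
}

circ_dist <- function(a, b, len) {
  d <- abs(((a - b) %% len))
  pmin(d, len - d)
}

# Brute-force one-sided (enrichment) Fisher p-value by hypergeometric
# enumeration over all tables with the observed margins.
fisher_enumerate <- function(a, b, c, d) {
  n <- a + b + c + d
  row1 <- a + b
  col1 <- a + c
  lo <- max(0, row1 + col1 - n)
  hi <- min(row1, col1)
  probs <- vapply(lo:hi, function(x) {
    choose(col1, x) * choose(n - col1, row1 - x) / choose(n, row1)
  }, numeric(1))
  sum(probs[(lo:hi) >= a])
}
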