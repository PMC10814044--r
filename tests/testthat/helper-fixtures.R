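# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

test_locus <- function() memo("locus", build_locus(seed = 1))

test_probes <- function() memo("probes", default_probe_set(test_locus()))

test_transcripts <- function() memo("tx", enumerate_all_transcripts(test_locus()))

# Abundance vector putting equal weight on every transcript class.
all_class_abundance <- function() {
  stats::setNames(rep(1, 13),
                  c("v1", "v2", "v3", "v3down1", "v3down2", "v2v3up",
                    "v2v3down", "vE5a1", "vE5a2", "vE5a3", "vE2E5a",
                    "vE5c", "vE5d"))
}

# A moderately deep error-free paired-end sample expressing all classes,
# reused by the discovery tests.
test_discovery_sample <- function() {
  memo("disc_sample", simulate_sample(
    test_locus(), all_class_abundance(),
    sim_params(n_reads = 25000L, paired = TRUE,
               fragment_len_mean = 150, fragment_len_sd = 15),
    seed = 7, probes = test_probes()
  ))
}

# Independent brute-force oracle for the signed-rank two-sided p-value:
# enumerate all 2^n sign assignments of the observed ranks and tally
# Pr(|W - mu| >= |w_obs - mu|).
oracle_signed_rank_p <- function(normal, tumor) {
  d <- tumor - normal
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Independent Spearman rho oracle: explicit average ranks, then the textbook
# product-moment formula.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    sapply(seq_along(v), function(i) {
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    })
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Seed-controlled random DNA for constructed-read tests.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
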