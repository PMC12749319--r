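# Shared fixtures for the test suite; everything is generated in code.

quick_config <- function(...) analysis_config(n_components = 5, ...)

# small cohort used by several integration tests
small_cohort <- function(seed = 3, n_regions = 60,
                         sizes = c(HC = 6, "PD-NC" = 6, LBD = 8)) {
  make_cohort(group_sizes = sizes, seed = seed, n_regions = n_regions)
}

# symmetric random affinity with unit diagonal, entries in (0, 1)
random_affinity <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.05, 1), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# independent dense eigendecomposition oracle of the Markov operator P,
# coded directly from the definition (no symmetric conjugation trick)
dense_markov_oracle <- function(A, n_components, alpha = 0.5) {
  d <- rowSums(A)
  W <- A / outer(d^alpha, d^alpha)
  P <- W / rowSums(W)
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  list(values = vals[seq.int(2, n_components + 1)],
       vectors = vecs[, seq.int(2, n_components + 1), drop = FALSE])
}

random_orthogonal <- function(k) {
  Q <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  Q
}
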