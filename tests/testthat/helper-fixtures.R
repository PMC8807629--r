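# Shared helpers: all fixtures are built in code at test time.

# adjusted Rand index (independent implementation for oracle comparisons)
ari <- function(a, b) {
  tb <- table(a, b)
  n <- sum(tb)
  sij <- sum(choose(tb, 2))
  si <- sum(choose(rowSums(tb), 2))
  sj <- sum(choose(colSums(tb), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# FPKM matrix whose log2(FPKM + 1) equals z exactly (for z >= 0)
fpkm_from_log2 <- function(z) pmax(2^z - 1, 0)

# two-class Gaussian log-expression fixture: genes x (2n) FPKM matrix with
# per-gene class-mean difference `effect` (log2 scale, unit within-class sd)
two_class_fpkm <- function(n_genes, n_per_class, effect, baseline = 6,
                           seed = 1) {
  withr::local_seed(seed)
  n <- 2 * n_per_class
  z <- matrix(rnorm(n_genes * n), n_genes, n) + baseline
  z[, seq_len(n_per_class)] <- z[, seq_len(n_per_class)] + effect / 2
  z[, n_per_class + seq_len(n_per_class)] <-
    z[, n_per_class + seq_len(n_per_class)] - effect / 2
  mat <- fpkm_from_log2(z)
  dimnames(mat) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%03d", seq_len(n)))
  mat
}

# random censored survival fixture for evaluator cross-checks
random_surv_fixture <- function(n, seed) {
  withr::local_seed(seed)
  group <- rep(c("A", "B"), length.out = n)
  scale <- ifelse(group == "A", runif(1, 20, 80), runif(1, 10, 60))
  t_true <- rexp(n, 1 / scale)
  cens <- runif(n, 0, quantile(t_true, 0.9))
  list(times = pmax(pmin(t_true, cens), 1e-4),
       events = as.integer(t_true <= cens),
       group = group)
}

# brute-force posterior for the equicorrelated Gaussian example, via the
# explicit multivariate densities (independent of the closed form)
brute_equicorrelated_posterior <- function(d, r, t) {
  sigma <- (1 - r) * diag(d) + r
  sigma_inv <- solve(sigma)
  logq <- function(mu) {
    u <- rep(t, d) - mu
    -0.5 * drop(t(u) %*% sigma_inv %*% u)
  }
  a <- logq(rep(1, d))
  b <- logq(rep(-1, d))
  1 / (1 + exp(b - a))
}
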