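# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Scalar NB maximum likelihood for one group mean on the log scale:
# mu_j = s_j * exp(beta), dispersion alpha fixed. Coarse grid + golden
# refinement; independent of the package's Newton fitter.
oracle_nb_mle <- function(y, s, alpha) {
  loglik <- function(beta) {
    mu <- s * exp(beta)
    sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  grid <- seq(log(sum(y) / sum(s)) - 3, log(sum(y) / sum(s)) + 3,
              length.out = 4001)
  ll <- vapply(grid, loglik, numeric(1))
  b0 <- grid[which.max(ll)]
  opt <- optimize(loglik, c(b0 - 0.01, b0 + 0.01), maximum = TRUE,
                  tol = 1e-12)
  opt$maximum
}

# Fisher information for the scalar NB group mean at beta.
oracle_nb_info <- function(beta, s, alpha) {
  mu <- s * exp(beta)
  sum(mu / (1 + alpha * mu))
}

# Exhaustive hypergeometric upper tail: draw n from a universe of size N
# containing K marked items; P(overlap >= k) by enumerating all C(N, n)
# draws. Feasible for N <= 12.
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Textbook pooled-variance two-sample t-test on raw vectors.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2,
       p = 2 * pt(-abs(tt), na + nb - 2))
}

# Brute-force median-of-ratios on a small matrix (hand enumeration path).
oracle_size_factors <- function(m) {
  ref <- apply(m, 1, function(r) exp(mean(log(r))))
  apply(m, 2, function(col) median(col / ref))
}

# Tiny aligned differential-result table for classification tests.
make_result <- function(id, log2fc, p) {
  data.frame(transcript_id = id, log2fc = log2fc, p_value = p,
             stringsAsFactors = FALSE)
}
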