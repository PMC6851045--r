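# Negative binomial group-mean fitting with fixed dispersion.
#
# Both differential tests in this package reduce to fitting, per transcript,
# the NB log-link model  mu_ij = s_j * exp(beta_g)  within each cell of the
# design (condition, or assay x condition). Because the designs are
# saturated in cell means, the per-cell 1-D maximum likelihood fits give the
# exact GLM coefficient estimates, and Wald variances follow from the
# per-cell Fisher information. This lets every transcript be fit
# simultaneously with a vectorized Newton iteration.

# Fit one design cell for all transcripts at once.
# counts: transcripts x libraries matrix for the libraries in this cell;
# size_factors: per-library; dispersion: scalar or per-transcript alpha
# (var = mu + alpha mu^2). Returns beta (log normalized mean) and the
# Fisher information for beta. Cells whose count total is zero are held at
# the pseudocount floor (pseudocount counts over the cell's effective
# depth) rather than diverging to -Inf.
nb_fit_cell <- function(counts, size_factors, dispersion,
                        pseudocount = 0.5, max_iter = 100, tol = 1e-12) {
  counts <- as.matrix(counts)
  n_tx <- nrow(counts)
  alpha <- rep_len(dispersion, n_tx)
  S <- sum(size_factors)
  ytot <- rowSums(counts)
  zero <- ytot == 0
  beta <- log(ifelse(zero, pseudocount / S, ytot / S))
  free <- !zero
  for (it in seq_len(max_iter)) {
    if (!any(free)) break
    mu <- exp(beta[free]) %o% size_factors
    w <- 1 + alpha[free] * mu
    score <- rowSums((counts[free, , drop = FALSE] - mu) / w)
    info <- rowSums(mu / w)
    step <- score / info
    # damp occasional overshoot at extreme starts
    step <- pmax(pmin(step, 5), -5)
    beta[free] <- beta[free] + step
    conv <- abs(step) < tol
    idx <- which(free)
    free[idx[conv]] <- FALSE
  }
  mu <- exp(beta) %o% size_factors
  info <- rowSums(mu / (1 + alpha * mu))
  list(beta = beta, info = info, zero = zero)
}
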