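# Small simulated fixtures and independently coded oracles used across tests.

# tiny backcross with one moderate QTL at 20 cM of chromosome 1
make_small_bc <- function(n = 100, seed = 42, a = 1.5, h2 = 0.5,
                          n_chr = 2, n_markers = 6, spacing = 10) {
  mp <- sim_map(n_chr, n_markers, spacing)
  cr <- sim_cross(mp, n, "bc", seed = seed)
  sim_phenotype(cr, qtl_spec("1", 20, a), h2, seed = seed + 1000)
}

make_small_f2 <- function(n = 150, seed = 42, a = 1, d = 0.5, h2 = 0.5) {
  mp <- sim_map(1, 6, 10)
  cr <- sim_cross(mp, n, "f2", seed = seed)
  sim_phenotype(cr, qtl_spec("1", 20, a, d), h2, seed = seed + 1000)
}

# Markov-chain oracle for backcross conditional QTL probabilities:
# P(aQ | aL, aR) = P(aQ | aL) P(aR | aQ) / P(aR | aL) using two-locus
# transition probabilities (a different derivation than the package's
# joint gamete-pattern enumeration).
oracle_bc_probs <- function(gL, gR, d1, d2) {
  trans <- function(r, same) ifelse(same, 1 - r, r)
  r1 <- 0.5 * (1 - exp(-2 * d1 / 100))
  r2 <- 0.5 * (1 - exp(-2 * d2 / 100))
  r12 <- r1 + r2 - 2 * r1 * r2
  pQ1 <- trans(r1, gL == 1) * trans(r2, gR == 1) / trans(r12, gL == gR)
  cbind(QQ = pQ1, Qq = 1 - pQ1)
}

# plain-R classical EM for a mixture regression with shared variance:
# y_j ~ sum_i p_ji N(X_j g + D_i E, s2). Joint WLS update of (gamma, E)
# over the class-expanded data; independent of the package's m_step order.
oracle_classical_em <- function(y, X, probs, D, iters = 500) {
  n <- length(y); m <- nrow(D)
  Xg <- X[rep(seq_len(n), each = m), , drop = FALSE]
  Dg <- D[rep(seq_len(m), times = n), , drop = FALSE]
  Zg <- cbind(Xg, Dg)
  yg <- rep(y, each = m)
  gamma <- qr.solve(X, y); E <- rep(0, ncol(D)); s2 <- stats::var(y)
  for (t in seq_len(iters)) {
    mu <- outer(as.numeric(X %*% gamma), rep(1, m)) +
      matrix(as.numeric(D %*% E), n, m, byrow = TRUE)
    num <- probs * stats::dnorm(y, mu, sqrt(s2))
    post <- num / rowSums(num)
    wg <- as.numeric(t(post)) # row-major: obs 1 classes, obs 2 classes, ...
    fit <- stats::lm.wfit(Zg, yg, wg)
    gamma <- fit$coefficients[seq_len(ncol(X))]
    E <- fit$coefficients[-seq_len(ncol(X))]
    res <- yg - as.numeric(Zg %*% c(gamma, E))
    s2 <- sum(wg * res^2) / n
  }
  list(gamma = as.numeric(gamma), E = as.numeric(E), sigma2 = s2)
}

# brute-force mean log-likelihood of the mixture model
oracle_mean_loglik <- function(y, X, probs, D, theta) {
  n <- length(y); m <- nrow(D)
  mu <- outer(as.numeric(as.matrix(X) %*% theta$gamma), rep(1, m)) +
    matrix(as.numeric(D %*% theta$E), n, m, byrow = TRUE)
  mean(log(rowSums(probs * stats::dnorm(y, mu, sqrt(theta$sigma2)))))
}
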