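# Shared fixtures and independent oracles used across test files.

# Random small hyperparameter set with a nonzero cross block.
random_theta <- function(seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(16, sd = 0.6), 4)
  Sigma <- crossprod(A) + diag(0.2, 4)
  hyperparams(mu = rnorm(4, c(7, 7, 9, 9), 0.5), Sigma = Sigma,
              sigma2 = runif(1, 0.1, 0.5), delta2 = runif(1, 0.05, 0.3),
              omega2 = runif(1, 0.1, 0.5), tau2 = runif(1, 0.05, 0.4))
}

# Random gene block drawn from the generative model at theta.
random_block <- function(theta, J = 2, H = 2, K = 2, seed = 1,
                         gene_id = "g") {
  set.seed(seed)
  g4 <- drop(mvtnorm::rmvnorm(1, theta$mu, theta$Sigma))
  b <- rnorm(J, 0, sqrt(theta$sigma2))
  a <- rnorm(H, 0, sqrt(theta$omega2))
  G <- numeric(0)
  for (j in seq_len(J)) for (l in 1:2)
    G <- c(G, g4[l] + b[j] + rnorm(K, 0, sqrt(theta$delta2)))
  M <- numeric(0)
  for (h in seq_len(H)) for (l in 1:2)
    M <- c(M, g4[2 + l] + a[h] + rnorm(1, 0, sqrt(theta$tau2)))
  gene_block(gene_id, G, M, J = J, H = H, K = K)
}

# Explicit prior covariance / error covariance of a block (full matrices).
prior_matrices <- function(block, theta) {
  p <- 4 + block$J + block$H
  Sp <- matrix(0, p, p)
  Sp[1:4, 1:4] <- theta$Sigma
  diag(Sp)[4 + seq_len(block$J)] <- theta$sigma2
  diag(Sp)[4 + block$J + seq_len(block$H)] <- theta$omega2
  Se <- diag(c(rep(theta$delta2, block$N), rep(theta$tau2, block$M_len)))
  list(Sp = Sp, Se = Se, mu_star = c(theta$mu, rep(0, block$J + block$H)))
}

# Brute-force posterior by conditioning the explicit joint Gaussian of
# (beta, D): independent of the Cholesky/Woodbury route in the package.
brute_posterior <- function(block, theta) {
  pm <- prior_matrices(block, theta)
  D <- block$Delta
  S_bD <- pm$Sp %*% t(D)
  S_DD <- D %*% pm$Sp %*% t(D) + pm$Se
  y <- c(block$G, block$M)
  m <- pm$mu_star + drop(S_bD %*% solve(S_DD, y - drop(D %*% pm$mu_star)))
  V <- pm$Sp - S_bD %*% solve(S_DD, t(S_bD))
  list(mean = m, cov = (V + t(V)) / 2)
}

# Marginal log density assembled directly as an n x n Gaussian.
brute_loglik <- function(block, theta) {
  pm <- prior_matrices(block, theta)
  D <- block$Delta
  S <- D %*% pm$Sp %*% t(D) + pm$Se
  mvtnorm::dmvnorm(c(block$G, block$M), drop(D %*% pm$mu_star), S,
                   log = TRUE)
}

# Dataset -> blocks in one call.
sim_blocks <- function(n_genes, seed, ...) {
  d <- generate_dataset(sim_config(n_genes = n_genes, seed = seed, ...))
  list(blocks = build_gene_blocks(d$expr, d$meth)$blocks, truth = d$truth)
}

# Small literal expression table for filter tests.
toy_expression <- function(calls_rows, K = 4) {
  n <- length(calls_rows)
  intens <- matrix(2^rnorm(n * 2 * K, 7), n)
  calls <- do.call(rbind, calls_rows)
  expression_table(paste0("p", seq_len(n)), paste0("g", seq_len(n)),
                   intens, calls, K = K)
}
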