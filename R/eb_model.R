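#' Hyperparameter set for the hierarchical model
#'
#' Holds the gene-level prior mean mu = (mu1, mu2, eta1, eta2), its 4x4
#' covariance Sigma (expression block, methylation block and a free cross
#' block), the probe-effect variances sigma2 (expression) and omega2
#' (methylation), and the error variances delta2 (expression) and tau2
#' (methylation).
#'
#' @param mu numeric length-4 vector.
#' @param Sigma symmetric positive semi-definite 4x4 matrix.
#' @param sigma2,delta2,omega2,tau2 positive scalars.
#' @return An object of class \code{hyperparams}.
#' @export
hyperparams <- function(mu, Sigma, sigma2, delta2, omega2, tau2) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  stopifnot(length(mu) == 4L, all(dim(Sigma) == 4L),
            sigma2 > 0, delta2 > 0, omega2 > 0, tau2 > 0)
  if (max(abs(Sigma - t(Sigma))) > 1e-8)
    stop("Sigma must be symmetric")
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("Sigma is not positive semi-definite (smallest eigenvalue ",
         format(min(ev)), ")")
  structure(list(mu = mu, Sigma = Sigma, sigma2 = sigma2, delta2 = delta2,
                 omega2 = omega2, tau2 = tau2),
            class = "hyperparams")
}

# Clip tiny negative eigenvalues so chol() succeeds on boundary estimates.
repair_psd <- function(S, eps = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < eps) {
    warning("clipping eigenvalues of a near-singular covariance at ", eps)
    e$values <- pmax(e$values, eps)
    S <- e$vectors %*% (e$values * t(e$vectors))
  }
  (S + t(S)) / 2
}

# Prior precision of beta_i: block-diag(Sigma^-1, I/sigma2, I/omega2),
# and the matching prior mean (mu, 0).
prior_precision <- function(block, theta) {
  p <- 4L + block$J + block$H
  P <- matrix(0, p, p)
  Sinv <- chol2inv(chol(repair_psd(theta$Sigma)))
  P[1:4, 1:4] <- Sinv
  if (block$J > 0) diag(P)[4L + seq_len(block$J)] <- 1 / theta$sigma2
  if (block$H > 0) diag(P)[4L + block$J + seq_len(block$H)] <- 1 / theta$omega2
  P
}

prior_mean_star <- function(block, theta) {
  c(theta$mu, rep(0, block$J + block$H))
}

#' Exact conditional posterior of a gene's coefficient vector
#'
#' For one gene the model is D_i | beta_i ~ N(Delta_i beta_i, Sigma_e) with
#' Gaussian prior beta_i ~ N(mu*, Sigma_p), so the posterior is Gaussian with
#' covariance (Delta' Sigma_e^-1 Delta + Sigma_p^-1)^-1 and mean
#' cov (Delta' Sigma_e^-1 D + Sigma_p^-1 mu*). Sigma_e is diagonal, so all
#' products reduce to the block's cached cross-products; the central solve is
#' a Cholesky factorization of the (4+J+H) posterior precision.
#'
#' @param block a \code{gene_block}.
#' @param theta a \code{hyperparams} object.
#' @return A \code{gene_posterior}: list with \code{gene_id}, \code{mean}
#'   and \code{cov}.
#' @export
posterior_beta <- function(block, theta) {
  P <- prior_precision(block, theta)
  mu_star <- prior_mean_star(block, theta)
  A <- block$XtX_g / theta$delta2 + block$XtX_m / theta$tau2 + P
  rhs <- block$Xty_g / theta$delta2 + block$Xty_m / theta$tau2 +
    drop(P %*% mu_star)
  R <- tryCatch(chol(A), error = function(e)
    stop("posterior precision not positive definite for gene ",
         block$gene_id, ": ", conditionMessage(e)))
  V <- chol2inv(R)
  m <- drop(V %*% rhs)
  structure(list(gene_id = block$gene_id, mean = m, cov = (V + t(V)) / 2),
            class = "gene_posterior")
}

#' Posterior of the expression and methylation changes
#'
#' Applies the linear contrast (mu_2 - mu_1, eta_2 - eta_1) to a gene
#' posterior, yielding the bivariate Gaussian posterior of the gene's
#' expression change and methylation change between conditions.
#'
#' @param post a \code{gene_posterior}.
#' @return A \code{diff_posterior}: list with \code{gene_id}, length-2
#'   \code{mean} and 2x2 \code{cov}.
#' @export
diff_posterior <- function(post) {
  p <- length(post$mean)
  stopifnot(p >= 4L)
  A <- matrix(0, 2, p)
  A[1, 1] <- -1; A[1, 2] <- 1
  A[2, 3] <- -1; A[2, 4] <- 1
  cv <- A %*% post$cov %*% t(A)
  structure(list(gene_id = post$gene_id,
                 mean = drop(A %*% post$mean),
                 cov = (cv + t(cv)) / 2),
            class = "diff_posterior")
}

#' Observed-data log likelihood of one gene block
#'
#' Marginally D_i ~ N(Delta mu*, Delta Sigma_p Delta' + Sigma_e). Evaluated
#' through the Woodbury identity and the matrix determinant lemma so only
#' the small (4+J+H) posterior precision is factorized:
#' log|S| = log|Sigma_e| + log|Sigma_p| + log|A| and
#' r' S^-1 r = r' Sigma_e^-1 r - u' A^-1 u with u = Delta' Sigma_e^-1 r.
#'
#' @inheritParams posterior_beta
#' @return Scalar log density of the stacked data vector.
#' @export
loglik_gene <- function(block, theta) {
  P <- prior_precision(block, theta)
  mu_star <- prior_mean_star(block, theta)
  A <- block$XtX_g / theta$delta2 + block$XtX_m / theta$tau2 + P
  fitted_g <- drop(block$Delta[block$expr_rows, , drop = FALSE] %*% mu_star)
  fitted_m <- drop(block$Delta[block$meth_rows, , drop = FALSE] %*% mu_star)
  rg <- block$G - fitted_g
  rm_ <- block$M - fitted_m
  u <- drop(crossprod(block$Delta[block$expr_rows, , drop = FALSE], rg)) /
    theta$delta2 +
    drop(crossprod(block$Delta[block$meth_rows, , drop = FALSE], rm_)) /
    theta$tau2
  Ra <- tryCatch(chol(A), error = function(e)
    stop("marginal covariance not positive definite for gene ",
         block$gene_id))
  quad <- sum(rg^2) / theta$delta2 + sum(rm_^2) / theta$tau2 -
    sum(backsolve(Ra, u, transpose = TRUE)^2)
  # log|Sigma_p| = log|Sigma| + J log sigma2 + H log omega2;
  # log|A| appears with +, log|Sigma_p^-1| contributes via -log|Sigma_p|
  logdet_Sigma <- as.numeric(determinant(repair_psd(theta$Sigma),
                                         logarithm = TRUE)$modulus)
  logdet_S <- block$N * log(theta$delta2) + block$M_len * log(theta$tau2) +
    logdet_Sigma + block$J * log(theta$sigma2) + block$H * log(theta$omega2) +
    2 * sum(log(diag(Ra)))
  n <- block$N + block$M_len
  -0.5 * (n * log(2 * pi) + logdet_S + quad)
}
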