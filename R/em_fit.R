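#' E-step: posterior moment cache over all genes
#'
#' Stores for every gene the posterior mean m_i = E(beta_i | D_i, theta),
#' covariance V_i = Cov(beta_i | D_i, theta) and, implicitly, the second
#' moment m_i m_i' + V_i needed by the M-step closed forms.
#'
#' @param blocks list of \code{gene_block}.
#' @param theta \code{hyperparams}.
#' @return List (one entry per gene) of \code{gene_posterior}.
#' @export
e_step <- function(blocks, theta) {
  lapply(blocks, function(b) {
    tryCatch(posterior_beta(b, theta),
             error = function(e) stop("E-step failed for gene ", b$gene_id,
                                      ": ", conditionMessage(e)))
  })
}

#' M-step: closed-form maximizers of the expected complete-data likelihood
#'
#' Given the posterior moments, the maximizing updates are the natural
#' moment matches: the prior mean is the average posterior gene-level
#' 4-vector; the prior covariance is the average posterior second moment of
#' its centered version; probe-effect variances average E(b^2), E(a^2) over
#' probes; error variances average the expected squared residuals over
#' observations.
#'
#' @param blocks list of \code{gene_block}.
#' @param cache output of [e_step()] on the same blocks.
#' @param var_floor lower bound applied (with a warning) to any variance
#'   update that would otherwise be nonpositive.
#' @param constrain_cross if TRUE, zero the cross block of Sigma after the
#'   update (separable fit; used for model checking).
#' @return Updated \code{hyperparams}.
#' @export
m_step <- function(blocks, cache, var_floor = 1e-10,
                   constrain_cross = FALSE) {
  I <- length(blocks)
  stopifnot(I == length(cache))
  g_means <- t(vapply(cache, function(p) p$mean[1:4], numeric(4)))
  mu_hat <- colMeans(g_means)
  Sigma_hat <- matrix(0, 4, 4)
  sum_b2 <- 0; n_b <- 0
  sum_a2 <- 0; n_a <- 0
  sse_g <- 0; n_g <- 0
  sse_m <- 0; n_m <- 0
  for (i in seq_len(I)) {
    b <- blocks[[i]]; p <- cache[[i]]
    d <- p$mean[1:4] - mu_hat
    Sigma_hat <- Sigma_hat + p$cov[1:4, 1:4] + tcrossprod(d)
    jb <- 4L + seq_len(b$J)
    ja <- 4L + b$J + seq_len(b$H)
    sum_b2 <- sum_b2 + sum(p$mean[jb]^2) + sum(diag(p$cov)[jb])
    n_b <- n_b + b$J
    sum_a2 <- sum_a2 + sum(p$mean[ja]^2) + sum(diag(p$cov)[ja])
    n_a <- n_a + b$H
    # E||y - X beta||^2 = ||y - X m||^2 + tr(X'X V), per platform
    rg <- b$G - drop(b$Delta[b$expr_rows, , drop = FALSE] %*% p$mean)
    rm_ <- b$M - drop(b$Delta[b$meth_rows, , drop = FALSE] %*% p$mean)
    sse_g <- sse_g + sum(rg^2) + sum(b$XtX_g * p$cov)
    sse_m <- sse_m + sum(rm_^2) + sum(b$XtX_m * p$cov)
    n_g <- n_g + b$N
    n_m <- n_m + b$M_len
  }
  Sigma_hat <- Sigma_hat / I
  Sigma_hat <- (Sigma_hat + t(Sigma_hat)) / 2
  if (constrain_cross) {
    Sigma_hat[1:2, 3:4] <- 0
    Sigma_hat[3:4, 1:2] <- 0
  }
  clamp <- function(v, what) {
    if (v <= 0) {
      warning(what, " update nonpositive; floored at ", var_floor)
      var_floor
    } else v
  }
  hyperparams(mu_hat, repair_psd(Sigma_hat, var_floor),
              sigma2 = clamp(sum_b2 / n_b, "sigma2"),
              delta2 = clamp(sse_g / n_g, "delta2"),
              omega2 = clamp(sum_a2 / n_a, "omega2"),
              tau2 = clamp(sse_m / n_m, "tau2"))
}

#' Total observed-data log likelihood
#'
#' @inheritParams e_step
#' @return Scalar sum of per-gene marginal log densities.
#' @export
loglik_total <- function(blocks, theta) {
  sum(vapply(blocks, loglik_gene, numeric(1), theta = theta))
}

#' Method-of-moments starting values
#'
#' Condition means from probe-averaged per-gene means (prior mean and
#' covariance from their across-gene moments); the expression error variance
#' from within probe-by-condition replicate scatter; the methylation error
#' variance from cross-condition probe differences within genes (each has
#' variance 2*tau2 about the gene's mean difference); probe-effect variances
#' from between-probe scatter within genes with the error contribution
#' subtracted off.
#'
#' @param blocks list of \code{gene_block}.
#' @return \code{hyperparams} starting value.
#' @export
init_theta <- function(blocks, var_floor = 1e-4) {
  I <- length(blocks)
  g4 <- matrix(0, I, 4)
  sse_rep <- 0; n_rep <- 0
  sd_probe_g <- 0; n_probe_g <- 0
  sd_probe_m <- 0; n_probe_m <- 0
  ss_dm <- 0; n_dm <- 0
  for (i in seq_len(I)) {
    b <- blocks[[i]]
    K <- b$K
    Gm <- matrix(b$G, nrow = 2L * K)   # columns = probes; rows = (l,k) pairs
    g1 <- colMeans(Gm[seq_len(K), , drop = FALSE])        # probe means, cond 1
    g2 <- colMeans(Gm[K + seq_len(K), , drop = FALSE])
    Mm <- matrix(b$M, nrow = 2L)       # rows = condition, columns = probes
    g4[i, ] <- c(mean(g1), mean(g2), mean(Mm[1, ]), mean(Mm[2, ]))
    # within probe-by-condition replicate residuals -> delta2
    if (K >= 2) {
      for (l in 1:2) {
        sub <- Gm[(l - 1L) * K + seq_len(K), , drop = FALSE]
        sse_rep <- sse_rep + sum(sweep(sub, 2, colMeans(sub))^2)
        n_rep <- n_rep + (K - 1L) * b$J
      }
    }
    if (b$J >= 2) {
      pm <- (g1 + g2) / 2
      sd_probe_g <- sd_probe_g + sum((pm - mean(pm))^2)
      n_probe_g <- n_probe_g + b$J - 1L
    }
    if (b$H >= 2) {
      pm <- colMeans(Mm)
      sd_probe_m <- sd_probe_m + sum((pm - mean(pm))^2)
      n_probe_m <- n_probe_m + b$H - 1L
      dm <- Mm[2, ] - Mm[1, ]
      ss_dm <- ss_dm + sum((dm - mean(dm))^2)
      n_dm <- n_dm + b$H - 1L
    }
  }
  delta2 <- if (n_rep > 0) sse_rep / n_rep else var_floor
  tau2 <- if (n_dm > 0) ss_dm / (2 * n_dm) else var_floor
  K <- blocks[[1]]$K
  sigma2 <- if (n_probe_g > 0)
    max(sd_probe_g / n_probe_g - delta2 / (2 * K), var_floor) else var_floor
  omega2 <- if (n_probe_m > 0)
    max(sd_probe_m / n_probe_m - tau2 / 2, var_floor) else var_floor
  hyperparams(colMeans(g4), repair_psd(stats::cov(g4), var_floor),
              sigma2 = max(sigma2, var_floor),
              delta2 = max(delta2, var_floor),
              omega2 = max(omega2, var_floor),
              tau2 = max(tau2, var_floor))
}

#' Fit the hierarchical model by EM
#'
#' Alternates the posterior-moment E-step and closed-form M-step, tracking
#' the observed-data log likelihood, until its relative change falls below
#' \code{tol} or \code{max_iter} is reached. A likelihood decrease beyond
#' numerical noise aborts (it would indicate a defective update).
#'
#' @param blocks list of at least two \code{gene_block}.
#' @param init starting \code{hyperparams}; default method of moments.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param constrain_cross zero the expression-methylation cross-covariance
#'   every M-step (fits the separable model).
#' @return An \code{em_state}: list with \code{theta}, \code{iteration},
#'   \code{loglik}, \code{loglik_history}, \code{converged} and the final
#'   E-step \code{cache}.
#' @export
em_fit <- function(blocks, init = NULL, max_iter = 500L, tol = 1e-8,
                   constrain_cross = FALSE) {
  stopifnot(length(blocks) >= 2L, max_iter >= 1L)
  theta <- if (is.null(init)) init_theta(blocks) else init
  if (constrain_cross) {
    S <- theta$Sigma; S[1:2, 3:4] <- 0; S[3:4, 1:2] <- 0
    theta <- hyperparams(theta$mu, S, theta$sigma2, theta$delta2,
                         theta$omega2, theta$tau2)
  }
  ll <- loglik_total(blocks, theta)
  history <- ll
  converged <- FALSE
  cache <- NULL
  for (it in seq_len(max_iter)) {
    cache <- e_step(blocks, theta)
    theta <- m_step(blocks, cache, constrain_cross = constrain_cross)
    ll_new <- loglik_total(blocks, theta)
    if (ll_new < ll - 1e-6 * max(1, abs(ll)))
      stop("log likelihood decreased at iteration ", it, " (", ll, " -> ",
           ll_new, "); M-step defect")
    history <- c(history, ll_new)
    rel <- abs(ll_new - ll) / max(1, abs(ll))
    ll <- ll_new
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(theta = theta, iteration = length(history) - 1L,
                 loglik = ll, loglik_history = history,
                 converged = converged, cache = cache),
            class = "em_state")
}

#' Residual and latent-effect diagnostics
#'
#' Emits the raw material for model checking: per-observation standardized
#' residuals (data minus fitted posterior mean, scaled by the platform error
#' SD), per-gene posterior condition means (gene effects) and per-probe
#' posterior probe effects.
#'
#' @param blocks list of \code{gene_block}.
#' @param state fitted \code{em_state}.
#' @return List of data.frames \code{residuals}, \code{gene_effects},
#'   \code{probe_effects}.
#' @export
extract_diagnostics <- function(blocks, state) {
  theta <- state$theta
  cache <- state$cache
  if (is.null(cache)) cache <- e_step(blocks, theta)
  res <- vector("list", length(blocks))
  ge <- vector("list", length(blocks))
  pe <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; p <- cache[[i]]
    fit <- drop(b$Delta %*% p$mean)
    r <- c(b$G, b$M) - fit
    r[b$expr_rows] <- r[b$expr_rows] / sqrt(theta$delta2)
    r[b$meth_rows] <- r[b$meth_rows] / sqrt(theta$tau2)
    res[[i]] <- data.frame(
      gene_id = b$gene_id,
      platform = c(rep("expression", b$N), rep("methylation", b$M_len)),
      residual = r, stringsAsFactors = FALSE)
    ge[[i]] <- data.frame(
      gene_id = b$gene_id,
      effect = c("mu1", "mu2", "eta1", "eta2"),
      value = p$mean[1:4], stringsAsFactors = FALSE)
    pe[[i]] <- data.frame(
      gene_id = b$gene_id,
      platform = c(rep("expression", b$J), rep("methylation", b$H)),
      probe = c(seq_len(b$J), seq_len(b$H)),
      value = p$mean[-(1:4)], stringsAsFactors = FALSE)
  }
  list(residuals = do.call(rbind, res),
       gene_effects = do.call(rbind, ge),
       probe_effects = do.call(rbind, pe))
}

#' Expression-only marginal EM fit
#'
#' Fits the expression half of the model on its own: per gene,
#' G_ijkl = mu_il + b_ij + e_ijkl with (mu_i1, mu_i2) ~ N(mu12, Sigma1),
#' b ~ N(0, sigma2), e ~ N(0, delta2). Used as an independent check that
#' the joint fit with the cross-covariance pinned at zero separates into
#' its marginal fits.
#'
#' @param blocks list of \code{gene_block} (only the expression rows used).
#' @param init optional list(mu12, Sigma1, sigma2, delta2).
#' @param max_iter,tol as in [em_fit()].
#' @return List with \code{mu12}, \code{Sigma1}, \code{sigma2},
#'   \code{delta2}, \code{loglik_history}, \code{iteration}.
#' @export
fit_expression_marginal <- function(blocks, init = NULL, max_iter = 500L,
                                    tol = 1e-8) {
  # per gene: y = X b + e, X = [cond indicators | probe indicators]
  mk <- function(b) {
    X <- b$Delta[b$expr_rows, c(1:2, 4L + seq_len(b$J)), drop = FALSE]
    list(y = b$G, X = X, XtX = crossprod(X), Xty = drop(crossprod(X, b$G)),
         J = b$J, N = b$N)
  }
  eb <- lapply(blocks, mk)
  if (is.null(init)) {
    th0 <- init_theta(blocks)
    init <- list(mu12 = th0$mu[1:2], Sigma1 = th0$Sigma[1:2, 1:2],
                 sigma2 = th0$sigma2, delta2 = th0$delta2)
  }
  th <- init
  ll_one <- function(e, th) {
    p <- 2L + e$J
    P <- matrix(0, p, p)
    P[1:2, 1:2] <- chol2inv(chol(repair_psd(th$Sigma1)))
    diag(P)[2L + seq_len(e$J)] <- 1 / th$sigma2
    A <- e$XtX / th$delta2 + P
    mu_star <- c(th$mu12, rep(0, e$J))
    r <- e$y - drop(e$X %*% mu_star)
    u <- drop(crossprod(e$X, r)) / th$delta2
    Ra <- chol(A)
    quad <- sum(r^2) / th$delta2 - sum(backsolve(Ra, u, transpose = TRUE)^2)
    ld <- e$N * log(th$delta2) +
      as.numeric(determinant(repair_psd(th$Sigma1), TRUE)$modulus) +
      e$J * log(th$sigma2) + 2 * sum(log(diag(Ra)))
    -0.5 * (e$N * log(2 * pi) + ld + quad)
  }
  ll <- sum(vapply(eb, ll_one, numeric(1), th = th))
  history <- ll
  for (it in seq_len(max_iter)) {
    post <- lapply(eb, function(e) {
      p <- 2L + e$J
      P <- matrix(0, p, p)
      P[1:2, 1:2] <- chol2inv(chol(repair_psd(th$Sigma1)))
      diag(P)[2L + seq_len(e$J)] <- 1 / th$sigma2
      A <- e$XtX / th$delta2 + P
      V <- chol2inv(chol(A))
      m <- drop(V %*% (e$Xty / th$delta2 +
                         drop(P %*% c(th$mu12, rep(0, e$J)))))
      list(m = m, V = V)
    })
    g2 <- t(vapply(post, function(p) p$m[1:2], numeric(2)))
    mu12 <- colMeans(g2)
    S1 <- matrix(0, 2, 2); sb <- 0; nb <- 0; sse <- 0; nn <- 0
    for (i in seq_along(eb)) {
      e <- eb[[i]]; p <- post[[i]]
      d <- p$m[1:2] - mu12
      S1 <- S1 + p$V[1:2, 1:2] + tcrossprod(d)
      jb <- 2L + seq_len(e$J)
      sb <- sb + sum(p$m[jb]^2) + sum(diag(p$V)[jb]); nb <- nb + e$J
      r <- e$y - drop(e$X %*% p$m)
      sse <- sse + sum(r^2) + sum(e$XtX * p$V); nn <- nn + e$N
    }
    th <- list(mu12 = mu12, Sigma1 = repair_psd(S1 / length(eb)),
               sigma2 = sb / nb, delta2 = sse / nn)
    ll_new <- sum(vapply(eb, ll_one, numeric(1), th = th))
    history <- c(history, ll_new)
    rel <- abs(ll_new - ll) / max(1, abs(ll))
    ll <- ll_new
    if (rel < tol) break
  }
  c(th, list(loglik_history = history, iteration = length(history) - 1L))
}
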