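test_that("E-step caches the per-gene posterior moments deterministically", {
  th <- random_theta(seed = 1)
  b <- random_block(th, seed = 2)
  cache <- e_step(list(b, b), th)
  expect_identical(cache[[1]]$mean, cache[[2]]$mean)
  expect_identical(cache[[1]]$cov, cache[[2]]$cov)
  or <- brute_posterior(b, th)
  expect_lt(max(abs(cache[[1]]$mean - or$mean)), 1e-8)
})

test_that("M-step updates match Monte-Carlo maximization of Q", {
  # independent route: draw beta from the cached posterior, compute the
  # complete-data sufficient statistics empirically, maximize directly
  th <- random_theta(seed = 6)
  blocks <- list(random_block(th, J = 2, H = 2, K = 2, seed = 61,
                              gene_id = "g1"),
                 random_block(th, J = 1, H = 2, K = 2, seed = 62,
                              gene_id = "g2"),
                 random_block(th, J = 3, H = 1, K = 2, seed = 63,
                              gene_id = "g3"))
  cache <- e_step(blocks, th)
  upd <- suppressWarnings(m_step(blocks, cache))
  set.seed(99)
  R <- 2e5
  mu_mc <- matrix(0, length(blocks), 4)
  Sig_mc <- matrix(0, 4, 4)
  sb <- 0; nb <- 0; sa <- 0; na_ <- 0; sg <- 0; ng <- 0; sm <- 0; nm <- 0
  draws <- lapply(seq_along(blocks), function(i)
    mvtnorm::rmvnorm(R, cache[[i]]$mean, cache[[i]]$cov))
  for (i in seq_along(blocks)) {
    mu_mc[i, ] <- colMeans(draws[[i]][, 1:4])
  }
  mu_hat <- colMeans(mu_mc)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]; Bi <- draws[[i]]
    ctr <- sweep(Bi[, 1:4, drop = FALSE], 2, mu_hat)
    Sig_mc <- Sig_mc + crossprod(ctr) / R
    jb <- 4 + seq_len(b$J); ja <- 4 + b$J + seq_len(b$H)
    sb <- sb + sum(Bi[, jb]^2) / R; nb <- nb + b$J
    sa <- sa + sum(Bi[, ja]^2) / R; na_ <- na_ + b$H
    fit_g <- Bi %*% t(b$Delta[b$expr_rows, , drop = FALSE])
    fit_m <- Bi %*% t(b$Delta[b$meth_rows, , drop = FALSE])
    sg <- sg + sum(sweep(-fit_g, 2, b$G, "+")^2) / R; ng <- ng + b$N
    sm <- sm + sum(sweep(-fit_m, 2, b$M, "+")^2) / R; nm <- nm + b$M_len
  }
  expect_equal(upd$mu, mu_hat, tolerance = 0.01)
  expect_equal(unname(upd$Sigma), unname(Sig_mc / length(blocks)),
               tolerance = 0.05)
  expect_equal(upd$sigma2, sb / nb, tolerance = 0.02)
  expect_equal(upd$omega2, sa / na_, tolerance = 0.02)
  expect_equal(upd$delta2, sg / ng, tolerance = 0.02)
  expect_equal(upd$tau2, sm / nm, tolerance = 0.02)
})

test_that("degenerate cache collapses the prior to its floor", {
  th <- random_theta(seed = 7)
  blocks <- list(random_block(th, seed = 71, gene_id = "g1"),
                 random_block(th, seed = 72, gene_id = "g2"))
  v <- c(1, 2, 3, 4)
  cache <- lapply(blocks, function(b) {
    p <- 4 + b$J + b$H
    list(gene_id = b$gene_id, mean = c(v, rep(0, b$J + b$H)),
         cov = matrix(0, p, p))
  })
  upd <- suppressWarnings(m_step(blocks, cache))
  expect_equal(upd$mu, v)
  expect_lt(max(abs(upd$Sigma)), 1e-9)
  expect_equal(upd$sigma2, 1e-10)  # floored
})

test_that("EM never decreases the likelihood and stops per contract", {
  for (s in 1:5) {
    bl <- sim_blocks(60, seed = 400 + s)$blocks
    fit <- em_fit(bl, max_iter = 40)
    expect_true(all(diff(fit$loglik_history) >= -1e-8 *
                      pmax(1, abs(fit$loglik_history[-1]))))
  }
  bl <- sim_blocks(30, seed = 500)$blocks
  one <- em_fit(bl, max_iter = 1)
  expect_equal(one$iteration, 1L)
  expect_false(one$converged)
})

test_that("a fit started at the generative parameters stays there", {
  s <- sim_blocks(800, seed = 42)
  th0 <- s$truth$theta_true
  fit <- em_fit(s$blocks, init = th0, max_iter = 2, tol = 0)
  expect_lt(max(abs(fit$theta$mu - th0$mu)), 0.1)
  expect_lt(max(abs(fit$theta$Sigma - th0$Sigma)), 0.2)
  expect_lt(abs(fit$theta$delta2 - th0$delta2) / th0$delta2, 0.15)
})

test_that("gene order does not change the estimates", {
  bl <- sim_blocks(40, seed = 77)$blocks
  f1 <- em_fit(bl, max_iter = 10, tol = 0)
  f2 <- em_fit(rev(bl), max_iter = 10, tol = 0)
  # agreement to near machine precision (summation order may differ)
  expect_equal(f1$theta$mu, f2$theta$mu, tolerance = 1e-12)
  expect_equal(f1$theta$Sigma, f2$theta$Sigma, tolerance = 1e-12)
  expect_equal(f1$theta$delta2, f2$theta$delta2, tolerance = 1e-12)
})

test_that("diagnostics have the right bookkeeping and vanish without noise", {
  s <- sim_blocks(15, seed = 88)
  fit <- em_fit(s$blocks, max_iter = 20)
  diag_ <- extract_diagnostics(s$blocks, fit)
  expect_equal(nrow(diag_$residuals),
               sum(2 * 4 * s$truth$J + 2 * s$truth$H))
  expect_equal(nrow(diag_$gene_effects), 4 * length(s$blocks))
  expect_equal(nrow(diag_$probe_effects), sum(s$truth$J + s$truth$H))
  # near-noiseless data -> residuals collapse
  th <- default_sim_theta()
  quiet <- hyperparams(th$mu, th$Sigma, 1e-8, 1e-8, 1e-8, 1e-8)
  d <- generate_dataset(sim_config(n_genes = 5, seed = 9,
                                   theta_true = quiet))
  bl <- build_gene_blocks(d$expr, d$meth)$blocks
  st <- list(theta = quiet, cache = e_step(bl, quiet))
  r <- extract_diagnostics(bl, st)$residuals$residual
  expect_lt(max(abs(r)) * sqrt(1e-8), 1e-3)  # unstandardized residuals ~ 0
})

test_that("residuals on well-specified data look Gaussian", {
  s <- sim_blocks(400, seed = 31)
  fit <- em_fit(s$blocks, max_iter = 60)
  r <- extract_diagnostics(s$blocks, fit)$residuals$residual
  skew <- mean((r - mean(r))^3) / sd(r)^3
  expect_lt(abs(skew), 0.1)
})
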