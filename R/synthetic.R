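#' Default hyperparameters for simulation
#'
#' A realistic two-condition setting: gene-level log2 expression means near
#' 7 with across-gene spread ~1, methylation means near 9 with similar
#' spread, a weak negative cross-covariance between expression and
#' methylation levels (entries about -0.1 of the geometric mean of the
#' marginal variances, matching the weak negative coupling seen on promoter
#' arrays), probe-effect SDs ~0.5 and error SDs ~0.35-0.45 (log2 scale).
#'
#' @return A \code{hyperparams} object.
#' @export
default_sim_theta <- function() {
  S1 <- matrix(c(1.0, 0.8, 0.8, 1.0), 2)
  S2 <- matrix(c(0.9, 0.7, 0.7, 0.9), 2)
  Sx <- -0.1 * sqrt(outer(diag(S1), diag(S2)))
  Sigma <- rbind(cbind(S1, Sx), cbind(t(Sx), S2))
  hyperparams(mu = c(7, 7.2, 9, 8.8), Sigma = Sigma,
              sigma2 = 0.25, delta2 = 0.12, omega2 = 0.25, tau2 = 0.2)
}

#' Simulation configuration
#'
#' @param n_genes number of genes.
#' @param K expression replicates per condition (default 4, matching the
#'   study design; methylation always has one replicate).
#' @param probe_range inclusive integer range for per-gene probe counts on
#'   each platform (default 2:3, matching ~2-3 probes per gene).
#' @param theta_true generative \code{hyperparams}.
#' @param seed RNG seed (required).
#' @param log2_scale emit log2 intensities directly (default) or
#'   exponentiated "raw" intensities.
#' @param absent_rate probability that any single present call is flipped
#'   to "A" (default 0: all "P").
#' @param shift_frac fraction of genes whose true (expression change,
#'   methylation change) pair is displaced to a random nonzero center of
#'   magnitude \code{shift_size}, giving the dataset genuinely regulated
#'   genes for calibration studies.
#' @param shift_size magnitude of the displacement on each axis.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes, K = 4L, probe_range = 2:3,
                       theta_true = default_sim_theta(), seed,
                       log2_scale = TRUE, absent_rate = 0,
                       shift_frac = 0, shift_size = 2) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  stopifnot(n_genes >= 1L, K >= 1L, all(probe_range >= 1L),
            inherits(theta_true, "hyperparams"),
            absent_rate >= 0, absent_rate < 1,
            shift_frac >= 0, shift_frac <= 1)
  structure(list(n_genes = as.integer(n_genes), K = as.integer(K),
                 probe_range = as.integer(probe_range),
                 theta_true = theta_true, seed = as.integer(seed),
                 log2_scale = isTRUE(log2_scale),
                 absent_rate = absent_rate,
                 shift_frac = shift_frac, shift_size = shift_size),
            class = "sim_config")
}

# Draw from N(mean, Sigma) via Cholesky; rows are independent draws.
rmvn <- function(n, mean, Sigma) {
  L <- chol(repair_psd(Sigma))
  sweep(matrix(stats::rnorm(n * length(mean)), n) %*% L, 2, mean, "+")
}

#' Generate a synthetic probe-level dataset with known truth
#'
#' Draws each gene's condition means from N(mu, Sigma), probe effects from
#' N(0, sigma2) and N(0, omega2), and errors from N(0, delta2) and
#' N(0, tau2), then assembles the tables in the package's native layout.
#'
#' @param config a \code{sim_config}.
#' @return List with \code{expr} (expression_table), \code{meth}
#'   (methylation_table) and \code{truth} (list: per-gene means matrix
#'   \code{g4}, probe effect lists \code{b}, \code{a}, the per-gene true
#'   changes \code{diff}, and \code{theta_true}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  th <- config$theta_true
  I <- config$n_genes; K <- config$K
  J <- sample(config$probe_range, I, replace = TRUE)
  H <- sample(config$probe_range, I, replace = TRUE)
  g4 <- rmvn(I, th$mu, th$Sigma)
  if (config$shift_frac > 0) {
    n_shift <- round(config$shift_frac * I)
    if (n_shift > 0) {
      idx <- sample.int(I, n_shift)
      sgn <- function(n) sample(c(-1, 0, 1), n, replace = TRUE)
      se <- sgn(n_shift); sm <- sgn(n_shift)
      # redraw the zero/zero pairs so every shifted gene really moves
      while (any(se == 0 & sm == 0)) {
        z <- se == 0 & sm == 0
        se[z] <- sgn(sum(z)); sm[z] <- sgn(sum(z))
      }
      g4[idx, 2] <- g4[idx, 2] + se * config$shift_size
      g4[idx, 4] <- g4[idx, 4] + sm * config$shift_size
    }
  }
  gene_ids <- sprintf("gene%05d", seq_len(I))
  b <- lapply(J, function(j) stats::rnorm(j, 0, sqrt(th$sigma2)))
  a <- lapply(H, function(h) stats::rnorm(h, 0, sqrt(th$omega2)))
  e_rows <- vector("list", I)
  m_rows <- vector("list", I)
  for (i in seq_len(I)) {
    Ei <- matrix(0, J[i], 2L * K)
    for (j in seq_len(J[i])) for (l in 1:2) {
      cols <- (l - 1L) * K + seq_len(K)
      Ei[j, cols] <- g4[i, l] + b[[i]][j] +
        stats::rnorm(K, 0, sqrt(th$delta2))
    }
    e_rows[[i]] <- Ei
    Mi <- matrix(0, H[i], 2L)
    for (h in seq_len(H[i])) for (l in 1:2) {
      Mi[h, l] <- g4[i, 2L + l] + a[[i]][h] +
        stats::rnorm(1, 0, sqrt(th$tau2))
    }
    m_rows[[i]] <- Mi
  }
  e_mat <- do.call(rbind, e_rows)
  m_mat <- do.call(rbind, m_rows)
  e_gene <- rep(gene_ids, J)
  m_gene <- rep(gene_ids, H)
  e_probe <- paste0(e_gene, "_ep", unlist(lapply(J, seq_len)))
  m_probe <- paste0(m_gene, "_mp", unlist(lapply(H, seq_len)))
  calls <- matrix("P", nrow(e_mat), 2L * K)
  if (config$absent_rate > 0) {
    flip <- stats::runif(length(calls)) < config$absent_rate
    calls[flip] <- "A"
  }
  if (!config$log2_scale) e_mat <- 2^e_mat
  if (!config$log2_scale) m_mat <- 2^m_mat
  expr <- expression_table(e_probe, e_gene, e_mat, calls, K = K,
                           log2_scale = config$log2_scale)
  meth <- methylation_table(m_probe, m_gene, m_mat,
                            log2_scale = config$log2_scale)
  colnames(g4) <- c("mu1", "mu2", "eta1", "eta2")
  truth <- list(gene_id = gene_ids, g4 = g4, b = b, a = a,
                diff = cbind(ge = g4[, 2] - g4[, 1],
                             m = g4[, 4] - g4[, 3]),
                J = J, H = H, theta_true = th)
  list(expr = expr, meth = meth, truth = truth)
}

#' True nine-region labels for simulated genes
#'
#' Deterministic interval membership of each gene's true (expression
#' change, methylation change) pair in the grid's nine rectangles.
#'
#' @param truth truth component of [generate_dataset()].
#' @param grid a \code{region_grid}.
#' @return Character vector of labels in [category_labels()] vocabulary.
#' @export
truth_categories <- function(truth, grid) {
  cut3 <- function(x, thr) {
    ifelse(x < thr[1], 1L, ifelse(x < thr[2], 2L, 3L))
  }
  e <- c("DN", "NG", "UP")[cut3(truth$diff[, "ge"], grid$thr_ge)]
  m <- c("HO", "NM", "HR")[cut3(truth$diff[, "m"], grid$thr_m)]
  stats::setNames(paste(e, m, sep = "/"), truth$gene_id)
}
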