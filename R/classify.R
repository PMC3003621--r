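#' Nine-region category labels
#'
#' Fixed label order used everywhere (including argmax tie-breaks):
#' expression level (DN, NG, UP) outer, methylation level (HO, NM, HR)
#' inner. DN/NG/UP = down / no change / up regulation of expression;
#' HO/NM/HR = hypo / no change / hyper methylation.
#' @export
category_labels <- function() {
  as.vector(outer(c("HO", "NM", "HR"), c("DN", "NG", "UP"),
                  function(m, e) paste(e, m, sep = "/")))
}

#' Build the nine-region grid
#'
#' Thresholds on each axis are +/- C * s where s is the standard deviation
#' (sample SD, n-1 denominator) of the posterior mean change across genes,
#' computed separately for the expression and methylation axes.
#'
#' @param diffs list of \code{diff_posterior}.
#' @param c_mult positive threshold multiplier C (default 1.5).
#' @return A \code{region_grid}: list with \code{c_mult}, \code{sd_ge},
#'   \code{sd_m} and the per-axis \code{thresholds}.
#' @export
build_grid <- function(diffs, c_mult = 1.5) {
  stopifnot(length(diffs) >= 2L, is.numeric(c_mult), c_mult > 0)
  mges <- vapply(diffs, function(d) d$mean[1], numeric(1))
  etas <- vapply(diffs, function(d) d$mean[2], numeric(1))
  sd_ge <- stats::sd(mges)
  sd_m <- stats::sd(etas)
  if (sd_ge == 0 || sd_m == 0)
    stop("posterior mean changes are constant across genes; no grid")
  structure(list(c_mult = c_mult, sd_ge = sd_ge, sd_m = sd_m,
                 thr_ge = c(-c_mult * sd_ge, c_mult * sd_ge),
                 thr_m = c(-c_mult * sd_m, c_mult * sd_m)),
            class = "region_grid")
}

# Bivariate normal rectangle probability P(a1<X<b1, a2<Y<b2); bounds may be
# infinite. Degenerate (near-zero variance) axes fall back to point masses.
bvn_rect <- function(mean, cov, lower, upper) {
  # Miwa's deterministic scheme needs finite limits; 40 posterior SDs out
  # carries mass below double-precision resolution
  s <- sqrt(diag(cov))
  lower <- pmax(lower, mean - 40 * s)
  upper <- pmin(upper, mean + 40 * s)
  if (any(lower >= upper)) return(0)
  p <- mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                        sigma = cov, algorithm = mvtnorm::Miwa(steps = 512))
  if (attr(p, "msg") != "Normal Completion" && attr(p, "error") > 1e-6)
    stop("bivariate normal CDF did not converge: ", attr(p, "msg"))
  max(0, as.numeric(p))
}

#' Posterior probabilities of the nine regions
#'
#' Integrates the gene's bivariate Gaussian posterior of (expression
#' change, methylation change) over each axis-aligned rectangle of the
#' grid. Regions are half-open so they partition the plane; the boundary
#' has measure zero.
#'
#' @param diff a \code{diff_posterior}.
#' @param grid a \code{region_grid}.
#' @return Named numeric 9-vector in [category_labels()] order, summing
#'   to 1 within 1e-6.
#' @export
region_probs <- function(diff, grid) {
  stopifnot(inherits(diff, "diff_posterior"), inherits(grid, "region_grid"))
  gx <- c(-Inf, grid$thr_ge, Inf)
  gy <- c(-Inf, grid$thr_m, Inf)
  out <- numeric(9)
  k <- 0L
  for (ie in 1:3) for (im in 1:3) {   # expression outer, methylation inner
    k <- k + 1L
    out[k] <- bvn_rect(diff$mean, diff$cov,
                       lower = c(gx[ie], gy[im]),
                       upper = c(gx[ie + 1L], gy[im + 1L]))
  }
  names(out) <- category_labels()
  s <- sum(out)
  if (abs(s - 1) > 1e-6)
    stop("region probabilities sum to ", s, " for gene ", diff$gene_id)
  out / s
}

#' Assign genes to categories under a rule
#'
#' Each gene goes to its maximum-probability category; under the
#' thresholded rules ("max>0.6", "max>0.7") genes whose maximum falls below
#' the cutoff stay UNASSIGNED. Argmax ties break to the first label in
#' [category_labels()] order.
#'
#' @param prob_matrix numeric matrix, genes x 9, rows summing to 1; row
#'   names are gene ids.
#' @param rule one of "max", "max>0.6", "max>0.7" (or any "max>x").
#' @return data.frame with gene_id, assigned, max_prob, rule.
#' @export
assign_categories <- function(prob_matrix, rule = c("max", "max>0.6",
                                                    "max>0.7")) {
  rule <- match.arg(rule[1], c("max", "max>0.6", "max>0.7"))
  cutoff <- switch(rule, "max" = 0, "max>0.6" = 0.6, "max>0.7" = 0.7)
  stopifnot(ncol(prob_matrix) == 9L)
  labs <- category_labels()
  idx <- apply(prob_matrix, 1, which.max)   # which.max = first-max tie-break
  mx <- prob_matrix[cbind(seq_len(nrow(prob_matrix)), idx)]
  assigned <- ifelse(mx >= cutoff | (rule == "max"), labs[idx], "UNASSIGNED")
  data.frame(gene_id = rownames(prob_matrix), assigned = assigned,
             max_prob = as.numeric(mx), rule = rule,
             stringsAsFactors = FALSE)
}

#' Posterior-probability false discovery rate for one category
#'
#' Selecting the genes whose posterior probability of category s reaches
#' kappa, the FDR estimate is the average of one minus those posterior
#' probabilities: D(kappa) / K with D(kappa) = sum over selected genes of
#' (1 - P_i) and K the number selected.
#'
#' @param prob_matrix genes x 9 posterior probability matrix.
#' @param category one of [category_labels()].
#' @param kappa selection threshold in (0, 1].
#' @return List with \code{kappa}, \code{category}, \code{n_selected},
#'   \code{D} and \code{fdr_hat} (NA when nothing is selected).
#' @export
fdr_report <- function(prob_matrix, category, kappa) {
  stopifnot(kappa > 0, kappa <= 1, category %in% category_labels())
  p <- prob_matrix[, category]
  sel <- p >= kappa
  K <- sum(sel)
  D <- sum(1 - p[sel])
  list(kappa = kappa, category = category, n_selected = K, D = D,
       fdr_hat = if (K > 0) D / K else NA_real_)
}

#' Category count table across assignment rules
#'
#' Produces the familiar 3x3 grid (rows: methylation HR / NM / HO; columns:
#' expression DN / NG / UP) with per-cell counts joined by slashes across
#' the rules, e.g. "101/45/17" for max, max>0.6, max>0.7.
#'
#' @param assignments list of data.frames from [assign_categories()], one
#'   per rule, over identical genes.
#' @return character 3x3 matrix plus attribute \code{counts}, an integer
#'   array rule x 3 x 3.
#' @export
category_table <- function(assignments) {
  labs <- category_labels()
  meth_order <- c("HR", "NM", "HO")
  expr_order <- c("DN", "NG", "UP")
  counts <- array(0L, dim = c(length(assignments), 3, 3),
                  dimnames = list(vapply(assignments, function(a) a$rule[1],
                                         character(1)),
                                  meth_order, expr_order))
  for (r in seq_along(assignments)) {
    a <- assignments[[r]]
    tab <- table(factor(a$assigned, levels = labs))
    for (m in 1:3) for (e in 1:3) {
      counts[r, m, e] <- tab[paste(expr_order[e], meth_order[m], sep = "/")]
    }
  }
  cells <- matrix("", 3, 3, dimnames = list(meth_order, expr_order))
  for (m in 1:3) for (e in 1:3)
    cells[m, e] <- paste(counts[, m, e], collapse = "/")
  attr(cells, "counts") <- counts
  cells
}

#' Full classification of a fitted model
#'
#' Convenience wrapper: computes change posteriors for all genes, the grid,
#' region probabilities and the assignments under the three standard rules.
#'
#' @param blocks list of \code{gene_block}.
#' @param state fitted \code{em_state} (or a theta via \code{theta=}).
#' @param c_mult threshold multiplier.
#' @param theta optional \code{hyperparams} overriding \code{state$theta}.
#' @return List with \code{diffs}, \code{grid}, \code{probs} (matrix),
#'   \code{assignments} (list per rule), \code{table}.
#' @export
classify_genes <- function(blocks, state = NULL, c_mult = 1.5,
                           theta = NULL) {
  if (is.null(theta)) theta <- state$theta
  posts <- lapply(blocks, posterior_beta, theta = theta)
  diffs <- lapply(posts, diff_posterior)
  grid <- build_grid(diffs, c_mult = c_mult)
  probs <- t(vapply(diffs, region_probs, numeric(9), grid = grid))
  rownames(probs) <- vapply(diffs, function(d) d$gene_id, character(1))
  colnames(probs) <- category_labels()
  rules <- c("max", "max>0.6", "max>0.7")
  assignments <- lapply(rules, function(r) assign_categories(probs, r))
  names(assignments) <- rules
  list(posteriors = posts, diffs = diffs, grid = grid, probs = probs,
       assignments = assignments, table = category_table(assignments))
}
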