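#' Global and gene-specific expression-methylation correlations
#'
#' Global within-condition values are Pearson correlations across genes of
#' the posterior mean expression level versus the posterior mean methylation
#' level in that condition; the global difference value correlates the
#' posterior mean expression change with the posterior mean methylation
#' change. Gene-specific values are posterior correlations read off the
#' relevant 2x2 posterior covariance: the change pair from the change
#' posterior, and per-condition pairs (mu_l, eta_l) from the gene-level
#' 4x4 block.
#'
#' @param posteriors list of \code{gene_posterior}.
#' @param diffs matching list of \code{diff_posterior}.
#' @return A list with \code{global_within} (length-2, conditions 1 and 2),
#'   \code{global_diff}, and a data.frame \code{gene_specific} with columns
#'   gene_id, cor_diff, cor_cond1, cor_cond2.
#' @export
correlation_summary <- function(posteriors, diffs) {
  stopifnot(length(posteriors) == length(diffs), length(posteriors) >= 3L)
  means4 <- t(vapply(posteriors, function(p) p$mean[1:4], numeric(4)))
  dmeans <- t(vapply(diffs, function(d) d$mean, numeric(2)))
  pc <- function(C, a, b) C[a, b] / sqrt(C[a, a] * C[b, b])
  gs <- data.frame(
    gene_id = vapply(posteriors, function(p) p$gene_id, character(1)),
    cor_diff = vapply(diffs, function(d) pc(d$cov, 1, 2), numeric(1)),
    cor_cond1 = vapply(posteriors, function(p) pc(p$cov, 1, 3), numeric(1)),
    cor_cond2 = vapply(posteriors, function(p) pc(p$cov, 2, 4), numeric(1)),
    stringsAsFactors = FALSE)
  list(global_within = c(cond1 = stats::cor(means4[, 1], means4[, 3]),
                         cond2 = stats::cor(means4[, 2], means4[, 4])),
       global_diff = stats::cor(dmeans[, 1], dmeans[, 2]),
       gene_specific = gs)
}

#' Cross-analysis direction overlap within a methylation stratum
#'
#' Restricts to genes whose assigned category carries the given methylation
#' label in both analyses (e.g. hypomethylated in both the tamoxifen- and
#' fulvestrant-resistant comparisons) and tabulates the expression
#' direction (DN / NG / UP) in one analysis against the other.
#'
#' @param calls_a,calls_b data.frames from [assign_categories()] over a
#'   shared gene universe.
#' @param stratum methylation label: "HO", "NM" or "HR".
#' @return Integer 3x3 matrix (rows: direction in A; columns: in B).
#' @export
overlap_table <- function(calls_a, calls_b, stratum = "HO") {
  stopifnot(stratum %in% c("HO", "NM", "HR"))
  common <- intersect(calls_a$gene_id, calls_b$gene_id)
  if (length(common) == 0L) stop("the two analyses share no genes")
  a <- calls_a[match(common, calls_a$gene_id), ]
  b <- calls_b[match(common, calls_b$gene_id), ]
  split_lab <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    data.frame(expr = vapply(parts, function(p) p[1], character(1)),
               meth = vapply(parts, function(p) if (length(p) > 1) p[2]
                             else NA_character_, character(1)),
               stringsAsFactors = FALSE)
  }
  la <- split_lab(a$assigned); lb <- split_lab(b$assigned)
  keep <- !is.na(la$meth) & !is.na(lb$meth) &
    la$meth == stratum & lb$meth == stratum
  dirs <- c("DN", "NG", "UP")
  table(factor(la$expr[keep], levels = dirs),
        factor(lb$expr[keep], levels = dirs),
        dnn = c("A", "B"))
}

#' Fold-change contrast of per-gene scores between two categories
#'
#' Compares mean scores (e.g. histone-mark levels) between two gene groups
#' as a ratio of means, with a percentile bootstrap confidence interval
#' (genes resampled independently within each group).
#'
#' @param scores named numeric vector of nonnegative per-gene scores.
#' @param group_a,group_b disjoint character vectors of gene ids, each with
#'   at least two scored genes.
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return List with \code{fold_change}, \code{ci_low}, \code{ci_high},
#'   \code{n_a}, \code{n_b}.
#' @export
score_contrast <- function(scores, group_a, group_b, n_boot = 10000L,
                           conf = 0.95, seed = 1L) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  sa <- scores[intersect(group_a, names(scores))]
  sb <- scores[intersect(group_b, names(scores))]
  if (length(sa) < 2L || length(sb) < 2L)
    stop("each group needs at least two scored genes")
  if (any(c(sa, sb) < 0)) stop("scores must be nonnegative")
  if (mean(sb) == 0) stop("denominator group has zero mean score")
  fc <- mean(sa) / mean(sb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(sa, replace = TRUE)) / mean(sample(sb, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(fold_change = fc, ci_low = qs[1], ci_high = qs[2],
       n_a = length(sa), n_b = length(sb))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
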