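#' Run the full analysis pipeline on files
#'
#' Reads the probe-level tables, filters on present calls, log2-transforms
#' if needed, assembles gene blocks, fits the hierarchical model by EM,
#' classifies every gene into the nine regulation categories under the
#' three assignment rules, computes FDR reports and correlation summaries,
#' and writes all artifacts plus a machine-readable manifest to
#' \code{out_dir}.
#'
#' @param expr_file,calls_file,meth_file input TSV paths.
#' @param out_dir output directory (created if absent).
#' @param K expression replicates per condition.
#' @param min_present present-call threshold (per condition).
#' @param per_condition apply the present rule per condition (default) or
#'   pooled.
#' @param log2_scale whether inputs are already log2.
#' @param floor optional intensity floor before the log.
#' @param c_mult nine-region threshold multiplier.
#' @param kappa FDR selection threshold(s).
#' @param max_iter,tol EM controls.
#' @return Invisibly, a list with blocks, fit, classification, correlations
#'   and the manifest.
#' @export
run_fit <- function(expr_file, calls_file, meth_file, out_dir,
                    K = 4L, min_present = 2L, per_condition = TRUE,
                    log2_scale = FALSE, floor = NULL, c_mult = 1.5,
                    kappa = 0.9, max_iter = 500L, tol = 1e-8) {
  for (f in c(expr_file, calls_file, meth_file))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  expr <- read_expression(expr_file, calls_file, K = K,
                          log2_scale = log2_scale)
  meth <- read_methylation(meth_file, log2_scale = log2_scale)
  expr <- filter_present(expr, min_present, per_condition = per_condition)
  if (!expr$log2_scale) expr <- log2_transform(expr, floor = floor)
  if (!meth$log2_scale) meth <- log2_transform(meth, floor = floor)
  built <- build_gene_blocks(expr, meth)
  blocks <- built$blocks
  if (length(blocks) < 2L)
    stop("fewer than 2 genes available after filtering and intersection")
  fit <- em_fit(blocks, max_iter = max_iter, tol = tol)
  cls <- classify_genes(blocks, fit, c_mult = c_mult)
  cors <- correlation_summary(cls$posteriors, cls$diffs)

  write_theta_report(fit$theta, file.path(out_dir, "theta.yaml"))
  utils::write.table(
    data.frame(iteration = seq_along(fit$loglik_history) - 1L,
               loglik = fit$loglik_history),
    file.path(out_dir, "loglik_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  post_df <- data.frame(gene_id = rownames(cls$probs), cls$probs,
                        check.names = FALSE)
  for (r in names(cls$assignments)) {
    a <- cls$assignments[[r]]
    post_df[[paste0("assigned_", gsub("[^0-9a-z.]", "", r))]] <- a$assigned
  }
  post_df$max_prob <- cls$assignments[["max"]]$max_prob
  utils::write.table(post_df, file.path(out_dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cls$table),
                     file.path(out_dir, "category_table.tsv"),
                     sep = "\t", quote = FALSE)
  fdrs <- do.call(rbind, lapply(kappa, function(k) {
    do.call(rbind, lapply(category_labels(), function(s) {
      r <- fdr_report(cls$probs, s, k)
      data.frame(category = s, kappa = k, n_selected = r$n_selected,
                 D = r$D, fdr_hat = r$fdr_hat)
    }))
  }))
  utils::write.table(fdrs, file.path(out_dir, "fdr_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cors$gene_specific,
                     file.path(out_dir, "gene_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ebmex")),
    inputs = list(expr = expr_file, calls = calls_file, meth = meth_file),
    params = list(K = K, min_present = min_present,
                  per_condition = per_condition, c_mult = c_mult,
                  kappa = kappa, max_iter = max_iter, tol = tol),
    n_genes = length(blocks), skipped = nrow(built$skipped),
    em_iterations = fit$iteration, converged = fit$converged,
    loglik = fit$loglik,
    global_correlations = list(
      cond1 = unname(cors$global_within[1]),
      cond2 = unname(cors$global_within[2]),
      difference = cors$global_diff))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(blocks = blocks, fit = fit, classification = cls,
                 correlations = cors, manifest = manifest,
                 skipped = built$skipped))
}

#' Write a hyperparameter report
#'
#' @param theta \code{hyperparams}.
#' @param path output YAML path.
#' @export
write_theta_report <- function(theta, path) {
  yaml::write_yaml(list(
    mu = as.numeric(theta$mu),
    Sigma = lapply(seq_len(4), function(i) as.numeric(theta$Sigma[i, ])),
    sigma2 = theta$sigma2, delta2 = theta$delta2,
    omega2 = theta$omega2, tau2 = theta$tau2), path)
  invisible(path)
}

#' Simulate a dataset to disk
#'
#' Writes expression, calls, methylation and truth TSVs in the package's
#' native dialects.
#'
#' @param config a \code{sim_config}.
#' @param out_dir output directory.
#' @return Invisibly, the generated dataset.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- generate_dataset(config)
  write_table_tsv(d$expr, file.path(out_dir, "expression.tsv"),
                  file.path(out_dir, "expression_calls.tsv"))
  write_table_tsv(d$meth, file.path(out_dir, "methylation.tsv"))
  tdf <- data.frame(gene_id = d$truth$gene_id, d$truth$g4,
                    diff_ge = d$truth$diff[, "ge"],
                    diff_m = d$truth$diff[, "m"],
                    J = d$truth$J, H = d$truth$H)
  utils::write.table(tdf, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = config$seed, n_genes = config$n_genes,
                        K = config$K,
                        probe_range = as.integer(config$probe_range),
                        log2_scale = config$log2_scale,
                        absent_rate = config$absent_rate,
                        shift_frac = config$shift_frac,
                        shift_size = config$shift_size),
                   file.path(out_dir, "sim_manifest.yaml"))
  invisible(d)
}
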