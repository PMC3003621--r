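#' Expression table constructor
#'
#' A probe-level two-condition expression table with K replicates per
#' condition and MAS5-style present/absent detection calls. Intensities may
#' be raw (positive) or already on the log2 scale; [log2_transform()] records
#' the transition.
#'
#' @param probe_id character vector of probe identifiers (unique).
#' @param gene_id character vector mapping each probe to exactly one gene.
#' @param intensities numeric matrix, probes x (2K) columns ordered
#'   condition 1 replicates 1..K then condition 2 replicates 1..K.
#' @param calls character matrix of single characters in \{"P","M","A"\},
#'   same shape as \code{intensities}. "M" (marginal) counts as not present.
#' @param K integer, replicates per condition.
#' @param log2_scale logical, whether intensities are already log2.
#' @return An object of class \code{expression_table}.
#' @export
expression_table <- function(probe_id, gene_id, intensities, calls, K,
                             log2_scale = FALSE) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  intensities <- as.matrix(intensities)
  calls <- as.matrix(calls)
  stopifnot(length(probe_id) == length(gene_id),
            nrow(intensities) == length(probe_id),
            K >= 1, ncol(intensities) == 2L * K)
  if (!all(dim(calls) == dim(intensities))) {
    bad <- probe_id[seq_len(min(nrow(calls), nrow(intensities)))][1]
    stop("present-call matrix shape does not match intensities (first probe: ",
         if (length(probe_id)) probe_id[1] else "<none>", ")")
  }
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id: ", probe_id[duplicated(probe_id)][1])
  if (!all(calls %in% c("P", "M", "A")))
    stop("present calls must be one of P/M/A")
  structure(list(probe_id = probe_id, gene_id = gene_id,
                 intensities = intensities, calls = calls,
                 K = as.integer(K), log2_scale = isTRUE(log2_scale)),
            class = "expression_table")
}

#' Methylation table constructor
#'
#' Probe-level promoter methylation, one value per probe per condition
#' (the assay has no replicates).
#'
#' @param probe_id,gene_id character vectors as in [expression_table()].
#' @param intensities numeric matrix, probes x 2 (condition 1, condition 2).
#' @param log2_scale logical, whether intensities are already log2.
#' @return An object of class \code{methylation_table}.
#' @export
methylation_table <- function(probe_id, gene_id, intensities,
                              log2_scale = FALSE) {
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  intensities <- as.matrix(intensities)
  stopifnot(length(probe_id) == length(gene_id),
            nrow(intensities) == length(probe_id),
            ncol(intensities) == 2L)
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id: ", probe_id[duplicated(probe_id)][1])
  structure(list(probe_id = probe_id, gene_id = gene_id,
                 intensities = intensities, log2_scale = isTRUE(log2_scale)),
            class = "methylation_table")
}

#' Filter expression probes on present calls
#'
#' Keeps probes with at least \code{min_present} "P" calls. By default the
#' rule is applied within each condition's replicate set and both conditions
#' must pass, so that both condition means remain estimable; set
#' \code{per_condition = FALSE} to pool all 2K replicates.
#'
#' @param expr an \code{expression_table}.
#' @param min_present integer >= 0; number of "P" calls required.
#' @param per_condition apply the rule within each condition (default) or
#'   pooled over all replicates.
#' @return The filtered \code{expression_table}; probe order preserved.
#' @export
filter_present <- function(expr, min_present = 2L, per_condition = TRUE) {
  stopifnot(inherits(expr, "expression_table"), min_present >= 0)
  K <- expr$K
  is_p <- expr$calls == "P"
  if (per_condition) {
    n1 <- rowSums(is_p[, seq_len(K), drop = FALSE])
    n2 <- rowSums(is_p[, K + seq_len(K), drop = FALSE])
    keep <- n1 >= min_present & n2 >= min_present
  } else {
    keep <- rowSums(is_p) >= min_present
  }
  expression_table(expr$probe_id[keep], expr$gene_id[keep],
                   expr$intensities[keep, , drop = FALSE],
                   expr$calls[keep, , drop = FALSE],
                   K = K, log2_scale = expr$log2_scale)
}

#' Log2-transform probe intensities
#'
#' @param table an \code{expression_table} or \code{methylation_table} with
#'   raw-scale intensities.
#' @param floor optional positive value; intensities below it are raised to
#'   the floor before the log. With no floor (default), any nonpositive
#'   intensity is an error.
#' @return The same class of table with log2 intensities.
#' @export
log2_transform <- function(table, floor = NULL) {
  stopifnot(inherits(table, c("expression_table", "methylation_table")))
  if (table$log2_scale) stop("table is already log2 transformed")
  x <- table$intensities
  if (!is.null(floor)) {
    stopifnot(floor > 0)
    x[x < floor] <- floor
  } else if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)
    stop("nonpositive intensities and no floor configured; first offending ",
         "cell: probe ", table$probe_id[bad[1, 1]], ", column ", bad[1, 2])
  }
  table$intensities <- log2(x)
  table$log2_scale <- TRUE
  table
}

#' Assemble per-gene model blocks
#'
#' Builds, for every gene present on both platforms, the stacked data vector
#' D_i = (G_i, M_i) and its 0/1 design matrix linking observations to the
#' gene's condition means and probe effects. Expression rows are ordered
#' probe-outer, condition-middle, replicate-inner; methylation rows
#' probe-outer, condition-inner. Columns are ordered (mu_1, mu_2, eta_1,
#' eta_2, b_1..b_J, a_1..a_H) so that each row carries exactly two ones:
#' one condition mean and one probe effect.
#'
#' @param expr log2-scale \code{expression_table} (already filtered).
#' @param meth log2-scale \code{methylation_table}.
#' @return A list with \code{blocks} (named list of \code{gene_block}) and
#'   \code{skipped} (data.frame gene_id / reason for genes on only one
#'   platform).
#' @export
build_gene_blocks <- function(expr, meth) {
  stopifnot(inherits(expr, "expression_table"),
            inherits(meth, "methylation_table"))
  if (!expr$log2_scale || !meth$log2_scale)
    stop("both tables must be log2 transformed before block assembly")
  eg <- unique(expr$gene_id)
  mg <- unique(meth$gene_id)
  common <- intersect(eg, mg)
  skipped <- data.frame(
    gene_id = c(setdiff(eg, mg), setdiff(mg, eg)),
    reason = c(rep("no methylation probes", length(setdiff(eg, mg))),
               rep("no expression probes", length(setdiff(mg, eg)))),
    stringsAsFactors = FALSE)
  K <- expr$K
  e_idx <- split(seq_along(expr$gene_id), expr$gene_id)
  m_idx <- split(seq_along(meth$gene_id), meth$gene_id)
  blocks <- lapply(common, function(g) {
    ei <- e_idx[[g]]; mi <- m_idx[[g]]
    J <- length(ei); H <- length(mi)
    # probe-outer, condition-middle, replicate-inner: a probe's row of the
    # intensity matrix (cond1 reps, cond2 reps) is already in that order
    G <- as.vector(t(expr$intensities[ei, , drop = FALSE]))
    M <- as.vector(t(meth$intensities[mi, , drop = FALSE]))
    gene_block(g, G, M, J = J, H = H, K = K)
  })
  names(blocks) <- common
  list(blocks = blocks, skipped = skipped)
}

#' Gene block constructor
#'
#' @param gene_id gene identifier.
#' @param G numeric vector of log2 expression, length 2K*J, ordered probe
#'   (outer), condition (middle), replicate (inner).
#' @param M numeric vector of log2 methylation, length 2H, ordered probe
#'   (outer), condition (inner).
#' @param J,H,K probe counts on each platform and expression replicates.
#' @return \code{gene_block} with the design matrix \code{Delta}, row index
#'   bookkeeping, and cached cross-products used by the fitting code.
#' @export
gene_block <- function(gene_id, G, M, J, H, K) {
  J <- as.integer(J); H <- as.integer(H); K <- as.integer(K)
  stopifnot(J >= 1, H >= 1, K >= 1,
            length(G) == 2L * K * J, length(M) == 2L * H)
  if (anyNA(G) || anyNA(M))
    stop("missing values are not supported (gene ", gene_id, ")")
  N <- 2L * K * J
  p <- 4L + J + H
  Delta <- matrix(0, N + 2L * H, p)
  row <- 0L
  for (j in seq_len(J)) for (l in 1:2) for (k in seq_len(K)) {
    row <- row + 1L
    Delta[row, l] <- 1
    Delta[row, 4L + j] <- 1
  }
  for (h in seq_len(H)) for (l in 1:2) {
    row <- row + 1L
    Delta[row, 2L + l] <- 1
    Delta[row, 4L + J + h] <- 1
  }
  expr_rows <- seq_len(N)
  meth_rows <- N + seq_len(2L * H)
  Dg <- Delta[expr_rows, , drop = FALSE]
  Dm <- Delta[meth_rows, , drop = FALSE]
  structure(list(
    gene_id = as.character(gene_id), G = as.numeric(G), M = as.numeric(M),
    J = J, H = H, K = K, N = N, M_len = 2L * H,
    Delta = Delta, expr_rows = expr_rows, meth_rows = meth_rows,
    # cached pieces: Sigma_e is diagonal so all EM quantities reduce to these
    XtX_g = crossprod(Dg), XtX_m = crossprod(Dm),
    Xty_g = drop(crossprod(Dg, G)), Xty_m = drop(crossprod(Dm, M)),
    yty_g = sum(G^2), yty_m = sum(M^2)),
    class = "gene_block")
}

#' Read an expression TSV plus its calls TSV
#'
#' Expected header: \code{probe_id gene_id cond1_rep1..cond1_repK
#' cond2_rep1..cond2_repK}; the calls file has the same layout with single
#' P/M/A characters.
#'
#' @param intensity_file,calls_file paths to tab-delimited files.
#' @param K replicates per condition.
#' @param log2_scale whether the stored intensities are already log2.
#' @return An \code{expression_table}.
#' @export
read_expression <- function(intensity_file, calls_file, K = 4L,
                            log2_scale = FALSE) {
  d <- utils::read.delim(intensity_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  cl <- utils::read.delim(calls_file, check.names = FALSE,
                          colClasses = "character")
  stopifnot(ncol(d) == 2L + 2L * K)
  if (nrow(cl) != nrow(d) || ncol(cl) != ncol(d))
    stop("calls file ", calls_file, " does not match intensity file shape")
  if (!identical(as.character(cl[[1]]), as.character(d[[1]])))
    stop("calls file probe order differs from intensity file")
  expression_table(d[[1]], d[[2]], as.matrix(d[, -(1:2)]),
                   as.matrix(cl[, -(1:2)]), K = K, log2_scale = log2_scale)
}

#' Read a methylation TSV
#'
#' Expected header: \code{probe_id gene_id cond1 cond2}.
#'
#' @inheritParams read_expression
#' @return A \code{methylation_table}.
#' @export
read_methylation <- function(intensity_file, log2_scale = FALSE) {
  d <- utils::read.delim(intensity_file, check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(ncol(d) == 4L)
  methylation_table(d[[1]], d[[2]], as.matrix(d[, 3:4]),
                    log2_scale = log2_scale)
}

#' Write expression / methylation tables as TSV
#'
#' Values are serialized with full precision (15 significant digits) so a
#' write/read round trip reproduces doubles exactly.
#'
#' @param table table object to write.
#' @param intensity_file output path.
#' @param calls_file output path for the calls matrix (expression only).
#' @param cond_labels length-2 condition labels used in the header.
#' @return Invisibly, the intensity file path.
#' @export
write_table_tsv <- function(table, intensity_file, calls_file = NULL,
                            cond_labels = c("cond1", "cond2")) {
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (inherits(table, "expression_table")) {
    K <- table$K
    hdr <- c("probe_id", "gene_id",
             paste0(cond_labels[1], "_rep", seq_len(K)),
             paste0(cond_labels[2], "_rep", seq_len(K)))
    d <- data.frame(table$probe_id, table$gene_id,
                    apply(table$intensities, 2, fmt),
                    stringsAsFactors = FALSE)
    names(d) <- hdr
    utils::write.table(d, intensity_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(calls_file)) {
      dc <- data.frame(table$probe_id, table$gene_id, table$calls,
                       stringsAsFactors = FALSE)
      names(dc) <- hdr
      utils::write.table(dc, calls_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  } else {
    d <- data.frame(probe_id = table$probe_id, gene_id = table$gene_id,
                    apply(table$intensities, 2, fmt),
                    stringsAsFactors = FALSE)
    names(d)[3:4] <- cond_labels
    utils::write.table(d, intensity_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(intensity_file)
}
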