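#' Read a gene-level log2 expression matrix from TSV
#'
#' Adapter for externally normalized (e.g. RMA-summarized) gene-level
#' matrices: tab-separated, first column the gene identifier, header row
#' the sample ids. Duplicated gene symbols are refused.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("expected gene column plus >= 1 sample", call. = FALSE)
  genes <- as.character(x[[1]])
  if (anyDuplicated(genes))
    stop("duplicated gene symbols in expression matrix", call. = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression values must be finite", call. = FALSE)
  rownames(m) <- genes
  m
}

#' Write an expression matrix to TSV
#' @param mat Genes x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (gene, cytoband) from TSV
#' @param path TSV with columns `gene` and `cytoband`.
#' @return Data frame.
#' @export
read_gene_annotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "cytoband") %in% names(x)))
    stop("annotation must have 'gene' and 'cytoband' columns", call. = FALSE)
  x
}

.check_controls <- function(mat, controls) {
  if (length(controls) == 0) stop("at least one control sample is required",
                                  call. = FALSE)
  missing <- setdiff(controls, colnames(mat))
  if (length(missing))
    stop("control sample(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(setdiff(colnames(mat), controls)) == 0)
    stop("at least one knockdown sample is required", call. = FALSE)
  invisible(TRUE)
}

#' Per-knockdown log2 fold changes against the control mean
#'
#' For each gene and each knockdown sample,
#' `log2FC(g, s) = value(g, s) - mean(value(g, controls))` — on a log2
#' matrix a simple difference against the arithmetic control mean.
#' Control columns are dropped from the output.
#'
#' @param mat Log2 expression matrix, genes x samples.
#' @param controls Control sample ids (columns of `mat`).
#' @return Matrix of log2 fold changes, genes x knockdown samples.
#' @export
compute_logfc <- function(mat, controls) {
  .check_controls(mat, controls)
  baseline <- rowMeans(mat[, controls, drop = FALSE])
  kd <- setdiff(colnames(mat), controls)
  mat[, kd, drop = FALSE] - baseline
}

#' Genes consistently regulated across all knockdowns
#'
#' The consensus is an intersection, not an average: a gene is universally
#' downregulated when its log2 fold change is at or below
#' `-primary_threshold` in every knockdown sample (universally
#' upregulated symmetrically). Two auxiliary flags support reporting:
#' `down_report_tier` marks universally downregulated genes whose mean
#' log2FC is below `-report_tier`, and `near_threshold` marks genes with a
#' consistent sign in all knockdowns and `|mean| >= near_threshold` that
#' nevertheless miss the primary cutoff — a reporting convenience for
#' biologically interesting borderline genes, not a discovery criterion.
#'
#' @param logfc Log2 fold-change matrix from [compute_logfc()].
#' @param primary_threshold Per-sample |log2FC| cutoff, default 1.0
#'   (a halving/doubling of expression).
#' @param report_tier Mean cutoff for the strong-downregulation tier,
#'   default 1.5.
#' @param near_threshold Mean |log2FC| for the consistent-sign borderline
#'   flag, default 0.85.
#' @return Data frame, one row per gene: `gene`, `mean_log2fc`,
#'   `direction_consistent`, `universal_down`, `universal_up`,
#'   `down_report_tier`, `near_threshold`.
#' @export
universal_change_genes <- function(logfc, primary_threshold = 1.0,
                                   report_tier = 1.5, near_threshold = 0.85) {
  stopifnot(primary_threshold > 0, ncol(logfc) >= 1)
  mean_lfc <- rowMeans(logfc)
  all_dn <- rowSums(logfc <= -primary_threshold) == ncol(logfc)
  all_up <- rowSums(logfc >= primary_threshold) == ncol(logfc)
  consistent <- rowSums(logfc < 0) == ncol(logfc) |
    rowSums(logfc > 0) == ncol(logfc)
  data.frame(
    gene = rownames(logfc),
    mean_log2fc = mean_lfc,
    direction_consistent = consistent,
    universal_down = all_dn,
    universal_up = all_up,
    down_report_tier = all_dn & mean_lfc < -report_tier,
    near_threshold = consistent & abs(mean_lfc) >= near_threshold &
      !all_dn & !all_up,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-gene pooled-variance t-statistics, knockdowns vs controls
#'
#' Standard two-sample t with pooled variance and
#' `df = n_kd + n_controls - 2`; pooling accommodates a very small
#' control group. `t = (mean_kd - mean_control)/se`; two-sided p. Genes
#' with zero variance in both groups and equal means get `t = 0, p = 1`.
#'
#' @param mat Log2 expression matrix.
#' @param controls Control sample ids.
#' @return Data frame `gene`, `t`, `df`, `p_value`.
#' @export
pooled_t_statistics <- function(mat, controls) {
  .check_controls(mat, controls)
  kd <- setdiff(colnames(mat), controls)
  x1 <- mat[, kd, drop = FALSE]
  x2 <- mat[, controls, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 + n2 < 3) stop("need at least 3 samples in total", call. = FALSE)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tt[se == 0 & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- 0
  p[tt == 0 & se == 0] <- 1
  data.frame(gene = rownames(mat), t = tt, df = df, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Knockdown expression consensus analysis
#'
#' One call for the expression arm: per-knockdown log2 fold changes
#' against the control mean, the all-samples consensus flags, and
#' per-gene pooled-variance t-statistics. Returns a classed object with
#' print/summary/plot methods.
#'
#' @inheritParams compute_logfc
#' @inheritParams universal_change_genes
#' @param annotation Optional data frame (`gene`, `cytoband`) merged into
#'   the consensus table.
#' @return Object of class `"kd_consensus"` with components `logfc`,
#'   `consensus` (see [universal_change_genes()]), `t_stats`, `controls`,
#'   and the thresholds used.
#' @examples
#' sim <- simulate_expression(expression_sim_config(
#'   n_genes = 300, planted_down = c(POSTN = -2.21), residual_sd = 0.1,
#'   seed = 11))
#' fit <- kd_consensus(sim$matrix, sim$controls, annotation = sim$annotation)
#' subset(fit$consensus, universal_down)
#' @export
kd_consensus <- function(mat, controls, primary_threshold = 1.0,
                         report_tier = 1.5, near_threshold = 0.85,
                         annotation = NULL) {
  lfc <- compute_logfc(mat, controls)
  consensus <- universal_change_genes(lfc, primary_threshold, report_tier,
                                      near_threshold)
  if (!is.null(annotation))
    consensus <- merge(consensus, annotation[, c("gene", "cytoband")],
                       by = "gene", all.x = TRUE, sort = FALSE)
  t_stats <- pooled_t_statistics(mat, controls)
  structure(list(logfc = lfc, consensus = consensus, t_stats = t_stats,
                 controls = controls,
                 thresholds = list(primary = primary_threshold,
                                   report_tier = report_tier,
                                   near = near_threshold),
                 call = match.call()),
            class = "kd_consensus")
}
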