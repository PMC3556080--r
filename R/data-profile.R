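#' Reference knockdown consensus profile (GIST imatinib-sensitizer study)
#'
#' The published consensus profile of genes consistently regulated across
#' 14 gene knockdowns in GIST-T1 cells: per-gene mean log2 fold change
#' versus non-targeting controls, with cytogenetic band annotation. Six
#' genes are universally downregulated with mean log2FC below -1.5, one
#' gene (TMCO1) universally upregulated beyond +1, and NEDD9 is
#' consistently but sub-threshold downregulated (mean -0.91). Shipped as
#' a small TSV fixture; useful as a worked example and as a desk check of
#' the consensus stage.
#'
#' @return Data frame `gene`, `description`, `cytoband`, `mean_log2fc`.
#' @export
gist_consensus_profile <- function() {
  path <- system.file("extdata", "gist_consensus_profile.tsv",
                      package = "sensiscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Render a mean-profile table as a noiseless expression matrix
#'
#' Expands a per-gene mean log2 fold-change profile into an expression
#' matrix in which every knockdown sample carries exactly the stated
#' shift and control samples sit at baseline — the matrix a consensus
#' analysis would need to see to reproduce the profile exactly. Optional
#' unshifted background genes can be appended.
#'
#' @param profile Data frame with columns `gene` and `mean_log2fc`.
#' @param n_knockdowns Knockdown samples, default 14.
#' @param n_controls Control samples, default 2.
#' @param n_background Extra unshifted genes appended, default 0.
#' @param baseline Baseline log2 expression, default 8.
#' @return List with `matrix` and `controls` ready for [kd_consensus()].
#' @export
profile_expression_matrix <- function(profile, n_knockdowns = 14,
                                      n_controls = 2, n_background = 0,
                                      baseline = 8) {
  stopifnot(all(c("gene", "mean_log2fc") %in% names(profile)))
  genes <- profile$gene
  shift <- profile$mean_log2fc
  if (n_background > 0) {
    genes <- c(genes, sprintf("BG%04d", seq_len(n_background)))
    shift <- c(shift, rep(0, n_background))
  }
  kd <- sprintf("KD%02d", seq_len(n_knockdowns))
  con <- sprintf("CON%d", seq_len(n_controls))
  mat <- cbind(matrix(baseline + shift, length(genes), n_knockdowns),
               matrix(baseline, length(genes), n_controls))
  dimnames(mat) <- list(genes, c(kd, con))
  list(matrix = mat, controls = con)
}
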