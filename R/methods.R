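#' @export
print.si_screen <- function(x, ...) {
  r <- x$records
  cat("Sensitization screen fit (", x$by, "-level, ",
      if (x$moderate) "moderated" else "plain OLS", " drug-effect test)\n",
      sep = "")
  for (d in unique(r$drug)) {
    rd <- r[r$drug == d, ]
    cat(sprintf("  %s: %d units scored, %d primary hit(s) at SI < %.2f, FDR < %.2f\n",
                d, nrow(rd), sum(rd$primary_hit),
                x$thresholds$si_threshold, x$thresholds$fdr_threshold))
  }
  invisible(x)
}

#' @export
summary.si_screen <- function(object, ...) {
  r <- object$records
  hits <- r[r$primary_hit, , drop = FALSE]
  out <- list(n_units = nrow(r), drugs = unique(r$drug),
              hits = hits[order(hits$si), ],
              si_range = range(r$si), thresholds = object$thresholds)
  class(out) <- "summary.si_screen"
  out
}

#' @export
print.summary.si_screen <- function(x, ...) {
  cat(sprintf("Units scored: %d over drug(s) %s; SI range [%.3f, %.3f]\n",
              x$n_units, paste(x$drugs, collapse = ", "),
              x$si_range[1], x$si_range[2]))
  cat("Primary hits (dual SI/FDR criterion), strongest first:\n")
  print(x$hits[, c("gene", "sirna_id", "drug", "si", "p_value", "fdr")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Log2 sensitization indices of a screen fit
#' @param object A `"si_screen"`.
#' @param ... Unused.
#' @return Named vector (single drug) or gene x drug matrix of log2 SI.
#' @export
coef.si_screen <- function(object, ...) {
  r <- object$records
  drugs <- unique(r$drug)
  if (length(drugs) == 1L) {
    nm <- if (object$by == "sirna") paste(r$gene, r$sirna_id, sep = ":") else r$gene
    return(stats::setNames(r$log2_si, nm))
  }
  genes <- unique(r$gene)
  m <- matrix(NA_real_, length(genes), length(drugs),
              dimnames = list(genes, drugs))
  m[cbind(r$gene, r$drug)] <- r$log2_si
  m
}

#' @export
as.data.frame.si_screen <- function(x, ...) x$records

#' Plot a screen fit: per-unit log2 SI with the hit threshold
#'
#' SI values are plotted on the log scale; primary hits are filled. The
#' dashed line marks `log2(si_threshold)`.
#' @param x A `"si_screen"`.
#' @param drug Drug to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.si_screen <- function(x, drug = NULL, ...) {
  r <- x$records
  if (is.null(drug)) drug <- r$drug[1]
  r <- r[r$drug == drug, , drop = FALSE]
  r <- r[order(r$log2_si), ]
  graphics::plot(seq_len(nrow(r)), r$log2_si,
                 pch = ifelse(r$primary_hit, 19, 1),
                 col = ifelse(r$primary_hit, "steelblue4", "grey40"),
                 xlab = "units (ranked)", ylab = "log2 SI",
                 main = paste("Sensitization indices,", drug), ...)
  graphics::abline(h = log2(x$thresholds$si_threshold), lty = 2)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("Drug specificity matrix (", nrow(x$si), " genes x ", ncol(x$si),
      " drugs, flag: ", x$hit_flag, ")\n", sep = "")
  cat("Sensitizer counts per drug:\n")
  for (d in names(x$counts))
    cat(sprintf("  %-12s %d / %d\n", d, x$counts[[d]],
                sum(!is.na(x$hit[, d]))))
  invisible(x)
}

#' Heatmap of a specificity matrix (log2 SI scale)
#' @param x A `"specificity_matrix"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.specificity_matrix <- function(x, ...) {
  m <- log2(x$si)
  pal <- grDevices::hcl.colors(33, "Blue-Yellow")
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, col = pal,
                  xlab = "", ylab = "", axes = FALSE,
                  main = "log2 SI by gene and drug", ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.6)
  graphics::axis(2, seq_len(ncol(m)), colnames(m), las = 1, cex.axis = 0.8)
  graphics::box()
  invisible(x)
}

#' @export
print.kd_consensus <- function(x, ...) {
  cs <- x$consensus
  cat("Knockdown expression consensus (", ncol(x$logfc), " knockdowns, ",
      length(x$controls), " controls, ", nrow(cs), " genes)\n", sep = "")
  cat(sprintf("  universally down (all samples <= -%.1f): %d\n",
              x$thresholds$primary, sum(cs$universal_down)))
  cat(sprintf("    of which mean < -%.1f: %d\n", x$thresholds$report_tier,
              sum(cs$down_report_tier)))
  cat(sprintf("  universally up (all samples >= +%.1f): %d\n",
              x$thresholds$primary, sum(cs$universal_up)))
  cat(sprintf("  near-threshold consistent: %d\n", sum(cs$near_threshold)))
  invisible(x)
}

#' @export
summary.kd_consensus <- function(object, ...) {
  cs <- object$consensus
  flagged <- cs[cs$universal_down | cs$universal_up | cs$near_threshold, ,
                drop = FALSE]
  flagged <- flagged[order(flagged$mean_log2fc), ]
  rownames(flagged) <- NULL
  structure(list(flagged = flagged, thresholds = object$thresholds),
            class = "summary.kd_consensus")
}

#' @export
print.summary.kd_consensus <- function(x, ...) {
  cat("Consensus-flagged genes (sorted by mean log2FC):\n")
  print(x$flagged, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Dotplot of per-sample log2 fold changes for flagged genes
#' @param x A `"kd_consensus"`.
#' @param genes Genes to show (default: all consensus-flagged genes).
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.kd_consensus <- function(x, genes = NULL, ...) {
  cs <- x$consensus
  if (is.null(genes))
    genes <- cs$gene[cs$universal_down | cs$universal_up | cs$near_threshold]
  if (!length(genes)) {
    warning("no flagged genes to plot", call. = FALSE)
    return(invisible(x))
  }
  lf <- x$logfc[genes, , drop = FALSE]
  vals <- lapply(seq_len(nrow(lf)), function(i) lf[i, ])
  names(vals) <- genes
  graphics::stripchart(vals, vertical = TRUE, pch = 19, cex = 0.6,
                       col = "firebrick3", las = 2,
                       ylab = "log2 fold change vs control mean", ...)
  graphics::abline(h = c(-1, 0, 1), lty = c(2, 1, 2),
                   col = c("grey40", "grey70", "grey40"))
  invisible(x)
}

#' Row-centered, clustered expression heatmap for a gene set
#'
#' Renders relative expression for the genes of one set: each row (gene)
#' is centered on its own mean so only relative differences show, and
#' samples are clustered hierarchically (average linkage on Euclidean
#' distance).
#'
#' @param mat Log2 expression matrix.
#' @param genes Genes to display (rows of `mat`).
#' @param cluster_genes Also cluster rows (default `FALSE`).
#' @param ... Passed to [stats::heatmap()].
#' @export
plot_geneset_heatmap <- function(mat, genes, cluster_genes = FALSE, ...) {
  genes <- intersect(genes, rownames(mat))
  if (length(genes) < 2) stop("need >= 2 measured genes", call. = FALSE)
  m <- mat[genes, , drop = FALSE]
  m <- m - rowMeans(m)
  hc <- function(d) stats::hclust(d, method = "average")
  stats::heatmap(m, hclustfun = hc,
                 Rowv = if (cluster_genes) NULL else NA,
                 scale = "none", col = grDevices::hcl.colors(33, "Blue-Red 2"),
                 ...)
  invisible(m)
}
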