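#' Hit-calling thresholds
#'
#' The dual hit criterion: a gene is a primary hit when its sensitization
#' index falls below `si_threshold` (biological significance — a decrease
#' in SI greater than 15\% at the default) AND its BH-adjusted drug-effect
#' p-value falls below `fdr_threshold` (statistical significance). Both
#' inequalities are strict. Deconvolution validation requires at least
#' `min_confirming_sirnas` of the gene's individual duplexes to meet the
#' same dual criterion.
#'
#' @param si_threshold SI cutoff, default 0.85.
#' @param fdr_threshold FDR cutoff, default 0.15.
#' @param min_confirming_sirnas Duplexes required to validate, default 2.
#' @param sirnas_per_gene Expected duplexes per gene, default 4.
#' @return An object of class `"hit_thresholds"`.
#' @export
hit_thresholds <- function(si_threshold = 0.85, fdr_threshold = 0.15,
                           min_confirming_sirnas = 2, sirnas_per_gene = 4) {
  stopifnot(si_threshold > 0, si_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1,
            min_confirming_sirnas >= 1, sirnas_per_gene >= 1)
  structure(list(si_threshold = si_threshold, fdr_threshold = fdr_threshold,
                 min_confirming_sirnas = min_confirming_sirnas,
                 sirnas_per_gene = sirnas_per_gene),
            class = "hit_thresholds")
}

#' Normalize well viabilities to the per-plate GL2 control median
#'
#' Divides every well's raw value by the median raw value of the
#' non-targeting GL2 control wells on the same plate. The shared plate
#' factor (transfection batch, reagent lot, reader drift) multiplies GL2
#' wells and target wells alike, so it cancels exactly. GL2 wells are
#' retained, flagged by `is_control`, for QC.
#'
#' @param measurements Validated measurement data frame.
#' @param gl2_label Control label, default `"GL2"`.
#' @return The input with columns `norm_value` and `is_control` added.
#' @export
normalize_to_gl2 <- function(measurements, gl2_label = "GL2") {
  x <- measurements
  gl2 <- x[x$gene == gl2_label, , drop = FALSE]
  if (!nrow(gl2)) stop("no '", gl2_label, "' control wells found", call. = FALSE)
  med <- c(tapply(gl2$raw_value, gl2$plate_id, stats::median))  # drop 1-d dim
  missing_plates <- setdiff(unique(x$plate_id), names(med))
  if (length(missing_plates))
    stop("plate(s) without ", gl2_label, " wells: ",
         paste(missing_plates, collapse = ", "), call. = FALSE)
  if (any(!is.finite(med) | med <= 0))
    stop("non-positive ", gl2_label, " median on plate(s): ",
         paste(names(med)[!is.finite(med) | med <= 0], collapse = ", "),
         call. = FALSE)
  x$norm_value <- x$raw_value / med[x$plate_id]
  x$is_control <- x$gene == gl2_label
  x
}

# arm summary of replicate normalized viabilities
.arm_summary <- function(v, type) {
  if (type == "geometric") exp(mean(log(v))) else mean(v)
}

# per-unit per-drug arm statistics used by both compute_si and the drug
# effect test; unit is gene or gene:sirna depending on `by`
.arm_table <- function(normalized, by = c("gene", "sirna")) {
  by <- match.arg(by)
  x <- normalized[!normalized$is_control, , drop = FALSE]
  pairs <- .pair_plates(x)
  if (!nrow(pairs)) stop("no paired vehicle/drug plates found", call. = FALSE)
  unit_of <- function(d) {
    if (by == "sirna") paste(d$gene, d$sirna_id, sep = "\r") else d$gene
  }
  res <- list()
  for (d in unique(pairs$drug)) {
    pp <- pairs[pairs$drug == d, , drop = FALSE]
    drug_rows <- x[x$plate_id %in% pp$drug_plate, , drop = FALSE]
    veh_rows <- x[x$plate_id %in% pp$vehicle_plate, , drop = FALSE]
    du <- split(drug_rows$norm_value, unit_of(drug_rows))
    vu <- split(veh_rows$norm_value, unit_of(veh_rows))
    units <- names(du)
    skipped <- setdiff(units, names(vu))
    if (length(skipped)) {
      warning("unit(s) without vehicle arm skipped for ", d, ": ",
              length(skipped), call. = FALSE)
      units <- setdiff(units, skipped)
    }
    parts <- strsplit(units, "\r", fixed = TRUE)
    res[[d]] <- data.frame(
      gene = vapply(parts, `[`, "", 1L),
      sirna_id = if (by == "sirna") vapply(parts, `[`, "", 2L) else "pooled",
      drug = d,
      drug_values = I(unname(du[units])),
      vehicle_values = I(unname(vu[units])),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compute sensitization indices
#'
#' For every gene (or individual duplex) and drug, the sensitization index
#' is the ratio of the summarized control-normalized viability in the drug
#' arm to that in the paired vehicle arm:
#' \deqn{SI = (V_{drug}/GL2_{drug}) / (V_{vehicle}/GL2_{vehicle})}
#' SI < 1 means silencing the gene sensitizes the cells to the drug.
#' Replicate wells within an arm are summarized by the arithmetic mean of
#' normalized viabilities (geometric by `summary = "geometric"`).
#'
#' @param normalized Output of [normalize_to_gl2()].
#' @param by `"gene"` (pooled screens) or `"sirna"` (deconvolution).
#' @param summary Replicate summary, `"mean"` or `"geometric"`.
#' @return Data frame with `gene`, `sirna_id`, `drug`, `si`, `log2_si`,
#'   `n_drug`, `n_vehicle`.
#' @export
compute_si <- function(normalized, by = c("gene", "sirna"),
                       summary = c("mean", "geometric")) {
  by <- match.arg(by)
  summary <- match.arg(summary)
  arms <- .arm_table(normalized, by)
  si <- mapply(function(dv, vv) .arm_summary(dv, summary) / .arm_summary(vv, summary),
               arms$drug_values, arms$vehicle_values)
  data.frame(gene = arms$gene, sirna_id = arms$sirna_id, drug = arms$drug,
             si = si, log2_si = log2(si),
             n_drug = lengths(arms$drug_values),
             n_vehicle = lengths(arms$vehicle_values),
             stringsAsFactors = FALSE)
}

#' Z'-factor assay quality statistic
#'
#' Screening-window statistic
#' \eqn{Z' = 1 - 3(\sigma_{pos}+\sigma_{neg}) / |\mu_{pos}-\mu_{neg}|};
#' an assay with Z' of at least 0.5 is conventionally accepted for
#' high-throughput screening. With equal group means the window is empty
#' and `-Inf` is returned, so the gate fails.
#'
#' @param pos_control_values,neg_control_values At least two readings each.
#' @return The Z' statistic (numeric scalar).
#' @export
zprime_factor <- function(pos_control_values, neg_control_values) {
  stopifnot(length(pos_control_values) >= 2, length(neg_control_values) >= 2)
  mu_p <- mean(pos_control_values)
  mu_n <- mean(neg_control_values)
  if (mu_p == mu_n) return(-Inf)
  1 - 3 * (stats::sd(pos_control_values) + stats::sd(neg_control_values)) /
    abs(mu_p - mu_n)
}

# per-unit two-arm linear-model statistics on log2 normalized viability:
# the arm-indicator coefficient equals the log2 drug/vehicle contrast and
# its OLS t equals the two-sample pooled-variance t
.effect_stats <- function(arms) {
  n1 <- lengths(arms$drug_values)
  n2 <- lengths(arms$vehicle_values)
  coef <- s2 <- numeric(nrow(arms))
  for (i in seq_len(nrow(arms))) {
    ld <- log2(arms$drug_values[[i]])
    lv <- log2(arms$vehicle_values[[i]])
    coef[i] <- mean(ld) - mean(lv)
    s2[i] <- if (n1[i] >= 2 || n2[i] >= 2) {
      (sum((ld - mean(ld))^2) + sum((lv - mean(lv))^2)) / max(n1[i] + n2[i] - 2, 1)
    } else NA_real_
  }
  data.frame(gene = arms$gene, sirna_id = arms$sirna_id, drug = arms$drug,
             coef = coef, s2 = s2, df = n1 + n2 - 2,
             su = sqrt(1 / n1 + 1 / n2),
             insufficient = n1 < 2 | n2 < 2,
             stringsAsFactors = FALSE)
}

# turn effect stats into two-sided p-values; optional empirical-Bayes
# moderation pools residual variances across units (limma::squeezeVar)
.effect_pvalues <- function(st, moderate = TRUE) {
  p <- rep(1, nrow(st))
  ok <- !st$insufficient
  if (any(st$insufficient))
    warning(sum(st$insufficient),
            " unit(s) with < 2 replicates per arm: p set to 1", call. = FALSE)
  if (!any(ok)) return(p)
  s2 <- st$s2[ok]
  df <- st$df[ok]
  if (moderate && length(s2) >= 2 && any(s2 > 1e-12)) {
    sq <- limma::squeezeVar(s2, df)
    s2_post <- sq$var.post
    df_tot <- df + sq$df.prior
  } else {
    s2_post <- s2
    df_tot <- df
  }
  se <- st$su[ok] * sqrt(s2_post)
  tt <- st$coef[ok] / se
  # zero residual variance: a coefficient at floating-point round-off is
  # "identical arms" (p = 1), a real one is an exact effect (p -> 0)
  tt[se == 0 & abs(st$coef[ok]) < 1e-8] <- 0
  df_tot <- pmin(df_tot, 1e6)                    # finite df for pt()
  p[ok] <- 2 * stats::pt(-abs(tt), df_tot)
  p[ok][is.nan(p[ok])] <- 1
  p
}

#' Per-gene drug-effect p-value from a two-arm linear model
#'
#' Fits, for one gene, a linear model on the log2 control-normalized
#' viabilities with a single drug-vs-vehicle arm indicator and returns the
#' two-sided p-value of the arm coefficient. Without moderation this is
#' exactly the pooled-variance two-sample t-test on log2 values.
#'
#' @param normalized Output of [normalize_to_gl2()].
#' @param gene Gene symbol.
#' @param drug Drug label; defaults to the only drug present.
#' @return Two-sided p-value.
#' @export
fit_drug_effect <- function(normalized, gene, drug = NULL) {
  arms <- .arm_table(normalized, by = "gene")
  if (is.null(drug)) {
    drug <- unique(arms$drug)
    if (length(drug) != 1)
      stop("several drugs present; specify 'drug'", call. = FALSE)
  }
  arms <- arms[arms$gene == gene & arms$drug == drug, , drop = FALSE]
  if (!nrow(arms)) stop("gene/drug combination not found", call. = FALSE)
  st <- .effect_stats(arms)
  .effect_pvalues(st, moderate = FALSE)[1]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]); input p-values must
#' lie in `[0, 1]`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Flag primary hits by the dual criterion
#'
#' @param records Data frame with columns `si` and `fdr`.
#' @param thresholds A [hit_thresholds()].
#' @return `records` with a logical `primary_hit` column:
#'   `si < si_threshold & fdr < fdr_threshold` (both strict).
#' @export
call_primary_hits <- function(records, thresholds = hit_thresholds()) {
  records$primary_hit <- records$si < thresholds$si_threshold &
    records$fdr < thresholds$fdr_threshold
  records
}

#' Score a sensitization screen
#'
#' The full scoring chain for one measurement table: design validation,
#' per-plate GL2 normalization, sensitization indices, per-gene two-arm
#' linear-model drug-effect tests (empirical-Bayes variance moderation
#' across genes by default), Benjamini-Hochberg adjustment within each
#' drug, and dual-criterion hit calling.
#'
#' @param measurements Long-format measurement data frame (see
#'   [read_plate_table()]).
#' @param design Optional [screen_design()].
#' @param thresholds A [hit_thresholds()].
#' @param by `"gene"` for pooled screens, `"sirna"` for deconvolution.
#' @param moderate Moderate residual variances across genes (default
#'   `TRUE`); `FALSE` gives plain per-gene OLS / pooled t.
#' @param summary Replicate summary inside the SI (`"mean"` or
#'   `"geometric"`).
#' @param gl2_label Control label.
#' @return An object of class `"si_screen"` with the per-unit
#'   `records` (`gene`, `sirna_id`, `drug`, `si`, `log2_si`, `p_value`,
#'   `fdr`, `primary_hit`), the normalized table, and the call settings.
#' @examples
#' cfg <- screen_sim_config(n_genes = 6, sensitizers = list(IM = "G01"),
#'                          noise_sd = 0, plate_effect_sd = 0, seed = 3)
#' fit <- score_screen(simulate_screen(cfg)$measurements)
#' subset(as.data.frame(fit), primary_hit)
#' @export
score_screen <- function(measurements, design = NULL,
                         thresholds = hit_thresholds(),
                         by = c("gene", "sirna"), moderate = TRUE,
                         summary = c("mean", "geometric"),
                         gl2_label = "GL2") {
  by <- match.arg(by)
  summary <- match.arg(summary)
  validate_design(measurements, design, gl2_label = gl2_label, strict = TRUE)
  normalized <- normalize_to_gl2(measurements, gl2_label = gl2_label)
  arms <- .arm_table(normalized, by)
  si <- mapply(function(dv, vv) .arm_summary(dv, summary) / .arm_summary(vv, summary),
               arms$drug_values, arms$vehicle_values)
  st <- .effect_stats(arms)
  records <- data.frame(gene = arms$gene, sirna_id = arms$sirna_id,
                        drug = arms$drug, si = si, log2_si = log2(si),
                        p_value = NA_real_, fdr = NA_real_,
                        stringsAsFactors = FALSE)
  # moderation and BH within each drug: one screen, one testing family
  for (d in unique(records$drug)) {
    idx <- records$drug == d
    records$p_value[idx] <- .effect_pvalues(st[idx, , drop = FALSE], moderate)
    records$fdr[idx] <- bh_adjust(records$p_value[idx])
  }
  records <- call_primary_hits(records, thresholds)
  structure(list(records = records, normalized = normalized,
                 thresholds = thresholds, by = by, moderate = moderate,
                 summary = summary, call = match.call()),
            class = "si_screen")
}

#' Validate pooled hits with deconvoluted duplex records
#'
#' Applies the at-least-`min_confirming_sirnas`-of-`sirnas_per_gene` rule:
#' a pooled hit is validated when at least that many of its individual
#' duplexes independently meet the dual SI/FDR criterion.
#'
#' @param deconv A `"si_screen"` scored with `by = "sirna"`, or its
#'   records data frame.
#' @param thresholds A [hit_thresholds()].
#' @return Gene-level data frame with `gene`, `drug`, `n_sirnas`,
#'   `n_confirming_sirnas`, `validated_hit`, and `mean_confirming_si`
#'   (mean SI over the confirming duplexes, `NA` when none confirm).
#' @export
validate_hits_deconvolution <- function(deconv, thresholds = hit_thresholds()) {
  records <- if (inherits(deconv, "si_screen")) deconv$records else deconv
  if (!all(c("gene", "sirna_id", "drug", "si", "fdr") %in% names(records)))
    stop("duplex-level records with si and fdr are required", call. = FALSE)
  records <- call_primary_hits(records, thresholds)
  key <- interaction(records$gene, records$drug, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(r) {
    conf <- r$primary_hit
    data.frame(gene = r$gene[1], drug = r$drug[1],
               n_sirnas = nrow(r),
               n_confirming_sirnas = sum(conf),
               validated_hit = sum(conf) >= thresholds$min_confirming_sirnas,
               mean_confirming_si = if (any(conf)) mean(r$si[conf]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  short <- out$n_sirnas < thresholds$sirnas_per_gene
  if (any(short))
    warning(sum(short), " gene(s) screened with fewer than ",
            thresholds$sirnas_per_gene,
            " duplexes; evaluated against the available count", call. = FALSE)
  rownames(out) <- NULL
  out[order(out$drug, out$gene), , drop = FALSE]
}

#' Select each gene's best-performing duplexes
#'
#' For specificity re-screens the strongest duplexes of each validated
#' gene are re-pooled. "Best" is defined as lowest sensitization index in
#' the reference screen (ties broken by duplex id for determinism); the
#' selection should be recorded in the run provenance.
#'
#' @param deconv A `"si_screen"` scored with `by = "sirna"`, or its
#'   records.
#' @param n Duplexes to keep per gene, default 2.
#' @param drug Reference drug (default: the only drug present).
#' @return Data frame `gene`, `sirna_id`, `si`, `rank`.
#' @export
best_sirnas <- function(deconv, n = 2, drug = NULL) {
  records <- if (inherits(deconv, "si_screen")) deconv$records else deconv
  if (is.null(drug)) {
    drug <- unique(records$drug)
    if (length(drug) != 1)
      stop("several drugs present; specify the reference 'drug'", call. = FALSE)
  }
  r <- records[records$drug == drug, c("gene", "sirna_id", "si")]
  r <- r[order(r$gene, r$si, r$sirna_id), ]
  out <- do.call(rbind, lapply(split(r, r$gene), function(g) {
    k <- min(n, nrow(g))
    cbind(g[seq_len(k), ], rank = seq_len(k))
  }))
  rownames(out) <- NULL
  out
}

#' Gene-by-drug specificity matrix
#'
#' Collects per-drug records into a gene x drug matrix of sensitization
#' indices with matching hit flags and per-drug sensitizer counts — the
#' multi-drug specificity report. SI is reported on the log2 scale in
#' plots.
#'
#' @param records A `"si_screen"`, its records, or a data frame binding
#'   records from several drugs (columns `gene`, `drug`, `si` and a hit
#'   flag `primary_hit` or `validated_hit`).
#' @return Object of class `"specificity_matrix"`: list with `si`
#'   (gene x drug), `hit` (logical gene x drug), `counts` (named per-drug
#'   hit counts).
#' @export
drug_specificity_matrix <- function(records) {
  if (inherits(records, "si_screen")) records <- records$records
  if (!"si" %in% names(records) && "mean_confirming_si" %in% names(records))
    records$si <- records$mean_confirming_si
  flag <- if ("validated_hit" %in% names(records)) "validated_hit" else "primary_hit"
  if (!all(c("gene", "drug", "si", flag) %in% names(records)))
    stop("records must carry gene, drug, si and a hit flag", call. = FALSE)
  genes <- unique(records$gene)
  drugs <- unique(records$drug)
  si <- matrix(NA_real_, length(genes), length(drugs),
               dimnames = list(genes, drugs))
  hit <- matrix(NA, length(genes), length(drugs), dimnames = list(genes, drugs))
  si[cbind(records$gene, records$drug)] <- records$si
  hit[cbind(records$gene, records$drug)] <- records[[flag]]
  structure(list(si = si, hit = hit,
                 counts = colSums(hit, na.rm = TRUE),
                 hit_flag = flag),
            class = "specificity_matrix")
}
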