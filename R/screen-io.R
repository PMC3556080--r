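#' Screen design description
#'
#' A light container recording what the plate files are expected to
#' contain: the gene library, the siRNA duplexes per gene, and the label
#' used for the non-targeting negative-control wells whose per-plate
#' median is the normalization denominator.
#'
#' @param genes Character vector of library gene symbols.
#' @param sirnas Optional named list mapping gene -> character vector of
#'   duplex ids (at most 4 per gene in the classic 4-duplex library);
#'   `"pooled"` is always accepted.
#' @param gl2_label Label of the negative-control wells (default `"GL2"`).
#' @param drug_arms Optional character vector of drug labels (metadata).
#' @return An object of class `"screen_design"`.
#' @export
screen_design <- function(genes, sirnas = NULL, gl2_label = "GL2",
                          drug_arms = NULL) {
  stopifnot(is.character(genes), length(genes) >= 1)
  if (!is.null(sirnas)) {
    stopifnot(is.list(sirnas), all(names(sirnas) %in% genes))
  }
  structure(list(genes = genes, sirnas = sirnas, gl2_label = gl2_label,
                 drug_arms = drug_arms), class = "screen_design")
}

# normalize well coordinates to zero-padded form (A1 -> A01) for stable sorting
.normalize_wells <- function(well) {
  m <- regmatches(well, regexec("^([A-Za-z]+)0*([0-9]+)$", well))
  vapply(seq_along(well), function(i) {
    p <- m[[i]]
    if (length(p) != 3L) return(well[i])
    sprintf("%s%02d", toupper(p[2]), as.integer(p[3]))
  }, character(1))
}

.PLATE_COLUMNS <- c("plate_id", "well", "gene", "sirna_id", "condition",
                    "drug", "raw_value")

#' Read and validate a long-format plate measurement table
#'
#' Reads a CSV with one row per well (columns `plate_id`, `well`, `gene`,
#' `sirna_id`, `condition`, `drug`, `raw_value`, optionally `pair_id` for
#' explicit vehicle/drug plate pairing). Well labels are normalized to
#' zero-padded form. Rows with non-positive or missing raw values are
#' rejected with a warning naming how many were dropped; a missing column
#' or a plate without any control well is fatal.
#'
#' @param path CSV file path.
#' @param design Optional [screen_design()]; when given, measured genes and
#'   duplex ids are checked against it.
#' @param gl2_label Negative-control label (overridden by the design's).
#' @return Validated measurement data frame.
#' @export
read_plate_table <- function(path, design = NULL, gl2_label = "GL2") {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = list(drug = "character",
                                         plate_id = "character"))
  validate_measurements(x, design = design, gl2_label = gl2_label)
}

#' Validate an in-memory plate measurement table
#'
#' The checking core of [read_plate_table()], usable on tables built in R.
#' @inheritParams read_plate_table
#' @param x Measurement data frame.
#' @return The validated (possibly row-filtered) data frame.
#' @export
validate_measurements <- function(x, design = NULL, gl2_label = "GL2") {
  if (!is.null(design)) gl2_label <- design$gl2_label
  missing_cols <- setdiff(.PLATE_COLUMNS, names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x$well <- .normalize_wells(as.character(x$well))
  x$drug <- ifelse(is.na(x$drug), "", as.character(x$drug))
  x$condition <- as.character(x$condition)
  bad_cond <- !x$condition %in% c("vehicle", "drug")
  if (any(bad_cond))
    stop("condition must be 'vehicle' or 'drug' (rows ",
         paste(utils::head(which(bad_cond), 5), collapse = ", "), ")",
         call. = FALSE)
  x$drug[x$condition == "vehicle"] <- ""

  bad <- !is.finite(x$raw_value) | x$raw_value <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected: non-positive or missing raw_value",
            call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  if (anyDuplicated(x[c("plate_id", "well")]))
    stop("duplicate (plate_id, well) coordinates", call. = FALSE)

  gl2_per_plate <- tapply(x$gene == gl2_label, x$plate_id, sum)
  if (any(gl2_per_plate == 0))
    stop("plate(s) without any '", gl2_label, "' control well: ",
         paste(names(gl2_per_plate)[gl2_per_plate == 0], collapse = ", "),
         call. = FALSE)

  if (!is.null(design)) {
    unknown <- setdiff(unique(x$gene), c(design$genes, gl2_label))
    if (length(unknown))
      warning("measured gene(s) not in design: ",
              paste(unknown, collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Write a plate measurement table to CSV
#' @param x Measurement data frame.
#' @param path Output path.
#' @export
write_plate_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check measurements against a design and report screen structure
#'
#' Summarizes the screen layout: control-well counts per plate, genes or
#' duplexes not covered by the design, and vehicle/drug arm pairing. Each
#' drug plate must have a paired vehicle plate (by explicit `pair_id`
#' column when present, else by plate order within each drug); without a
#' vehicle arm the sensitization index is undefined, so an unpaired drug
#' plate is a fatal problem.
#'
#' @param measurements Measurement data frame.
#' @param design Optional [screen_design()].
#' @param gl2_label Negative-control label.
#' @param strict Stop on fatal problems (default `TRUE`); otherwise they
#'   are returned in the report.
#' @return A list of class `"design_report"` with `gl2_wells_per_plate`,
#'   `unmatched_genes`, `pairs`, and `fatal`.
#' @export
validate_design <- function(measurements, design = NULL, gl2_label = "GL2",
                            strict = TRUE) {
  if (!is.null(design)) gl2_label <- design$gl2_label
  x <- measurements
  gl2_per_plate <- tapply(x$gene == gl2_label, x$plate_id, sum)
  unmatched <- if (is.null(design)) character(0) else
    setdiff(unique(x$gene), c(design$genes, gl2_label))

  pairs <- .pair_plates(x)
  fatal <- character(0)
  drug_plates <- unique(x$plate_id[x$condition == "drug"])
  unpaired <- setdiff(drug_plates, pairs$drug_plate)
  if (length(unpaired))
    fatal <- c(fatal, paste0("drug plate without paired vehicle plate: ",
                             paste(unpaired, collapse = ", ")))
  if (any(gl2_per_plate == 0))
    fatal <- c(fatal, paste0("plate without ", gl2_label, " wells: ",
                             paste(names(gl2_per_plate)[gl2_per_plate == 0],
                                   collapse = ", ")))
  report <- structure(list(gl2_wells_per_plate = gl2_per_plate,
                           unmatched_genes = unmatched,
                           pairs = pairs, fatal = fatal),
                      class = "design_report")
  if (strict && length(fatal)) stop(paste(fatal, collapse = "; "), call. = FALSE)
  report
}

# pair each drug plate with a vehicle plate: explicit pair_id wins, else
# vehicle plates are matched to drug plates in order of appearance per drug
.pair_plates <- function(x) {
  plates <- unique(x[, c("plate_id", "condition", "drug",
                         intersect("pair_id", names(x))), drop = FALSE])
  drug_pl <- plates[plates$condition == "drug", , drop = FALSE]
  veh_pl <- plates[plates$condition == "vehicle", , drop = FALSE]
  out <- data.frame(drug = character(0), drug_plate = character(0),
                    vehicle_plate = character(0), stringsAsFactors = FALSE)
  if ("pair_id" %in% names(plates)) {
    for (i in seq_len(nrow(drug_pl))) {
      v <- veh_pl$plate_id[veh_pl$pair_id == drug_pl$pair_id[i]]
      if (length(v))
        out <- rbind(out, data.frame(drug = drug_pl$drug[i],
                                     drug_plate = drug_pl$plate_id[i],
                                     vehicle_plate = v[1],
                                     stringsAsFactors = FALSE))
    }
    return(out)
  }
  # order-based fallback: i-th drug plate of a drug pairs with i-th vehicle plate
  for (d in unique(drug_pl$drug)) {
    dp <- drug_pl$plate_id[drug_pl$drug == d]
    vp <- veh_pl$plate_id
    n <- min(length(dp), length(vp))
    if (n)
      out <- rbind(out, data.frame(drug = d, drug_plate = dp[seq_len(n)],
                                   vehicle_plate = vp[seq_len(n)],
                                   stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.design_report <- function(x, ...) {
  cat("Screen design report\n")
  cat("  GL2 control wells per plate:\n")
  for (p in names(x$gl2_wells_per_plate))
    cat(sprintf("    %-24s %d\n", p, x$gl2_wells_per_plate[[p]]))
  if (length(x$unmatched_genes))
    cat("  Genes not in design:", paste(x$unmatched_genes, collapse = ", "), "\n")
  cat(sprintf("  Vehicle/drug plate pairs: %d\n", nrow(x$pairs)))
  if (length(x$fatal)) cat("  FATAL:", paste(x$fatal, collapse = "; "), "\n")
  else cat("  No fatal problems.\n")
  invisible(x)
}
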