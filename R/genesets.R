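#' Parse cytogenetic band labels
#'
#' Splits labels like `"19q13.1"` into chromosome, arm, major band and
#' optional sub-band. Range labels (`"6p25-p24"`) are resolved to their
#' first band. Unparseable labels yield `NA` components rather than an
#' error.
#'
#' @param band Character vector of band labels.
#' @return Data frame `chrom`, `arm`, `major`, `sub`, `major_band`
#'   (e.g. `"19q13"`), `sub_band` (full label or `NA`).
#' @export
parse_cytoband <- function(band) {
  first <- sub("-.*$", "", as.character(band))     # "6p25-p24" -> "6p25"
  m <- regmatches(first,
                  regexec("^([0-9]{1,2}|X|Y)([pq])([0-9]+)(\\.([0-9]+))?$", first))
  get <- function(i) vapply(m, function(p) if (length(p)) p[i] else "", "")
  chrom <- get(2); arm <- get(3); major <- get(4); sub <- get(6)
  ok <- nzchar(chrom)
  data.frame(
    chrom = ifelse(ok, chrom, NA),
    arm = ifelse(ok, arm, NA),
    major = ifelse(ok, major, NA),
    sub = ifelse(ok & nzchar(sub), sub, NA),
    major_band = ifelse(ok, paste0(chrom, arm, major), NA),
    sub_band = ifelse(ok, first, NA),
    stringsAsFactors = FALSE
  )
}

#' Build chromosomal-region gene sets from a cytoband annotation
#'
#' Groups genes into one set per cytogenetic band. At the default major
#' granularity sub-bands are collapsed (`19q13.1` and `19q13.2` both feed
#' set `"19q13"`), matching the resolution at which regional signals are
#' usually reported; `granularity = "sub"` keeps full sub-band sets.
#' Genes with unparseable band labels are placed in no set and reported
#' via the `"unparsed"` attribute (with a warning).
#'
#' @param annotation Data frame with columns `gene` and `cytoband`.
#' @param granularity `"major"` or `"sub"`.
#' @return Named list of character vectors (gene sets); attribute
#'   `"unparsed"` holds the excluded gene symbols.
#' @export
region_sets_from_cytoband <- function(annotation,
                                      granularity = c("major", "sub")) {
  granularity <- match.arg(granularity)
  stopifnot(all(c("gene", "cytoband") %in% names(annotation)))
  parsed <- parse_cytoband(annotation$cytoband)
  key <- if (granularity == "major") parsed$major_band else parsed$sub_band
  bad <- is.na(key)
  if (any(bad))
    warning(sum(bad), " gene(s) with unparseable cytoband excluded from ",
            "region sets", call. = FALSE)
  sets <- split(annotation$gene[!bad], key[!bad])
  attr(sets, "unparsed") <- annotation$gene[bad]
  sets
}

#' Region sets plus curated pass-through sets
#'
#' Convenience wrapper pairing [region_sets_from_cytoband()] output with
#' curated gene sets (e.g. pathway collections read from GMT); region and
#' curated families are kept apart so they can be corrected for multiple
#' testing separately.
#'
#' @param annotation Data frame (`gene`, `cytoband`).
#' @param curated_sets Optional named list of curated gene sets.
#' @param granularity Passed to [region_sets_from_cytoband()].
#' @return List with components `regions` and `curated`.
#' @export
generate_gene_sets <- function(annotation, curated_sets = NULL,
                               granularity = "major") {
  regions <- region_sets_from_cytoband(annotation, granularity)
  list(regions = regions,
       curated = if (is.null(curated_sets)) list() else curated_sets)
}

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Second GMT column (recycled), default `"na"`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

# rank-sum core: given the ranks of all gene statistics and a set index,
# the Mann-Whitney U of set vs complement. Exact null distribution
# (pwilcox) when both groups are below 50 and there are no ties — the
# normal tail is badly wrong for extreme small sets — else the normal
# approximation with tie and continuity corrections.
.rank_sum_p <- function(ranks, tie_term, N, in_set) {
  m <- sum(in_set)
  n <- N - m
  U <- sum(ranks[in_set]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (tie_term == 0 && m < 50 && n < 50) {
    p <- if (U > mu) stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    else stats::pwilcox(U, m, n)
    p <- min(1, 2 * p)
    z <- stats::qnorm(pmax(p / 2, .Machine$double.xmin)) * sign(mu - U)
    return(list(U = U, z = z, p = p,
                direction = if (U > mu) "up" else if (U < mu) "down" else "none"))
  }
  sigma2 <- (m * n / 12) * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, z = 0, p = 1, direction = "none"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  list(U = U, z = z, p = p, direction = if (U > mu) "up" else if (U < mu) "down" else "none")
}

#' Wilcoxon rank-sum gene-set test on per-gene statistics
#'
#' Tests whether the statistics (typically per-gene t-statistics) of a
#' gene set are shifted relative to all other genes, using the two-sided
#' Wilcoxon rank-sum test in its normal approximation with tie and
#' continuity corrections. A set containing every measured gene has no
#' complement to contrast against and is returned degenerate (`p = 1`).
#'
#' @param statistics Named numeric vector of per-gene statistics
#'   (names are gene ids).
#' @param gene_set Character vector of set members.
#' @param min_size Minimum overlap with the measured genes, default 3.
#' @return List with `set_size`, `statistic` (Mann-Whitney U), `z`, `p`,
#'   `direction` (`"up"`/`"down"`: sign of the set's rank shift).
#' @export
wilcoxon_gene_set_test <- function(statistics, gene_set, min_size = 3) {
  stopifnot(!is.null(names(statistics)))
  in_set <- names(statistics) %in% gene_set
  m <- sum(in_set)
  if (m < min_size)
    stop("gene set overlaps fewer than min_size measured genes", call. = FALSE)
  N <- length(statistics)
  if (m == N) {
    warning("set covers all measured genes: degenerate, p = 1", call. = FALSE)
    return(list(set_size = m, statistic = NA_real_, z = 0, p = 1,
                direction = "none"))
  }
  ranks <- rank(statistics)
  tab <- table(statistics)
  tie_term <- sum(tab^3 - tab)
  r <- .rank_sum_p(ranks, tie_term, N, in_set)
  list(set_size = m, statistic = r$U, z = r$z, p = r$p, direction = r$direction)
}

#' Rank-sum tests over a collection of gene sets
#'
#' Applies [wilcoxon_gene_set_test()] to every set in a collection,
#' computing the global ranking once, and Bonferroni-adjusts the p-values
#' within the collection (sets actually tested form the family).
#' Undersized sets are skipped and listed in the `"skipped"` attribute.
#'
#' @param statistics Named numeric vector of per-gene statistics.
#' @param sets Named list of gene sets.
#' @param min_size Minimum measured overlap, default 3.
#' @return Data frame `set`, `set_size`, `statistic`, `z`, `p_value`,
#'   `bonferroni`, `direction`, sorted by p; attribute `"skipped"`.
#' @export
gene_set_rank_test <- function(statistics, sets, min_size = 3) {
  stopifnot(!is.null(names(statistics)), !is.null(names(sets)))
  N <- length(statistics)
  ranks <- rank(statistics)
  tab <- table(statistics)
  tie_term <- sum(tab^3 - tab)
  gene_names <- names(statistics)
  size <- vapply(sets, function(s) sum(gene_names %in% s), 0L)
  keep <- size >= min_size & size < N
  skipped <- names(sets)[!keep]
  rows <- lapply(names(sets)[keep], function(nm) {
    in_set <- gene_names %in% sets[[nm]]
    r <- .rank_sum_p(ranks, tie_term, N, in_set)
    data.frame(set = nm, set_size = sum(in_set), statistic = r$U, z = r$z,
               p_value = r$p, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), set_size = integer(0),
               statistic = numeric(0), z = numeric(0), p_value = numeric(0),
               direction = character(0), stringsAsFactors = FALSE)
  out$bonferroni <- bonferroni_adjust(out$p_value)
  out <- out[order(out$p_value), c("set", "set_size", "statistic", "z",
                                   "p_value", "bonferroni", "direction")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Bonferroni-adjusted p-values
#'
#' `min(1, p * m)` with `m` the size of the testing family (defaults to
#' the number of p-values supplied; region and curated-pathway families
#' should be corrected separately).
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @param m Family size, default `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "bonferroni", n = max(m, length(p_values)))
}
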