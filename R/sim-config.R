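#' Configuration for a simulated arrayed siRNA sensitization screen
#'
#' Describes a plate screen in which a library of gene-targeting siRNAs
#' (pooled or deconvoluted into individual duplexes) is assayed for
#' viability under paired vehicle and drug arms. Raw well values are
#' generated multiplicatively:
#'
#' \deqn{raw = baseline \times plate \times gene \times interaction \times noise}
#'
#' where the plate factor is shared by every well on a plate (including the
#' GL2 control wells, so that per-plate control normalization cancels it),
#' the gene factor models the viability cost of the knockdown itself, the
#' interaction factor applies only in the drug arm of planted sensitizer
#' genes (attenuated by knockdown efficacy), and the noise is lognormal
#' (viability readings are positive and right-skewed).
#'
#' @param n_genes Number of library genes (default 53).
#' @param n_sirnas_per_gene Independent siRNA duplexes per gene (default 4).
#' @param n_gl2_wells_per_plate Non-targeting GL2 control wells on every
#'   plate (default 5); their median is the normalization denominator.
#' @param n_replicate_wells Replicate wells per gene (or per siRNA) and
#'   condition (default 3).
#' @param drugs Named numeric vector mapping drug label to its sensitizer
#'   interaction factor, a multiplicative viability factor applied in the
#'   drug arm when a planted sensitizer is silenced (e.g. `c(IM = 0.7)`;
#'   values < 1 sensitize).
#' @param sensitizers Named list, one character vector of planted sensitizer
#'   gene ids per drug. Drugs absent from the list have no sensitizers.
#' @param knockdown_efficacy Fraction of target silencing in `[0, 1]`.
#'   A scalar (all duplexes), a vector of length `n_sirnas_per_gene`
#'   (recycled across genes), or an `n_genes x n_sirnas_per_gene` matrix.
#'   The efficacy of a 4-duplex pool is the maximum over its duplexes.
#' @param gene_effect_sd Lognormal sigma of per-gene knockdown viability
#'   factors (drug-independent; cancels out of the SI).
#' @param plate_effect_sd Lognormal sigma of the shared per-plate factor.
#' @param noise_sd Lognormal sigma of per-well measurement noise.
#' @param baseline Mean raw fluorescence of an unperturbed well.
#' @param seed Integer seed; required (reproducibility contract).
#'
#' @return An object of class `"screen_sim_config"`.
#' @seealso [simulate_screen()], [simulate_deconvolution()]
#' @export
screen_sim_config <- function(n_genes = 53,
                              n_sirnas_per_gene = 4,
                              n_gl2_wells_per_plate = 5,
                              n_replicate_wells = 3,
                              drugs = c(IM = 0.7),
                              sensitizers = list(),
                              knockdown_efficacy = 1,
                              gene_effect_sd = 0.1,
                              plate_effect_sd = 0.05,
                              noise_sd = 0.1,
                              baseline = 1000,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: simulated datasets must be reproducible", call. = FALSE)
  }
  seed <- as.integer(seed)
  stopifnot(n_genes >= 1, n_sirnas_per_gene >= 1,
            n_gl2_wells_per_plate >= 1, n_replicate_wells >= 1)
  if (length(drugs) < 1 || is.null(names(drugs)) || any(!nzchar(names(drugs))))
    stop("'drugs' must be a named numeric vector of interaction factors", call. = FALSE)
  if (any(drugs <= 0)) stop("drug interaction factors must be > 0", call. = FALSE)
  if (baseline <= 0) stop("'baseline' must be > 0", call. = FALSE)
  if (any(c(gene_effect_sd, plate_effect_sd, noise_sd) < 0))
    stop("noise sigmas must be >= 0", call. = FALSE)

  genes <- sprintf("G%02d", seq_len(n_genes))

  if (length(sensitizers)) {
    if (is.null(names(sensitizers)) || !all(names(sensitizers) %in% names(drugs)))
      stop("names of 'sensitizers' must be drug labels", call. = FALSE)
    bad <- setdiff(unlist(sensitizers), genes)
    if (length(bad))
      stop("sensitizer ids not in the gene library: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }

  eff <- .efficacy_matrix(knockdown_efficacy, n_genes, n_sirnas_per_gene)
  if (any(eff < 0 | eff > 1))
    stop("'knockdown_efficacy' must lie in [0, 1]", call. = FALSE)

  structure(list(
    genes = genes,
    n_sirnas_per_gene = n_sirnas_per_gene,
    n_gl2_wells_per_plate = n_gl2_wells_per_plate,
    n_replicate_wells = n_replicate_wells,
    drugs = drugs,
    sensitizers = sensitizers,
    knockdown_efficacy = eff,
    gene_effect_sd = gene_effect_sd,
    plate_effect_sd = plate_effect_sd,
    noise_sd = noise_sd,
    baseline = baseline,
    seed = seed
  ), class = "screen_sim_config")
}

# expand scalar / per-duplex / full-matrix efficacy into genes x duplexes
.efficacy_matrix <- function(e, n_genes, n_sirnas) {
  if (is.matrix(e)) {
    if (!all(dim(e) == c(n_genes, n_sirnas)))
      stop("efficacy matrix must be n_genes x n_sirnas_per_gene", call. = FALSE)
    return(e)
  }
  if (length(e) == 1L) return(matrix(e, n_genes, n_sirnas))
  if (length(e) == n_sirnas) return(matrix(e, n_genes, n_sirnas, byrow = TRUE))
  stop("'knockdown_efficacy' must be scalar, length n_sirnas_per_gene, or a matrix",
       call. = FALSE)
}

#' Configuration for a simulated knockdown expression experiment
#'
#' Describes a log2-scale gene-level expression matrix with a small number
#' of control samples and one sample per gene knockdown, into which
#' universally shifted genes and band-coordinated regional shifts are
#' planted. Control samples are centered at a per-gene baseline; each
#' knockdown sample adds the planted per-gene shift, any regional shift for
#' the gene's cytogenetic band, and Gaussian residual noise.
#'
#' @param n_genes Genes on the array (default 22011).
#' @param n_knockdowns Knockdown samples (default 14).
#' @param n_controls Control samples (default 2).
#' @param planted_down Named numeric vector: gene symbol -> negative log2
#'   shift applied in every knockdown (e.g. `c(POSTN = -2.21)`).
#' @param planted_up Named numeric vector of positive shifts.
#' @param near_threshold Named numeric vector of consistent shifts with
#'   magnitude below the primary fold-change cutoff (e.g. `c(NEDD9 = -0.91)`).
#' @param region_shift Named numeric vector: major cytogenetic band
#'   (e.g. `"19q13"`) -> mean log2 shift applied to every gene in the band.
#' @param residual_sd Per-gene Gaussian residual sd on the log2 scale.
#' @param baseline_range Range of per-gene baseline log2 expression.
#' @param seed Integer seed; required.
#'
#' @return An object of class `"expression_sim_config"`.
#' @seealso [simulate_expression()]
#' @export
expression_sim_config <- function(n_genes = 22011,
                                  n_knockdowns = 14,
                                  n_controls = 2,
                                  planted_down = numeric(),
                                  planted_up = numeric(),
                                  near_threshold = numeric(),
                                  region_shift = numeric(),
                                  residual_sd = 0.3,
                                  baseline_range = c(4, 12),
                                  seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is required: simulated datasets must be reproducible", call. = FALSE)
  }
  seed <- as.integer(seed)
  stopifnot(n_genes >= 1, n_knockdowns >= 1, n_controls >= 1, residual_sd >= 0)
  planted <- c(planted_down, planted_up, near_threshold)
  if (length(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      stop("planted gene vectors must be named by gene symbol", call. = FALSE)
    if (anyDuplicated(names(planted)))
      stop("every planted gene may appear only once", call. = FALSE)
    if (any(!is.finite(planted))) stop("planted shifts must be finite", call. = FALSE)
    if (length(planted) > n_genes)
      stop("more planted genes than 'n_genes'", call. = FALSE)
  }
  if (length(region_shift)) {
    if (is.null(names(region_shift)))
      stop("'region_shift' must be named by major band (e.g. '19q13')", call. = FALSE)
    if (any(!is.finite(region_shift)))
      stop("region shifts must be finite", call. = FALSE)
  }

  structure(list(
    n_genes = n_genes,
    n_knockdowns = n_knockdowns,
    n_controls = n_controls,
    planted_down = planted_down,
    planted_up = planted_up,
    near_threshold = near_threshold,
    region_shift = region_shift,
    residual_sd = residual_sd,
    baseline_range = baseline_range,
    seed = seed
  ), class = "expression_sim_config")
}
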