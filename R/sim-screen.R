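# run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# sequential well labels A01, A02, ... zero-padded, rows A..P x 24 columns;
# beyond 384 wells fall back to flat W0001-style labels (virtual plate)
.well_labels <- function(n) {
  if (n > 16L * 24L) return(sprintf("W%04d", seq_len(n)))
  rows <- rep(LETTERS[1:16], each = 24L)
  cols <- rep(1:24, times = 16L)
  sprintf("%s%02d", rows[seq_len(n)], cols[seq_len(n)])
}

# effective drug-arm viability factor for a planted sensitizer: linear
# attenuation of the interaction factor by knockdown efficacy (e = 0 -> no
# effect, e = 1 -> full factor)
.attenuate <- function(factor, efficacy) 1 - efficacy * (1 - factor)

#' Simulate an arrayed pooled-siRNA sensitization screen
#'
#' Generates paired vehicle/drug plates for every drug in the
#' configuration. Each plate carries one well set per library gene
#' (`n_replicate_wells` replicates, pooled siRNA) plus the GL2
#' non-targeting control wells. Raw viability is built multiplicatively
#' from baseline, shared plate factor, per-gene knockdown factor, the
#' drug-interaction factor for planted sensitizers (attenuated by pool
#' efficacy, taken as the maximum over the pool's duplexes), and lognormal
#' well noise. The planted truth is returned alongside, never embedded in
#' the measurement table.
#'
#' @param cfg A [screen_sim_config()].
#' @return A list with `measurements` (a long-format data frame with
#'   columns `plate_id`, `well`, `gene`, `sirna_id`, `condition`, `drug`,
#'   `pair_id`, `raw_value`) and `truth` (data frame `gene`, `drug`,
#'   `is_sensitizer`).
#' @examples
#' cfg <- screen_sim_config(n_genes = 8, sensitizers = list(IM = c("G01", "G02")),
#'                          seed = 1)
#' sim <- simulate_screen(cfg)
#' head(sim$measurements)
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  .with_seed(cfg$seed, {
    gene_effect <- stats::setNames(
      exp(stats::rnorm(length(cfg$genes), 0, cfg$gene_effect_sd)), cfg$genes)
    pool_eff <- stats::setNames(apply(cfg$knockdown_efficacy, 1L, max),
                                cfg$genes)
    rows <- vector("list", 2L * length(cfg$drugs))
    k <- 0L
    for (drug in names(cfg$drugs)) {
      for (condition in c("vehicle", "drug")) {
        k <- k + 1L
        rows[[k]] <- .simulate_plate(cfg, drug, condition, gene_effect, pool_eff,
                                     sirna_id = "pooled")
      }
    }
    measurements <- do.call(rbind, rows)
    rownames(measurements) <- NULL
    truth <- expand.grid(gene = cfg$genes, drug = names(cfg$drugs),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$is_sensitizer <- mapply(function(g, d) {
      g %in% cfg$sensitizers[[d]]
    }, truth$gene, truth$drug, USE.NAMES = FALSE)
    list(measurements = measurements, truth = truth)
  })
}

# one plate: either every gene's pooled well set, or (deconvolution) one
# well set per individual duplex of the requested genes
.simulate_plate <- function(cfg, drug, condition, gene_effect, pool_eff,
                            sirna_id = "pooled", deconv_genes = NULL) {
  plate_factor <- exp(stats::rnorm(1L, 0, cfg$plate_effect_sd))
  if (identical(sirna_id, "pooled")) {
    genes <- rep(cfg$genes, each = cfg$n_replicate_wells)
    sirnas <- rep("pooled", length(genes))
    eff <- pool_eff[genes]
  } else {
    per <- expand.grid(sirna = seq_len(cfg$n_sirnas_per_gene),
                       gene = deconv_genes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    genes <- rep(per$gene, each = cfg$n_replicate_wells)
    sidx <- rep(per$sirna, each = cfg$n_replicate_wells)
    sirnas <- sprintf("%s_s%d", genes, sidx)
    eff <- cfg$knockdown_efficacy[cbind(match(genes, cfg$genes), sidx)]
  }
  interaction <- rep(1, length(genes))
  if (condition == "drug") {
    hit <- genes %in% cfg$sensitizers[[drug]]
    interaction[hit] <- .attenuate(cfg$drugs[[drug]], eff[hit])
  }
  value <- cfg$baseline * plate_factor * gene_effect[genes] * interaction
  gl2 <- rep(cfg$baseline * plate_factor, cfg$n_gl2_wells_per_plate)
  raw <- c(value, gl2) * exp(stats::rnorm(length(value) + length(gl2), 0, cfg$noise_sd))
  n <- length(raw)
  arm_tag <- if (identical(sirna_id, "pooled")) "" else "_deconv"
  data.frame(
    plate_id = sprintf("%s_%s%s", drug, condition, arm_tag),
    well = .well_labels(n),
    gene = c(genes, rep("GL2", cfg$n_gl2_wells_per_plate)),
    sirna_id = c(sirnas, rep("GL2", cfg$n_gl2_wells_per_plate)),
    condition = condition,
    drug = if (condition == "drug") drug else "",
    pair_id = drug,
    raw_value = raw,
    stringsAsFactors = FALSE
  )
}

#' Simulate a deconvolution screen over individual siRNA duplexes
#'
#' Re-screens the given genes with their individual siRNA duplexes rather
#' than the 4-duplex pool, so that duplexes with low knockdown efficacy
#' fail to reproduce the sensitization and the at-least-2-of-4 validation
#' rule can be exercised against known truth.
#'
#' @param cfg A [screen_sim_config()]; per-duplex efficacies come from its
#'   `knockdown_efficacy` matrix.
#' @param genes Genes to deconvolute (default: the whole library).
#' @return As [simulate_screen()], with one well set per individual duplex
#'   (`sirna_id` of the form `"G01_s3"`).
#' @export
simulate_deconvolution <- function(cfg, genes = cfg$genes) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  bad <- setdiff(genes, cfg$genes)
  if (length(bad))
    stop("unknown gene id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  .with_seed(cfg$seed + 1L, {
    gene_effect <- stats::setNames(
      exp(stats::rnorm(length(cfg$genes), 0, cfg$gene_effect_sd)), cfg$genes)
    rows <- vector("list", 2L * length(cfg$drugs))
    k <- 0L
    for (drug in names(cfg$drugs)) {
      for (condition in c("vehicle", "drug")) {
        k <- k + 1L
        rows[[k]] <- .simulate_plate(cfg, drug, condition, gene_effect,
                                     pool_eff = NULL, sirna_id = "individual",
                                     deconv_genes = genes)
      }
    }
    measurements <- do.call(rbind, rows)
    rownames(measurements) <- NULL
    truth <- expand.grid(gene = genes, drug = names(cfg$drugs),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$is_sensitizer <- mapply(function(g, d) {
      g %in% cfg$sensitizers[[d]]
    }, truth$gene, truth$drug, USE.NAMES = FALSE)
    list(measurements = measurements, truth = truth)
  })
}
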