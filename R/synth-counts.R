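#' Configuration for a simulated multiplexed count screen
#'
#' Parameters for [simulate_counts()], which emulates a plate-multiplexed,
#' well-barcoded bulk RNA-seq readout of compound treatments: gene baseline
#' means are log-normal, counts are negative-binomial with a common
#' dispersion, wells carry log-normal library-size multipliers, and active
#' compounds get a planted set of differentially expressed genes at a fixed
#' log2 effect size (half up, half down).
#'
#' @param n_genes number of genes (the generator emulates a matrix already
#'   filtered to reliably detected genes).
#' @param n_dmso_wells replicate DMSO wells.
#' @param n_wells_per_compound replicate wells per compound.
#' @param n_compounds number of compounds.
#' @param active logical vector (length `n_compounds`, recycled) marking
#'   transcriptionally active compounds.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   gene baseline means.
#' @param dispersion negative-binomial dispersion (Var = mu + a mu^2).
#' @param n_de_genes planted DE genes per active compound.
#' @param de_lfc absolute log2 fold-change of planted DE genes.
#' @param libsize_sdlog SD of the log library-size multipliers.
#' @param batch single batch label applied to all wells.
#' @param seed integer seed.
#' @return validated list of class `counts_sim_config`.
#' @export
counts_sim_config <- function(n_genes = 2000L,
                              n_dmso_wells = 12L,
                              n_wells_per_compound = 4L,
                              n_compounds = 10L,
                              active = FALSE,
                              baseline_meanlog = log(50),
                              baseline_sdlog = 1,
                              dispersion = 0.1,
                              n_de_genes = 300L,
                              de_lfc = 2,
                              libsize_sdlog = 0.1,
                              batch = "B1",
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_dmso_wells = as.integer(n_dmso_wells),
              n_wells_per_compound = as.integer(n_wells_per_compound),
              n_compounds = as.integer(n_compounds),
              active = rep_len(as.logical(active), n_compounds),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              dispersion = dispersion,
              n_de_genes = as.integer(n_de_genes),
              de_lfc = de_lfc,
              libsize_sdlog = libsize_sdlog,
              batch = batch,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_dmso_wells < 2L ||
      cfg$n_wells_per_compound < 2L || cfg$n_compounds < 1L)
    stop("invalid counts configuration: counts must be positive ",
         "(>= 2 wells per group)", call. = FALSE)
  if (cfg$dispersion <= 0)
    stop("invalid counts configuration: dispersion must be > 0",
         call. = FALSE)
  if (cfg$n_de_genes > cfg$n_genes)
    stop("invalid counts configuration: n_de_genes exceeds n_genes",
         call. = FALSE)
  if (cfg$baseline_sdlog <= 0 || cfg$libsize_sdlog < 0)
    stop("invalid counts configuration: scale parameters must be positive",
         call. = FALSE)
  class(cfg) <- "counts_sim_config"
  cfg
}

#' Simulate a gene x well count matrix with known ground truth
#'
#' Wells of inactive compounds are exchangeable with DMSO wells by
#' construction; active compounds shift `n_de_genes` randomly chosen genes
#' by `de_lfc` log2 units (half up, half down). Deterministic given the
#' config (which carries the seed).
#'
#' @param config a [counts_sim_config()].
#' @return list with `counts` (integer matrix, genes x wells), `meta`
#'   (data.frame: well, compound, role, batch), `truth` (per-compound
#'   active flag and planted DE gene table).
#' @export
simulate_counts <- function(config) {
  cfg <- config
  if (!inherits(cfg, "counts_sim_config"))
    stop("config must be a counts_sim_config", call. = FALSE)
  set.seed(cfg$seed)
  genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
  mu0 <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                       cfg$baseline_sdlog)
  compounds <- sprintf("cmpd%03d", seq_len(cfg$n_compounds))
  meta <- data.frame(
    well = c(sprintf("DMSO_%02d", seq_len(cfg$n_dmso_wells)),
             sprintf("%s_w%d", rep(compounds,
                                   each = cfg$n_wells_per_compound),
                     rep(seq_len(cfg$n_wells_per_compound),
                         cfg$n_compounds))),
    compound = c(rep(NA_character_, cfg$n_dmso_wells),
                 rep(compounds, each = cfg$n_wells_per_compound)),
    role = c(rep("dmso", cfg$n_dmso_wells),
             rep("compound", cfg$n_compounds * cfg$n_wells_per_compound)),
    batch = cfg$batch,
    stringsAsFactors = FALSE)
  n_wells <- nrow(meta)
  lib <- stats::rlnorm(n_wells, -cfg$libsize_sdlog^2 / 2, cfg$libsize_sdlog)

  de_tab <- list()
  fc <- matrix(1, cfg$n_genes, cfg$n_compounds,
               dimnames = list(genes, compounds))
  for (j in seq_len(cfg$n_compounds)) {
    if (!cfg$active[j] || cfg$n_de_genes == 0L) next
    pick <- sample.int(cfg$n_genes, cfg$n_de_genes)
    sgn <- rep_len(c(1, -1), cfg$n_de_genes)
    fc[pick, j] <- 2^(sgn * cfg$de_lfc)
    de_tab[[compounds[j]]] <- data.frame(compound = compounds[j],
                                         gene = genes[pick],
                                         log2fc = sgn * cfg$de_lfc,
                                         stringsAsFactors = FALSE)
  }
  mu <- matrix(mu0, cfg$n_genes, n_wells)
  ci <- match(meta$compound, compounds)
  has_fc <- which(!is.na(ci))
  for (w in has_fc) mu[, w] <- mu[, w] * fc[, ci[w]]
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   cfg$n_genes, n_wells,
                   dimnames = list(genes, meta$well))
  storage.mode(counts) <- "integer"
  truth <- list(active = stats::setNames(cfg$active, compounds),
                de_genes = if (length(de_tab))
                  do.call(rbind, c(de_tab, list(make.row.names = FALSE)))
                else NULL,
                library_factors = stats::setNames(lib, meta$well))
  list(counts = counts, meta = meta, truth = truth, config = cfg)
}
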