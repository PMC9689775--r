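#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. Defaults describe the study conditions the pipeline is exercised
#' under: a multi-megabase multi-chromosome genome with ~2000 genes, four
#' TE annotation tools with partially redundant calls, TE copies diverged
#' ~10% from consensus under a K2P process with CpG-accelerated
#' transitions, six RNA-seq libraries per caste group with 10% of genes
#' planted at a 2-unit log2 fold change, and a moderately deep GO DAG.
#'
#' @param seed integer root seed; per-stage child seeds are derived
#'   deterministically so identical configs give byte-identical outputs.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_genes number of genes to place (non-overlapping).
#' @param exon_count_range integer `c(min, max)` exons per gene.
#' @param exon_length_range `c(min, max)` exon length (bp).
#' @param intron_length_range `c(min, max)` intron length (bp).
#' @param n_tools number of TE annotation tools to emulate.
#' @param te_density true TE insertions per Mb per superfamily.
#' @param te_length_range `c(min, max)` TE length (bp).
#' @param redundancy probability that a true TE is re-reported by each
#'   additional tool (with boundary jitter).
#' @param jitter_sd standard deviation (bp) of boundary jitter on
#'   redundant re-reports.
#' @param fp_rate fraction of spurious calls added per tool.
#' @param te_bias_mult named insertion-rate multipliers per gene bias
#'   class (`none`, `worker_nymph`, `queen_female`); values above 1 plant
#'   extra insertions in genes of that class, values below 1 thin them.
#' @param k_true target Kimura divergence of simulated TE copies
#'   (substitutions/site).
#' @param kappa transition/transversion rate ratio of the K2P process.
#' @param cpg_mult multiplier on the transition rate at consensus CpG
#'   dinucleotides.
#' @param consensus_gc GC content of the simulated consensus sequence.
#' @param n_libs_per_group RNA-seq libraries per caste group.
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (`variance = mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param planted_frac fraction of genes with planted expression bias.
#' @param planted_lfc absolute log2 fold change of planted genes.
#' @param go_terms number of GO terms in the simulated DAG.
#' @param go_depth maximum DAG depth (1 gives a star ontology).
#' @param n_species number of species tips for the comparative stage.
#' @param trait_rho true correlation of the bivariate Brownian traits.
#' @param trait_sigma Brownian step standard deviation per unit branch.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, chrom_length = 1e6)
#' cfg$n_genes
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 4e6,
                       n_genes = 2000L,
                       exon_count_range = c(2L, 8L),
                       exon_length_range = c(100L, 400L),
                       intron_length_range = c(200L, 2000L),
                       n_tools = 4L,
                       te_density = 40,
                       te_length_range = c(200L, 3000L),
                       redundancy = 0.3,
                       jitter_sd = 10,
                       fp_rate = 0.05,
                       te_bias_mult = c(none = 1, worker_nymph = 1,
                                        queen_female = 1),
                       k_true = 0.10,
                       kappa = 2,
                       cpg_mult = 10,
                       consensus_gc = 0.4,
                       n_libs_per_group = 6L,
                       nb_dispersion = 0.2,
                       planted_frac = 0.1,
                       planted_lfc = 2,
                       go_terms = 100L,
                       go_depth = 5L,
                       n_species = 6L,
                       trait_rho = 0.8,
                       trait_sigma = 1) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              exon_count_range = as.integer(exon_count_range),
              exon_length_range = as.integer(exon_length_range),
              intron_length_range = as.integer(intron_length_range),
              n_tools = as.integer(n_tools), te_density = te_density,
              te_length_range = as.integer(te_length_range),
              redundancy = redundancy, jitter_sd = jitter_sd,
              fp_rate = fp_rate, te_bias_mult = te_bias_mult,
              k_true = k_true, kappa = kappa, cpg_mult = cpg_mult,
              consensus_gc = consensus_gc,
              n_libs_per_group = as.integer(n_libs_per_group),
              nb_dispersion = nb_dispersion, planted_frac = planted_frac,
              planted_lfc = planted_lfc, go_terms = as.integer(go_terms),
              go_depth = as.integer(go_depth),
              n_species = as.integer(n_species),
              trait_rho = trait_rho, trait_sigma = trait_sigma)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chroms", "n_genes", "n_tools", "n_libs_per_group",
              "go_terms", "go_depth", "n_species")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: `", f, "` must be a non-negative count")
  }
  probs <- c("redundancy", "fp_rate", "planted_frac", "consensus_gc")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: `", f, "` must lie in [0, 1]")
  }
  if (!is.finite(cfg$planted_lfc)) stop("sim_config: `planted_lfc` must be finite")
  if (cfg$k_true < 0) stop("sim_config: `k_true` must be >= 0")
  if (cfg$kappa <= 0 || cfg$cpg_mult <= 0)
    stop("sim_config: rate ratios must be positive")
  if (cfg$nb_dispersion < 0) stop("sim_config: `nb_dispersion` must be >= 0")
  if (cfg$chrom_length <= 0) stop("sim_config: `chrom_length` must be positive")
  if (abs(cfg$trait_rho) > 1) stop("sim_config: `trait_rho` must lie in [-1, 1]")
  stopifnot(length(cfg$exon_count_range) == 2L,
            length(cfg$exon_length_range) == 2L,
            length(cfg$intron_length_range) == 2L,
            length(cfg$te_length_range) == 2L)
  if (cfg$exon_count_range[1] < 1)
    stop("sim_config: genes need at least one exon")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_chroms, "chrom x",
      format(x$chrom_length, big.mark = ","), "bp |", x$n_genes, "genes |",
      x$n_tools, "tools | k_true", x$k_true, "|",
      x$n_libs_per_group, "libs/group\n")
  invisible(x)
}

BIAS_CLASSES <- c("none", "worker_nymph", "queen_female")
SUPERFAMILIES <- c("Tc-Mariner", "hAT", "Gypsy", "LINE")
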