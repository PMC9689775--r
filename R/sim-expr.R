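#' Negative-binomial count draws
#'
#' Draws counts with `mean = mu` and `variance = mu + dispersion * mu^2`;
#' `dispersion = 0` falls back to Poisson. Used by [simulate_expression()]
#' and exposed for moment checks.
#'
#' @param n number of draws.
#' @param mu mean (vectorized).
#' @param dispersion NB dispersion (scalar, >= 0).
#' @return integer-valued numeric vector.
#' @export
rnb_counts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate caste RNA-seq counts with planted bias
#'
#' Per-gene baseline means are log-normal; a fraction `planted_frac` of
#' genes is planted with an absolute log2 fold change `planted_lfc`
#' between the two caste groups (half biased toward each group, applied
#' symmetrically so the planted log2 ratio is exactly `planted_lfc`).
#' Library size factors vary uniformly in [0.6, 1.5]. Counts are drawn
#' negative-binomial with dispersion `nb_dispersion`.
#'
#' @param models a `gene_models` object (supplies gene ids; its gene
#'   count caps the number of simulated genes).
#' @param config a [sim_config()] object.
#' @return list with `counts` (gene x library matrix), `samples` (data
#'   frame `library, group`), and `truth` (`gene_id, true_class,
#'   true_lfc`).
#' @export
simulate_expression <- function(models, config) {
  stopifnot(inherits(config, "sim_config"), config$n_libs_per_group >= 2L)
  set.seed(stage_seed(config$seed, "expr"))
  gene_ids <- models$genes$gene_id
  n <- length(gene_ids)
  groups <- rep(c("worker_nymph", "queen_female"),
                each = config$n_libs_per_group)
  libs <- sprintf("%s_%02d", groups,
                  rep(seq_len(config$n_libs_per_group), times = 2))
  samples <- data.frame(library = libs, group = groups)
  if (n == 0L)
    return(list(counts = matrix(0, 0, length(libs),
                                dimnames = list(NULL, libs)),
                samples = samples,
                truth = data.frame(gene_id = character(),
                                   true_class = character(),
                                   true_lfc = numeric())))
  base_mu <- stats::rlnorm(n, meanlog = log(150), sdlog = 1)
  true_class <- rep("none", n)
  true_lfc <- rep(0, n)
  n_planted <- round(config$planted_frac * n)
  if (n_planted > 0 && config$planted_lfc != 0) {
    planted <- sample.int(n, n_planted)
    up <- planted[seq_len(ceiling(n_planted / 2))]     # queen-biased
    down <- setdiff(planted, up)                       # worker-biased
    true_class[up] <- "queen_female"; true_lfc[up] <- config$planted_lfc
    true_class[down] <- "worker_nymph"; true_lfc[down] <- -config$planted_lfc
  }
  sf <- stats::runif(length(libs), 0.6, 1.5)
  mu_q <- base_mu * 2^(true_lfc / 2)
  mu_w <- base_mu * 2^(-true_lfc / 2)
  counts <- matrix(0, n, length(libs), dimnames = list(gene_ids, libs))
  for (j in seq_along(libs)) {
    mu <- if (groups[j] == "queen_female") mu_q else mu_w
    counts[, j] <- rnb_counts(n, sf[j] * mu, config$nb_dispersion)
  }
  list(counts = counts, samples = samples,
       truth = data.frame(gene_id = gene_ids, true_class = true_class,
                          true_lfc = true_lfc))
}
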