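#' Evolve TE copies from a consensus under a CpG-aware K2P process
#'
#' Generates a random consensus sequence and `n_copies` descendant
#' copies, each diverged under a Kimura 2-parameter substitution process
#' with transition/transversion rate ratio `kappa`. Transitions at
#' consensus CpG dinucleotides (the C and the G it precedes) are
#' accelerated by `cpg_mult`, mimicking CpG hypermutability. The overall
#' per-site substitution rate is calibrated so the expected divergence
#' across the sequence equals `k_true`; alignments are gap-free, so the
#' copy/consensus pair is its own alignment.
#'
#' Site outcomes are drawn from the exact K2P transition probabilities at
#' the site's scaled divergence, so the Kimura estimator applied to the
#' emitted alignments is consistent for `k_true` (with `cpg_mult = 1`).
#'
#' @param consensus_length consensus length in bp.
#' @param n_copies number of copies to evolve.
#' @param config a [sim_config()] object (uses `k_true`, `kappa`,
#'   `cpg_mult`, `consensus_gc`, `seed`).
#' @return data frame with `copy_id`, `copy_aln`, `consensus_aln`;
#'   attributes `consensus` (string) and `cpg_sites` (integer positions).
#' @examples
#' cfg <- sim_config(seed = 1, k_true = 0.1)
#' aln <- evolve_te_copies(500, 3, cfg)
#' nchar(aln$copy_aln[1])
#' @export
evolve_te_copies <- function(consensus_length, n_copies, config) {
  stopifnot(inherits(config, "sim_config"), consensus_length >= 1,
            n_copies >= 0, config$k_true >= 0)
  set.seed(stage_seed(config$seed, "copies"))
  bases <- c("A", "C", "G", "T")
  gc <- config$consensus_gc
  cons <- sample(bases, consensus_length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  cpg_c <- which(cons[-length(cons)] == "C" & cons[-1] == "G")
  cpg_sites <- sort(unique(c(cpg_c, cpg_c + 1L)))
  is_cpg <- seq_along(cons) %in% cpg_sites

  k <- config$kappa
  cm <- config$cpg_mult
  f <- mean(is_cpg)
  # per-site scaled rates: alpha*t = kappa*beta*t (cpg: cm*kappa*beta*t)
  beta_t <- config$k_true / ((1 - f) * (k + 2) + f * (cm * k + 2))
  d_site <- ifelse(is_cpg, (cm * k + 2) * beta_t, (k + 2) * beta_t)
  alpha_t <- ifelse(is_cpg, cm * k * beta_t, k * beta_t)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta_t) -
    0.5 * exp(-2 * (alpha_t + beta_t))
  p_tv <- 0.5 - 0.5 * exp(-4 * beta_t)
  if (any((1 - 2 * p_ts - p_tv) * sqrt(1 - 2 * p_tv) < 0.02))
    stop("divergence out of range: K2P process saturates at k_true = ",
         config$k_true)

  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_map2 <- c(A = "T", G = "T", C = "G", T = "G")
  copies <- character(n_copies)
  for (i in seq_len(n_copies)) {
    u <- stats::runif(consensus_length)
    out <- cons
    ts <- u < p_ts
    tv1 <- !ts & u < p_ts + p_tv / 2
    tv2 <- !ts & !tv1 & u < p_ts + p_tv
    out[ts] <- ts_map[cons[ts]]
    out[tv1] <- tv_map1[cons[tv1]]
    out[tv2] <- tv_map2[cons[tv2]]
    copies[i] <- paste(out, collapse = "")
  }
  res <- data.frame(copy_id = sprintf("copy%04d", seq_len(n_copies)),
                    copy_aln = copies,
                    consensus_aln = paste(cons, collapse = ""))
  attr(res, "consensus") <- paste(cons, collapse = "")
  attr(res, "cpg_sites") <- cpg_sites
  attr(res, "expected_divergence") <- mean(d_site)
  res
}
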