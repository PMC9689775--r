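#' Kimura 2-parameter distance
#'
#' `K = -1/2 * log((1 - 2p - q) * sqrt(1 - 2q))` where `p` and `q` are
#' the observed proportions of transition and transversion differences.
#' Vectorized over `p` and `q`.
#'
#' @param p transition proportion(s), in `[0, 1]`.
#' @param q transversion proportion(s), in `[0, 1]`.
#' @return Kimura distance(s) in substitutions per site.
#' @examples
#' kimura_k2p(0.1, 0.05)  # 0.17018
#' @export
kimura_k2p <- function(p, q) {
  if (any(p < 0 | q < 0 | p > 1 | q > 1 | !is.finite(p) | !is.finite(q)))
    stop("p and q must be finite proportions in [0, 1]")
  a <- 1 - 2 * p - q
  b <- 1 - 2 * q
  if (any(a <= 0 | b <= 0))
    stop("saturated divergence: 1 - 2p - q and 1 - 2q must be positive")
  -0.5 * log(a * sqrt(b))
}

#' Divergence of an aligned TE copy against its consensus
#'
#' Counts transition and transversion differences over ungapped,
#' unambiguous alignment columns and converts them into a Kimura
#' 2-parameter distance. With `cpg_correct = TRUE`, a transition at a
#' consensus CpG dinucleotide position (the C or the following G)
#' contributes only `cpg_weight` (default 1/10) to the transition count,
#' down-weighting CpG hypermutability the same way the widely used
#' RepeatMasker divergence script does.
#'
#' @param copy_aln aligned copy sequence (string; `-` for gaps).
#' @param consensus_aln aligned consensus sequence of equal length.
#' @param cpg_correct down-weight transitions at consensus CpG sites?
#' @param cpg_weight weight given to a CpG-site transition.
#' @return a list of class `divergence_estimate` with `p`, `q`,
#'   `n_sites`, `K` (NA with `saturated = TRUE` when the K2P formula is
#'   undefined for the observed counts).
#' @examples
#' alignment_divergence("GCGT", "ACGT", cpg_correct = FALSE)$K  # 0.34657
#' @export
alignment_divergence <- function(copy_aln, consensus_aln,
                                 cpg_correct = TRUE, cpg_weight = 0.1) {
  if (nchar(copy_aln) != nchar(consensus_aln))
    stop("aligned sequences differ in length")
  cp <- strsplit(toupper(copy_aln), "")[[1]]
  cs <- strsplit(toupper(consensus_aln), "")[[1]]
  bases <- c("A", "C", "G", "T")
  valid <- cp %in% bases & cs %in% bases
  n_sites <- sum(valid)
  if (n_sites == 0) stop("empty ungapped overlap between copy and consensus")

  # CpG positions on the consensus as given (gap columns break a CpG)
  cpg_c <- which(cs[-length(cs)] == "C" & cs[-1] == "G")
  is_cpg <- seq_along(cs) %in% sort(unique(c(cpg_c, cpg_c + 1L)))

  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  diff <- valid & cp != cs
  transition <- diff & purine[cp] == purine[cs]
  transversion <- diff & purine[cp] != purine[cs]
  w <- ifelse(cpg_correct & is_cpg, cpg_weight, 1)
  p <- sum(w[transition]) / n_sites
  q <- sum(transversion) / n_sites
  K <- tryCatch(kimura_k2p(p, q), error = function(e) NA_real_)
  structure(list(p = p, q = q, n_sites = n_sites, K = K,
                 saturated = is.na(K)),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> p=%.4f q=%.4f n=%d K=%s\n",
              x$p, x$q, x$n_sites,
              if (x$saturated) "saturated" else sprintf("%.5f", x$K)))
  invisible(x)
}

#' Divergence of a table of aligned copy/consensus pairs
#'
#' Applies [alignment_divergence()] to each row of a pair table (as
#' produced by [evolve_te_copies()] or read from TSV).
#'
#' @param pairs data frame with `copy_id`, `copy_aln`, `consensus_aln`.
#' @inheritParams alignment_divergence
#' @return data frame `copy_id,p,q,n_sites,K,saturated`.
#' @export
divergence_table <- function(pairs, cpg_correct = TRUE, cpg_weight = 0.1) {
  est <- lapply(seq_len(nrow(pairs)), function(i)
    alignment_divergence(pairs$copy_aln[i], pairs$consensus_aln[i],
                         cpg_correct, cpg_weight))
  data.frame(copy_id = pairs$copy_id,
             p = vapply(est, `[[`, numeric(1), "p"),
             q = vapply(est, `[[`, numeric(1), "q"),
             n_sites = vapply(est, `[[`, integer(1), "n_sites"),
             K = vapply(est, `[[`, numeric(1), "K"),
             saturated = vapply(est, `[[`, logical(1), "saturated"))
}

#' Per-superfamily TE divergence landscape
#'
#' Bins each TE copy's genomic length by its Kimura divergence (in %) and
#' reports, per superfamily and bin, the percentage of the genome the
#' copies in that bin occupy -- the classical repeat-landscape histogram.
#'
#' @param copies data frame with `superfamily`, `K` (substitutions/site)
#'   and either a `length` column or `start`/`end` (1-based inclusive).
#' @param genome_size genome size in bp.
#' @param bin_width bin width in % divergence.
#' @param max_div right edge of the last bin in % divergence; copies
#'   beyond it (or with `NA` K) are dropped with a message.
#' @return data frame `superfamily,bin_low,bin_high,percent`, with a full
#'   bin grid (zero-filled) per superfamily.
#' @export
build_landscape <- function(copies, genome_size, bin_width = 1,
                            max_div = 55) {
  stopifnot(genome_size > 0, bin_width > 0)
  if (!"length" %in% names(copies))
    copies$length <- copies$end - copies$start + 1
  edges <- seq(0, max_div, by = bin_width)
  if (edges[length(edges)] < max_div) edges <- c(edges, max_div)
  sfs <- sort(unique(as.character(copies$superfamily)))
  if (!length(sfs)) sfs <- SUPERFAMILIES
  grid <- expand.grid(bin = seq_len(length(edges) - 1L), superfamily = sfs,
                      stringsAsFactors = FALSE)
  grid$bin_low <- edges[grid$bin]
  grid$bin_high <- edges[grid$bin + 1L]
  grid$percent <- 0
  drop <- is.na(copies$K) | 100 * copies$K >= edges[length(edges)]
  if (any(drop))
    message(sum(drop), " copies beyond the landscape range were dropped")
  cc <- copies[!drop, , drop = FALSE]
  if (nrow(cc)) {
    bin <- findInterval(100 * cc$K, edges, rightmost.closed = FALSE)
    agg <- stats::aggregate(cc$length,
                            by = list(bin = bin, superfamily = cc$superfamily),
                            FUN = sum)
    i <- match(paste(agg$bin, agg$superfamily),
               paste(grid$bin, grid$superfamily))
    grid$percent[i] <- 100 * agg$x / genome_size
  }
  grid[, c("superfamily", "bin_low", "bin_high", "percent")]
}
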