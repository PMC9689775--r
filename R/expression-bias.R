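#' Median-of-ratios library size factors
#'
#' Per-library normalization factors computed as the median, over genes
#' expressed in every library, of the ratio of the library's count to the
#' gene's geometric mean across libraries.
#'
#' @param counts numeric gene x library matrix (or data frame).
#' @return named numeric vector of positive size factors.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(NULL, c("a", "b")))
#' size_factors(m)  # b is scaled x2
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no gene has nonzero counts in all libraries")
  logc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - geo)))
  if (any(sf <= 0)) stop("non-positive size factor")
  sf
}

#' Lightweight differential-expression stand-in
#'
#' A documented stand-in for a full negative-binomial DE analysis,
#' intended for synthetic data: counts are normalized by median-of-ratios
#' size factors, log2(normalized + 1) values are compared between the
#' two groups with Welch's unequal-variance t test, and p-values are
#' BH-adjusted over the tested genes. Genes with all-zero counts are
#' reported as untested (`NA` p-values). Pipelines on real data should
#' inject an external DE table (`gene_id, log2fc, pvalue, padj`) instead;
#' such tables pass through [classify_bias()] untouched.
#'
#' The log2 fold change is `queen_female` over `worker_nymph` (positive
#' means higher in queens/adult females).
#'
#' @param counts gene x library count matrix with dimnames.
#' @param groups character/factor of length `ncol(counts)` with values
#'   `worker_nymph` / `queen_female` (or a `samples` data frame with
#'   `library` and `group` columns).
#' @return data frame `gene_id, log2fc, pvalue, padj` (one row per gene).
#' @export
de_lite <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.data.frame(groups) || is.list(groups)) {
    g <- as.character(groups$group[match(colnames(counts), groups$library)])
  } else g <- as.character(groups)
  lv <- c("worker_nymph", "queen_female")
  if (!all(g %in% lv)) stop("groups must be worker_nymph / queen_female")
  if (any(table(factor(g, lv)) < 2L))
    stop("each group needs at least 2 libraries")
  sf <- size_factors(counts)
  y <- log2(sweep(counts, 2, sf, "/") + 1)
  a <- y[, g == "queen_female", drop = FALSE]
  b <- y[, g == "worker_nymph", drop = FALSE]
  na_ <- ncol(a); nb_ <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se2 <- va / na_ + vb / nb_
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb_)^2 / (nb_ - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero-variance degenerate cases: identical values give p = 1
  zero_se <- is.finite(ma) & se2 == 0
  p[zero_se & ma == mb] <- 1
  p[zero_se & ma != mb] <- 0
  untested <- rowSums(counts) == 0
  p[untested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[!untested] <- bh_adjust(p[!untested])
  data.frame(gene_id = rownames(counts), log2fc = unname(ma - mb),
             pvalue = unname(p), padj = unname(padj))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (a thin wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues numeric vector of p-values.
#' @return adjusted p-values, each at least its input p and at most 1.
#' @export
bh_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Classify expression bias
#'
#' Applies the significance rule: a gene is biased when its adjusted
#' p-value is strictly below `alpha`; the sign of the log2 fold change
#' (queen/adult-female over worker/nymph) sets the direction. Genes with
#' a missing adjusted p-value are `untested` and are discarded by the
#' downstream overlap and enrichment stages.
#'
#' @param records data frame with `gene_id, log2fc, pvalue, padj`.
#' @param alpha significance threshold on the adjusted p-value.
#' @return `records` with a `bias_class` factor column
#'   (`none`, `worker_nymph`, `queen_female`, `untested`).
#' @examples
#' classify_bias(data.frame(gene_id = "g", log2fc = 1.2,
#'                          pvalue = 0.01, padj = 0.04))$bias_class
#' @export
classify_bias <- function(records, alpha = 0.05) {
  cls <- rep("none", nrow(records))
  cls[is.na(records$padj)] <- "untested"
  sig <- !is.na(records$padj) & records$padj < alpha
  cls[sig & records$log2fc > 0] <- "queen_female"
  cls[sig & records$log2fc < 0] <- "worker_nymph"
  records$bias_class <- factor(cls, levels = c(BIAS_CLASSES, "untested"))
  records
}

#' Summarize bias classes and fold-change subsets
#'
#' Counts genes per bias class and, within each biased class, the subset
#' with at least `fc_threshold`-fold change (`|log2fc| >= log2(fc)`).
#' Percentages use the total number of differentially expressed genes
#' (padj < alpha, i.e. biased either way) as denominator, matching how
#' such proportions are conventionally reported; `percent_printed`
#' rounds to 2 significant figures.
#'
#' @param records output of [classify_bias()].
#' @param fc_threshold fold-change threshold on the natural scale.
#' @param alpha significance threshold (only used to recompute the DEG
#'   total when `bias_class` is absent).
#' @return data frame with one row per bias class: `bias_class, n,
#'   n_fc, percent_fc, percent_printed`, plus attributes `n_tested` and
#'   `n_deg`.
#' @export
summarize_bias <- function(records, fc_threshold = 2, alpha = 0.05) {
  if (!"bias_class" %in% names(records))
    records <- classify_bias(records, alpha)
  tested <- records[records$bias_class != "untested", , drop = FALSE]
  deg <- tested[tested$bias_class != "none", , drop = FALSE]
  n_deg <- nrow(deg)
  lfc_cut <- log2(fc_threshold)
  out <- do.call(rbind, lapply(BIAS_CLASSES, function(cl) {
    rows <- tested[tested$bias_class == cl, , drop = FALSE]
    n_fc <- if (cl == "none") NA_integer_ else
      sum(abs(rows$log2fc) >= lfc_cut)
    data.frame(bias_class = cl, n = nrow(rows), n_fc = n_fc,
               percent_fc = if (is.na(n_fc) || n_deg == 0) NA_real_ else
                 100 * n_fc / n_deg)
  }))
  out$percent_printed <- signif(out$percent_fc, 2)
  attr(out, "n_tested") <- nrow(tested)
  attr(out, "n_deg") <- n_deg
  out
}
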