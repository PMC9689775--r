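#' Gene Ontology DAG with ancestor-closed annotations
#'
#' Validates the term graph (acyclic; edges point child to parent),
#' computes each term's depth (longest path from a root) and ancestor
#' set, and propagates gene annotations to all ancestors (a gene
#' annotated to a term is annotated to every ancestor of that term).
#'
#' @param edges data frame `child, parent`.
#' @param annotations data frame `gene_id, term_id` (raw, unpropagated).
#' @return object of class `go_dag`: list with `terms`, `parents`,
#'   `ancestors`, `depth` (named integer), `genes` (term -> character
#'   vector, ancestor-closed).
#' @export
go_dag <- function(edges, annotations) {
  terms <- sort(unique(c(edges$child, edges$parent, annotations$term_id)))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  # Kahn topological order (parents first); leftover nodes mean a cycle
  indeg <- lengths(parents)
  queue <- terms[indeg == 0L]
  topo <- character(0)
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_left[ch] <- indeg_left[ch] - 1L
      if (indeg_left[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(terms))
    stop("cycle detected in GO edges")
  depth <- stats::setNames(integer(length(terms)), terms)
  ancestors <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    ps <- parents[[t]]
    if (length(ps)) {
      depth[t] <- max(depth[ps]) + 1L
      ancestors[[t]] <- sort(unique(c(ps, unlist(ancestors[ps]))))
    } else ancestors[[t]] <- character()
  }
  genes <- stats::setNames(vector("list", length(terms)), terms)
  if (nrow(annotations)) {
    raw <- split(annotations$gene_id,
                 factor(annotations$term_id, levels = terms))
    for (t in rev(topo)) {   # children before parents
      gs <- raw[[t]]
      for (ch in children[[t]]) gs <- c(gs, genes[[ch]])
      genes[[t]] <- sort(unique(gs))
    }
  } else genes[] <- list(character())
  structure(list(terms = terms, parents = parents, ancestors = ancestors,
                 depth = depth, genes = genes),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag>", length(x$terms), "terms, max depth", max(x$depth),
      ",", length(unique(unlist(x$genes))), "annotated genes\n")
  invisible(x)
}

#' Gene scores from expression bias
#'
#' Scores genes for stage-biased enrichment: the score is the negative
#' log10 of the adjusted p-value. Genes biased toward the *opposite*
#' stage are neutralized; by default their adjusted p-value is treated
#' as 1 (score 0, maximally non-focal). The alternative reading -- a
#' literal score of 1 -- is available via `opposite = "score_one"`;
#' neither is privileged, the choice is recorded in the output
#' attributes. Untested genes must be discarded beforehand (they are
#' dropped with a message if present).
#'
#' @param de_records output of [classify_bias()].
#' @param focal_stage `worker_nymph` or `queen_female`: the stage whose
#'   biased genes are the signal.
#' @param opposite how to neutralize opposite-stage genes: `padj_one`
#'   (score 0) or `score_one` (score 1).
#' @return data frame `gene_id, score, significant` (significant = biased
#'   toward the focal stage), with attribute `scoring`.
#' @export
bias_gene_scores <- function(de_records,
                             focal_stage = c("worker_nymph", "queen_female"),
                             opposite = c("padj_one", "score_one")) {
  focal_stage <- match.arg(focal_stage)
  opposite <- match.arg(opposite)
  other <- setdiff(c("worker_nymph", "queen_female"), focal_stage)
  rec <- de_records
  drop <- is.na(rec$padj) | (!is.null(rec$bias_class) &
                               rec$bias_class == "untested")
  if (any(drop)) {
    message("discarding ", sum(drop), " untested genes")
    rec <- rec[!drop, , drop = FALSE]
  }
  if (!"bias_class" %in% names(rec)) rec <- classify_bias(rec)
  score <- -log10(pmax(rec$padj, 1e-300))
  opp <- rec$bias_class == other
  score[opp] <- if (opposite == "padj_one") 0 else 1
  out <- data.frame(gene_id = rec$gene_id, score = score,
                    significant = rec$bias_class == focal_stage)
  attr(out, "scoring") <- paste0("-log10(padj), opposite=", opposite)
  out
}

#' Gene scores from TE insertion rates
#'
#' Scores genes for TE-rich enrichment: the score is the TE insertion
#' rate per gene kilobase, and the significant flag is the TE-rich flag.
#'
#' @param profiles [profile_genes()] output (after [flag_te_rich()]).
#' @return data frame `gene_id, score, significant`.
#' @export
te_gene_scores <- function(profiles) {
  out <- data.frame(gene_id = profiles$gene_id, score = profiles$rate,
                    significant = isTRUE_vec(profiles$te_rich))
  attr(out, "scoring") <- "TE insertions per gene kb"
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' One-sided two-sample KS enrichment p-value
#'
#' Kolmogorov-Smirnov-type rank test for the genes of a term having
#' systematically larger scores than the background genes (the rest of
#' the universe). Uses the asymptotic one-sided two-sample KS p-value.
#' Degenerate inputs (empty term or empty background, e.g. when the term
#' annotates every gene) return 1.
#'
#' @param term_gene_scores numeric scores of the term's genes.
#' @param background_scores numeric scores of the remaining genes.
#' @param direction `greater` tests for larger term scores, `less` for
#'   smaller.
#' @return a p-value in `[0, 1]`.
#' @export
ks_term_test <- function(term_gene_scores, background_scores,
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(term_gene_scores) || !length(background_scores)) return(1)
  alt <- if (direction == "greater") "less" else "greater"
  p <- suppressWarnings(
    stats::ks.test(term_gene_scores, background_scores,
                   alternative = alt, exact = FALSE)$p.value)
  min(1, max(0, p))
}

#' Score-based GO enrichment with elim pruning
#'
#' Tests every annotated term with the one-sided KS statistic against
#' the rest of the score universe, walking the DAG from the most
#' specific terms (greatest depth; ties in lexicographic term order) to
#' the root. When a term's p-value falls below `elim_cutoff`, its
#' significant genes (flagged in `scores`; or all its genes with
#' `remove = "all"`) are eliminated from all ancestor terms' gene sets
#' before those are tested, so enrichment localizes to the most specific
#' responsible terms. With `elim_cutoff = 0` (or an edge-free DAG) the
#' result equals classical per-term testing.
#'
#' @param dag a [go_dag()] object.
#' @param scores data frame `gene_id, score, significant`.
#' @param elim_cutoff p-value below which a term's genes are eliminated
#'   from its ancestors.
#' @param remove which genes a significant term eliminates from its
#'   ancestors: its flagged `significant` genes (default) or `all` its
#'   annotated genes.
#' @return data frame `term_id, pvalue, n_annotated, depth`, sorted by
#'   p-value.
#' @export
elim_enrichment <- function(dag, scores, elim_cutoff = 0.01,
                            remove = c("significant", "all")) {
  stopifnot(inherits(dag, "go_dag"))
  remove <- match.arg(remove)
  universe <- unique(scores$gene_id)
  score <- stats::setNames(scores$score, scores$gene_id)[universe]
  sig_genes <- unique(scores$gene_id[isTRUE_vec(scores$significant)])
  current <- lapply(dag$genes, intersect, universe)
  testable <- dag$terms[lengths(current) > 0L]
  if (!length(testable))
    return(data.frame(term_id = character(), pvalue = numeric(),
                      n_annotated = integer(), depth = integer()))
  ord <- testable[order(-dag$depth[testable], testable)]
  res <- data.frame(term_id = ord, pvalue = NA_real_,
                    n_annotated = NA_integer_,
                    depth = unname(dag$depth[ord]))
  for (i in seq_along(ord)) {
    t <- ord[i]
    tg <- current[[t]]
    bg <- setdiff(universe, tg)
    res$n_annotated[i] <- length(tg)
    res$pvalue[i] <- if (length(tg)) ks_term_test(score[tg], score[bg]) else 1
    if (res$pvalue[i] < elim_cutoff) {
      elim <- if (remove == "significant") intersect(tg, sig_genes) else tg
      if (length(elim))
        for (anc in dag$ancestors[[t]])
          current[[anc]] <- setdiff(current[[anc]], elim)
    }
  }
  res <- res[order(res$pvalue, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Three-criterion specificity filter for TE-rich DEG enrichment
#'
#' Removes from a primary enrichment result (TE-rich DEGs at social
#' level `social` and life stage `stage`) every GO term that is also
#' significant in comparison analyses, so the surviving terms are
#' specific to that stage, social level and high TE insertion rate. A
#' term is removed when it is significant (p < `alpha`) in:
#'
#' 1. stage-`stage` DEG enrichment at **both** social levels;
#' 2. TE-rich DEG enrichment at stage `stage` in the **other** social
#'    level;
#' 3. TE-rich enrichment of a **different** stage (including no-bias) at
#'    social level `social`.
#'
#' `removal_reason` records the first triggering criterion in order.
#'
#' @param primary enrichment result data frame (`term_id, pvalue`, ...).
#' @param comparisons long data frame of comparison results with columns
#'   `term_id, pvalue, social, stage, te_rich` (one row per term per
#'   analysis). An empty comparison table removes nothing.
#' @param social,stage labels of the primary analysis (`social` is
#'   typically `eusocial`/`gregarious`; `stage` a bias class or `none`).
#' @param alpha significance level used throughout the cascade.
#' @param social_levels the two social levels criterion 1 requires.
#' @return `primary` with `survived_specificity` and `removal_reason`
#'   (`none`, `criterion1`, `criterion2`, `criterion3`) columns.
#' @export
specificity_filter <- function(primary, comparisons, social, stage,
                               alpha = 0.05,
                               social_levels = c("eusocial", "gregarious")) {
  primary$survived_specificity <- TRUE
  primary$removal_reason <- "none"
  if (is.null(comparisons) || !nrow(comparisons)) return(primary)
  stopifnot(all(c("term_id", "pvalue", "social", "stage", "te_rich") %in%
                  names(comparisons)))
  sig <- comparisons[comparisons$pvalue < alpha, , drop = FALSE]
  for (i in seq_len(nrow(primary))) {
    t <- primary$term_id[i]
    s <- sig[sig$term_id == t, , drop = FALSE]
    crit1 <- all(social_levels %in%
                   s$social[!s$te_rich & s$stage == stage])
    crit2 <- any(s$te_rich & s$stage == stage & s$social != social)
    crit3 <- any(s$te_rich & s$social == social & s$stage != stage)
    reason <- if (crit1) "criterion1" else if (crit2) "criterion2"
              else if (crit3) "criterion3" else "none"
    primary$removal_reason[i] <- reason
    primary$survived_specificity[i] <- reason == "none"
  }
  primary
}
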