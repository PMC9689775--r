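#' Simulate a GO DAG and gene annotations with planted enrichment
#'
#' Builds an acyclic, single-rooted term DAG of depth `go_depth` (depth 1
#' gives a star ontology), annotates each gene to a few random terms, and
#' optionally plants terms whose annotated gene set is dominated by a
#' designated gene set (e.g. planted TE-rich biased genes), so that
#' downstream enrichment should recover them. Annotations are returned
#' raw (unpropagated); [go_dag()] performs ancestor closure.
#'
#' @param models a `gene_models` object (supplies gene ids).
#' @param config a [sim_config()] object (`go_terms`, `go_depth`).
#' @param planted_genes character vector of gene ids to concentrate the
#'   planted terms on (optional).
#' @param n_planted_terms number of planted terms.
#' @return list with `edges` (`child,parent`), `annotations`
#'   (`gene_id,term_id`), `dag` (a [go_dag()] object), and `truth`
#'   (planted term ids).
#' @export
simulate_go <- function(models, config, planted_genes = NULL,
                        n_planted_terms = 2L) {
  stopifnot(inherits(config, "sim_config"), config$go_terms >= 1L,
            config$go_depth >= 1L)
  set.seed(stage_seed(config$seed, "go"))
  n_terms <- config$go_terms
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  root <- terms[1]
  depth <- integer(n_terms)
  if (n_terms > 1) {
    # spread terms over depths 1..go_depth, keeping every depth populated
    depth[-1] <- sort(rep_len(seq_len(config$go_depth), n_terms - 1L))
  }
  edges <- NULL
  for (i in seq_len(n_terms)[-1]) {
    cand <- which(depth == depth[i] - 1L)
    parent <- terms[if (length(cand) == 1L) cand else sample(cand, 1L)]
    e <- data.frame(child = terms[i], parent = parent)
    # occasional second parent from any strictly shallower depth: a DAG,
    # not a tree
    shallower <- which(depth < depth[i] & terms != parent)
    if (length(shallower) && stats::runif(1) < 0.2) {
      p2 <- terms[if (length(shallower) == 1L) shallower else
        sample(shallower, 1L)]
      if (p2 != parent) e <- rbind(e, data.frame(child = terms[i],
                                                 parent = p2))
    }
    edges <- rbind(edges, e)
  }
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character())

  gene_ids <- models$genes$gene_id
  annotable <- terms[depth >= 1 | n_terms == 1L]
  ann <- NULL
  if (length(gene_ids) && length(annotable)) {
    k <- sample(1:3, length(gene_ids), replace = TRUE)
    ann <- data.frame(
      gene_id = rep(gene_ids, k),
      term_id = unlist(lapply(k, function(m)
        sample(annotable, min(m, length(annotable))))))
  }
  planted <- character()
  if (!is.null(planted_genes) && length(planted_genes) && n_terms > 1) {
    deep <- terms[depth == max(depth)]
    n_pl <- min(n_planted_terms, length(deep))
    planted <- sample(deep, n_pl)
    extra <- lapply(planted, function(t) {
      others <- setdiff(gene_ids, planted_genes)
      noise <- if (length(others))
        sample(others, min(length(others), ceiling(0.1 * length(planted_genes))))
      else character()
      data.frame(gene_id = c(planted_genes, noise), term_id = t)
    })
    ann <- rbind(ann, do.call(rbind, extra))
  }
  if (is.null(ann))
    ann <- data.frame(gene_id = character(), term_id = character())
  ann <- unique(ann)
  rownames(ann) <- NULL
  list(edges = edges, annotations = ann,
       dag = go_dag(edges, ann), truth = planted)
}
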