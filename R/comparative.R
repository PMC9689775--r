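#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning transform of tip traits into standardized,
#' statistically independent differences: at each internal node with
#' daughters `i, j` carrying values `x_i, x_j` and (extended) branch
#' lengths `v_i, v_j`, the contrast is `(x_i - x_j) / sqrt(v_i + v_j)`;
#' the node's ancestral value is the `1/v`-weighted average of the
#' daughters, and its own branch is extended by `v_i v_j / (v_i + v_j)`.
#' Requires a rooted, fully bifurcating tree with positive branch
#' lengths; polytomies are rejected rather than resolved silently.
#'
#' @param tree an `ape` phylo tree.
#' @param trait numeric vector named by tip labels (every tip covered).
#' @param scaled standardize each contrast by its standard deviation?
#' @return numeric vector of `n_tips - 1` contrasts named by internal
#'   node number (ascending, as in `ape`).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
#' pic_contrasts(tr, c(a = 1, b = 3, c = 5))
#' @export
pic_contrasts <- function(tree, trait, scaled = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("polytomies rejected: resolve the tree before computing contrasts")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  n_tip <- length(tree$tip.label)
  if (is.null(names(trait))) {
    if (length(trait) != n_tip) stop("trait length != number of tips")
    names(trait) <- tree$tip.label
  }
  if (!all(tree$tip.label %in% names(trait)))
    stop("missing trait value for tip: ",
         paste(setdiff(tree$tip.label, names(trait)), collapse = ", "))
  n_node <- n_tip + tree$Nnode
  x <- numeric(n_node)
  v <- numeric(n_node)
  x[seq_len(n_tip)] <- trait[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")
  contrasts <- numeric(tree$Nnode)
  names(contrasts) <- character(tree$Nnode)
  # postorder edges come in daughter pairs for a binary tree
  for (k in seq(1, nrow(po$edge), by = 2)) {
    node <- po$edge[k, 1]
    d <- po$edge[c(k, k + 1), 2]
    vv <- po$edge.length[c(k, k + 1)] + v[d]
    cst <- x[d[1]] - x[d[2]]
    if (scaled) cst <- cst / sqrt(sum(vv))
    contrasts[node - n_tip] <- cst
    names(contrasts)[node - n_tip] <- as.character(node)
    x[node] <- sum(x[d] / vv) / sum(1 / vv)
    v[node] <- prod(vv) / sum(vv)
  }
  contrasts[order(as.integer(names(contrasts)))]
}

#' Correlation test on independent contrasts
#'
#' Pearson correlation of two contrast vectors with a Student-t test:
#' `t = r * sqrt(df / (1 - r^2))`, two-sided p from the t distribution.
#' The default degrees of freedom are `k - 2` for `k` contrasts
#' (ordinary correlation of the contrast pairs); the textbook
#' through-origin alternative (`df = k - 1`, correlation forced through
#' the origin) is available via `df_method`.
#'
#' @param cx,cy standardized contrast vectors of equal length (`k >= 3`).
#' @param df_method `"correlation"` (df = k - 2) or `"through_origin"`
#'   (df = k - 1, r computed through the origin).
#' @return list of class `contrast_cor`: `r, t, df, p, k, degenerate`
#'   (`degenerate = TRUE` with `p = 0` when `|r| = 1`).
#' @examples
#' contrast_cor_test(t = 1.382, df = 3)$p  # 0.261
#' @export
pic_correlation <- function(cx, cy,
                            df_method = c("correlation", "through_origin")) {
  df_method <- match.arg(df_method)
  stopifnot(length(cx) == length(cy))
  k <- length(cx)
  if (k < 3) stop("need at least 3 contrasts")
  if (df_method == "correlation") {
    r <- stats::cor(cx, cy)
    df <- k - 2
  } else {
    r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
    df <- k - 1
  }
  res <- contrast_cor_test(r = r, df = df)
  res$k <- k
  res$contrasts <- data.frame(cx = cx, cy = cy)
  res
}

#' @rdname pic_correlation
#' @param r Pearson correlation (used when `t` is not given).
#' @param t precomputed t statistic (bypasses `r`).
#' @param df degrees of freedom of the test.
#' @export
contrast_cor_test <- function(r = NULL, t = NULL, df) {
  degenerate <- FALSE
  if (is.null(t)) {
    if (abs(r) >= 1 - 1e-12) {
      return(structure(list(r = r, t = sign(r) * Inf, df = df, p = 0,
                            degenerate = TRUE), class = "contrast_cor"))
    }
    t <- r * sqrt(df / (1 - r^2))
  } else if (is.null(r)) {
    r <- t / sqrt(t^2 + df)
  }
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(r = r, t = t, df = df, p = p, degenerate = degenerate),
            class = "contrast_cor")
}

#' @export
print.contrast_cor <- function(x, ...) {
  cat(sprintf("<contrast_cor> r = %.3f, t = %.3f, df = %d, p = %.3f%s\n",
              x$r, x$t, as.integer(x$df), x$p,
              if (x$degenerate) " (degenerate: |r| = 1)" else ""))
  invisible(x)
}

#' Poisson log-linear model for contingency tables
#'
#' Frequentist stand-in for the phylogenetic Poisson mixed models: fits
#' a log-linear Poisson regression to a long-format count table by
#' iteratively reweighted least squares (convergence tolerance 1e-8, at
#' most 100 iterations, initialized at `log(count + 0.5)`). The
#' factorial hypotheses (e.g. a three-way social-level x bias x overlap
#' interaction) are then tested with [lrt()] deviance differences. No
#' phylogenetic random effects are included; results are labelled
#' accordingly.
#'
#' @param table long-format data frame with a `count` column and factor
#'   columns.
#' @param formula model formula, e.g. `count ~ social_level * bias_class`.
#' @return object of class `loglinear_fit`: list with `coefficients`,
#'   `deviance`, `df_residual`, `fitted`, `converged`, `formula`, `fit`.
#' @examples
#' tab <- expand.grid(a = c("x", "y"), b = c("u", "v"))
#' tab$count <- c(10, 20, 30, 60)
#' loglinear_fit(tab, count ~ a + b)$deviance
#' @export
loglinear_fit <- function(table, formula) {
  stopifnot(is.data.frame(table), "count" %in% all.vars(formula))
  if (any(table$count < 0)) stop("counts must be non-negative")
  table$.eta_init <- log(table$count + 0.5)
  fit <- stats::glm(formula, data = table, family = stats::poisson(),
                    etastart = .eta_init,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) stop("IRLS did not converge within 100 iterations")
  if (any(!is.finite(stats::coef(fit))))
    warning("separation: non-finite coefficients")
  structure(list(coefficients = stats::coef(fit),
                 deviance = stats::deviance(fit),
                 df_residual = stats::df.residual(fit),
                 fitted = stats::fitted(fit),
                 converged = fit$converged,
                 formula = formula, fit = fit),
            class = "loglinear_fit")
}

#' @export
print.loglinear_fit <- function(x, ...) {
  cat("<loglinear_fit>", deparse(x$formula), "| deviance",
      format(x$deviance, digits = 5), "on", x$df_residual, "df\n")
  invisible(x)
}

#' Likelihood-ratio test between nested log-linear fits
#'
#' Deviance difference between a reduced and a full model, referred to a
#' chi-square distribution on the difference in residual degrees of
#' freedom.
#'
#' @param reduced,full [loglinear_fit()] objects, `reduced` nested in
#'   `full`.
#' @return list `statistic, df, p`.
#' @export
lrt <- function(reduced, full) {
  stopifnot(inherits(reduced, "loglinear_fit"),
            inherits(full, "loglinear_fit"))
  df <- reduced$df_residual - full$df_residual
  if (df < 0) stop("`reduced` must be nested in `full` (fewer terms)")
  stat <- max(0, reduced$deviance - full$deviance)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Export model-ready tables and tree
#'
#' Writes the contingency tables of [build_tables()] as long TSVs with
#' the conventional numeric factor encodings (bias: 0 = no bias, 1 =
#' worker/nymph, 2 = queen/female adult; social level: 0 = gregarious,
#' 1 = eusocial; overlap/feature: 0 = no/intron, 1 = yes/exon) alongside
#' the species tree, ready for external phylogenetic mixed-model
#' fitting.
#'
#' @param tables named list from [build_tables()].
#' @param tree the species tree (`phylo`).
#' @param dir output directory.
#' @return invisibly, a list with the encoded tables and the file paths.
#' @export
export_model_tables <- function(tables, tree, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enc <- list(
    bias_class = c(none = 0, worker_nymph = 1, queen_female = 2),
    gene_bias = c(none = 0, worker_nymph = 1, queen_female = 2),
    social_level = c(gregarious = 0, eusocial = 1),
    te_overlap = c(no = 0, yes = 1),
    gene_overlap = c(no = 0, yes = 1),
    feature = c(intron = 0, exon = 1),
    superfamily = c("hAT" = 0, "Tc-Mariner" = 1, "Gypsy" = 2, "LINE" = 3))
  paths <- character()
  encoded <- lapply(names(tables), function(nm) {
    d <- tables[[nm]]
    for (col in intersect(names(enc), names(d)))
      d[[paste0(col, "_code")]] <- unname(enc[[col]][as.character(d[[col]])])
    f <- file.path(dir, sprintf("model_table_%s.tsv", nm))
    write_tsv(d, f)
    paths[nm] <<- f
    d
  })
  names(encoded) <- names(tables)
  tree_path <- file.path(dir, "species_tree.nwk")
  ape::write.tree(tree, tree_path)
  paths["tree"] <- tree_path
  invisible(list(tables = encoded, files = paths))
}
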