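# Two-level prediction tree: a root classifier separates long (L) from short
# (S) survival; two child classifiers refine L into LL/LS and S into SL/SS.
# Each of the three classifiers has its own fixed-size gene panel selected by
# the cross-validated discriminant on its own sample subset.

#' Fit the full hierarchical survival model
#'
#' Pipeline: impute censored survival from the KM curve, build the two-level
#' survival tree, then per split (root on all samples, L-side on the L group,
#' S-side on the S group) score all genes with the cross-validated
#' discriminant, select the top panel, and fit a generalized naive Bayes
#' classifier on that panel. Deterministic given `cfg$seed`.
#'
#' @param cohort a `cohort` from [join_cohort()] or [generate_cohort()].
#' @param cfg a [default_config()] list.
#' @return an object of class `hierarchical_model`: `root`, `left`, `right`
#'   (`gnb_model`s whose gene lists are their panels), `tree` (the training
#'   survival-tree labels) and `config`.
#' @export
fit_hierarchical <- function(cohort, cfg = default_config()) {
  if (!inherits(cohort, "cohort")) {
    stop("'cohort' must be a cohort object", call. = FALSE)
  }
  expr <- cohort$expression
  clin <- cohort$clinical
  tree <- build_survival_tree(clin$time, clin$event, clin$sample_id,
                              min_leaf = cfg$min_leaf,
                              mean_rule = cfg$mean_rule,
                              split_rule = cfg$split_rule)

  fit_split <- function(idx, labels, classes, y, split_id) {
    sub <- expr[, idx, drop = FALSE]
    scores <- score_genes(sub, labels, y, classes,
                          folds = cfg$folds, seed = cfg$seed,
                          cv_mode = cfg$cv_mode,
                          use_soft_weights = cfg$use_soft_weights,
                          log_offset = cfg$log_offset,
                          variance_floor = cfg$variance_floor)
    panel <- select_panel(rank_genes(scores), cfg$panel_size, split_id)
    fit_gnb(sub, labels, panel$gene_ids, y, classes,
            use_soft_weights = cfg$use_soft_weights,
            log_offset = cfg$log_offset,
            variance_floor = cfg$variance_floor)
  }

  root <- fit_split(seq_len(ncol(expr)), tree$level1, c("L", "S"),
                    tree$imputed_time, "root")
  iL <- which(tree$level1 == "L")
  iS <- which(tree$level1 == "S")
  left <- fit_split(iL, tree$level2[iL], c("LL", "LS"),
                    tree$imputed_within[iL], "L_side")
  right <- fit_split(iS, tree$level2[iS], c("SL", "SS"),
                     tree$imputed_within[iS], "S_side")

  structure(list(root = root, left = left, right = right,
                 tree = tree, config = cfg),
            class = "hierarchical_model")
}

#' @export
print.hierarchical_model <- function(x, ...) {
  cat("hierarchical survival model (two-level tree)\n")
  cat(sprintf("  root : L vs S   (%d-gene panel)\n", x$root$d))
  cat(sprintf("  left : LL vs LS (%d-gene panel)\n", x$left$d))
  cat(sprintf("  right: SL vs SS (%d-gene panel)\n", x$right$d))
  invisible(x)
}

.check_panel_genes <- function(model, expr) {
  needed <- unique(c(model$root$gene_ids, model$left$gene_ids,
                     model$right$gene_ids))
  missing <- setdiff(needed, rownames(expr))
  if (length(missing)) {
    stop("expression matrix is missing panel gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Predict survival subgroups (LL/LS/SL/SS) for new samples
#'
#' Hard routing: the root classifier assigns L or S; the corresponding child
#' classifier assigns the leaf. New samples are preprocessed with the
#' training transform (`log2(FPKM + offset)`); missing panel genes are an
#' error, never silently imputed.
#'
#' @param model a `hierarchical_model`.
#' @param expr FPKM matrix, genes x samples, containing all panel genes.
#' @return data.frame: `sample_id`, `level1`, `level2`, `posterior_root_L`
#'   (root-classifier probability of L) and `posterior_leaf` (probability of
#'   the assigned leaf under its child classifier).
#' @export
predict_subgroup <- function(model, expr) {
  .check_panel_genes(model, expr)
  off <- model$root$log_offset
  n <- ncol(expr)
  ids <- colnames(expr)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))

  xroot <- log2(expr[model$root$gene_ids, , drop = FALSE] + off)
  level1 <- classify(model$root, xroot)
  proot <- posterior(model$root, xroot)

  level2 <- character(n)
  post_leaf <- numeric(n)
  for (side in c("L", "S")) {
    idx <- which(level1 == side)
    if (!length(idx)) next
    child <- if (side == "L") model$left else model$right
    xc <- log2(expr[child$gene_ids, idx, drop = FALSE] + off)
    leaf <- classify(child, xc)
    pc <- posterior(child, xc)
    level2[idx] <- leaf
    post_leaf[idx] <- pc[cbind(match(leaf, child$classes), seq_along(idx))]
  }
  data.frame(sample_id = ids, level1 = level1, level2 = level2,
             posterior_root_L = proot["L", ], posterior_leaf = post_leaf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Predict the two-group (S/L) labels only
#'
#' Root classifier alone; equals the first letter of [predict_subgroup()].
#'
#' @inheritParams predict_subgroup
#' @return data.frame: `sample_id`, `level1`, `posterior_root_L`.
#' @export
predict_two_group <- function(model, expr) {
  missing <- setdiff(model$root$gene_ids, rownames(expr))
  if (length(missing)) {
    stop("expression matrix is missing panel gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- colnames(expr)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(ncol(expr)))
  xroot <- log2(expr[model$root$gene_ids, , drop = FALSE] + model$root$log_offset)
  proot <- posterior(model$root, xroot)
  data.frame(sample_id = ids,
             level1 = classify(model$root, xroot),
             posterior_root_L = proot["L", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
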