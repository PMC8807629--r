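# Cross-validated single-gene discriminant (d12) and panel selection.
#
# For each gene, a one-gene generalized naive Bayes classifier (at d = 1 the
# geometric-mean transform is the identity) is trained and tested across
# `folds` rotations of a stratified partition; d12 = 1 - pooled error rate.
# In "paper" mode the classifier is trained on ONE fold and tested on the
# union of the remaining folds; "conventional" mode is the usual inverse.

#' Score every gene with the cross-validated discriminant d12
#'
#' @param expr FPKM matrix, genes x samples.
#' @param labels two-class labels per sample.
#' @param y imputed survival times (for soft-weight estimation).
#' @param classes ordered class pair, longer-survival class first.
#' @param folds number of cross-validation folds (default 12).
#' @param seed seed for the stratified fold assignment.
#' @param cv_mode `"paper"` (train on 1 fold, test on the rest) or
#'   `"conventional"`.
#' @param use_soft_weights survival-weighted parameter estimation (default
#'   TRUE).
#' @param log_offset,variance_floor preprocessing knobs (see [fit_gnb()]).
#' @return data.frame with `gene_id`, `d12` (in [0,1]) and `smd` (absolute
#'   standardized mean difference on the log2 scale, used for tie-breaking).
#' @export
score_genes <- function(expr, labels, y = NULL,
                        classes = sort(unique(labels)),
                        folds = 12L, seed = 1L,
                        cv_mode = c("paper", "conventional"),
                        use_soft_weights = TRUE,
                        log_offset = 1, variance_floor = 1e-6) {
  cv_mode <- match.arg(cv_mode)
  n <- ncol(expr)
  if (length(labels) != n) stop("labels length must match sample count", call. = FALSE)
  if (length(classes) != 2 || !all(labels %in% classes)) {
    stop("labels must take exactly the two values in 'classes'", call. = FALSE)
  }
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (n < folds) stop("need at least as many samples as folds", call. = FALSE)
  if (use_soft_weights && is.null(y)) {
    stop("soft-weight mode requires imputed survival times 'y'", call. = FALSE)
  }

  xmat <- log2(expr + log_offset)
  fold <- .stratified_folds(labels, folds, seed)
  truth2 <- labels == classes[2]

  errors <- numeric(nrow(expr))
  total <- 0L
  used_rotations <- 0L
  for (f in seq_len(folds)) {
    train <- if (cv_mode == "paper") which(fold == f) else which(fold != f)
    test <- setdiff(seq_len(n), train)
    if (length(unique(labels[train])) < 2 || length(test) == 0) {
      warning(sprintf("rotation %d skipped: training subset lacks a class", f))
      next
    }
    priors <- c(mean(labels[train] == classes[1]),
                mean(labels[train] == classes[2]))
    w <- matrix(NA_real_, length(train), 2)
    if (use_soft_weights) {
      link <- fit_logistic_link(y[train], labels[train], classes)
      p1 <- link_prob(link, y[train])
      w[, 1] <- p1 / sum(p1)
      w[, 2] <- (1 - p1) / sum(1 - p1)
    } else {
      for (k in 1:2) {
        ind <- as.numeric(labels[train] == classes[k])
        w[, k] <- ind / sum(ind)
      }
    }
    xtr <- xmat[, train, drop = FALSE]
    xte <- xmat[, test, drop = FALSE]
    score <- vector("list", 2)
    for (k in 1:2) {
      p <- .weighted_params_matrix(xtr, w[, k], variance_floor)
      # per-gene log density of each test sample under class k (+ log prior)
      score[[k]] <- -0.5 * log(2 * pi * p$var) -
        (xte - p$mean)^2 / (2 * p$var) + log(priors[k])
    }
    pred2 <- score[[2]] > score[[1]]  # ties -> class 1, the documented rule
    errs <- pred2 != matrix(truth2[test], nrow(expr), length(test), byrow = TRUE)
    errors <- errors + rowSums(errs)
    total <- total + length(test)
    used_rotations <- used_rotations + 1L
  }
  if (used_rotations == 0L) {
    stop("all cross-validation rotations were skipped", call. = FALSE)
  }

  # tie-break statistic: absolute standardized mean difference (hard labels)
  i1 <- which(!truth2); i2 <- which(truth2)
  m1 <- rowMeans(xmat[, i1, drop = FALSE])
  m2 <- rowMeans(xmat[, i2, drop = FALSE])
  ss <- rowSums((xmat[, i1, drop = FALSE] - m1)^2) +
    rowSums((xmat[, i2, drop = FALSE] - m2)^2)
  pooled_sd <- sqrt(pmax(ss / n, variance_floor))
  data.frame(gene_id = rownames(expr),
             d12 = 1 - errors / total,
             smd = abs(m1 - m2) / pooled_sd,
             stringsAsFactors = FALSE)
}

#' Cross-validated discriminant measure of a single gene
#'
#' Convenience wrapper around [score_genes()] for one gene.
#'
#' @param x per-sample values (FPKM) of one gene.
#' @inheritParams score_genes
#' @return d12, a scalar in [0, 1].
#' @export
cv_discriminant <- function(x, labels, y = NULL,
                            classes = sort(unique(labels)),
                            folds = 12L, seed = 1L, cv_mode = "paper",
                            use_soft_weights = TRUE,
                            log_offset = 1, variance_floor = 1e-6) {
  expr <- matrix(x, nrow = 1, dimnames = list("gene", NULL))
  score_genes(expr, labels, y, classes, folds, seed, cv_mode,
              use_soft_weights, log_offset, variance_floor)$d12
}

#' Rank genes by discriminant score
#'
#' Descending d12; ties broken by larger absolute standardized mean
#' difference, then lexicographic gene id — a fully deterministic order.
#'
#' @param scores data.frame from [score_genes()].
#' @return the same data.frame sorted, with a `rank` column (1 = best).
#' @export
rank_genes <- function(scores) {
  stopifnot(all(c("gene_id", "d12") %in% colnames(scores)))
  if (is.null(scores$smd)) scores$smd <- 0
  o <- order(-scores$d12, -scores$smd, scores$gene_id)
  out <- scores[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked gene panel for one separation step
#'
#' @param ranked output of [rank_genes()].
#' @param size panel size (default 60).
#' @param split_id one of `"root"`, `"L_side"`, `"S_side"`.
#' @return list of class `gene_panel` with `split_id` and ordered `gene_ids`.
#' @export
select_panel <- function(ranked, size = 60L,
                         split_id = c("root", "L_side", "S_side")) {
  split_id <- match.arg(split_id)
  .check_scalar_number(size, "size", lower = 1, integer = TRUE)
  if (size > nrow(ranked)) {
    stop(sprintf("panel size %d exceeds number of scored genes (%d)",
                 size, nrow(ranked)), call. = FALSE)
  }
  structure(list(split_id = split_id,
                 gene_ids = ranked$gene_id[seq_len(size)]),
            class = "gene_panel")
}
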