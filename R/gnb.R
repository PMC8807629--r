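# Generalized naive Bayes: the likelihood product over d genes is replaced
# by its d-th root (the geometric mean), which preserves the argmax but keeps
# the transformed likelihood bounded away from 0 at transcriptome dimension
# (for i.i.d. U(0,1) per-gene likelihoods its expectation is 1/(1+1/d)^d,
# tending to 1/e, whereas the raw product has mean 1/2^d). All products are
# computed as sums of logs; the transform is the log-sum divided by d.

.LIK_FLOOR <- 1e-300

#' Geometric-mean likelihood transform
#'
#' `h(x, d) = x^(1/d)` applied to the product of `d` per-gene likelihoods,
#' computed as `exp(mean(log(lik)))` — the raw product is never formed.
#' Inputs are floored at 1e-300 before the log.
#'
#' @param lik vector of `d` positive per-gene likelihood values.
#' @return the geometric mean, a positive scalar.
#' @export
#' @examples
#' transform_likelihood(0.3)              # identity at d = 1
#' transform_likelihood(rep(0.25, 1408))  # 0.25 for any d
transform_likelihood <- function(lik) {
  if (length(lik) < 1 || !is.numeric(lik)) {
    stop("need at least one likelihood value", call. = FALSE)
  }
  if (any(!is.finite(lik)) || any(lik <= 0)) {
    stop("likelihood values must be positive and finite", call. = FALSE)
  }
  exp(mean(log(pmax(lik, .LIK_FLOOR))))
}

#' Per-gene Gaussian likelihoods under one class
#'
#' @param model a `gnb_model`.
#' @param x numeric vector on the model's (log2) expression scale, one value
#'   per model gene.
#' @param class one of `model$classes`.
#' @return vector of `d` positive density values (floored at 1e-300).
#' @export
gaussian_likelihood <- function(model, x, class) {
  k <- match(class, model$classes)
  if (is.na(k)) stop("unknown class: ", class, call. = FALSE)
  if (length(x) != model$d) {
    stop(sprintf("dimension mismatch: model has %d genes, x has %d",
                 model$d, length(x)), call. = FALSE)
  }
  d <- stats::dnorm(x, mean = model$means[, k], sd = sqrt(model$vars[, k]))
  pmax(d, .LIK_FLOOR)
}

# log-scores for a matrix of samples (rows = genes of the model, cols =
# samples, already log2-transformed). aggregate = "mean" gives the
# geometric-mean transform (log prior + mean per-gene log-density, used for
# the reported posterior); "sum" gives the exact untransformed log-space
# score (log prior + summed log-density, used for classification, where it
# reproduces the raw naive Bayes argmax without ever forming the product).
.gnb_logscores <- function(model, xmat, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(xmat) != model$d) {
    stop(sprintf("dimension mismatch: model has %d genes, input has %d rows",
                 model$d, nrow(xmat)), call. = FALSE)
  }
  out <- matrix(NA_real_, 2, ncol(xmat))
  for (k in 1:2) {
    m <- model$means[, k]
    v <- model$vars[, k]
    ll <- -0.5 * log(2 * pi * v) - (xmat - m)^2 / (2 * v)
    ll <- pmax(ll, log(.LIK_FLOOR))
    agg <- if (aggregate == "mean") colMeans(ll) else colSums(ll)
    out[k, ] <- log(model$priors[k]) + agg
  }
  rownames(out) <- model$classes
  out
}

#' Posterior class probabilities of the generalized classifier
#'
#' Class probabilities proportional to `prior_k * h(prod_i P(x_i|C_k), d)`.
#' All arithmetic stays in log space until the final normalization, so the
#' result is well-defined at any dimension.
#'
#' @param model a `gnb_model`.
#' @param x numeric vector (one sample, log2 scale) or matrix
#'   (genes x samples).
#' @return for a vector input, a named 2-vector summing to 1; for a matrix,
#'   a 2 x nsamples matrix. If every per-gene likelihood hit the floor for
#'   both classes the posterior equals the priors and carries attribute
#'   `degenerate = TRUE`.
#' @export
posterior <- function(model, x) {
  single <- is.null(dim(x))
  xmat <- if (single) matrix(x, ncol = 1) else x
  ls <- .gnb_logscores(model, xmat)
  degenerate <- apply(ls, 2, function(s) {
    all(s - log(model$priors) <= log(.LIK_FLOOR) + 1e-9)
  })
  post <- apply(ls, 2, function(s) exp(s - .logsumexp(s)))
  if (any(degenerate)) {
    post[, degenerate] <- model$priors
    warning("degenerate sample(s): all per-gene likelihoods at floor; posterior set to priors")
  }
  rownames(post) <- model$classes
  if (single) {
    p <- post[, 1]
    attr(p, "degenerate") <- unname(degenerate[1])
    p
  } else {
    attr(post, "degenerate") <- unname(degenerate)
    post
  }
}

#' Classify samples with a fitted generalized naive Bayes model
#'
#' The decision is the exact naive Bayes argmax, computed entirely in log
#' space (`log prior + sum of per-gene log-densities`), so it agrees with the
#' untransformed classifier at any dimension without ever forming the
#' underflowing product. The geometric-mean transform only rescales the
#' likelihood term, so with equal priors this is also the argmax of
#' [posterior()]; with unequal priors the summed rule is the one that
#' preserves the raw classifier's order, which is the behaviour the transform
#' is meant to leave untouched. An exact tie goes to the first class in model
#' order (by convention the longer-survival class).
#'
#' @param model a `gnb_model`.
#' @param x vector (one sample) or genes x samples matrix, log2 scale.
#' @return character vector of class labels.
#' @export
classify <- function(model, x) {
  xmat <- if (is.null(dim(x))) matrix(x, ncol = 1) else x
  ls <- .gnb_logscores(model, xmat, aggregate = "sum")
  model$classes[ifelse(ls[2, ] > ls[1, ], 2L, 1L)]
}

#' Logistic link between survival time and class membership
#'
#' Under equal-variance Gaussian class-conditionals for the survival time y
#' (and equal priors inside the link), Bayes' theorem gives
#' `P(C1 | y) = 1 / (1 + exp(a (y - b)))` with `b` the midpoint of the class
#' means and `a = (mu2 - mu1) / pooled variance`. `C1` is the first (longer
#' survival) class, so `a < 0` and `P(C1|y)` increases with y.
#'
#' @param y survival times (imputed).
#' @param labels class labels; `classes[1]` is taken as C1.
#' @param classes ordered pair of class labels, longer-survival class first.
#' @return list of class `logistic_link` with `a`, `b`, `classes`.
#' @export
#' @examples
#' ll <- fit_logistic_link(c(100, 90, 20, 10), c("L", "L", "S", "S"),
#'                         classes = c("L", "S"))
#' link_prob(ll, ll$b)  # 0.5 at the midpoint
fit_logistic_link <- function(y, labels, classes = sort(unique(labels))) {
  if (length(classes) != 2) stop("exactly two classes required", call. = FALSE)
  i1 <- labels == classes[1]
  i2 <- labels == classes[2]
  if (!any(i1) || !any(i2)) stop("both classes must be non-empty", call. = FALSE)
  mu1 <- mean(y[i1])
  mu2 <- mean(y[i2])
  n1 <- sum(i1); n2 <- sum(i2)
  pooled <- (sum((y[i1] - mu1)^2) + sum((y[i2] - mu2)^2)) / (n1 + n2)
  if (pooled <= 0) {
    stop("zero pooled variance: survival times carry no class information",
         call. = FALSE)
  }
  structure(list(a = (mu2 - mu1) / pooled, b = (mu1 + mu2) / 2,
                 classes = classes),
            class = "logistic_link")
}

#' Membership probability of the first class given survival time
#' @param link a `logistic_link`.
#' @param y survival time(s).
#' @return `P(C1 | y) = 1 / (1 + exp(a (y - b)))`.
#' @export
link_prob <- function(link, y) {
  1 / (1 + exp(link$a * (y - link$b)))
}

#' Survival-weighted mean and variance of one gene
#'
#' Weighted maximum-likelihood estimates with fixed weights:
#' `m_k = sum(w_i x_i)` and `sigma2_k = sum(w_i (x_i - m_k)^2)`; single pass,
#' no iteration. With hard 0/1 weights these are the ordinary class mean and
#' (biased) class variance.
#'
#' @param x per-sample values of one gene.
#' @param w non-negative weights summing to 1.
#' @param variance_floor minimum admissible variance.
#' @return list with `mean`, `var` and logical `floored`.
#' @export
weighted_class_params <- function(x, w, variance_floor = 1e-6) {
  if (length(x) != length(w)) stop("x and w lengths differ", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  floored <- v < variance_floor
  if (floored) {
    warning("variance floored (all weight on near-constant values)")
    v <- variance_floor
  }
  list(mean = m, var = v, floored = floored)
}

# Vectorized weighted parameter estimation over all genes of a matrix.
# xmat: genes x samples (log2 scale); w: normalized weights over samples.
.weighted_params_matrix <- function(xmat, w, variance_floor) {
  m <- as.vector(xmat %*% w)
  v <- as.vector((xmat - m)^2 %*% w)
  n_floored <- sum(v < variance_floor)
  v <- pmax(v, variance_floor)
  list(mean = m, var = v, n_floored = n_floored)
}

#' Fit a two-class generalized naive Bayes model
#'
#' Priors are empirical label frequencies. Per-gene Gaussian parameters are
#' estimated with survival-derived soft weights (`w_i` proportional to
#' `P(C_k | y_i)` from the logistic link) or, in hard mode, with 0/1 class
#' indicator weights. Expression is modeled after a `log2(FPKM + offset)`
#' transform.
#'
#' @param expr FPKM matrix, genes x samples (only panel genes are used).
#' @param labels two-level class labels per sample.
#' @param panel gene ids to use (rows of `expr`).
#' @param y imputed survival times per sample (used only in soft mode).
#' @param classes ordered class pair, longer-survival class first.
#' @param use_soft_weights logical, default TRUE.
#' @param log_offset offset of the log2 transform (default 1).
#' @param variance_floor minimum per-gene class variance (default 1e-6).
#' @return an object of class `gnb_model`.
#' @export
fit_gnb <- function(expr, labels, panel, y = NULL,
                    classes = sort(unique(labels)),
                    use_soft_weights = TRUE, log_offset = 1,
                    variance_floor = 1e-6) {
  if (length(classes) != 2) stop("exactly two classes required", call. = FALSE)
  missing_genes <- setdiff(panel, rownames(expr))
  if (length(missing_genes)) {
    stop("panel gene(s) absent from expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  if (use_soft_weights && is.null(y)) {
    stop("soft-weight mode requires imputed survival times 'y'", call. = FALSE)
  }
  n <- ncol(expr)
  if (length(labels) != n) stop("labels length must match sample count", call. = FALSE)
  xmat <- log2(expr[panel, , drop = FALSE] + log_offset)
  priors <- c(mean(labels == classes[1]), mean(labels == classes[2]))
  if (any(priors == 0)) stop("both classes must be non-empty", call. = FALSE)

  weights <- matrix(NA_real_, n, 2)
  if (use_soft_weights) {
    link <- fit_logistic_link(y, labels, classes)
    p1 <- link_prob(link, y)
    weights[, 1] <- p1 / sum(p1)
    weights[, 2] <- (1 - p1) / sum(1 - p1)
  } else {
    for (k in 1:2) {
      ind <- as.numeric(labels == classes[k])
      weights[, k] <- ind / sum(ind)
    }
  }

  means <- matrix(NA_real_, length(panel), 2,
                  dimnames = list(panel, classes))
  vars <- means
  n_floored <- 0
  for (k in 1:2) {
    p <- .weighted_params_matrix(xmat, weights[, k], variance_floor)
    means[, k] <- p$mean
    vars[, k] <- p$var
    n_floored <- n_floored + p$n_floored
  }
  if (n_floored > 0) {
    warning(sprintf("%d gene/class variance(s) floored at %g", n_floored,
                    variance_floor))
  }
  structure(list(classes = classes, priors = priors, gene_ids = panel,
                 means = means, vars = vars, d = length(panel),
                 log_offset = log_offset),
            class = "gnb_model")
}

#' @export
print.gnb_model <- function(x, ...) {
  cat(sprintf("generalized naive Bayes model: %s vs %s, d = %d genes, priors = (%.3f, %.3f)\n",
              x$classes[1], x$classes[2], x$d, x$priors[1], x$priors[2]))
  invisible(x)
}
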