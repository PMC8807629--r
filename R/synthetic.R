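# Synthetic cohort generator. Emulates a targeted-transcriptome cohort:
# ~1408 cancer-associated genes measured in FPKM on patients falling into
# four latent survival subgroups (LL, LS, SL, SS), with a minority of genes
# whose expression separates the subgroups and independent right censoring.

#' Configuration for the synthetic cohort generator
#'
#' @param n_per_subgroup integer vector of length 4: samples in LL, LS, SL, SS.
#' @param n_genes total number of genes (default 1408, the size of a
#'   targeted pan-cancer RNA panel).
#' @param n_informative_per_split genes planted per split (default 60,
#'   matching the panel size the classifier selects).
#' @param effect_size difference of class means for informative genes, in
#'   units of the within-class standard deviation on the log2 scale.
#' @param survival_scale exponential mean survival (months) for LL, LS, SL,
#'   SS; must satisfy LL > LS >= SL > SS.
#' @param censoring_rate expected fraction of censored samples, in [0, 1).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_subgroup = c(100L, 100L, 100L, 100L),
                             n_genes = 1408L,
                             n_informative_per_split = 60L,
                             effect_size = 1,
                             survival_scale = c(100, 40, 25, 8),
                             censoring_rate = 0.2,
                             seed = 1L) {
  if (length(n_per_subgroup) != 4 || any(n_per_subgroup < 1)) {
    stop("n_per_subgroup must be 4 positive integers", call. = FALSE)
  }
  .check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  .check_scalar_number(n_informative_per_split, "n_informative_per_split",
                       lower = 1, integer = TRUE)
  if (3 * n_informative_per_split > n_genes) {
    stop("infeasible config: 3 * n_informative_per_split exceeds n_genes",
         call. = FALSE)
  }
  .check_scalar_number(effect_size, "effect_size", lower = 0)
  if (length(survival_scale) != 4 || any(survival_scale <= 0)) {
    stop("survival_scale must be 4 positive reals (LL, LS, SL, SS)",
         call. = FALSE)
  }
  if (!(survival_scale[1] > survival_scale[2] &&
        survival_scale[2] >= survival_scale[3] &&
        survival_scale[3] > survival_scale[4])) {
    stop("survival_scale must be ordered LL > LS >= SL > SS", call. = FALSE)
  }
  .check_scalar_number(censoring_rate, "censoring_rate", lower = 0, upper = 1 - 1e-9)
  structure(list(n_per_subgroup = as.integer(n_per_subgroup),
                 n_genes = as.integer(n_genes),
                 n_informative_per_split = as.integer(n_informative_per_split),
                 effect_size = effect_size,
                 survival_scale = survival_scale,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Uniform-censoring calibration: for C ~ U(0, c) independent of T ~ Exp(mean
# theta), P(censored) = P(C < T) = theta * (1 - exp(-c/theta)) / c. The
# cohort-level censored fraction is the sample-size-weighted average over
# subgroups; c is solved by bisection on a bracket that always contains the
# root because the expression decreases from 1 (c -> 0) towards 0 (c -> Inf).
.censoring_upper_bound <- function(scales, weights, rate) {
  p_cens <- function(cc) {
    sum(weights * scales * (1 - exp(-cc / scales)) / cc)
  }
  if (rate <= 0) return(Inf)
  stats::uniroot(function(cc) p_cens(cc) - rate,
                 lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic survival cohort with planted truth
#'
#' Log2-expression is Gaussian with unit within-class standard deviation and
#' gene-specific baselines; FPKM values are `2^z - 1` (floored at 0), the
#' inverse of the classifier's `log2(FPKM + 1)` transform, so planted effects
#' live on exactly the scale the model sees. The gene architecture (baseline
#' levels and the identity of the informative genes) is derived from a fixed
#' internal stream, so two cohorts generated with different seeds are
#' independent patient samples from the *same* simulated biology and can
#' serve as training and validation sets for one model. Three disjoint informative gene
#' sets separate, respectively, {LL,LS} from {SL,SS} (root split), LL from LS
#' only, and SL from SS only; all remaining genes are identically distributed
#' across subgroups. Survival is exponential with a subgroup-specific mean and
#' censoring is independent uniform, calibrated to the configured rate.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `cohort` (a `cohort` object) and `truth` (list with
#'   per-sample `subgroup` labels and `informative_genes`, three disjoint
#'   gene-id sets named `root`, `L_side`, `S_side`).
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) {
    stop("'cfg' must come from synthetic_config()", call. = FALSE)
  }
  # Gene architecture (baseline expression levels and which genes carry each
  # split's signal) is a property of the simulated biology, shared by every
  # cohort drawn from the same config dimensions: it is generated from a
  # fixed internal stream so that cohorts with different seeds are
  # independent *patient* samples from one world, and a model trained on one
  # cohort is applicable to another.
  arch <- .with_seed(740955813L, {
    k <- cfg$n_informative_per_split
    info_idx <- sample.int(cfg$n_genes, 3L * k)
    list(sets = list(root = info_idx[seq_len(k)],
                     L_side = info_idx[k + seq_len(k)],
                     S_side = info_idx[2L * k + seq_len(k)]),
         baseline = stats::runif(cfg$n_genes, 3, 8))
  })
  .with_seed(cfg$seed, {
    n <- sum(cfg$n_per_subgroup)
    subgroups <- c("LL", "LS", "SL", "SS")
    labels <- rep(subgroups, cfg$n_per_subgroup)
    sample_ids <- sprintf("P%04d", seq_len(n))
    gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
    sets <- arch$sets

    # baseline log2 expression per gene; sigma = 1 within class
    baseline <- arch$baseline
    z <- matrix(stats::rnorm(cfg$n_genes * n, mean = 0, sd = 1),
                nrow = cfg$n_genes, ncol = n)
    z <- z + baseline
    half <- cfg$effect_size / 2
    is_L <- labels %in% c("LL", "LS")
    z[sets$root, is_L] <- z[sets$root, is_L] + half
    z[sets$root, !is_L] <- z[sets$root, !is_L] - half
    z[sets$L_side, labels == "LL"] <- z[sets$L_side, labels == "LL"] + half
    z[sets$L_side, labels == "LS"] <- z[sets$L_side, labels == "LS"] - half
    z[sets$S_side, labels == "SL"] <- z[sets$S_side, labels == "SL"] + half
    z[sets$S_side, labels == "SS"] <- z[sets$S_side, labels == "SS"] - half

    fpkm <- pmax(2^z - 1, 0)
    dimnames(fpkm) <- list(gene_ids, sample_ids)

    scale_of <- cfg$survival_scale[match(labels, subgroups)]
    surv_true <- stats::rexp(n, rate = 1 / scale_of)
    if (cfg$censoring_rate > 0) {
      cmax <- .censoring_upper_bound(cfg$survival_scale,
                                     cfg$n_per_subgroup / n,
                                     cfg$censoring_rate)
      cens <- stats::runif(n, 0, cmax)
      time <- pmin(surv_true, cens)
      event <- as.integer(surv_true <= cens)
    } else {
      time <- surv_true
      event <- rep(1L, n)
    }
    time <- pmax(time, 1e-6)  # clinical tables require time > 0

    clin <- data.frame(sample_id = sample_ids, time = time, event = event,
                       stringsAsFactors = FALSE)
    cohort <- join_cohort(fpkm, clin)
    truth <- list(
      subgroup = stats::setNames(labels, sample_ids)[cohort$clinical$sample_id],
      informative_genes = lapply(sets, function(i) gene_ids[i])
    )
    list(cohort = cohort, truth = truth)
  })
}

#' Sample vectors of independent uniform likelihood values
#'
#' Auxiliary generator for validating the geometric-mean transform: each row
#' is a vector of `d` i.i.d. U(0,1) "per-gene likelihoods".
#'
#' @param d dimension (>= 1).
#' @param n number of vectors (>= 1).
#' @param seed RNG seed.
#' @return an `n` x `d` numeric matrix.
#' @export
sample_uniform_likelihoods <- function(d, n, seed = 1L) {
  .check_scalar_number(d, "d", lower = 1, integer = TRUE)
  .check_scalar_number(n, "n", lower = 1, integer = TRUE)
  .with_seed(seed, matrix(stats::runif(n * d), nrow = n, ncol = d))
}

#' Sample labelled equicorrelated Gaussian vectors
#'
#' Two classes with means (1,...,1) and (-1,...,-1) and common covariance
#' `(1-r) I + r J`, generated via the one-factor representation
#' `sqrt(1-r) * e_i + sqrt(r) * shared`.
#'
#' @param d dimension.
#' @param r pairwise correlation in [0, 1).
#' @param n samples per class.
#' @param seed RNG seed.
#' @return list with `x` (2n x d matrix) and `class` (1 or 2 per row).
#' @export
sample_equicorrelated_gaussians <- function(d, r, n, seed = 1L) {
  .check_scalar_number(d, "d", lower = 1, integer = TRUE)
  .check_scalar_number(n, "n", lower = 1, integer = TRUE)
  if (!is.numeric(r) || length(r) != 1 || r < 0 || r >= 1) {
    stop("'r' must be a correlation in [0, 1)", call. = FALSE)
  }
  .with_seed(seed, {
    m <- 2L * n
    shared <- stats::rnorm(m)
    eps <- matrix(stats::rnorm(m * d), nrow = m, ncol = d)
    x <- sqrt(1 - r) * eps + sqrt(r) * shared
    cls <- rep(c(1L, 2L), each = n)
    x <- x + ifelse(cls == 1L, 1, -1)
    list(x = x, class = cls)
  })
}

#' Write a synthetic cohort (and its truth) to a directory
#'
#' Emits `expression.tsv`, `clinical.tsv`, `truth.tsv` (sample_id, subgroup)
#' and `genes_truth.tsv` (gene_id, split).
#'
#' @param sim output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(sim$cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(
    data.frame(sample_id = names(sim$truth$subgroup),
               subgroup = unname(sim$truth$subgroup)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- do.call(rbind, lapply(names(sim$truth$informative_genes), function(s) {
    data.frame(gene_id = sim$truth$informative_genes[[s]], split = s,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(gt, file.path(dir, "genes_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
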