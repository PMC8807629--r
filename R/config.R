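#' Default pipeline configuration
#'
#' Returns the full set of tunable knobs for the stratification pipeline,
#' with documented defaults. Any subset may be overridden via `...` or by
#' [read_config()].
#'
#' @param ... named overrides of the default values.
#'
#' @details
#' * `panel_size` (60): genes retained per separation step.
#' * `folds` (12): cross-validation folds for the single-gene discriminant.
#' * `cv_mode` (`"paper"`): `"paper"` trains on one fold and tests on the
#'   other eleven; `"conventional"` is the usual inverse.
#' * `use_soft_weights` (`TRUE`): survival-weighted Gaussian parameter
#'   estimation via the logistic link; `FALSE` uses hard class indicators.
#' * `mean_rule` (`"km"`): the "mean" of the imputation rule is the
#'   Kaplan-Meier restricted mean; `"arithmetic"` uses the plain average of
#'   observed times (sensitivity analysis only).
#' * `log_offset` (1): expression is modeled as `log2(FPKM + log_offset)`.
#' * `variance_floor` (1e-6): minimum per-gene class variance on the log2
#'   scale; `likelihood_floor` (1e-300) guards per-gene densities.
#' * `min_leaf` (10): smallest admissible survival-tree leaf.
#'
#' @return a named list of class `survclass_config`.
#' @export
#' @examples
#' cfg <- default_config(panel_size = 10, folds = 4)
#' cfg$panel_size
default_config <- function(...) {
  cfg <- list(
    panel_size      = 60L,
    folds           = 12L,
    cv_mode         = "paper",
    use_soft_weights = TRUE,
    mean_rule       = "km",
    split_rule      = "log_variance",
    log_offset      = 1,
    variance_floor  = 1e-6,
    likelihood_floor = 1e-300,
    min_leaf        = 10L,
    seed            = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  cfg$panel_size <- as.integer(cfg$panel_size)
  cfg$folds <- as.integer(cfg$folds)
  cfg$min_leaf <- as.integer(cfg$min_leaf)
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$cv_mode %in% c("paper", "conventional")) {
    stop("cv_mode must be 'paper' or 'conventional'", call. = FALSE)
  }
  if (!cfg$mean_rule %in% c("km", "arithmetic")) {
    stop("mean_rule must be 'km' or 'arithmetic'", call. = FALSE)
  }
  if (!cfg$split_rule %in% c("log_variance", "variance", "median")) {
    stop("split_rule must be 'log_variance', 'variance' or 'median'",
         call. = FALSE)
  }
  structure(cfg, class = "survclass_config")
}

#' Read a flat key = value configuration file
#'
#' The config dialect is deliberately minimal: one `key = value` pair per
#' line, `#` comments, blank lines ignored. Values are parsed as logical
#' (`true`/`false`), numeric where possible, otherwise kept as strings.
#' Unknown keys are an error (they are almost always typos).
#'
#' @param path file path.
#' @return a `survclass_config` list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      stop("malformed config line (expected 'key = value'): ", ln,
           call. = FALSE)
    }
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (tolower(val) %in% c("true", "false")) {
      val <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    overrides[[key]] <- val
  }
  do.call(default_config, overrides)
}
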