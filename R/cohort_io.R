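# Tabular I/O for expression matrices, clinical tables and cohorts.
# Dialect: tab-separated, UTF-8, mandatory header row, no quoting.

#' Load an expression matrix from a TSV file
#'
#' Reads a numeric matrix of FPKM values with gene and sample identifiers.
#' The canonical orientation is genes x samples; files written samples x
#' genes are normalized via `orientation = "samples_rows"`.
#'
#' @param path path to a tab-separated file whose first column holds row
#'   identifiers and whose header holds column identifiers.
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @return a numeric matrix, genes as rows, samples as columns.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, 2, 0, 5.5), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' write_expression(m, tf)
#' identical(load_expression(tf), m)
load_expression <- function(path, orientation = c("genes_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (ncol(df) < 2) stop("expression file needs an id column plus at least one data column",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop(sprintf("malformed numeric cell in column '%s', row '%s'",
                   colnames(body)[j], ids[bad]), call. = FALSE)
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  if (orientation == "samples_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(mat)) stop("missing expression values are not supported", call. = FALSE)
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  mat
}

#' Write an expression matrix as TSV (genes x samples)
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a clinical table
#'
#' Requires columns `sample_id`, `time` (months, > 0) and `event`
#' (1 = death observed, 0 = censored). Any extra columns are retained as
#' covariates.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with one row per sample.
#' @export
load_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  required <- c("sample_id", "time", "event")
  missing <- setdiff(required, colnames(df))
  if (length(missing)) {
    stop("clinical table missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s) in clinical table", call. = FALSE)
  }
  if (!is.numeric(df$time) || anyNA(df$time) || any(df$time <= 0)) {
    bad <- df$sample_id[which(!is.finite(df$time) | df$time <= 0)][1]
    stop("survival time must be > 0 (offending sample: ", bad, ")",
         call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    bad <- df$sample_id[which(!df$event %in% c(0, 1))][1]
    stop("event indicator must be 0 or 1 (offending sample: ", bad, ")",
         call. = FALSE)
  }
  df
}

#' Write a clinical table as TSV
#' @param clin data.frame with at least sample_id, time, event.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join expression and clinical data into a cohort
#'
#' Restricts both components to their common samples, ordered by sample id,
#' and reports what was dropped on either side. The join is idempotent.
#'
#' @param expr expression matrix (genes x samples).
#' @param clin clinical data.frame (see [load_clinical()]).
#' @return an object of class `cohort` with elements `expression`,
#'   `clinical`, and `dropped` (list of ids absent from the other side).
#' @export
join_cohort <- function(expr, clin) {
  common <- sort(intersect(colnames(expr), clin$sample_id))
  if (length(common) == 0) {
    stop("expression and clinical tables share no samples", call. = FALSE)
  }
  dropped <- list(
    expression_only = sort(setdiff(colnames(expr), common)),
    clinical_only   = sort(setdiff(clin$sample_id, common))
  )
  expr <- expr[, common, drop = FALSE]
  clin <- clin[match(common, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  structure(list(expression = expr, clinical = clin, dropped = dropped),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d genes x %d samples, %d events (%.0f%% censored)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$clinical$event),
              100 * mean(x$clinical$event == 0)))
  invisible(x)
}

# ---- model serialization ----------------------------------------------------

.MODEL_SCHEMA_VERSION <- "1.0"

.gnb_to_list <- function(m) {
  list(classes = m$classes, priors = m$priors, gene_ids = m$gene_ids,
       means = as.data.frame(m$means), vars = as.data.frame(m$vars),
       d = m$d, log_offset = m$log_offset)
}

.gnb_from_list <- function(l) {
  means <- as.matrix(as.data.frame(l$means))
  vars <- as.matrix(as.data.frame(l$vars))
  rownames(means) <- rownames(vars) <- l$gene_ids
  structure(list(classes = unlist(l$classes), priors = unlist(l$priors),
                 gene_ids = unlist(l$gene_ids), means = means, vars = vars,
                 d = as.integer(l$d), log_offset = l$log_offset),
            class = "gnb_model")
}

#' Save a fitted hierarchical survival model
#'
#' Serializes all model parameters (priors, per-gene means and variances,
#' gene panels, configuration snapshot) as versioned JSON at full float
#' precision, so that `load_model(save_model(m))` reproduces the model
#' bit-exactly.
#'
#' @param model a `hierarchical_model` from [fit_hierarchical()].
#' @param path output path.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "hierarchical_model")) {
    stop("'model' must be a fitted hierarchical_model", call. = FALSE)
  }
  payload <- list(
    schema_version = .MODEL_SCHEMA_VERSION,
    config = unclass(model$config),
    root = .gnb_to_list(model$root),
    left = .gnb_to_list(model$left),
    right = .gnb_to_list(model$right)
  )
  # I(17) significant digits: the shortest representation guaranteeing that
  # every double round-trips bit-exactly through decimal text
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a hierarchical survival model saved by [save_model()]
#' @param path path to the JSON model file.
#' @return a `hierarchical_model` object.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("failed to parse model file: ", conditionMessage(e),
                             call. = FALSE)
                      })
  if (is.null(payload$schema_version)) {
    stop("model file has no schema_version field", call. = FALSE)
  }
  if (!identical(payload$schema_version, .MODEL_SCHEMA_VERSION)) {
    stop(sprintf("model schema version mismatch: file has '%s', package expects '%s'",
                 payload$schema_version, .MODEL_SCHEMA_VERSION), call. = FALSE)
  }
  for (part in c("config", "root", "left", "right")) {
    if (is.null(payload[[part]])) {
      stop("model file is incomplete: missing '", part, "'", call. = FALSE)
    }
  }
  cfg <- do.call(default_config, payload$config)
  model <- structure(list(root = .gnb_from_list(payload$root),
                          left = .gnb_from_list(payload$left),
                          right = .gnb_from_list(payload$right),
                          config = cfg),
                     class = "hierarchical_model")
  for (part in c("root", "left", "right")) {
    m <- model[[part]]
    if (m$d != length(m$gene_ids) || nrow(m$means) != m$d) {
      stop("corrupt model file: dimension mismatch in '", part, "'",
           call. = FALSE)
    }
    if (length(m$gene_ids) != cfg$panel_size) {
      stop(sprintf("model file panel size (%d) disagrees with its recorded config (%d)",
                   length(m$gene_ids), cfg$panel_size), call. = FALSE)
    }
  }
  model
}
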