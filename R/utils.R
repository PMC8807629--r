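#' @keywords internal
"_PACKAGE"

# Shared input checks. All user-facing errors go through stop(call. = FALSE)
# so the message, not the internal call stack, is what the user sees.

.check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lower),
                 format(upper)), call. = FALSE)
  }
  invisible(x)
}

.check_times_events <- function(times, events) {
  if (length(times) != length(events)) {
    stop("'times' and 'events' must have equal length", call. = FALSE)
  }
  if (!is.numeric(times) || any(!is.finite(times)) || any(times <= 0)) {
    stop("all survival times must be finite and > 0", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("all event indicators must be 0 (censored) or 1 (death)",
         call. = FALSE)
  }
  invisible(NULL)
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic stratified fold assignment: within each class, samples are
# shuffled and dealt round-robin into `folds` folds, so class proportions are
# preserved up to rounding.
.stratified_folds <- function(labels, folds, seed) {
  n <- length(labels)
  fold <- integer(n)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run an expression with a locally-seeded RNG, restoring caller state after.
.with_seed <- function(seed, expr) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  expr
}
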