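# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
check_named_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop_fmt("%s must be a numeric matrix", what)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop_fmt("%s must have row and column names", what)
  }
  if (anyDuplicated(rownames(m))) {
    stop_fmt("%s has duplicate row names: %s", what,
             paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop_fmt("%s has duplicate column names: %s", what,
             paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  invisible(m)
}

# deterministic per-member seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(base_seed, index) {
  (as.integer(base_seed) + as.integer(index)) %% 2147483647L
}
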