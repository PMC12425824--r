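#' @importFrom methods as is
#' @importFrom stats rpois rbinom rbeta rnorm rexp runif rmultinom
#' @importFrom stats quantile wilcox.test cor p.adjust phyper pchisq sd setNames dist
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# scalar checks used by constructors; all fail loudly with the field name
check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x))
    stop_input(sprintf("'%s' must be a single positive integer", name))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input(sprintf("'%s' must be a single value in [0, 1]", name))
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_input(sprintf("'%s' must be a single positive number", name))
  as.numeric(x)
}

# column scaling for sparse or dense matrices, preserving dimnames
scale_columns <- function(X, f) {
  if (is(X, "sparseMatrix")) {
    out <- X %*% Matrix::Diagonal(x = f)
    dimnames(out) <- dimnames(X)
    out
  } else {
    sweep(X, 2L, f, "*")
  }
}

col_sums <- function(X) {
  if (is(X, "sparseMatrix")) Matrix::colSums(X) else colSums(X)
}

row_sums <- function(X) {
  if (is(X, "sparseMatrix")) Matrix::rowSums(X) else rowSums(X)
}

row_means <- function(X) {
  if (is(X, "sparseMatrix")) Matrix::rowMeans(X) else rowMeans(X)
}
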