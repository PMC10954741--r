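#' @useDynLib cladealign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Softplus and its inverse
#'
#' `softplus(x) = log(1 + exp(x))`, computed stably; `softplus_inv` is its
#' inverse `log(exp(y) - 1)` for `y > 0`.
#'
#' @param x,y numeric vectors.
#' @return numeric vector of the same length.
#' @export
softplus <- function(x) {
  # stable: log1p(exp(-|x|)) + max(x, 0)
  log1p(exp(-abs(x))) + pmax(x, 0)
}

#' @rdname softplus
#' @export
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  # log(exp(y) - 1) = y + log1p(-exp(-y))
  y + log1p(-exp(-y))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p) - log1p(-p)

## row-wise log-sum-exp of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## statistical mode of an integer vector; ties broken by the smallest value
int_mode <- function(x) {
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

ca_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

stop_ca <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## deterministic child seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
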