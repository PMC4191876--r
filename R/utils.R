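#' @useDynLib coevosite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# log(sum(exp(x))) without overflow; -Inf for empty/all -Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logit <- function(p) log(p) - log1p(-p)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a global seed
#'
#' All stochastic stages draw their own seed deterministically from one global
#' seed so that stages can be rerun independently yet reproducibly.  Seeds are
#' kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}
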