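#' @useDynLib physage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef cor cutree hclust as.dist isoreg lm.fit
#'   median p.adjust pchisq phyper pnorm prcomp predict quantile rbinom
#'   rlnorm rnbinom rnorm runif sd setNames smooth.spline var
#' @importFrom utils read.csv read.delim write.csv write.table modifyList
NULL

# Deterministic substream seed derived from a master seed and a stage name.
# Keeps every derived seed inside the 32-bit integer range.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (.Machine$integer.max - 1) + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_physage <- function(...) stop(sprintf(...), call. = FALSE)

warn_physage <- function(...) warning(sprintf(...), call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
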