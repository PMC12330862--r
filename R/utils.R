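#' @importFrom stats rnorm runif var sd cor quantile qnorm binom.test fft
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_es <- function(..., class) {
  stop(rlang::error_cnd(class = c(class, "eigenstrapr_error"),
                        message = paste0(...)))
}

#' Draw reproducible integer sub-seeds from a root seed
#'
#' All randomized stages of the package derive their RNG streams from a
#' single root seed through this helper, so one integer reproduces an
#' entire pipeline. Seeds are drawn without replacement and kept strictly
#' below 2^31 so they remain valid R integers.
#'
#' @param seed integer root seed.
#' @param n number of sub-seeds.
#' @param stream optional character tag so different stages sharing one
#'   root seed receive distinct streams.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n, stream = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  offset <- if (nzchar(stream)) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% 1000003L
  } else 0L
  withr::with_seed(as.integer((as.numeric(seed) + offset) %% 2147483646) + 1L,
                   sample.int(2147483646L, n))
}

## stable content hash used for provenance records
content_hash <- function(x) rlang::hash(x)
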