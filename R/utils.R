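#' @importFrom rlang hash abort warn .data
#' @importFrom stats rgamma runif cor sd setNames cmdscale quantile
#' @importFrom utils head combn
NULL

# Deterministic child seeds: every stage draws its own 32-bit seed from the
# study seed plus a stage tag, so adding a stage never perturbs another.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_rate <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

stop_config <- function(msg) rlang::abort(msg, class = "siteshift_config_error")
stop_data <- function(msg) rlang::abort(msg, class = "siteshift_data_error")
stop_metric <- function(msg) rlang::abort(msg, class = "siteshift_metric_error")
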