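#' @useDynLib sbifinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict rbinom rnorm runif sd pchisq pbinom
#' @importFrom utils head read.delim write.table
NULL

# Canonical vocabularies used across modules.
LABELS3 <- c("positive", "indeterminate", "negative")
SITES <- c("site_a", "site_b")
SCAN_TYPES <- c("ct", "mri")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user sessions.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit FNV-1a style hash of a string, mixed with a seed.
# Used to derive per-token RNG streams that do not depend on vocabulary order.
hash_string <- function(x, seed = 0L) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647L), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(bitwXor(as.integer(h), as.integer(seed %% 2147483647L)) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
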