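#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library code never
#' disturbs the caller's random stream. All randomised routines in the
#' package route their draws through this helper with an explicit seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash). Stays inside
# the exactly-representable double range, so it is platform independent.
string_hash31 <- function(text) {
  codes <- utf8ToInt(enc2utf8(text))
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Derive a child seed from a parent seed and a string tag, keeping the
# result strictly below 2^31.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + string_hash31(tag)) %% 2147483647)
}

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

log_msg <- function(...) message(sprintf(...))
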