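# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @useDynLib foldear, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft mvfft predict rnorm runif sd
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary Mersenne-Twister RNG state seeded with
# `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derivation; keeps results < 2^31 so they are valid
# R integer seeds.
child_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1e6) * 1009 + as.numeric(k) * 9973 + 1
  as.integer(s %% 2147483647L)
}

stop_foldear <- function(msg, class) {
  stop(structure(class = c(class, "foldear_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
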