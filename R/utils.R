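#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Evaluate an expression under a temporary RNG state derived from `seed`,
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index; stays < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
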