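#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor pnorm pt phyper qnorm rnorm runif sd setNames p.adjust
#' @importFrom utils read.delim write.table head
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All generators use this so that adding or
# reordering calls never perturbs another generator's output.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic 31-bit hash of a string (polynomial over UTF-8 bytes).
# Used to derive per-drug permutation seeds that do not depend on drug order.
string_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x) && x > 0
}
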