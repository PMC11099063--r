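#' @keywords internal
"_PACKAGE"

# Validation helper: stop with the caller-facing message when cond is FALSE.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

#' Derive a stream of independent child seeds from a single master seed
#'
#' A single experiment seed fans out to per-stage seeds so each stage is
#' independently reproducible. The rule is documented and fixed: child i is
#' `(seed * 48271 + i * 8191) mod (2^31 - 1)`, a Lehmer-style jump that keeps
#' every child a valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  check_that(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  m <- 2147483647
  s <- as.numeric(seed) %% m
  vapply(seq_len(n), function(i) {
    as.integer((s * 48271 + i * 8191) %% m)
  }, integer(1))
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
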