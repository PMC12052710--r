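# Internal helpers: seeded evaluation and small-n permutation enumeration.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package randomness never perturbs the
# user's session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 32-bit sub-seed from a base seed and an index, so per-genus
# permutation streams are independent of genus processing order.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 69069 + as.double(index) * 1234567
  as.integer(s %% 2147483647L)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9 in practice).
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 10L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}
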