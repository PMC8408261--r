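# Small-n permutation utilities shared by the order-error model and the
# order analyses. n here is the number of intermediate items (<= 3 in the
# experiments), so full enumeration is the right tool.

#' Enumerate all permutations of 1..n
#'
#' @param n Number of elements (small; enumeration is factorial in `n`).
#' @return A `factorial(n)` x `n` integer matrix, one permutation per row,
#'   in lexicographic order (row 1 is the identity).
#' @export
permutations <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- first
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Label "132"-style for a permutation given as the rank vector of the items.
perm_label <- function(p) paste(p, collapse = "")

# Weights over the n! rank patterns consistent with reported values x
# (ties shared equally among all consistent patterns). Returns a numeric
# vector of length n! aligned with the rows of permutations(n).
rank_pattern_weights <- function(x, perms = permutations(length(x))) {
  n <- length(x)
  if (anyDuplicated(x) == 0L) {
    w <- numeric(nrow(perms))
    r <- rank(x)
    hit <- which(colSums(t(perms) != r) == 0L)
    w[hit] <- 1
    return(w)
  }
  # a rank pattern p is consistent with x iff x_i < x_j implies p_i < p_j
  ok <- vapply(seq_len(nrow(perms)), function(k) {
    p <- perms[k, ]
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (x[i] < x[j] && p[i] > p[j]) return(FALSE)
      if (x[i] > x[j] && p[i] < p[j]) return(FALSE)
    }
    TRUE
  }, logical(1))
  w <- as.numeric(ok)
  w / sum(w)
}

# Row index of rank pattern p in permutations(n).
perm_index <- function(p, perms = permutations(length(p))) {
  which(colSums(t(perms) != p) == 0L)
}
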