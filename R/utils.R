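#' @keywords internal
"_PACKAGE"

# shared helpers; nothing here is exported

chk <- function(cond, ..., call. = FALSE) {
  if (!cond) stop(..., call. = call.)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

#' @noRd
lower_tri_vec <- function(m) m[lower.tri(m)]

# all permutations of 1..n, one per row; deterministic lexicographic order
perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_all(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[r, ] <- c(k, rest[sub[i, ]])
      r <- r + 1L
    }
  }
  out
}

# derive a reproducible sub-seed for a named pipeline stage
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, process = 211L, project = 307L, diversity = 401L,
            select = 503L, tree = 601L, imaging = 701L)
  base <- if (stage %in% names(offs)) offs[[stage]] else 997L
  (as.integer(seed) %% 1000000L) * 1000L + base
}
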