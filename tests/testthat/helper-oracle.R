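# Independent reference implementations used as oracles.
#
# The alignment oracles are written in plain R as recursions over prefix
# scores (memoized so whole-alphabet sweeps finish), entirely separate from
# the package's C++ dynamic programming. Their own correctness is pinned by
# `enum_global_score`, which literally enumerates every alignment of tiny
# inputs as strings.

# all gapped alignments of a and b (character vectors), linear gap penalty;
# returns the maximum total score. Exponential: lengths <= 4 only.
enum_global_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0L)
    best <- -.Machine$integer.max
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (a[i] == b[j] && a[i] != "N") match else mismatch))
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(a), length(b))
}

# memoized prefix-score recursion, linear gaps (independent of the C++ path)
oracle_global_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L && j == 0L) 0L else {
      best <- -1000000L
      if (i > 0L && j > 0L)
        best <- max(best, rec(i - 1L, j - 1L) +
                      (if (a[i] == b[j] && a[i] != "N") match else mismatch))
      if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
      if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
      best
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(n, m)
}

# local score oracle: zero-floored prefix recursion, maximum over all cells
oracle_local_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- matrix(NA_integer_, n + 1L, m + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L || j == 0L) 0L else {
      best <- 0L
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (a[i] == b[j] && a[i] != "N") match else mismatch))
      best <- max(best, rec(i - 1L, j) + gap)
      best <- max(best, rec(i, j - 1L) + gap)
      best
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  for (i in 0:n) for (j in 0:m) rec(i, j)
  max(memo)
}

# true local oracle for tiny inputs: best global score over all substrings
enum_local_score <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0L
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv))
      best <- max(best, enum_global_score(av[i1:i2], bv[j1:j2], match, mismatch, gap))
  best
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# mutate a sequence to approximately `p` per-site substitution divergence
mutate_seq <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# linear-gap params used wherever an oracle comparison is involved
linear_params <- function(gap = -2L) {
  alignment_params(match = 1L, mismatch = -1L, gap_open = gap, gap_mode = "linear")
}

# mutate exactly k distinct positions (bounds member-to-member divergence,
# unlike the per-site Bernoulli version)
mutate_seq_exact <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  for (i in sample(length(v), k))
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
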