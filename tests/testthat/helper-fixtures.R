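# seeded random fixtures and independent brute-force oracles

random_hard <- function(h, w, p = 0.5) matrix(as.double(rbinom(h * w, 1, p)), h, w)

random_soft <- function(h, w) matrix(runif(h * w), h, w)

random_hard_ensemble <- function(n, h, w, p = 0.5) {
  mask_ensemble(replicate(n, random_hard(h, w, p), simplify = FALSE))
}

random_soft_ensemble <- function(n, h, w) {
  mask_ensemble(replicate(n, random_soft(h, w), simplify = FALSE))
}

# two disjoint nonempty masks of one shape (left half vs right half)
disjoint_pair <- function(h = 4, w = 4) {
  a <- matrix(0, h, w); a[, seq_len(floor(w / 2))] <- 1
  b <- matrix(0, h, w); b[, (floor(w / 2) + 1):w] <- 1
  list(a = a, b = b)
}

# literal O(n^2) winners, independent of the package's expanded-form path
brute_winner_1d <- function(s) {
  tot <- vapply(seq_along(s), function(i) {
    acc <- 0
    for (j in seq_along(s)) acc <- acc + (s[i] - s[j])^2
    acc
  }, numeric(1))
  which.min(tot)
}

brute_winner_2d <- function(pts) {
  n <- nrow(pts)
  tot <- vapply(seq_len(n), function(i) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + sum((pts[i, ] - pts[j, ])^2)
    acc
  }, numeric(1))
  which.min(tot)
}

fused_of <- function(report) unclass(report$fused)
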