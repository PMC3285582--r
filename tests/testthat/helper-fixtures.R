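# shared fixtures and independent oracles, built in code

# brute-force O(n^3) TOM oracle: literal triple loop over the formula
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- setdiff(seq_len(n), c(i, j))
    num <- sum(a[i, u] * a[u, j]) + a[i, j]
    w[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# brute-force BH step-up: literal definition q_(i) = min_{j>=i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ps <- sort(p)
  qs <- sapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / (i:m))))
  qs[rank(p, ties.method = "first")]
}

# one-sided (greater) Fisher p by explicit hypergeometric enumeration
fisher_oracle <- function(k, m, s, N) {
  ks <- max(0, m + s - N):min(m, s)
  probs <- choose(s, ks) * choose(N - s, m - ks) / choose(N, m)
  sum(probs[ks >= k])
}

# chi-square HWE test (asymptotic oracle for the exact test)
hwe_chisq <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  p <- (2 * n_aa + n_ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
  pchisq(stat, 1, lower.tail = FALSE)
}

# exact binomial tail by full enumeration over counts
binom_tail_oracle <- function(n, p, k) {
  sum(sapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j)))
}

# random symmetric adjacency in [0,1] with unit diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  a
}

make_network <- function(a, beta = 1L, kind = "adjacency") {
  adiponet:::new_network(a, beta, kind)
}

# tiny two-tissue annotation for DE tests
toy_annotation <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", 1:n),
             subject_id = sprintf("subj%03d", 1:n),
             case_status = sample(c("case", "control"), n, TRUE),
             gender = sample(c("F", "M"), n, TRUE),
             plate = sample(c("p1", "p2"), n, TRUE),
             stringsAsFactors = FALSE)
}
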