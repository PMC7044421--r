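# Small fixtures shared across tests; everything is built in code.

# tiny abundance matrix with two groups (3 + 3 samples)
tiny_matrix <- function() {
  v <- matrix(c(1, 2, 3, 2, 3, 4,
                4, 5, 6, 8, 10, 12,
                2, 2, 2, 2, 2, 2), nrow = 3, byrow = TRUE)
  ids <- c("m1", "m2", "m3")
  samples <- c("a1", "a2", "a3", "b1", "b2", "b3")
  metabolite_matrix(v, ids, samples,
                    groups = stats::setNames(rep(c("A", "B"), each = 3), samples))
}

# exhaustive-combinatorics oracle for the hypergeometric upper tail:
# P[overlap >= ov] when drawing `l` from a universe of `u` with `s` marked
hyper_tail_oracle <- function(u, s, l, ov) {
  ks <- ov:min(s, l)
  ks <- ks[ks >= 0 & (l - ks) <= (u - s)]
  if (length(ks) == 0) return(0)
  sum(choose(s, ks) * choose(u - s, l - ks)) / choose(u, l)
}

# by-hand Benjamini-Hochberg: q(i) = min_{j >= i} m p(j) / j after sorting
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# closed-form pooled-variance two-sample t-test
student_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
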