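# Independent oracles used to validate the implementation routes.

# Atom-by-atom direct (time-domain) convolution of isotope abundance
# vectors: enumerates the isotopologue distribution without any Fourier
# step. `n15` = NULL for natural nitrogen, else the enrichment.
oracle_isotope_envelope <- function(comp, n15 = NULL, tail_cut = 1e-15) {
  vecs <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = if (is.null(n15)) c(0.99636, 0.00364) else c(1 - n15, n15),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  d <- 1
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    v <- vecs[[el]]
    for (i in seq_len(comp[[el]])) {
      out <- numeric(length(d) + length(v) - 1L)
      for (j in seq_along(v))
        out[j:(j + length(d) - 1L)] <- out[j:(j + length(d) - 1L)] +
          v[j] * d
      # drop a negligible upper tail to keep the vector short
      cum <- rev(cumsum(rev(out)))
      keep <- max(which(cum > tail_cut))
      d <- out[seq_len(keep)]
    }
  }
  d
}

# Conditional two-sided exact p-value for an NB count split, with the
# group-sum pmfs built by repeated numeric convolution of per-sample
# dnbinom vectors (never using the closed-form NB-sum identity).
oracle_nb_conditional_p <- function(sa, sb, nA, nB, phi) {
  s <- sa + sb
  if (s == 0) return(1)
  mu <- s / (nA + nB)
  single <- stats::dnbinom(0:s, size = 1 / phi, mu = mu)
  convolve_n <- function(n) {
    p <- single
    for (i in seq_len(n - 1L)) {
      out <- numeric(s + 1L)
      for (k in 0:s)
        out[k + 1L] <- sum(p[1:(k + 1L)] * single[(k + 1L):1])
      p <- out
    }
    p
  }
  pa <- convolve_n(nA); pb <- convolve_n(nB)
  joint <- pa * rev(pb)        # P(SA = a) * P(SB = s - a), a = 0..s
  joint <- joint / sum(joint)
  pobs <- joint[sa + 1L]
  min(1, sum(joint[joint <= pobs * (1 + 1e-9)]))
}

# Upper-tail hypergeometric probability by enumerating all C(N, n) draws.
oracle_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the "pathway" items
  mean(hits >= k)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
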