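# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# quadratic all-pairs cobinding count: peaks of `a` with any summit of `b`
# on the same chromosome within d_s
oracle_count_cobinding <- function(a, b, d_s) {
  pa <- a$peaks; pb <- b$peaks
  k <- 0L
  for (i in seq_len(nrow(pa))) {
    hit <- FALSE
    for (j in seq_len(nrow(pb))) {
      if (pa$chrom[i] == pb$chrom[j] &&
          abs(pa$summit[i] - pb$summit[j]) <= d_s) { hit <- TRUE; break }
    }
    if (hit) k <- k + 1L
  }
  k
}

# Poisson upper tail P(X >= k) by term-by-term summation (log-space start,
# multiplicative recurrence, stop when terms vanish)
oracle_poisson_upper <- function(k, lambda) {
  if (k <= 0) return(1)
  if (lambda == 0) return(0)
  t <- exp(-lambda + k * log(lambda) - lgamma(k + 1))
  s <- 0
  x <- k
  repeat {
    s <- s + t
    x <- x + 1
    t <- t * lambda / x
    if (t < s * 1e-18 && x > k + 10) break
  }
  min(s, 1)
}

# Poisson lower tail P(X <= k) by direct summation from 0
oracle_poisson_lower <- function(k, lambda) {
  if (k < 0) return(0)
  t <- exp(-lambda)
  s <- t
  if (k >= 1) for (x in 1:k) {
    t <- t * lambda / x
    s <- s + t
  }
  min(s, 1)
}

# hypergeometric tails by explicit combinatorial summation
oracle_hyper_point <- function(x, n, m, N) {
  exp(lchoose(n, x) + lchoose(N - n, m - x) - lchoose(N, m))
}
oracle_hyper_upper <- function(k, n, m, N) {
  hi <- min(n, m)
  if (k > hi) return(0)
  sum(vapply(k:hi, oracle_hyper_point, 0, n = n, m = m, N = N))
}
oracle_hyper_lower <- function(k, n, m, N) {
  lo <- max(0, n + m - N)
  if (k < lo) return(0)
  sum(vapply(lo:k, oracle_hyper_point, 0, n = n, m = m, N = N))
}

# exhaustive PWM scan: every offset, both strands, naive scoring
oracle_scan_best <- function(seq, p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_at <- function(chars, off) {
    s <- 0
    for (pos in seq_len(p$length)) {
      b <- chars[off + pos - 1]
      s <- s + if (b %in% rownames(p$freq)) p$freq[b, pos] else
        mean(p$freq[, pos])
    }
    (s - p$min_score) / (p$max_score - p$min_score)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  rc <- rev(unname(comp[chars]))
  W <- length(chars)
  best <- -Inf; boff <- NA; bstrand <- NA
  for (off in seq_len(W - p$length + 1)) {
    s <- score_at(chars, off)
    if (s > best + 1e-12) { best <- s; boff <- off - 1L; bstrand <- "+" }
  }
  for (off in seq_len(W - p$length + 1)) {
    s <- score_at(rc, off)
    fwd <- W - p$length - (off - 1L)
    better <- s > best + 1e-12
    tie <- abs(s - best) <= 1e-12 && bstrand == "-" && fwd < boff
    if (better || tie) { best <- s; boff <- fwd; bstrand <- "-" }
  }
  list(best_score = min(max(best, 0), 1), offset = boff, strand = bstrand)
}

# tiny experiment builder for hand-rolled summit lists
make_exp <- function(id, summits, chrom = "chr1", factor_name = id,
                     flags = character()) {
  summits <- as.integer(summits)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(summits))
  experiment(id, factor_name,
             data.frame(chrom = chrom, start = summits - 50L,
                        end = summits + 50L, summit = summits),
             flags = flags)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
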