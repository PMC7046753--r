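## Summit-proximity cobinding counts and their significance against the
## accessible-chromatin null.
##
## Two peaks from different experiments are "cobinding" when their summits
## lie on the same chromosome within d_s bp (default 150). Significance is
## assessed against a null in which each experiment's summits fall at random
## into N genome-wide accessible slots of width d_s, giving an expected
## cobinding count lambda = n*m/N.

#' Count cobinding peaks between two experiments
#'
#' Counts the peaks of `a` whose summit has at least one summit of `b` on the
#' same chromosome within `d_s` bp. Each contributing peak of `a` is paired
#' with its nearest qualifying summit of `b` (ties broken toward the lower
#' coordinate). The counting anchor is the first experiment, so `k` is
#' bounded by `min(n_peaks(a), n_peaks(b))` only through `n_peaks(a)`;
#' orientation asymmetry is limited to many-to-one matches.
#'
#' @param a,b `tf_experiment` objects, peaks sorted by (chrom, summit).
#' @param d_s maximum summit distance in bp (default 150).
#' @return list with elements `k` (count) and `pairs` (data.frame
#'   `chrom`, `a_index`, `summit_a`, `summit_b`, `distance`).
#' @export
count_cobinding <- function(a, b, d_s = 150) {
  .check_sorted(a); .check_sorted(b)
  pa <- a$peaks; pb <- b$peaks
  out <- vector("list", 0L)
  for (ch in unique(pa$chrom)) {
    ia <- which(pa$chrom == ch)
    sa <- pa$summit[ia]
    sb <- pb$summit[pb$chrom == ch]
    if (!length(sa) || !length(sb)) next
    idx <- findInterval(sa, sb)
    left  <- ifelse(idx >= 1L, sb[pmax(idx, 1L)], -Inf)
    right <- ifelse(idx < length(sb), sb[pmin(idx + 1L, length(sb))], Inf)
    dl <- sa - left
    dr <- right - sa
    nearest <- ifelse(dl <= dr, left, right)  # tie -> lower coordinate
    dist <- pmin(dl, dr)
    keep <- which(dist <= d_s)
    if (length(keep))
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, a_index = ia[keep],
                   summit_a = sa[keep], summit_b = nearest[keep],
                   distance = dist[keep])
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), a_index = integer(),
               summit_a = integer(), summit_b = integer(),
               distance = integer())
  list(k = nrow(pairs), pairs = pairs)
}

.check_sorted <- function(exp) {
  p <- exp$peaks
  if (!nrow(p)) return(invisible(TRUE))
  o <- order(p$chrom, p$summit)
  if (!identical(o, seq_len(nrow(p))))
    stop_tf("experiment ", exp$id, ": peaks are not sorted by (chrom, summit)")
  invisible(TRUE)
}

#' Null model: number of accessible binding slots
#'
#' The null assumes the genome offers `N` non-overlapping accessible regions
#' ("slots") of width `d_s` available for TF binding. Recommended defaults:
#' 250,000 for somatic mammalian cells and 500,000 for embryonic stem cells,
#' where nucleosome occupancy is markedly lower. Alternatively `N` is counted
#' from a digital-genomic-footprinting BED of fixed-width accessible regions
#' (one row per slot).
#'
#' @param mode one of `"default_somatic"`, `"default_esc"`,
#'   `"counted_from_bed"` or `"user"`.
#' @param bed accessible-regions BED3 path, required iff
#'   `mode = "counted_from_bed"`.
#' @param N slot count, required iff `mode = "user"`.
#' @param d_s slot width / summit-distance threshold in bp.
#' @return list of class `tf_null` with elements `N`, `d_s`, `source`.
#' @export
estimate_N <- function(mode = c("default_somatic", "default_esc",
                                "counted_from_bed", "user"),
                       bed = NULL, N = NULL, d_s = 150) {
  mode <- match.arg(mode)
  if (mode == "counted_from_bed") {
    if (is.null(bed)) stop_tf("mode 'counted_from_bed' requires `bed`")
    lines <- .read_tab(bed)
    if (!length(lines)) stop_tf("accessible-regions BED is empty: ", bed)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    widths <- vapply(fields, function(f)
      as.integer(f[[3]]) - as.integer(f[[2]]), 0L)
    if (any(widths != d_s))
      warning(sum(widths != d_s), " accessible region(s) have width != ",
              d_s, " bp", call. = FALSE)
    N <- length(lines)
  } else if (mode == "default_somatic") {
    N <- 250000L
  } else if (mode == "default_esc") {
    N <- 500000L
  } else if (is.null(N)) {
    stop_tf("mode 'user' requires `N`")
  }
  stopifnot(N >= 1, d_s >= 1)
  structure(list(N = as.numeric(N), d_s = d_s, source = mode),
            class = "tf_null")
}

# one-sided Poisson tail with direction chosen by k vs lambda;
# p floored at 1e-300 so downstream corrections and logs stay finite
.poisson_tail <- function(k, lambda) {
  if (k >= lambda) {
    list(p = max(stats::ppois(k - 1, lambda, lower.tail = FALSE), .P_FLOOR),
         direction = "enriched")
  } else {
    list(p = max(stats::ppois(k, lambda), .P_FLOOR), direction = "depleted")
  }
}

#' Poisson cobinding p-value
#'
#' Tail probability of observing `k` cobinding peaks under a Poisson null
#' with mean `lambda = n*m/N`: the upper tail `P(X >= k)` when `k` is at or
#' above expectation (direction `"enriched"`), the lower tail `P(X <= k)`
#' otherwise (`"depleted"`).
#'
#' @param k observed cobinding count.
#' @param n,m peak counts of the two experiments.
#' @param N number of accessible slots.
#' @return list with `p`, `direction`, `lambda`.
#' @export
poisson_pvalue <- function(k, n, m, N) {
  if (N <= 0) stop_tf("N must be positive")
  stopifnot(k >= 0, n >= 0, m >= 0)
  if (n * m == 0 && k > 0)
    stop_tf("k > 0 is impossible when one experiment has no peaks")
  if (k > min(n, m)) stop_tf("k cannot exceed min(n, m)")
  lambda <- n * m / N
  c(.poisson_tail(k, lambda), list(lambda = lambda))
}

#' Hypergeometric cobinding p-value
#'
#' Exact tail probability of `k` shared slots when experiment A occupies `n`
#' and experiment B `m` of `N` slots, drawn without replacement. Direction is
#' chosen relative to the mean `n*m/N` as in [poisson_pvalue()].
#'
#' @inheritParams poisson_pvalue
#' @return list with `p`, `direction`, `lambda` (the mean `n*m/N`).
#' @export
hypergeom_pvalue <- function(k, n, m, N) {
  if (N <= 0) stop_tf("N must be positive")
  if (n > N || m > N) stop_tf("n and m cannot exceed N")
  lo <- max(0, n + m - N); hi <- min(n, m)
  if (k < lo || k > hi)
    stop_tf("k = ", k, " outside hypergeometric support [", lo, ", ", hi, "]")
  mu <- n * m / N
  if (k >= mu) {
    p <- stats::phyper(k - 1, n, N - n, m, lower.tail = FALSE)
    dir <- "enriched"
  } else {
    p <- stats::phyper(k, n, N - n, m)
    dir <- "depleted"
  }
  list(p = max(p, .P_FLOOR), direction = dir, lambda = mu)
}

#' Bonferroni correction for all-pairs cobinding scans
#'
#' With `T` experiments all `T x T` ordered pairs are tested, so the raw
#' p-value is multiplied by `T^2` and capped at 1 (for T = 329 the factor is
#' 329^2 = 108,241). `method = "pairs"` uses the unordered-pair count
#' `T*(T-1)/2` instead.
#'
#' @param p raw p-value in (0, 1].
#' @param T number of experiments.
#' @param method `"squared"` (default) or `"pairs"`.
#' @return corrected p-value, capped at 1.
#' @export
bonferroni <- function(p, T, method = c("squared", "pairs")) {
  method <- match.arg(method)
  stopifnot(T >= 1, all(p > 0), all(p <= 1))
  fac <- if (method == "squared") T^2 else T * (T - 1) / 2
  pmin(1, p * max(fac, 1))
}

#' Pairwise cobinding test between two experiments
#'
#' Runs the full pairwise analysis: counts cobinding peaks at `d_s`, computes
#' the expected count `lambda = n*m/N`, the directional tail p-value under
#' the chosen model (Poisson by default — its p-values are the more
#' conservative of the two), the Bonferroni-corrected p over `T^2` tests and
#' the signed coassociation score `-log10 p` (enriched) or `+log10 p`
#' (depleted), with p floored at 1e-300 before taking logs.
#'
#' @param a,b `tf_experiment` objects.
#' @param null a `tf_null` from [estimate_N()].
#' @param T number of experiments in the family being scanned (default 1,
#'   i.e. no correction).
#' @param model `"poisson"` (default) or `"hypergeom"`.
#' @param d_s summit distance; defaults to the null model's slot width.
#' @return list of class `tf_cobinding` with fields `exp_a`, `exp_b`,
#'   `factor_a`, `factor_b`, `n`, `m`, `k`, `lambda`, `p_raw`, `direction`,
#'   `p_corrected`, `score`, `pairs`.
#' @export
pairwise_cobinding <- function(a, b, null, T = 1,
                               model = c("poisson", "hypergeom"),
                               d_s = NULL) {
  model <- match.arg(model)
  if (is.null(d_s)) d_s <- null$d_s
  cc <- count_cobinding(a, b, d_s = d_s)
  n <- n_peaks(a); m <- n_peaks(b)
  k <- min(cc$k, min(n, m))  # many-to-one matches cannot exceed the bound
  res <- if (model == "poisson") poisson_pvalue(k, n, m, null$N)
         else hypergeom_pvalue(k, n, m, null$N)
  p_corr <- bonferroni(res$p, T)
  structure(list(exp_a = a$id, exp_b = b$id,
                 factor_a = a$factor, factor_b = b$factor,
                 n = n, m = m, k = k, lambda = res$lambda,
                 p_raw = res$p, direction = res$direction,
                 p_corrected = p_corr,
                 score = signed_log_score(res$p, res$direction),
                 pairs = cc$pairs),
            class = "tf_cobinding")
}

#' @export
print.tf_cobinding <- function(x, ...) {
  cat(sprintf(
    "<tf_cobinding> %s vs %s: k=%d (n=%d, m=%d, lambda=%.3g), %s, p=%.3g (corrected %.3g), score=%.2f\n",
    x$exp_a, x$exp_b, x$k, x$n, x$m, x$lambda, x$direction,
    x$p_raw, x$p_corrected, x$score))
  invisible(x)
}

#' All ordered-pair cobinding tests over a set of experiments
#'
#' @param experiments named list of `tf_experiment`.
#' @param null a `tf_null`.
#' @param model,d_s passed to [pairwise_cobinding()].
#' @param T correction family size; defaults to the number of experiments.
#' @return named list (names `"idA|idB"`) of `tf_cobinding` covering every
#'   ordered pair of distinct experiments.
#' @export
all_pairwise <- function(experiments, null, model = "poisson",
                         d_s = NULL, T = length(experiments)) {
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_tf("duplicate experiment ids")
  out <- list()
  for (i in seq_along(experiments)) for (j in seq_along(experiments)) {
    if (i == j) next
    r <- pairwise_cobinding(experiments[[i]], experiments[[j]], null,
                            T = T, model = model, d_s = d_s)
    out[[paste(ids[i], ids[j], sep = "|")]] <- r
  }
  out
}

#' Flatten cobinding results into a table
#'
#' @param results list of `tf_cobinding` (e.g. from [all_pairwise()]).
#' @return data.frame with one row per result.
#' @export
cobinding_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(exp_a = r$exp_a, exp_b = r$exp_b,
               factor_a = r$factor_a, factor_b = r$factor_b,
               n = r$n, m = r$m, k = r$k, lambda = r$lambda,
               p_raw = r$p_raw, direction = r$direction,
               p_corrected = r$p_corrected, score = r$score)))
}
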