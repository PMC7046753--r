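## Score-matrix construction, clustering, and conditional (base-TF) tests
## extending pairwise cobinding to triplets and larger modules.

#' Build the signed coassociation score matrix
#'
#' Entry (i, j) is the mean of the two orientation scores of the pair — the
#' coassociation score is `-log10 p` when the overlap is above expectation
#' and `+log10 p` (negative) when below — averaged to symmetrize the small
#' counting-convention asymmetry. The diagonal is 0.
#'
#' @param results named list of `tf_cobinding` covering every ordered pair
#'   (as returned by [all_pairwise()]).
#' @return object of class `tf_score_matrix`: list with `ids` and `scores`
#'   (square numeric matrix with id dimnames).
#' @export
build_score_matrix <- function(results) {
  ids <- sort(unique(unlist(lapply(results, function(r) c(r$exp_a, r$exp_b)))))
  key <- vapply(results, function(r) paste(r$exp_a, r$exp_b, sep = "|"), "")
  names(results) <- key
  M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in ids) for (j in ids) {
    if (i == j) next
    kij <- paste(i, j, sep = "|"); kji <- paste(j, i, sep = "|")
    if (is.null(results[[kij]]) || is.null(results[[kji]]))
      stop_tf("missing pairwise result for (", i, ", ", j, ")")
    M[i, j] <- (results[[kij]]$score + results[[kji]]$score) / 2
  }
  structure(list(ids = ids, scores = M), class = "tf_score_matrix")
}

#' Cluster a coassociation score matrix
#'
#' Hierarchical clustering of experiments with distance
#' `d(i, j) = 1 - Pearson r` between their score-matrix rows. A constant
#' (zero-variance) row has undefined correlation; its distance to every
#' other experiment is set to 1 and the affected ids are flagged.
#'
#' @param M a `tf_score_matrix`.
#' @param method agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param k desired number of flat clusters (optional).
#' @param h cut height for flat clusters (optional, used when `k` is NULL).
#' @return object of class `tf_cluster_tree`: list with `hclust` (the merge
#'   history), `order` (leaf ordering for heatmap rendering), `labels`
#'   (named flat assignment, NULL when no cut requested) and
#'   `constant_rows` (flagged ids).
#' @export
cluster_scores <- function(M, method = "average", k = NULL, h = NULL) {
  S <- M$scores
  if (nrow(S) < 2L) stop_tf("need at least 2 experiments to cluster")
  sds <- apply(S, 1, stats::sd)
  const <- rownames(S)[sds == 0 | !is.finite(sds)]
  cc <- suppressWarnings(stats::cor(t(S)))
  cc[!is.finite(cc)] <- 0           # constant rows: r undefined -> distance 1
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = method)
  labels <- NULL
  if (!is.null(k)) labels <- stats::cutree(hc, k = k)
  else if (!is.null(h)) labels <- stats::cutree(hc, h = h)
  structure(list(hclust = hc, order = hc$order, labels = labels,
                 constant_rows = const),
            class = "tf_cluster_tree")
}

#' Conditional cobinding of two TFs within a base TF's peaks
#'
#' Restricts the universe to the `k_b` peaks of the base factor and asks
#' whether factors i and j co-occur there more often than chance. With
#' `k_i` (`k_j`) the number of base peaks having a summit of i (j) within
#' `d_s`, and `k_ij` the number of base peaks cobound by both
#' simultaneously, the null expectation is `lambda = k_i * k_j / k_b` and
#' the p-value is the directional Poisson tail. The statistic is symmetric
#' in i and j.
#'
#' @param base,i,j `tf_experiment` objects; `base` must have peaks.
#' @param d_s summit-distance threshold (bp).
#' @param n_tests Bonferroni family size for the corrected p (default 1;
#'   use the number of (i, j) pairs tested within the base).
#' @return list of class `tf_conditional` with fields `base`, `tf_i`,
#'   `tf_j`, `k_b`, `k_i`, `k_j`, `k_ij`, `lambda`, `p_raw`, `direction`,
#'   `p_corrected`, `score`, and `region_index` (indices of base peaks
#'   cobound by both, the region set for further iteration).
#' @export
conditional_cobinding <- function(base, i, j, d_s = 150, n_tests = 1) {
  if (n_peaks(base) == 0L) stop_tf("base experiment has no peaks")
  qi <- .base_hits(base, i, d_s)
  qj <- .base_hits(base, j, d_s)
  k_b <- n_peaks(base)
  k_i <- sum(qi); k_j <- sum(qj); k_ij <- sum(qi & qj)
  lambda <- k_i * k_j / k_b
  tl <- .poisson_tail(k_ij, lambda)
  structure(list(base = base$id, tf_i = i$id, tf_j = j$id,
                 k_b = k_b, k_i = k_i, k_j = k_j, k_ij = k_ij,
                 lambda = lambda, p_raw = tl$p, direction = tl$direction,
                 p_corrected = min(1, tl$p * max(1, n_tests)),
                 score = signed_log_score(tl$p, tl$direction),
                 region_index = which(qi & qj)),
            class = "tf_conditional")
}

# logical vector over base peaks: TRUE if >= 1 summit of `other` within d_s
.base_hits <- function(base, other, d_s) {
  hit <- logical(n_peaks(base))
  cc <- count_cobinding(base, other, d_s = d_s)
  hit[cc$pairs$a_index] <- TRUE
  hit
}

#' @export
print.tf_conditional <- function(x, ...) {
  cat(sprintf(
    "<tf_conditional> %s + %s | base %s: k_ij=%d (k_i=%d, k_j=%d, k_b=%d, lambda=%.3g), %s, p=%.3g, score=%.2f\n",
    x$tf_i, x$tf_j, x$base, x$k_ij, x$k_i, x$k_j, x$k_b, x$lambda,
    x$direction, x$p_raw, x$score))
  invisible(x)
}

#' Extend a cobinding module by one more factor
#'
#' `base_set` is a list whose first element is the base TF and whose
#' remaining elements are factors already accepted into the module. The
#' current cobinding-region set — base peaks cobound by every member — plays
#' the role of factor i in the conditional construction: with `k_r` its
#' size, `k_c` the candidate's cobinding count with the base, and `k_obs`
#' the number of current regions the candidate cobinds, the expectation is
#' `lambda = k_r * k_c / k_b` and the p-value the directional Poisson tail.
#' At the first iteration (one member) this is exactly the triplet test of
#' [conditional_cobinding()].
#'
#' @param base_set list of `tf_experiment`; first element is the base.
#' @param candidate `tf_experiment` to evaluate.
#' @param d_s summit-distance threshold (bp).
#' @param n_tests Bonferroni family size for the corrected p.
#' @return list of class `tf_conditional` (with `tf_i = "<module>"`), whose
#'   `region_index` gives the new, smaller region set including the
#'   candidate.
#' @export
iterate_module <- function(base_set, candidate, d_s = 150, n_tests = 1) {
  stopifnot(length(base_set) >= 1L)
  base <- base_set[[1]]
  if (n_peaks(base) == 0L) stop_tf("base experiment has no peaks")
  region <- rep(TRUE, n_peaks(base))
  for (memb in base_set[-1]) region <- region & .base_hits(base, memb, d_s)
  k_r <- sum(region)
  if (k_r == 0L) stop_tf("current cobinding-region set is empty")
  qc <- .base_hits(base, candidate, d_s)
  k_b <- n_peaks(base)
  k_c <- sum(qc)
  k_obs <- sum(region & qc)
  lambda <- k_r * k_c / k_b
  tl <- .poisson_tail(k_obs, lambda)
  structure(list(base = base$id, tf_i = "<module>", tf_j = candidate$id,
                 k_b = k_b, k_i = k_r, k_j = k_c, k_ij = k_obs,
                 lambda = lambda, p_raw = tl$p, direction = tl$direction,
                 p_corrected = min(1, tl$p * max(1, n_tests)),
                 score = signed_log_score(tl$p, tl$direction),
                 region_index = which(region & qc)),
            class = "tf_conditional")
}

#' Conditional coassociation heatmap anchored on a base TF
#'
#' Keeps the factors whose pairwise cobinding with the base is significant
#' at `theta` (Bonferroni-corrected p strictly below the threshold; 1e-10 by
#' default, 1e-100 being a stricter choice for strongly connected anchors),
#' computes the matrix of conditional coassociation scores over all their
#' pairs within the base's peaks, and clusters it as in [cluster_scores()].
#'
#' @param base `tf_experiment` used as anchor.
#' @param others list of candidate `tf_experiment`.
#' @param null `tf_null` for the pairwise pre-filter.
#' @param theta significance threshold on the corrected pairwise p
#'   (default 1e-10).
#' @param d_s summit-distance threshold (bp).
#' @param model pairwise model for the pre-filter.
#' @param T correction family for the pre-filter; defaults to
#'   `length(others) + 1`.
#' @param method clustering linkage.
#' @param k,h optional flat cut passed to [cluster_scores()].
#' @return list with `matrix` (a `tf_score_matrix` of conditional scores),
#'   `tree` (a `tf_cluster_tree`), `selected` (ids passing `theta`),
#'   `conditional` (list of `tf_conditional` per unordered pair) and
#'   `pairwise_p` (named corrected pairwise p-values vs the base).
#' @export
conditional_heatmap <- function(base, others, null, theta = 1e-10,
                                d_s = NULL, model = "poisson",
                                T = length(others) + 1,
                                method = "average", k = NULL, h = NULL) {
  if (is.null(d_s)) d_s <- null$d_s
  pw <- vapply(others, function(o)
    pairwise_cobinding(base, o, null, T = T, model = model,
                       d_s = d_s)$p_corrected, 0)
  names(pw) <- vapply(others, `[[`, "", "id")
  sel <- others[pw < theta]
  if (length(sel) < 2L)
    stop_tf("fewer than 2 factors pass the pairwise threshold theta = ",
            format(theta), " with base ", base$id,
            " (got ", length(sel), "); relax theta or choose another base")
  ids <- vapply(sel, `[[`, "", "id")
  n_pairs <- length(sel) * (length(sel) - 1) / 2
  M <- matrix(0, length(sel), length(sel), dimnames = list(ids, ids))
  cond <- list()
  for (a in seq_along(sel)) for (b in seq_along(sel)) {
    if (a >= b) next
    r <- conditional_cobinding(base, sel[[a]], sel[[b]], d_s = d_s,
                               n_tests = n_pairs)
    M[a, b] <- M[b, a] <- r$score
    cond[[paste(ids[a], ids[b], sep = "|")]] <- r
  }
  SM <- structure(list(ids = ids, scores = M), class = "tf_score_matrix")
  list(matrix = SM, tree = cluster_scores(SM, method = method, k = k, h = h),
       selected = ids, conditional = cond, pairwise_p = pw)
}

#' Write a score matrix as TSV
#'
#' Ids as header row and first column.
#'
#' @param M a `tf_score_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(M, path) {
  df <- data.frame(id = rownames(M$scores), M$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_score_matrix()]
#' @param path TSV path.
#' @return a `tf_score_matrix`.
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  structure(list(ids = df$id, scores = m), class = "tf_score_matrix")
}

#' Render a clustered score heatmap to PNG
#'
#' Cosmetic output: blue for enrichment, grey/black toward depletion. The
#' numeric matrices, not the colors, are the tested contract.
#'
#' @param M a `tf_score_matrix`.
#' @param tree a `tf_cluster_tree` for leaf ordering.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_score_heatmap <- function(M, tree, path) {
  ord <- tree$order
  S <- M$scores[ord, ord, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("black", "grey40", "white",
                                       "steelblue", "navy"))(101)
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(seq_len(nrow(S)), seq_len(ncol(S)),
                  t(S)[, rev(seq_len(nrow(S))), drop = FALSE],
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "coassociation scores")
  graphics::axis(1, seq_len(ncol(S)), colnames(S), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(S)), rev(rownames(S)), las = 2,
                 cex.axis = 0.7)
  invisible(path)
}
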