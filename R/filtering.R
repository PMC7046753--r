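## Redundancy filtering of ChIP-Seq datasets profiling the same factor.

#' Filter redundant experiments per factor
#'
#' Applies, independently within each factor (exact factor-name match), the
#' following rules in order:
#' \enumerate{
#'   \item experiments flagged `stimulated` are discarded;
#'   \item if both wild-type and tagged-protein experiments remain, the
#'     tagged ones are discarded;
#'   \item among remaining duplicates, any experiment with fewer than 10,000
#'     peaks and fewer than half the peaks of every other remaining duplicate
#'     is discarded;
#'   \item if more than one duplicate still remains, pairwise summit-overlap
#'     fractions `k / min(n, m)` are computed at `d_s`; if all exceed 0.66
#'     the experiment with the most peaks is kept, otherwise all remaining
#'     duplicates for that factor are discarded.
#' }
#' A factor with a single surviving experiment keeps it. The result is
#' independent of the input order.
#'
#' @param experiments list of `tf_experiment`.
#' @param d_s summit-distance threshold for the overlap fraction (bp).
#' @param min_peaks small-experiment threshold for rule 3 (default 10,000).
#' @param overlap_threshold fraction above which duplicates are considered
#'   redundant (default 0.66).
#' @return list of class `tf_filter_report` with elements `kept` (character
#'   ids) and `discarded` (data.frame `id`, `factor`, `reason`), partitioning
#'   the input ids. Reasons: `stimulated`, `tagged_duplicate`,
#'   `small_and_minor`, `redundant_fewer_peaks`, `ambiguous_overlap`.
#' @export
filter_redundant <- function(experiments, d_s = 150, min_peaks = 10000,
                             overlap_threshold = 0.66) {
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop_tf("duplicate experiment ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # canonical order makes the outcome independent of input order
  experiments <- experiments[order(ids)]
  ids <- sort(ids)
  factors <- vapply(experiments, `[[`, "", "factor")

  kept <- character()
  disc_id <- character(); disc_factor <- character(); disc_reason <- character()
  drop <- function(es, reason) {
    for (e in es) {
      disc_id <<- c(disc_id, e$id)
      disc_factor <<- c(disc_factor, e$factor)
      disc_reason <<- c(disc_reason, reason)
    }
  }

  for (fac in unique(factors)) {
    grp <- experiments[factors == fac]

    stim <- vapply(grp, function(e) "stimulated" %in% e$flags, TRUE)
    drop(grp[stim], "stimulated")
    grp <- grp[!stim]

    tagged <- vapply(grp, function(e) "tagged" %in% e$flags, TRUE)
    if (any(tagged) && any(!tagged)) {
      drop(grp[tagged], "tagged_duplicate")
      grp <- grp[!tagged]
    }

    if (length(grp) > 1L) {
      counts <- vapply(grp, n_peaks, 0L)
      minor <- vapply(seq_along(grp), function(i) {
        others <- counts[-i]
        counts[i] < min_peaks && all(counts[i] < others / 2)
      }, TRUE)
      drop(grp[minor], "small_and_minor")
      grp <- grp[!minor]; counts <- counts[!minor]
    }

    if (length(grp) > 1L) {
      counts <- vapply(grp, n_peaks, 0L)
      fracs <- c()
      for (i in seq_along(grp)) for (j in seq_along(grp)) {
        if (i >= j) next
        fracs <- c(fracs, overlap_fraction(grp[[i]], grp[[j]], d_s = d_s))
      }
      if (all(fracs > overlap_threshold)) {
        best <- which(counts == max(counts))[1]  # ties: first by id order
        drop(grp[-best], "redundant_fewer_peaks")
        grp <- grp[best]
      } else {
        drop(grp, "ambiguous_overlap")
        grp <- list()
      }
    }

    kept <- c(kept, vapply(grp, `[[`, "", "id"))
  }

  structure(list(
    kept = unname(sort(kept)),
    discarded = {
      d <- data.frame(id = disc_id, factor = disc_factor,
                      reason = disc_reason)
      d[order(d$id), , drop = FALSE]
    }), class = "tf_filter_report")
}

#' Summit-overlap fraction between two experiments
#'
#' Fraction of the smaller experiment's peaks that have a summit of the
#' larger experiment within `d_s` bp: `k / min(n, m)` with the count anchored
#' on the smaller experiment, which makes the fraction symmetric and bounded
#' by 1.
#'
#' @param a,b `tf_experiment` objects.
#' @param d_s summit-distance threshold (bp).
#' @return overlap fraction in [0, 1]; `NaN` if either experiment is empty.
#' @export
overlap_fraction <- function(a, b, d_s = 150) {
  # anchor deterministically on the smaller experiment (ties: lower id)
  if (n_peaks(b) < n_peaks(a) ||
      (n_peaks(b) == n_peaks(a) && b$id < a$id)) {
    tmp <- a; a <- b; b <- tmp
  }
  if (n_peaks(a) == 0L) return(NaN)
  count_cobinding(a, b, d_s = d_s)$k / n_peaks(a)
}

#' @export
print.tf_filter_report <- function(x, ...) {
  cat(sprintf("<tf_filter_report> kept %d, discarded %d\n",
              length(x$kept), nrow(x$discarded)))
  if (nrow(x$discarded)) print(x$discarded)
  invisible(x)
}

#' Write a filter report as TSV
#'
#' One row per input experiment with columns `id`, `factor`, `status`
#' (`kept`/`discarded`) and `reason` (empty for kept experiments).
#'
#' @param report a `tf_filter_report`.
#' @param experiments the experiments the report was computed from (used to
#'   recover factor names for kept ids).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, experiments, path) {
  facs <- vapply(experiments, `[[`, "", "factor")
  names(facs) <- vapply(experiments, `[[`, "", "id")
  rows <- rbind(
    if (length(report$kept))
      data.frame(id = report$kept, factor = unname(facs[report$kept]),
                 status = "kept", reason = ""),
    if (nrow(report$discarded))
      data.frame(id = report$discarded$id, factor = report$discarded$factor,
                 status = "discarded", reason = report$discarded$reason))
  rows <- rows[order(rows$id), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
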