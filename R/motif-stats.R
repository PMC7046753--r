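## Motif enrichment statistics (global, local, positional) and the
## motif-centered spacing analysis.

# 0-based in-window center of an instance of length L starting at `offset`
.instance_center <- function(offset, L) offset + (L - 1L) %/% 2L

# achievable range of instance centers inside a window, for the chi-square
.center_range <- function(window, L) {
  c0 <- (L - 1L) %/% 2L
  c(c0, window - L + c0)
}

#' Global motif enrichment versus a genomic background
#'
#' One-tailed two-sample z-test comparing the mean best-instance score in
#' the input regions against background regions drawn from the accessible
#' genome, using both sample variances. Small p-values indicate the motif
#' scores higher in the input regions than in the accessible background.
#'
#' @param hits best-instance table for the input regions (from
#'   [scan_regions()] / [scan_sequences()]).
#' @param background_hits best-instance table for background regions
#'   (recommended >= 200 regions).
#' @return p-value in (0, 1], with attributes `z`, `mean_input`,
#'   `mean_background`; attribute `flag = "zero_variance"` when both
#'   samples are constant (p = 1).
#' @export
global_enrichment <- function(hits, background_hits) {
  x <- hits$best_score; y <- background_hits$best_score
  if (length(y) < 200)
    warning("background has fewer than 200 regions; the z approximation ",
            "may be poor", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    p <- 1
    attr(p, "flag") <- "zero_variance"
    return(p)
  }
  se <- sqrt(vx / length(x) + vy / length(y))
  z <- (mean(x) - mean(y)) / se
  p <- max(stats::pnorm(z, lower.tail = FALSE), .P_FLOOR)
  attr(p, "z") <- z
  attr(p, "mean_input") <- mean(x)
  attr(p, "mean_background") <- mean(y)
  p
}

#' Local motif enrichment versus flanking windows
#'
#' Paired one-tailed test: for each summit the best score in the
#' summit-centered window is compared with the mean of the best scores in
#' the two immediately adjacent flanking windows of width `flank`, and a z
#' statistic is computed on the per-region differences. Small p-values
#' indicate the motif concentrates at the summit rather than its
#' surroundings.
#'
#' @param regions data.frame `chrom`, `center` (0-based summits).
#' @param genome named character vector from [read_genome_fasta()].
#' @param p a `tf_pwm`.
#' @param window summit window width (bp).
#' @param flank flanking window width (bp).
#' @return p-value in (0, 1] with attributes `z`, `n` (regions used).
#' @export
local_enrichment <- function(regions, genome, p, window = 150, flank = 150) {
  half <- window %/% 2L
  start0 <- regions$center - half
  s_in <- .extract_windows(genome, regions$chrom, start0, window)
  s_lf <- .extract_windows(genome, regions$chrom, start0 - flank, flank)
  s_rf <- .extract_windows(genome, regions$chrom, start0 + window, flank)
  keep <- which(!is.na(s_in) & !is.na(s_lf) & !is.na(s_rf))
  if (length(keep) < length(s_in))
    warning(length(s_in) - length(keep),
            " region(s) lack complete flanks; skipped", call. = FALSE)
  if (length(keep) < 2L) stop_tf("fewer than 2 usable regions")
  b_in <- scan_sequences(s_in[keep], p)$best_score
  b_lf <- scan_sequences(s_lf[keep], p)$best_score
  b_rf <- scan_sequences(s_rf[keep], p)$best_score
  d <- b_in - (b_lf + b_rf) / 2
  sdd <- stats::sd(d)
  if (sdd == 0) {
    pv <- if (mean(d) > 0) .P_FLOOR else if (mean(d) < 0) 1 else 0.5
    attr(pv, "flag") <- "zero_variance"
    attr(pv, "n") <- length(d)
    return(pv)
  }
  z <- mean(d) / (sdd / sqrt(length(d)))
  pv <- max(stats::pnorm(z, lower.tail = FALSE), .P_FLOOR)
  attr(pv, "z") <- z
  attr(pv, "n") <- length(d)
  pv
}

#' Positional bias of best motif instances
#'
#' Chi-square goodness-of-fit of best-instance center positions across
#' equal-width bins against the uniform distribution over the achievable
#' position range. A small p-value indicates the motif concentrates at
#' preferred positions (e.g. the window center, or a fixed spacing from a
#' motif anchor).
#'
#' @param positions numeric vector of 0-based in-window center positions.
#' @param window window width (bp).
#' @param bins number of equal-width bins (default 15); reduced to
#'   `max(5, floor(n/10))` (and flagged) when there are fewer positions
#'   than bins.
#' @param range positional support used for binning, default
#'   `c(0, window)`; pass the achievable center range of the motif for an
#'   exactly calibrated null.
#' @return p-value in (0, 1] with attributes `statistic`, `bins`, and
#'   `flag` when the bin count was reduced.
#' @export
positional_bias <- function(positions, window = 150, bins = 15,
                            range = c(0, window)) {
  n <- length(positions)
  if (n < 1L) stop_tf("no positions supplied")
  flag <- NULL
  if (n < bins) {
    bins <- max(5L, n %/% 10L)
    flag <- "bins_reduced"
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1L)
  breaks[1] <- breaks[1] - 1e-9
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
  obs <- tabulate(cut(positions, breaks, labels = FALSE), nbins = bins)
  if (sum(obs) < n)
    stop_tf("positions outside the stated range")
  expd <- n / bins
  stat <- sum((obs - expd)^2 / expd)
  pv <- max(stats::pchisq(stat, df = bins - 1L, lower.tail = FALSE), .P_FLOOR)
  attr(pv, "statistic") <- stat
  attr(pv, "bins") <- bins
  if (!is.null(flag)) attr(pv, "flag") <- flag
  pv
}

#' Motif-centered rescan: spacing and arrangement of partner motifs
#'
#' Re-anchors each region on the best instance of the anchor motif: regions
#' whose anchor best score falls below `quality_threshold` are discarded, the
#' remaining ones are re-centered on the anchor instance center and
#' strand-normalized so the anchor reads on the plus strand. Each partner
#' motif is then rescanned in the re-centered window; the signed
#' center-to-center distance (negative = upstream of the anchor), the
#' partner strand, the per-strand distance histogram, the modal distance(s)
#' and the positional-bias p-value of the partner positions are reported.
#'
#' @param regions data.frame `chrom`, `center`.
#' @param genome named character vector from [read_genome_fasta()].
#' @param anchor a `tf_pwm` whose best instance defines the new center.
#' @param partners list of `tf_pwm` to rescan.
#' @param window scan width (bp).
#' @param quality_threshold minimum normalized anchor score for a region to
#'   be retained (default 0.8).
#' @param bins bins for the partner positional-bias test.
#' @return named list (one element per partner) of class `tf_arrangement`:
#'   `anchor`, `partner`, `n_input`, `n_discarded`, `n_regions`, `hits`
#'   (data.frame `region`, `distance`, `strand`, `score`), `histogram`
#'   (data.frame `distance`, `strand`, `count`), `modal_distance`,
#'   `positional_bias_p`.
#' @export
motif_centered_rescan <- function(regions, genome, anchor, partners,
                                  window = 150, quality_threshold = 0.8,
                                  bins = 15) {
  stopifnot(quality_threshold > 0, quality_threshold < 1)
  if (inherits(partners, "tf_pwm")) partners <- list(partners)
  ahits <- scan_regions(regions, genome, anchor, window = window)
  keep <- ahits[ahits$best_score >= quality_threshold, , drop = FALSE]
  n_disc <- nrow(ahits) - nrow(keep)
  if (!nrow(keep))
    stop_tf("no region contains an anchor instance at quality >= ",
            quality_threshold)
  half <- window %/% 2L
  acenter <- .instance_center(keep$abs_start, anchor$length)
  nstart0 <- ifelse(keep$strand == "+", acenter - half,
                    acenter - (window - half - 1L))
  seqs <- .extract_windows(genome, keep$chrom, nstart0, window)
  ok <- which(!is.na(seqs))
  if (length(ok) < nrow(keep))
    warning(nrow(keep) - length(ok), " re-centered window(s) leave the ",
            "chromosome; skipped", call. = FALSE)
  keep <- keep[ok, , drop = FALSE]; seqs <- seqs[ok]
  minus <- keep$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))

  out <- lapply(partners, function(pp) {
    ph <- scan_sequences(seqs, pp)
    centers <- .instance_center(ph$offset, pp$length)
    dist <- centers - half
    hits <- data.frame(region = keep$region, distance = dist,
                       strand = ph$strand, score = ph$best_score)
    tab <- as.data.frame(table(distance = dist, strand = ph$strand),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    names(tab) <- c("distance", "strand", "count")
    tab$distance <- as.integer(tab$distance)
    dcount <- table(dist)
    modal <- as.integer(names(dcount)[dcount == max(dcount)])
    pb <- positional_bias(centers, window = window, bins = bins,
                          range = .center_range(window, pp$length))
    structure(list(anchor = anchor$name, partner = pp$name,
                   n_input = nrow(ahits), n_discarded = n_disc,
                   n_regions = nrow(keep), hits = hits, histogram = tab,
                   modal_distance = modal, positional_bias_p = as.numeric(pb)),
              class = "tf_arrangement")
  })
  names(out) <- vapply(partners, `[[`, "", "name")
  out
}

#' @export
print.tf_arrangement <- function(x, ...) {
  cat(sprintf(
    "<tf_arrangement> %s anchored on %s: %d regions (%d discarded), modal distance %s, positional bias p = %.3g\n",
    x$partner, x$anchor, x$n_regions, x$n_discarded,
    paste(x$modal_distance, collapse = "/"), x$positional_bias_p))
  invisible(x)
}

#' Motif enrichment report over a PWM library
#'
#' Scans the input regions and the background with every motif in the
#' library and reports, per motif, the mean and variance of best-instance
#' scores, the global enrichment p-value (plus its Bonferroni correction
#' across the library), the local enrichment p-value and the positional-bias
#' p-value, sorted by global p ascending.
#'
#' @param regions data.frame `chrom`, `center`.
#' @param genome named character vector from [read_genome_fasta()].
#' @param pwms named list of `tf_pwm`.
#' @param background_regions data.frame `chrom`, `center` of accessible
#'   background regions.
#' @param window scan width (bp).
#' @param bins bins for the positional-bias test.
#' @return data.frame of class `tf_motif_report` with columns `motif`,
#'   `mean_score`, `var_score`, `global_p`, `global_p_bonferroni`,
#'   `local_p`, `positional_bias_p`, `n_regions`; per-motif hit tables in
#'   attribute `hits`.
#' @export
enrichment_report <- function(regions, genome, pwms, background_regions,
                              window = 150, bins = 15) {
  if (!length(pwms)) stop_tf("empty PWM library")
  hits_list <- list()
  rows <- lapply(pwms, function(pp) {
    hits <- scan_regions(regions, genome, pp, window = window)
    bg <- scan_regions(background_regions, genome, pp, window = window)
    gp <- global_enrichment(hits, bg)
    lp <- local_enrichment(regions, genome, pp, window = window,
                           flank = window)
    centers <- .instance_center(hits$offset, pp$length)
    pb <- positional_bias(centers, window = window, bins = bins,
                          range = .center_range(window, pp$length))
    hits_list[[pp$name]] <<- hits
    data.frame(motif = pp$name,
               mean_score = mean(hits$best_score),
               var_score = stats::var(hits$best_score),
               global_p = as.numeric(gp),
               global_p_bonferroni = min(1, as.numeric(gp) * length(pwms)),
               local_p = as.numeric(lp),
               positional_bias_p = as.numeric(pb),
               n_regions = nrow(hits))
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$global_p), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "hits") <- hits_list
  class(rep) <- c("tf_motif_report", "data.frame")
  rep
}

#' Interpret motif enrichment for a two-TF module
#'
#' Applies the three-way reading of a motif report for a pair of module TFs:
#' if both motifs are globally enriched, both factors are called in direct
#' contact with DNA ("direct binding"); if only one is, the other factor is
#' presumed tethered by its partner ("tethered (no motif)"); if neither is,
#' there is "no direct evidence; possible third factor".
#'
#' @param report a `tf_motif_report`.
#' @param motif_a,motif_b names of the two module TFs' motifs.
#' @param alpha significance threshold applied to the Bonferroni-corrected
#'   global p (default 0.01).
#' @return named character vector of length 2 (labels for `motif_a` and
#'   `motif_b`), with attribute `case` in 1:3.
#' @export
interpret_motif_roles <- function(report, motif_a, motif_b, alpha = 0.01) {
  get_p <- function(m) {
    row <- report[report$motif == m, , drop = FALSE]
    if (!nrow(row)) stop_tf("motif ", m, " not in report")
    row$global_p_bonferroni
  }
  sig <- c(get_p(motif_a), get_p(motif_b)) < alpha
  labels <- if (all(sig)) {
    structure(c("direct binding", "direct binding"), case = 1L)
  } else if (any(sig)) {
    l <- ifelse(sig, "direct binding", "tethered (no motif)")
    structure(l, case = 2L)
  } else {
    structure(rep("no direct evidence; possible third factor", 2), case = 3L)
  }
  names(labels) <- c(motif_a, motif_b)
  labels
}

#' Write a motif arrangement histogram as TSV
#' @param arr a `tf_arrangement`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_arrangement <- function(arr, path) {
  utils::write.table(arr$histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
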