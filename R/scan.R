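## PWM scanning of fixed-width windows.
##
## A motif instance at an offset is scored as the sum over positions of the
## frequency of the observed base; the raw score is min/max-normalized to
## [0, 1] using the per-position frequency minima and maxima, so the
## consensus scores 1 and the anti-consensus 0. Ambiguous bases (N)
## contribute the column mean frequency.

.CODE_COMP <- c(4L, 3L, 2L, 1L, 5L)  # A<->T, C<->G, N->N

# character vector of equal-length sequences -> integer code matrix
# (n x width): A=1 C=2 G=3 T=4, anything else 5
encode_sequences <- function(seqs) {
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop_tf("sequences must all have the same width")
  ch <- strsplit(toupper(seqs), "", fixed = TRUE)
  codes <- match(unlist(ch), .BASES)
  codes[is.na(codes)] <- 5L
  matrix(codes, nrow = length(seqs), ncol = w, byrow = TRUE)
}

# raw frequency-sum scores for every offset: n x (W - L + 1)
.raw_scores <- function(C, F5) {
  n <- nrow(C); W <- ncol(C); L <- ncol(F5)
  noff <- W - L + 1L
  S <- matrix(0, n, noff)
  for (o in seq_len(noff)) {
    s <- numeric(n)
    for (p in seq_len(L)) s <- s + F5[, p][C[, o + p - 1L]]
    S[, o] <- s
  }
  S
}

#' Scan equal-width sequences with a PWM
#'
#' Evaluates every offset on both strands and keeps the best instance per
#' sequence. Strand ties are broken toward `+`; offset ties toward the lower
#' (forward-coordinate) offset.
#'
#' @param seqs character vector of equal-width sequences (ACGT, `N` scored
#'   at the column mean).
#' @param p a `tf_pwm`.
#' @param both_strands scan the reverse complement as well (default TRUE);
#'   set FALSE for strand-specific scoring.
#' @return data.frame with one row per sequence: `region`, `best_score`
#'   (normalized to [0, 1]), `offset` (0-based forward start of the best
#'   instance) and `strand`.
#' @export
scan_sequences <- function(seqs, p, both_strands = TRUE) {
  stopifnot(inherits(p, "tf_pwm"))
  if (!length(seqs))
    return(data.frame(region = integer(), best_score = numeric(),
                      offset = integer(), strand = character()))
  C <- encode_sequences(seqs)
  W <- ncol(C); L <- p$length
  if (W < L) stop_tf("window (", W, " bp) shorter than motif (", L, " bp)")
  F5 <- rbind(p$freq, colMeans(p$freq))
  Sp <- .raw_scores(C, F5)
  Sm <- if (both_strands) {
    Crc <- matrix(.CODE_COMP[C], nrow(C), W)[, W:1, drop = FALSE]
    .raw_scores(Crc, F5)
  } else {
    matrix(-Inf, nrow(Sp), ncol(Sp))
  }
  denom <- p$max_score - p$min_score
  if (denom <= 0) denom <- 1
  norm <- function(x) pmin(1, pmax(0, (x - p$min_score) / denom))

  n <- nrow(C)
  best_score <- numeric(n); offset <- integer(n); strand <- character(n)
  for (r in seq_len(n)) {
    sp <- Sp[r, ]; sm <- Sm[r, ]
    bp <- max(sp); bm <- max(sm)
    if (bp >= bm) {                       # strand tie -> +
      o <- which.max(sp)                  # first max -> lowest offset
      best_score[r] <- norm(bp); offset[r] <- o - 1L; strand[r] <- "+"
    } else {
      # rc offset o' maps to forward 0-based offset W - L - o' + 1;
      # lowest forward offset = highest o' -> take the last max
      om <- length(sm) - which.max(rev(sm)) + 1L
      best_score[r] <- norm(bm)
      offset[r] <- W - L - om + 1L
      strand[r] <- "-"
    }
  }
  data.frame(region = seq_len(n), best_score = best_score,
             offset = offset, strand = strand)
}

#' Read a genome FASTA into memory
#'
#' @param path FASTA path.
#' @return named character vector, one element per chromosome (name = first
#'   token of the FASTA header).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  seqs
}

# extract windows [start0, start0 + width) from an in-memory genome;
# NA where the window leaves the chromosome
.extract_windows <- function(genome, chrom, start0, width) {
  out <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) next
    len <- nchar(genome[[ch]])
    sel <- which(chrom == ch)
    ok <- sel[start0[sel] >= 0 & start0[sel] + width <= len]
    if (length(ok))
      out[ok] <- substring(genome[[ch]], start0[ok] + 1L,
                           start0[ok] + width)
  }
  out
}

#' Scan summit-centered genomic windows with a PWM
#'
#' Extracts the `window`-bp region centered on each summit (the summit sits
#' at 0-based in-window position `floor(window/2)`) and scans it with
#' [scan_sequences()]. Windows extending past a chromosome end are skipped
#' with a warning and recorded in the `skipped` attribute.
#'
#' @param regions data.frame with columns `chrom` and `center` (0-based
#'   summit positions), e.g. from [summit_regions()].
#' @param genome named character vector from [read_genome_fasta()].
#' @param p a `tf_pwm`.
#' @param window scan width in bp (default 150).
#' @return data.frame as in [scan_sequences()] plus columns `chrom`,
#'   `center` and `abs_start` (0-based genomic start of the best instance);
#'   `region` indexes rows of `regions`. Attribute `skipped` holds the
#'   indices of dropped regions.
#' @export
scan_regions <- function(regions, genome, p, window = 150) {
  stopifnot(all(c("chrom", "center") %in% names(regions)))
  half <- window %/% 2L
  start0 <- regions$center - half
  seqs <- .extract_windows(genome, regions$chrom, start0, window)
  skipped <- which(is.na(seqs))
  if (length(skipped))
    warning(length(skipped), " region(s) extend past a chromosome end; ",
            "skipped", call. = FALSE)
  keep <- which(!is.na(seqs))
  hits <- scan_sequences(seqs[keep], p)
  hits$region <- keep
  hits$chrom <- regions$chrom[keep]
  hits$center <- regions$center[keep]
  hits$abs_start <- start0[keep] + hits$offset
  attr(hits, "skipped") <- skipped
  hits
}

#' Regions table from experiment summits
#'
#' @param exp a `tf_experiment` (or the path of a BED3 summit file).
#' @return data.frame with columns `chrom`, `center` suitable for
#'   [scan_regions()].
#' @export
summit_regions <- function(exp) {
  if (is.character(exp)) exp <- read_narrowpeak(exp)
  data.frame(chrom = exp$peaks$chrom, center = exp$peaks$summit)
}
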