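## Position weight matrices: construction, JASPAR text I/O, consensus.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight model from a count matrix
#'
#' Frequencies are obtained by adding a pseudocount of 1% of the column
#' total, apportioned uniformly over the four bases (each cell gains
#' `0.01 * colsum / 4`), then normalizing each column to 1. The per-position
#' minima and maxima of the frequency matrix define the min/max score
#' normalization used by the scanner, so the per-position argmax (consensus)
#' string scores exactly 1 and the per-position argmin (anti-consensus)
#' string exactly 0.
#'
#' @param name motif identifier.
#' @param counts 4 x L non-negative matrix, rows A, C, G, T; L >= 4.
#' @return object of class `tf_pwm` with fields `name`, `counts`, `freq`,
#'   `min_score`, `max_score`, `length`.
#' @export
pwm <- function(name, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L)
    stop_tf("PWM counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 4L)
    stop_tf("PWM must have length >= 4 (got ", ncol(counts), ")")
  if (any(counts < 0)) stop_tf("PWM counts must be non-negative")
  rownames(counts) <- .BASES
  tot <- colSums(counts)
  if (any(tot <= 0)) stop_tf("PWM has an empty column")
  adj <- sweep(counts, 2, 0.01 * tot / 4, `+`)
  freq <- sweep(adj, 2, colSums(adj), `/`)
  structure(list(name = name, counts = counts, freq = freq,
                 min_score = sum(apply(freq, 2, min)),
                 max_score = sum(apply(freq, 2, max)),
                 length = ncol(counts)),
            class = "tf_pwm")
}

#' @export
print.tf_pwm <- function(x, ...) {
  cat(sprintf("<tf_pwm> %s, length %d, consensus %s\n",
              x$name, x$length, consensus(x)))
  invisible(x)
}

#' Consensus and anti-consensus strings of a PWM
#'
#' Per-position argmax (resp. argmin) base, ties broken toward the first
#' base in A, C, G, T order.
#'
#' @param x a `tf_pwm`.
#' @return a single string of length `x$length`.
#' @export
consensus <- function(x) {
  paste(.BASES[apply(x$freq, 2, which.max)], collapse = "")
}

#' @rdname consensus
#' @export
anticonsensus <- function(x) {
  paste(.BASES[apply(x$freq, 2, which.min)], collapse = "")
}

#' Read a JASPAR-format PFM file
#'
#' Text format: a header line `>ID NAME` followed by four rows, one per base
#' in A, C, G, T order, with counts optionally wrapped in brackets, e.g.
#' `A  [ 10  3  0 ... ]`.
#'
#' @param path file path.
#' @return named list of `tf_pwm`.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop_tf("no JASPAR records in ", path)
  out <- list()
  for (hi in seq_along(heads)) {
    h <- heads[hi]
    stop_line <- if (hi < length(heads)) heads[hi + 1] - 1 else length(lines)
    body <- lines[(h + 1):stop_line]
    if (length(body) != 4L)
      stop_tf("motif at line ", h, " of ", path,
              ": expected 4 base rows, got ", length(body))
    tokens <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    name <- if (length(tokens) >= 2) paste(tokens[1], tokens[2]) else tokens[1]
    rows <- lapply(seq_along(body), function(bi) {
      txt <- gsub("\\[|\\]", " ", body[bi])
      txt <- sub(paste0("^", .BASES[bi], "\\s+"), "", txt)
      txt <- sub("^[ACGTacgt]\\s+", "", txt)  # tolerate any base label
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1]]))
      if (anyNA(vals))
        stop_tf("motif ", name, ": non-numeric counts in row ", .BASES[bi])
      vals
    })
    if (length(unique(lengths(rows))) != 1L)
      stop_tf("motif ", name, ": count rows have unequal lengths")
    out[[name]] <- pwm(name, do.call(rbind, rows))
  }
  out
}

#' Write PWMs in JASPAR text format
#'
#' Inverse of [read_jaspar()]; counts round-trip exactly.
#'
#' @param pwms list of `tf_pwm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      vapply(1:4, function(bi)
        sprintf("%s  [ %s ]", .BASES[bi],
                paste(format(p$counts[bi, ], trim = TRUE, scientific = FALSE),
                      collapse = " ")), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
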