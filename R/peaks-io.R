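## Peak / experiment containers and narrowPeak / BED summit input-output.
##
## Coordinates are 0-based half-open throughout (BED convention); a summit is
## a single 0-based position with start <= summit < end.

#' Construct a ChIP-Seq experiment
#'
#' An experiment bundles one ChIP-Seq dataset: a unique identifier, the name
#' of the profiled factor, its peak table and optional metadata flags.
#' Peaks are stored sorted by (chrom, summit), the order every downstream
#' summit-proximity operation relies on.
#'
#' @param id unique dataset identifier.
#' @param factor_name TF or cofactor name.
#' @param peaks data.frame with columns `chrom`, `start`, `end`, `summit`
#'   and optionally `signal` (default 0).
#' @param flags character vector of metadata tags, a subset of
#'   `c("stimulated", "tagged", "wildtype")`.
#' @return an object of class `tf_experiment`.
#' @export
experiment <- function(id, factor_name, peaks, flags = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(factor_name), length(factor_name) == 1L)
  if (!is.data.frame(peaks))
    stop_tf("`peaks` must be a data.frame")
  need <- c("chrom", "start", "end", "summit")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop_tf("peak table is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(peaks$signal)) peaks$signal <- rep(0, nrow(peaks))
  peaks <- peaks[, c("chrom", "start", "end", "summit", "signal")]
  for (col in c("start", "end", "summit"))
    peaks[[col]] <- as.integer(peaks[[col]])
  if (nrow(peaks)) {
    bad <- which(!(peaks$start < peaks$end &
                   peaks$start <= peaks$summit &
                   peaks$summit < peaks$end &
                   nzchar(peaks$chrom)))
    if (length(bad))
      stop_tf("invalid peak(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
              ": need start < end and start <= summit < end")
    peaks <- peaks[order(peaks$chrom, peaks$summit, peaks$start), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
  }
  unknown <- setdiff(flags, c("stimulated", "tagged", "wildtype"))
  if (length(unknown))
    stop_tf("unknown flag(s): ", paste(unknown, collapse = ", "))
  structure(list(id = id, factor = factor_name, peaks = peaks,
                 flags = unique(flags)),
            class = "tf_experiment")
}

#' @export
print.tf_experiment <- function(x, ...) {
  cat(sprintf("<tf_experiment> %s (%s): %d peaks%s\n", x$id, x$factor,
              n_peaks(x),
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Number of peaks in an experiment
#' @param exp a `tf_experiment`.
#' @return integer peak count.
#' @export
n_peaks <- function(exp) nrow(exp$peaks)

#' Summit positions of an experiment, optionally for one chromosome
#' @param exp a `tf_experiment`.
#' @param chrom optional chromosome name.
#' @return integer vector of 0-based summit positions, sorted.
#' @export
summits <- function(exp, chrom = NULL) {
  p <- exp$peaks
  if (!is.null(chrom)) p <- p[p$chrom == chrom, , drop = FALSE]
  p$summit
}

.read_tab <- function(path) {
  if (!file.exists(path)) stop_tf("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  lines
}

#' Read a narrowPeak or BED summit file
#'
#' Auto-detects the format from the column count: rows with >= 10
#' tab-separated columns are parsed as ENCODE narrowPeak (column 10 is the
#' summit offset from `start`; an offset of -1 falls back to the region
#' midpoint), rows with 3-4 columns as plain BED whose intervals carry the
#' summit (for 1-bp intervals the summit is `start`, otherwise the midpoint).
#'
#' @param path file path.
#' @param id experiment identifier; defaults to the file name without
#'   extension.
#' @param factor_name factor name; defaults to `id`.
#' @param flags metadata flags passed to [experiment()].
#' @return a `tf_experiment` with peaks sorted by (chrom, summit).
#' @export
read_narrowpeak <- function(path, id = NULL, factor_name = NULL,
                            flags = character()) {
  lines <- .read_tab(path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(factor_name)) factor_name <- id
  if (!length(lines)) {
    return(experiment(id, factor_name,
                      data.frame(chrom = character(), start = integer(),
                                 end = integer(), summit = integer()),
                      flags))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  parse_fail <- function(i, why)
    stop_tf("parse error at line ", i, " of ", path, ": ", why)
  if (all(ncols >= 10L)) {
    mode <- "narrowPeak"
  } else if (all(ncols %in% c(3L, 4L))) {
    mode <- "bed"
  } else {
    parse_fail(which(ncols < 10L & !(ncols %in% c(3L, 4L)))[1],
               "expected 10+ columns (narrowPeak) or 3-4 columns (BED)")
  }
  n <- length(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) parse_fail(bad[1], "non-numeric coordinates")
  if (mode == "narrowPeak") {
    signal <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 7L)))
    offset <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    bad <- which(is.na(offset))
    if (length(bad)) parse_fail(bad[1], "non-numeric summit offset")
    summit <- ifelse(offset >= 0L, start + offset,
                     (start + end) %/% 2L)
    signal[is.na(signal)] <- 0
  } else {
    summit <- ifelse(end - start == 1L, start, (start + end) %/% 2L)
    signal <- rep(0, n)
  }
  bad <- which(!(start <= summit & summit < end))
  if (length(bad))
    stop_tf("validation error at line ", bad[1], " of ", path,
            ": summit outside [start, end)")
  experiment(id, factor_name,
             data.frame(chrom = chrom, start = start, end = end,
                        summit = summit, signal = signal),
             flags)
}

#' Write experiment summits as BED3
#'
#' Each peak becomes one row `chrom  summit  summit+1`, sorted by
#' (chrom, summit) — the 1-bp summit format the motif layer takes as input.
#' Round-trips through [read_narrowpeak()] with identical summit positions.
#'
#' @param exp a `tf_experiment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summits <- function(exp, path) {
  p <- exp$peaks
  lines <- if (nrow(p))
    sprintf("%s\t%d\t%d", p$chrom, p$summit, p$summit + 1L) else character()
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_tf("cannot write summit file: ", path)
  invisible(path)
}

#' Read an experiment metadata table
#'
#' Tab-separated with header columns `id`, `factor`, `flags` (flags
#' comma-separated, may be empty).
#'
#' @param path metadata TSV path.
#' @return data.frame with columns `id`, `factor` and list-column `flags`.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "factor")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop_tf("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$id))
    stop_tf("duplicate experiment ids in metadata: ",
            paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  if (is.null(md$flags)) md$flags <- ""
  md$flags <- as.character(md$flags)
  md$flags[is.na(md$flags)] <- ""
  md$flags <- lapply(strsplit(md$flags, ",", fixed = TRUE),
                     function(x) trimws(x[nzchar(trimws(x))]))
  md
}

#' Load all experiments named in a metadata table
#'
#' @param metadata path to a metadata TSV (see [read_metadata()]) or an
#'   already-parsed metadata data.frame.
#' @param peak_dir directory holding one peak file per experiment, named
#'   `<id>.narrowPeak`, `<id>.bed` or `<id>` (first match wins).
#' @return named list of `tf_experiment`.
#' @export
read_experiments <- function(metadata, peak_dir) {
  md <- if (is.character(metadata)) read_metadata(metadata) else metadata
  exps <- lapply(seq_len(nrow(md)), function(i) {
    id <- md$id[i]
    cand <- file.path(peak_dir, c(paste0(id, ".narrowPeak"),
                                  paste0(id, ".bed"), id))
    hit <- cand[file.exists(cand)]
    if (!length(hit)) stop_tf("no peak file found for experiment ", id)
    read_narrowpeak(hit[1], id = id, factor_name = md$factor[i],
                    flags = md$flags[[i]])
  })
  names(exps) <- md$id
  exps
}
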