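## Seeded synthetic fixtures: a toy genome with accessible slots, peak sets
## with planted cobinding / tethering structure, and motif-planted sequence.
##
## Accessible slots lie on a deterministic grid with a gap of at least one
## slot width between consecutive slots, so two summits are within d_s of
## one another exactly when they occupy the same slot — the fixture realizes
## the null model's "same accessible region" reading of cobinding exactly.
## Null experiments place one summit per uniformly chosen slot without
## replacement, jittered around the slot center.

#' Specify a synthetic fixture
#'
#' @param seed RNG seed; the whole bundle is deterministic given the spec.
#' @param n_slots number of accessible slots (the null model's N).
#' @param slot_width slot width in bp (the summit-distance threshold d_s).
#' @param slot_gap inaccessible gap between consecutive slots (bp); must be
#'   at least `slot_width` so distinct slots cannot produce cobinding calls.
#' @param margin sequence padding before the first and after the last slot
#'   (bp), sized so summit windows and their flanks stay on the chromosome.
#' @param jitter summit jitter around planted positions (uniform on
#'   `-jitter..jitter`, default 30 bp, reflecting how close summits track
#'   the underlying binding site).
#' @param experiments list of experiment descriptors, each a list with
#'   `id`, `factor`, `n_peaks` and optional `flags`.
#' @param cobind list of planted pairwise relations, each a list with `a`
#'   (the experiment receiving planted summits), `b` (the target experiment,
#'   generated earlier in `experiments`), `fraction` of a's peaks planted
#'   next to b's summits, and optional `jitter`.
#' @param tether list of planted tethered modules, each a list with `base`,
#'   `partners` (>= 2 ids), and `fraction` of the base peaks shared by all
#'   partners; partners' remaining peaks are placed outside the base and
#'   disjointly from each other, so the partners co-occur only inside base
#'   peaks.
#' @param spacing list of planted motif arrangements, each a list with
#'   `experiment`, `anchor` and `partner` (motif names in `motifs`),
#'   `distance` (signed bp between instance centers), optional `fraction`
#'   (default 1) and `partner_strand` (`"+"`/`"-"`).
#' @param motifs named list of `tf_pwm` available for planting and emitted
#'   with the bundle.
#' @param with_sequence generate genome sequence (required for the motif
#'   layer; defaults to TRUE when motifs or spacing relations are present).
#' @return a validated list of class `tf_fixture_spec`.
#' @export
fixture_spec <- function(seed, n_slots = 1000, slot_width = 150,
                         slot_gap = 150, margin = 450, jitter = 30,
                         experiments = list(), cobind = list(),
                         tether = list(), spacing = list(), motifs = list(),
                         with_sequence = length(spacing) > 0 ||
                           length(motifs) > 0) {
  stopifnot(n_slots >= 1, slot_width >= 1, slot_gap >= slot_width,
            jitter >= 0, 2 * jitter < slot_width)
  ids <- vapply(experiments, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_tf("duplicate experiment ids in fixture spec")
  for (e in experiments) {
    if (e$n_peaks > n_slots)
      stop_tf("experiment ", e$id, " requests more peaks (", e$n_peaks,
              ") than slots (", n_slots, ")")
  }
  for (r in c(cobind, tether))
    if (!is.null(r$fraction) && (r$fraction < 0 || r$fraction > 1))
      stop_tf("relation fractions must lie in [0, 1]")
  for (r in spacing)
    if (abs(r$distance) >= slot_width)
      stop_tf("planted motif distances must be below ", slot_width, " bp")
  structure(list(seed = seed, n_slots = n_slots, slot_width = slot_width,
                 slot_gap = slot_gap, margin = margin, jitter = jitter,
                 experiments = experiments, cobind = cobind,
                 tether = tether, spacing = spacing, motifs = motifs,
                 with_sequence = with_sequence),
            class = "tf_fixture_spec")
}

#' Generate a fixture bundle in memory
#'
#' Deterministic for a given spec (same seed, byte-identical output through
#' [write_fixture()]). The returned bundle holds everything the other
#' modules consume: experiments, the slot map and N, the genome sequence
#' (when requested), the motif library and a truth table recording every
#' planted relation with its realized count.
#'
#' @param spec a `tf_fixture_spec`.
#' @return list of class `tf_fixture` with elements `spec`, `N`, `d_s`,
#'   `slots` (data.frame `chrom`, `start`, `end`), `experiments` (named list
#'   of `tf_experiment`), `genome` (named character vector or NULL),
#'   `motifs`, `truth` (data.frame), `metadata` (data.frame).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "tf_fixture_spec"))
  with_seed(spec$seed, .generate_fixture_impl(spec))
}

.generate_fixture_impl <- function(spec) {
  pitch <- spec$slot_width + spec$slot_gap
  slot_start <- spec$margin + (seq_len(spec$n_slots) - 1L) * pitch
  slot_center <- slot_start + spec$slot_width %/% 2L
  genome_len <- 2L * spec$margin + spec$n_slots * pitch
  jit <- function(n, j = spec$jitter)
    if (j > 0) sample.int(2L * j + 1L, n, replace = TRUE) - j - 1L else
      integer(n)

  summits <- list()      # per experiment id
  truth <- list()
  tether_state <- lapply(spec$tether, function(r) NULL)

  for (e in spec$experiments) {
    id <- e$id; n <- e$n_peaks
    co <- Filter(function(r) identical(r$a, id), spec$cobind)
    te_idx <- which(vapply(spec$tether,
                           function(r) id %in% r$partners, TRUE))
    s <- integer(0)
    fill_pool <- NULL
    if (length(co)) {
      for (r in co) {
        if (is.null(summits[[r$b]]))
          stop_tf("cobind target ", r$b, " must be generated before ", r$a)
        n_co <- round(r$fraction * n)
        tgt <- summits[[r$b]]
        if (n_co > length(tgt))
          stop_tf("cobind relation for ", id, " needs ", n_co,
                  " target peaks but ", r$b, " has ", length(tgt))
        pick <- sample.int(length(tgt), n_co)
        rj <- if (is.null(r$jitter)) spec$jitter else r$jitter
        s <- c(s, tgt[pick] + jit(n_co, rj))
        truth[[length(truth) + 1L]] <-
          data.frame(relation = "cobind", members = paste(id, r$b, sep = "+"),
                     parameter = r$fraction, realized = n_co)
      }
    }
    for (ti in te_idx) {
      r <- spec$tether[[ti]]
      if (is.null(summits[[r$base]]))
        stop_tf("tether base ", r$base, " must be generated before ", id)
      if (is.null(tether_state[[ti]])) {
        base_s <- summits[[r$base]]
        n_sh <- round(r$fraction * length(base_s))
        shared <- sort(sample.int(length(base_s), n_sh))
        # slots free of the base, partitioned among partners as needed
        base_slot <- findInterval(summits[[r$base]], slot_start)
        free <- setdiff(seq_len(spec$n_slots), base_slot)
        tether_state[[ti]] <- list(shared = shared,
                                   free = sample(free))
        truth[[length(truth) + 1L]] <-
          data.frame(relation = "tether",
                     members = paste(c(r$base, r$partners), collapse = "+"),
                     parameter = r$fraction, realized = n_sh)
      }
      st <- tether_state[[ti]]
      base_s <- summits[[r$base]]
      n_sh <- length(st$shared)
      if (n < n_sh)
        stop_tf("tether partner ", id, " needs at least ", n_sh, " peaks")
      s <- c(s, base_s[st$shared] + jit(n_sh))
      fill_pool <- ti  # remaining peaks avoid the base and other partners
    }
    n_rest <- n - length(s)
    if (n_rest < 0)
      stop_tf("experiment ", id, ": planted relations require ",
              length(s), " peaks but n_peaks is ", n)
    if (n_rest > 0) {
      if (!is.null(fill_pool)) {
        st <- tether_state[[fill_pool]]
        if (n_rest > length(st$free))
          stop_tf("not enough free slots for tether partner ", id)
        take <- st$free[seq_len(n_rest)]
        tether_state[[fill_pool]]$free <- st$free[-seq_len(n_rest)]
        s <- c(s, slot_center[take] + jit(n_rest))
      } else {
        s <- c(s, slot_center[sample.int(spec$n_slots, n_rest)] +
                 jit(n_rest))
      }
    }
    summits[[id]] <- sort(s)
  }

  genome <- NULL
  if (spec$with_sequence) {
    chars <- sample(.BASES, genome_len, replace = TRUE)
    for (r in spec$spacing) {
      if (is.null(summits[[r$experiment]]))
        stop_tf("spacing relation names unknown experiment ", r$experiment)
      aw <- spec$motifs[[r$anchor]]; pw <- spec$motifs[[r$partner]]
      if (is.null(aw) || is.null(pw))
        stop_tf("spacing relation names motifs missing from the library")
      frac <- if (is.null(r$fraction)) 1 else r$fraction
      strand <- if (is.null(r$partner_strand)) "+" else r$partner_strand
      ss <- summits[[r$experiment]]
      sel <- sort(sample.int(length(ss), round(frac * length(ss))))
      acon <- strsplit(consensus(aw), "")[[1]]
      pcon <- strsplit(consensus(pw), "")[[1]]
      if (strand == "-")
        pcon <- rev(c(A = "T", C = "G", G = "C", T = "A")[pcon])
      for (pos in ss[sel]) {
        a0 <- pos - (aw$length - 1L) %/% 2L
        p0 <- pos + r$distance - (pw$length - 1L) %/% 2L
        chars[(a0 + 1L):(a0 + aw$length)] <- acon
        chars[(p0 + 1L):(p0 + pw$length)] <- pcon
      }
      truth[[length(truth) + 1L]] <-
        data.frame(relation = "spacing",
                   members = paste(r$experiment, r$anchor, r$partner,
                                   sep = "+"),
                   parameter = r$distance, realized = length(sel))
    }
    genome <- c(chr1 = paste(chars, collapse = ""))
  }

  experiments <- lapply(spec$experiments, function(e) {
    s <- summits[[e$id]]
    experiment(e$id, e$factor,
               data.frame(chrom = "chr1",
                          start = pmax(s - 100L, 0L),
                          end = pmin(s + 100L, genome_len - 1L),
                          summit = s),
               flags = if (is.null(e$flags)) character() else e$flags)
  })
  names(experiments) <- vapply(spec$experiments, `[[`, "", "id")

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(relation = character(), members = character(),
               parameter = numeric(), realized = integer())
  metadata <- data.frame(
    id = names(experiments),
    factor = vapply(experiments, `[[`, "", "factor"),
    flags = vapply(experiments, function(e)
      paste(e$flags, collapse = ","), ""))
  rownames(metadata) <- NULL

  structure(list(spec = spec, N = spec$n_slots, d_s = spec$slot_width,
                 slots = data.frame(chrom = "chr1", start = slot_start,
                                    end = slot_start + spec$slot_width),
                 experiments = experiments, genome = genome,
                 motifs = spec$motifs, truth = truth_df,
                 metadata = metadata),
            class = "tf_fixture")
}

#' Write a fixture bundle to disk
#'
#' Emits the exact formats the package's readers consume: one narrowPeak
#' file per experiment, a metadata TSV, the accessible-slot BED3, the truth
#' TSV, and — when present — the genome FASTA and the motif library in
#' JASPAR text format.
#'
#' @param bundle a `tf_fixture`.
#' @param dir output directory (created if missing).
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (e in bundle$experiments) {
    p <- e$peaks
    path <- file.path(dir, paste0(e$id, ".narrowPeak"))
    writeLines(sprintf("%s\t%d\t%d\t%s_%d\t0\t.\t%g\t-1\t-1\t%d",
                       p$chrom, p$start, p$end, e$id, seq_len(nrow(p)),
                       p$signal, p$summit - p$start),
               path)
    paths[[e$id]] <- path
  }
  paths$metadata <- file.path(dir, "metadata.tsv")
  utils::write.table(bundle$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$slots <- file.path(dir, "slots.bed")
  writeLines(sprintf("%s\t%d\t%d", bundle$slots$chrom, bundle$slots$start,
                     bundle$slots$end), paths$slots)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bundle$genome)) {
    paths$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(bundle$genome), paths$genome)
  }
  if (length(bundle$motifs)) {
    paths$motifs <- file.path(dir, "motifs.jaspar")
    write_jaspar(bundle$motifs, paths$motifs)
  }
  invisible(paths)
}

#' Replicate specs with independently derived seeds
#'
#' Expands one spec into `n_reps` specs whose seeds are derived
#' reproducibly from the master seed, for null-calibration and power
#' simulations.
#'
#' @param spec a `tf_fixture_spec`.
#' @param n_reps number of replicates (>= 1).
#' @return list of `tf_fixture_spec` of length `n_reps`.
#' @export
null_replicates <- function(spec, n_reps) {
  stopifnot(inherits(spec, "tf_fixture_spec"), n_reps >= 1)
  seeds <- replicate_seeds(spec$seed, n_reps)
  lapply(seeds, function(s) { spec$seed <- s; spec })
}

#' A small PWM library used by fixtures
#'
#' Two sharply informative motifs: a CCAAT-box-like anchor (the NF-Y class
#' of motif) and an E-box-like partner (`CACGTG`, the USF/bHLH class),
#' each column placing 97% of its mass on the consensus base.
#'
#' @return named list of two `tf_pwm` (`"CCAAT_box"`, `"E_box"`).
#' @export
fixture_motifs <- function() {
  col <- function(b) { v <- rep(1, 4); v[match(b, .BASES)] <- 97; v }
  mk <- function(name, cons)
    pwm(name, vapply(strsplit(cons, "")[[1]], col, numeric(4)))
  list(CCAAT_box = mk("CCAAT_box", "AGCCAATCAG"),
       E_box = mk("E_box", "GTCACGTGAC"))
}
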