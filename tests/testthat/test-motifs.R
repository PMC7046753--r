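random_pwm <- function(name, L) {
  counts <- matrix(sample.int(50, 4 * L, replace = TRUE) - 1L, 4, L)
  counts[, colSums(counts) == 0] <- 1L
  pwm(name, counts)
}

test_that("pseudocount normalization: columns sum to 1, sane frequencies", {
  p <- pwm("m", matrix(c(10, 0, 0, 0), 4, 4))
  expect_equal(colSums(p$freq), rep(1, 4))
  # counts (10,0,0,0), 1% pseudocount spread over bases:
  # A: (10 + 0.025) / 10.1, others: 0.025 / 10.1
  expect_equal(unname(p$freq["A", 1]), 10.025 / 10.1)
  expect_equal(unname(p$freq["C", 1]), 0.025 / 10.1)
  expect_error(pwm("bad", matrix(1, 3, 6)), "4 rows")
  expect_error(pwm("bad", matrix(1, 4, 3)), "length")
})

test_that("JASPAR files parse and round-trip counts exactly", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TESTMOTIF",
               "A  [ 10  3  0 12 ]",
               "C  [  0  9  2  0 ]",
               "G  [  1  0 11  0 ]",
               "T  [  2  1  0  1 ]"), path)
  pwms <- read_jaspar(path)
  expect_length(pwms, 1)
  p <- pwms[[1]]
  expect_equal(p$name, "MA0001.1 TESTMOTIF")
  expect_equal(unname(p$counts[1, ]), c(10, 3, 0, 12))
  out <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwms, out)
  back <- read_jaspar(out)
  expect_equal(back[[1]]$counts, p$counts)

  writeLines(c(">M BADROWS", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), path)
  expect_error(read_jaspar(path), "4 base rows")
  writeLines(c(">M RAGGED", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]",
               "T [ 1 2 ]"), path)
  expect_error(read_jaspar(path), "unequal")
})

test_that("consensus scores 1 and anti-consensus 0 for random PWMs", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      p <- random_pwm(paste0("m", rep), sample(8:12, 1))
      hit <- scan_sequences(paste0(random_dna(30), consensus(p),
                                   random_dna(30)), p)
      expect_equal(hit$best_score, 1)
      expect_equal(hit$offset, 30)
      expect_equal(hit$strand, "+")
      # the forward-strand score of the anti-consensus is exactly 0
      anti <- scan_sequences(anticonsensus(p), p, both_strands = FALSE)
      expect_equal(anti$best_score, 0)
    }
  })
  for (p in fixture_motifs()) {
    expect_equal(scan_sequences(consensus(p), p)$best_score, 1)
    expect_equal(scan_sequences(anticonsensus(p), p,
                                both_strands = FALSE)$best_score, 0)
  }
})

test_that("scanning agrees with the exhaustive oracle on random fixtures", {
  withr::with_seed(202, {
    for (rep in 1:200) {
      p <- random_pwm(paste0("m", rep), sample(5:11, 1))
      s <- random_dna(60)
      got <- scan_sequences(s, p)
      want <- oracle_scan_best(s, p)
      expect_equal(got$best_score, want$best_score, tolerance = 1e-9)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
    }
  })
})

test_that("reverse-complementing a region mirrors offset and flips strand", {
  withr::with_seed(203, {
    for (rep in 1:25) {
      p <- random_pwm(paste0("m", rep), 8)
      s <- random_dna(80)
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
      h1 <- scan_sequences(s, p)
      h2 <- scan_sequences(rc, p)
      expect_equal(h1$best_score, h2$best_score, tolerance = 1e-12)
      expect_equal(h2$offset, 80 - 8 - h1$offset)
      expect_equal(h2$strand, ifelse(h1$strand == "+", "-", "+"))
    }
  })
})

test_that("ambiguous bases score at the column mean", {
  p <- pwm("m", matrix(c(8, 4, 2, 2), 4, 6))
  hN <- scan_sequences(strrep("N", 6), p)
  # every position contributes mean frequency -> raw = sum of column means
  expected_raw <- sum(colMeans(p$freq))
  expect_equal(hN$best_score,
               (expected_raw - p$min_score) / (p$max_score - p$min_score))
})

test_that("windows leaving the chromosome are skipped with a warning", {
  genome <- c(chr1 = random_dna(400))
  p <- fixture_motifs()$E_box
  regions <- data.frame(chrom = "chr1", center = c(10, 200))
  expect_warning(hits <- scan_regions(regions, genome, p), "skipped")
  expect_equal(attr(hits, "skipped"), 1L)
  expect_equal(hits$region, 2L)
  expect_equal(hits$center, 200)
})

make_motif_genome <- function(seed, n_regions = 300, plant_frac = 0,
                              motif = NULL, offset_in_window = 70) {
  withr::with_seed(seed, {
    pitch <- 600L
    centers <- 450L + (seq_len(n_regions) - 1L) * pitch
    len <- max(centers) + 600L
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    planted <- integer(0)
    if (plant_frac > 0) {
      planted <- sort(sample.int(n_regions, round(plant_frac * n_regions)))
      con <- strsplit(consensus(motif), "")[[1]]
      for (ctr in centers[planted]) {
        st <- ctr - 75L + offset_in_window
        chars[(st + 1L):(st + motif$length)] <- con
      }
    }
    list(genome = c(chr1 = paste(chars, collapse = "")),
         regions = data.frame(chrom = "chr1", center = centers),
         planted = planted)
  })
}

test_that("global enrichment detects planted motifs and is one-tailed", {
  p <- fixture_motifs()$CCAAT_box
  g <- make_motif_genome(301, n_regions = 300, plant_frac = 0.8, motif = p,
                         offset_in_window = 70)
  bg <- make_motif_genome(302, n_regions = 300)
  hits <- scan_regions(g$regions, g$genome, p)
  bg_hits <- scan_regions(bg$regions, bg$genome, p)
  expect_lt(as.numeric(global_enrichment(hits, bg_hits)), 1e-10)
  # identical samples: no shift, p near 0.5
  expect_equal(as.numeric(global_enrichment(hits, hits)), 0.5,
               tolerance = 0.02)
  # input below background: p > 0.5
  expect_gt(as.numeric(global_enrichment(bg_hits, hits)), 0.5)
})

test_that("local enrichment contrasts summit windows with their flanks", {
  p <- fixture_motifs()$E_box
  g <- make_motif_genome(303, n_regions = 250, plant_frac = 1, motif = p,
                         offset_in_window = 70)
  expect_lt(as.numeric(local_enrichment(g$regions, g$genome, p)), 1e-6)
  # planting in the flanks instead reverses the direction
  gf <- make_motif_genome(304, n_regions = 250, plant_frac = 1, motif = p,
                          offset_in_window = -140)
  expect_gt(as.numeric(local_enrichment(gf$regions, gf$genome, p)), 0.5)
})

test_that("positional bias flags concentration and respects reduced bins", {
  expect_lt(as.numeric(positional_bias(rep(75, 200))), 1e-10)
  expect_lt(as.numeric(positional_bias(runif(500, 0, 75))), 1e-6)
  pb <- positional_bias(c(10, 30, 80), window = 150)
  expect_equal(attr(pb, "flag"), "bins_reduced")
  expect_error(positional_bias(numeric(0)), "no positions")
})

test_that("positional-bias p-values are near-uniform under the null", {
  withr::with_seed(401, {
    ps <- replicate(800, as.numeric(positional_bias(runif(120, 0, 150))))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("global and local enrichment p-values are near-uniform under the null", {
  p <- fixture_motifs()$E_box
  g <- make_motif_genome(401, n_regions = 600)
  hits <- scan_regions(g$regions, g$genome, p)
  # global: exchangeable input/background splits of the same region pool
  withr::with_seed(402, {
    ps_g <- replicate(400, {
      idx <- sample(600)
      as.numeric(global_enrichment(hits[idx[1:300], ],
                                   hits[idx[301:600], ]))
    })
  })
  ks_g <- suppressWarnings(stats::ks.test(ps_g, "punif"))
  expect_lt(unname(ks_g$statistic), 0.1)

  # local: independent genomes per replicate, nothing planted anywhere
  ps_l <- vapply(replicate_seeds(403, 250), function(s) {
    gi <- make_motif_genome(s, n_regions = 150)
    as.numeric(local_enrichment(gi$regions, gi$genome, p))
  }, 0)
  ks_l <- suppressWarnings(stats::ks.test(ps_l, "punif"))
  expect_lt(unname(ks_l$statistic), 0.1)
})

test_that("motif-centered rescan recovers a planted 17-bp arrangement", {
  motifs <- fixture_motifs()
  spec <- fixture_spec(
    seed = 71, n_slots = 700,
    experiments = list(list(id = "anc", factor = "NFY", n_peaks = 450)),
    spacing = list(list(experiment = "anc", anchor = "CCAAT_box",
                        partner = "E_box", distance = 17, fraction = 1)),
    motifs = motifs)
  b <- generate_fixture(spec)
  regions <- summit_regions(b$experiments$anc)
  arr <- motif_centered_rescan(regions, b$genome, motifs$CCAAT_box,
                               motifs["E_box"])$E_box
  expect_equal(arr$modal_distance, 17L)
  expect_lt(arr$positional_bias_p, 0.01)
  expect_true(all(arr$hits$strand[abs(arr$hits$distance - 17) <= 1] == "+"))
  expect_equal(sum(arr$histogram$count), arr$n_regions)
})

test_that("rescan discards low-quality anchors and errors when none pass", {
  motifs <- fixture_motifs()
  g <- make_motif_genome(305, n_regions = 100)  # no anchor planted
  expect_error(
    motif_centered_rescan(g$regions, g$genome, motifs$CCAAT_box,
                          motifs["E_box"], quality_threshold = 0.99),
    "no region")
})

test_that("an absent partner yields no repeated-distance mode signal", {
  motifs <- fixture_motifs()
  spec <- fixture_spec(
    seed = 72, n_slots = 600,
    experiments = list(list(id = "anc", factor = "NFY", n_peaks = 300)),
    spacing = list(list(experiment = "anc", anchor = "CCAAT_box",
                        partner = "CCAAT_box", distance = 0, fraction = 1)),
    motifs = motifs)
  b <- generate_fixture(spec)
  regions <- summit_regions(b$experiments$anc)
  arr <- motif_centered_rescan(regions, b$genome, motifs$CCAAT_box,
                               motifs["E_box"])$E_box
  # best E-box hits land at random positions: the mode is weak
  expect_lt(max(table(arr$hits$distance)) / nrow(arr$hits), 0.2)
})

test_that("enrichment report ranks planted motifs first and labels cases", {
  motifs <- fixture_motifs()
  spec <- fixture_spec(
    seed = 73, n_slots = 900,
    experiments = list(list(id = "co", factor = "NFY", n_peaks = 400)),
    spacing = list(list(experiment = "co", anchor = "CCAAT_box",
                        partner = "E_box", distance = 20, fraction = 0.9)),
    motifs = motifs)
  b <- generate_fixture(spec)
  regions <- summit_regions(b$experiments$co)
  # background: slots unused by the experiment
  used <- findInterval(b$experiments$co$peaks$summit, b$slots$start)
  free <- setdiff(seq_len(nrow(b$slots)), used)[1:400]
  bg <- data.frame(chrom = "chr1",
                   center = b$slots$start[free] + b$d_s %/% 2)
  decoys <- withr::with_seed(74, list(random_pwm("decoy1", 9),
                                      random_pwm("decoy2", 7)))
  lib <- c(motifs, decoys)
  rep <- enrichment_report(regions, b$genome, lib, bg)
  expect_setequal(rep$motif[1:2], c("CCAAT_box", "E_box"))
  expect_true(all(rep$global_p_bonferroni[1:2] < 1e-6))

  labels <- interpret_motif_roles(rep, "CCAAT_box", "E_box")
  expect_equal(attr(labels, "case"), 1L)
  labels2 <- interpret_motif_roles(rep, "CCAAT_box", "decoy1")
  expect_equal(attr(labels2, "case"), 2L)
  expect_equal(unname(labels2["decoy1"]), "tethered (no motif)")
  labels3 <- interpret_motif_roles(rep, "decoy1", "decoy2")
  expect_equal(attr(labels3, "case"), 3L)
  expect_error(interpret_motif_roles(rep, "CCAAT_box", "nope"),
               "not in report")
  expect_error(enrichment_report(regions, b$genome, list(), bg), "empty")
})
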