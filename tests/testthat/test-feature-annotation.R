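test_that("CAGE annotation reports signed distance and half-open membership", {
  iso_plus <- tm("p", rbind(c(1049, 1200)))   # 5' end at 1049
  peaks <- data.frame(contig = "chr1", start = 1000L, end = 1100L)
  # center of [1000,1100) is 1049 -> distance 0, within
  res <- cage_annotate(iso_plus, peaks)
  expect_equal(res$cage_distance, 0L)
  expect_true(res$within_cage)
  # 5' end at 1099 is inside; at 1100 it is not (half-open)
  expect_true(cage_annotate(tm("a", rbind(c(1099, 1200))), peaks)$within_cage)
  expect_false(cage_annotate(tm("b", rbind(c(1100, 1200))), peaks)$within_cage)
  # no peaks on the contig
  none <- cage_annotate(tm("c", rbind(c(0, 10)), contig = "chr9"), peaks)
  expect_true(is.na(none$cage_distance))
  expect_false(none$within_cage)
  # sign: minus-strand 5' end downstream of center in transcript orientation
  iso_minus <- tm("m", rbind(c(900, 1040)), "-")  # 5' end at 1039, center 1049
  expect_equal(cage_annotate(iso_minus, peaks)$cage_distance, 10L)
})

test_that("nearest CAGE center matches a linear-scan oracle on random fixtures", {
  set.seed(17)
  for (i in 1:300) {
    np <- sample(1:8, 1)
    start <- sort(sample.int(5000L, np))
    peaks <- data.frame(contig = "chr1", start = start,
                        end = start + sample(20:80, np, replace = TRUE))
    iso <- random_transcript("q")
    got <- cage_annotate(iso, peaks)
    pos <- if (iso$strand == "+") iso$exons[1, 1] else iso$exons[nrow(iso$exons), 2] - 1L
    centers <- (peaks$start + peaks$end - 1L) %/% 2L
    d <- if (iso$strand == "+") pos - centers else centers - pos
    expect_equal(got$cage_distance, unname(d[which.min(abs(d))]))
    expect_identical(got$within_cage, any(peaks$start <= pos & pos < peaks$end))
  }
})

test_that("polyA motif scan honours the 5-25 nt window on both strands", {
  # plus strand: transcript ends at 100 (3' base = 99); AATAAA with last base
  # 5 nt upstream occupies genomic [89, 95)
  seq_ <- strrep("C", 200)
  substr(seq_, 90, 95) <- "AATAAA"
  g <- Biostrings::DNAStringSet(c(chr1 = seq_))
  iso <- tm("p", rbind(c(0, 100)))
  res <- polya_motif_scan(iso, g)
  expect_true(res$found)
  expect_identical(res$motif, "AATAAA")
  expect_equal(res$offset_end, 5L)
  expect_equal(res$offset_start, 10L)
  # motif entirely 30 nt upstream -> outside window
  seq2 <- strrep("C", 200)
  substr(seq2, 65, 70) <- "AATAAA"   # last base at 0-based 69 = 30 nt upstream
  g2 <- Biostrings::DNAStringSet(c(chr1 = seq2))
  expect_false(polya_motif_scan(iso, g2)$found)
  # minus strand: sense AATAAA appears as TTTATT on the plus strand downstream
  seq3 <- strrep("C", 200)
  substr(seq3, 56, 61) <- "TTTATT"   # genomic [55,61), 0-based
  g3 <- Biostrings::DNAStringSet(c(chr1 = seq3))
  iso_m <- tm("m", rbind(c(50, 150)), "-")  # 3' end base at 50
  res_m <- polya_motif_scan(iso_m, g3)
  expect_true(res_m$found)
  expect_identical(res_m$motif, "AATAAA")
  expect_equal(res_m$offset_end, 5L)
})

test_that("polyA scan agrees with brute-force substring search on random fixtures", {
  set.seed(23)
  for (i in 1:300) {
    seq_ <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    g <- Biostrings::DNAStringSet(c(chr1 = seq_))
    strand <- sample(c("+", "-"), 1)
    iso <- tm("q", rbind(c(120, 280)), strand)
    got <- polya_motif_scan(iso, g)
    # oracle: explicit scan of offsets 5..20 for the motif's last base
    sense_at <- function(off) {
      if (strand == "+") {
        s <- substr(seq_, 280 - off - 5, 280 - off)  # 1-based
      } else {
        s <- capiso:::revcomp(substr(seq_, 121 + off, 121 + off + 5))
      }
      s
    }
    oracle <- NA_integer_; omot <- NA_character_
    for (off in 5:20) {
      s <- sense_at(off)
      if (s %in% c("AATAAA", "ATTAAA")) { oracle <- off; omot <- s; break }
    }
    expect_identical(got$found, !is.na(oracle))
    if (!is.na(oracle)) {
      expect_equal(got$offset_end, oracle)
      expect_identical(got$motif, omot)
    }
  }
})

test_that("generator-planted polyA motifs are recovered by the scanner", {
  sim <- simulate_annotation(n_genes = 20L, polya_rate = 1, seed = 61L)
  found <- vapply(sim$annotation$transcripts, function(t)
    polya_motif_scan(t, sim$genome)$found, TRUE)
  # planting is best-effort (skipped on constraint clashes or short exons)
  # but should succeed for the large majority
  expect_gte(mean(found), 0.7)
})

test_that("junction conservation uses strand-aware trinucleotide positions", {
  # plus-strand intron (200,300): donor {199,200,201}, acceptor {298,299,300}
  iso <- tm("p", rbind(c(100, 200), c(300, 400)))
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t199\t202\t2.0", "chr1\t298\t301\t1.0"), bg)
  tr <- read_track(bg)
  jc <- junction_conservation(iso, tr)
  expect_equal(jc$donor_mean, 2.0)
  expect_equal(jc$acceptor_mean, 1.0)
  # missing positions propagate as NA, never 0
  iso2 <- tm("q", rbind(c(0, 50), c(60, 100)))
  jc2 <- junction_conservation(iso2, tr)
  expect_true(is.na(jc2$donor_mean))
  # minus strand: donor at the intron's right edge, positions {300,299,298}
  iso_m <- tm("m", rbind(c(100, 200), c(300, 400)), "-")
  jcm <- junction_conservation(iso_m, tr)
  expect_equal(jcm$donor_mean, 1.0)
  expect_equal(jcm$acceptor_mean, 2.0)
})

test_that("junction dinucleotides are canonical on generator output", {
  sim <- simulate_annotation(n_genes = 8L, seed = 62L)
  for (t in sim$annotation$transcripts) {
    jc <- junction_conservation(t, track = NULL, genome = sim$genome)
    if (is.null(jc)) next
    expect_true(all(jc$donor_dinucleotide == "GT"))
    expect_true(all(jc$acceptor_dinucleotide == "AG"))
  }
})

test_that("validation filter requires every novel junction at min_support", {
  ann <- fixture_annotation()
  # i1: FSM (vacuously valid); i2..i5: NNC with one novel junction each at
  # short-read supports 0 / 2 / 3 / 10; i6: two novel junctions, one weak
  isoforms <- list(
    aligned_isoform("i1", "chr1", "+", rbind(c(100, 200), c(300, 400), c(500, 600))),
    aligned_isoform("i2", "chr1", "+", rbind(c(100, 210), c(300, 600))),
    aligned_isoform("i3", "chr1", "+", rbind(c(100, 212), c(300, 600))),
    aligned_isoform("i4", "chr1", "+", rbind(c(100, 214), c(300, 600))),
    aligned_isoform("i5", "chr1", "+", rbind(c(100, 216), c(300, 600))),
    aligned_isoform("i6", "chr1", "+", rbind(c(100, 214), c(300, 400), c(404, 600))))
  records <- classify_isoforms(isoforms, ann)
  counts <- data.frame(
    contig = "chr1",
    start = c(210L, 212L, 214L, 216L, 400L),
    end = c(300L, 300L, 300L, 300L, 404L),
    strand = "+",
    count = c(0L, 2L, 3L, 10L, 2L))
  out <- validate_novel_isoforms(records, counts, min_support = 3L)
  expect_identical(out$validated,
                   c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # monotone: raising min_support never validates a previously-invalid isoform
  for (ms in c(0L, 1L, 4L, 11L)) {
    v <- validate_novel_isoforms(records, counts, min_support = ms)$validated
    hi <- validate_novel_isoforms(records, counts, min_support = ms + 1L)$validated
    expect_true(all(v | !hi))
  }
  # junction absent from the table counts as 0
  out0 <- validate_novel_isoforms(records, counts[0, ], min_support = 3L)
  expect_identical(out0$validated, c(TRUE, rep(FALSE, 5)))
})
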