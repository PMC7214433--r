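test_that("annotation generator is deterministic and canonically spliced", {
  sim1 <- simulate_annotation(n_genes = 20L, seed = 7L)
  sim2 <- simulate_annotation(n_genes = 20L, seed = 7L)
  g1 <- tempfile(); g2 <- tempfile()
  write_gtf(sim1$annotation, g1); write_gtf(sim2$annotation, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_identical(as.character(sim1$genome), as.character(sim2$genome))

  # every intron of every isoform is GT..AG in the transcribed sense
  for (t in sim1$annotation$transcripts) {
    ch <- junction_chain(t)
    if (nrow(ch$introns) == 0L) next
    for (i in seq_len(nrow(ch$introns))) {
      s <- ch$introns[i, 1]; e <- ch$introns[i, 2]
      d <- capiso:::genome_subseq(sim1$genome, t$contig, s, s + 2L)
      a <- capiso:::genome_subseq(sim1$genome, t$contig, e - 2L, e)
      if (t$strand == "-") {
        tmp <- capiso:::revcomp(a); a <- capiso:::revcomp(d); d <- tmp
      }
      expect_identical(d, "GT")
      expect_identical(a, "AG")
    }
  }
})

test_that("one gene / one isoform gives exactly one appris-tagged transcript", {
  sim <- simulate_annotation(n_genes = 1L, isoforms_per_gene_range = c(1L, 1L),
                             seed = 3L)
  expect_length(sim$annotation$transcripts, 1L)
  expect_true("appris_principal" %in% sim$annotation$transcripts[[1]]$tags)
})

test_that("expression profiles normalise to 1e6 and span a wide dynamic range", {
  sim <- simulate_annotation(n_genes = 200L, isoforms_per_gene_range = c(1L, 3L),
                             seed = 11L)
  expr <- simulate_expression(sim$annotation, log10_range = 6, seed = 5L)
  expect_equal(sum(expr), 1e6, tolerance = 1e-9)
  expect_true(all(expr >= 0))
  gene_ab <- vapply(names(sim$annotation$genes), function(g)
    sum(expr[sim$annotation$genes[[g]]]), 0)
  # 200 log-uniform draws over 6 decades: max/min ratio >= 1e4 essentially surely
  expect_gte(max(gene_ab) / min(gene_ab), 1e4)
  # single gene: everything on that gene
  sim1 <- simulate_annotation(n_genes = 1L, seed = 2L)
  e1 <- simulate_expression(sim1$annotation, seed = 2L)
  expect_equal(sum(e1), 1e6, tolerance = 1e-9)
  expect_error(simulate_expression(sim$annotation, log10_range = 0),
               "positive")
})

test_that("capture with p_on == p_bg is a no-op after renormalisation", {
  sim <- simulate_annotation(n_genes = 5L, seed = 1L)
  expr <- simulate_expression(sim$annotation, seed = 1L)
  ann <- sim$annotation
  reps <- select_representative(ann, "appris")
  design <- capture_design(names(ann$genes), reps,
                           annotation = ann)
  m <- capture_model(p_on = 0.3, p_bg = 0.005)
  m$p_bg <- 0.3  # degenerate flat model (constructor forbids it by design)
  out <- simulate_capture(expr, design, m, ann)
  expect_equal(as.numeric(out$profile), as.numeric(expr), tolerance = 1e-12)
})

test_that("capture efficiency interpolates linearly between the overlap knees", {
  m <- capture_model(p_on = 0.5, p_bg = 0.005, overlap_full = 45L,
                     overlap_floor = 35L)
  expect_equal(capture_efficiency_curve(m, 34L), 0.005)
  expect_equal(capture_efficiency_curve(m, 45L), 0.5)
  expect_equal(capture_efficiency_curve(m, 2500L), 0.5)
  expect_equal(capture_efficiency_curve(m, 40L), 0.005 + (0.5 - 0.005) * 0.5)
  expect_equal(capture_efficiency_curve(m, 100L, targeted = FALSE), 0.005)
})

test_that("two-transcript full-overlap capture gives the closed-form on-target fraction", {
  ann <- annotation_set(list(
    tm("T1", rbind(c(100, 400)), gene = "G1", tags = c("basic", "appris_principal")),
    tm("T2", rbind(c(1000, 1300)), gene = "G2", tags = c("basic", "appris_principal"))))
  expr <- expression_profile(c(T1 = 5e5, T2 = 5e5), normalize = FALSE)
  design <- capture_design("G1", c(G1 = "T1"), annotation = ann)
  out <- simulate_capture(expr, design, capture_model(0.5, 0.005), ann)
  expect_equal(unname(out$profile[["T1"]]) / 1e6, 0.5 / (0.5 + 0.005),
               tolerance = 1e-12)
})

test_that("capture errors when the template transcript is missing", {
  ann <- annotation_set(list(tm("T1", rbind(c(0, 100)), gene = "G1")))
  expr <- expression_profile(c(T1 = 1))
  design <- capture_design("G1", c(G1 = "Tmissing"))
  expect_error(simulate_capture(expr, design, capture_model(), ann), "absent")
})

test_that("long-read simulation respects fl and chimera rates", {
  sim <- simulate_annotation(n_genes = 5L, seed = 4L)
  expr <- simulate_expression(sim$annotation, seed = 4L)
  reads <- simulate_long_reads(expr, sim$annotation, n_reads = 50000L,
                               fl_rate = 0.8, chimera_rate = 0.02, seed = 1L)
  expect_equal(nrow(reads), 50000L)
  # binomial 3SE bounds around the generating rates
  p_chim <- mean(reads$truth_chimera)
  expect_lt(abs(p_chim - 0.02), 3 * sqrt(0.02 * 0.98 / 50000))
  p_fl <- mean(classify_full_length(reads))
  expect_lt(abs(p_fl - 0.8), 3 * sqrt(0.8 * 0.2 / 50000))
  # non-FL reads drop exactly one element
  nfl <- reads[!classify_full_length(reads), ]
  expect_true(all(nfl$has_5p_primer + nfl$has_3p_primer + nfl$has_polyA == 2L))
  # chimera-free pool: inner barcodes always concordant
  r0 <- simulate_long_reads(expr, sim$annotation, 2000L, fl_rate = 1,
                            chimera_rate = 0, seed = 2L)
  expect_false(any(r0$truth_chimera))
  expect_true(all(dual_barcode_concordance(r0) == "concordant"))
  expect_true(all(r0$has_5p_primer & r0$has_3p_primer & r0$has_polyA))
})

test_that("long-read simulation is deterministic and validates inputs", {
  sim <- simulate_annotation(n_genes = 3L, seed = 4L)
  expr <- simulate_expression(sim$annotation, seed = 4L)
  a <- simulate_long_reads(expr, sim$annotation, 500L, seed = 9L)
  b <- simulate_long_reads(expr, sim$annotation, 500L, seed = 9L)
  expect_identical(a, b)
  empty_pairs <- data.frame(barcode_5p = character(),
                            barcode_3p = character(), pair_id = character())
  expect_error(simulate_long_reads(expr, sim$annotation, 10L,
                                   dual_barcode_pairs = empty_pairs),
               "empty")
})

test_that("junction counts are Poisson in depth and zero off-support", {
  ann <- annotation_set(list(
    tm("T1", rbind(c(0, 100), c(200, 300)), gene = "G1"),
    tm("T2", rbind(c(1000, 1100), c(1200, 1300)), gene = "G2")))
  # all mass on T1; T2's junction must get 0 counts
  expr <- expression_profile(c(T1 = 1e6, T2 = 0), normalize = FALSE)
  jc <- simulate_short_read_junction_counts(expr, ann, mean_depth = 30, seed = 1L)
  expect_equal(jc$count[jc$start == 1100L], 0L)
  # T1's junction has mass 1: mean 30, check across seeds within 3*sqrt(30)
  counts <- vapply(1:40, function(s)
    simulate_short_read_junction_counts(expr, ann, 30, seed = s)$count[1], 0L)
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 40))
})

test_that("doubling junction depth doubles mean counts (paired seeds)", {
  sim <- simulate_annotation(n_genes = 20L, seed = 6L)
  expr <- simulate_expression(sim$annotation, seed = 6L)
  j1 <- simulate_short_read_junction_counts(expr, sim$annotation, 2e5, seed = 3L)
  j2 <- simulate_short_read_junction_counts(expr, sim$annotation, 4e5, seed = 3L)
  expect_equal(mean(j2$count) / mean(j1$count), 2, tolerance = 0.1)
})

test_that("read FASTA emitter writes one record per read with the carried elements", {
  sim <- simulate_annotation(n_genes = 2L, seed = 5L)
  expr <- simulate_expression(sim$annotation, seed = 5L)
  reads <- simulate_long_reads(expr, sim$annotation, 20L, fl_rate = 0.5, seed = 5L)
  fa <- tempfile(fileext = ".fa")
  write_read_fasta(reads, sim$genome, sim$annotation, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_length(seqs, 20L)
  fl <- classify_full_length(reads)
  s <- as.character(seqs)[match(reads$read_id, names(seqs))]
  ends_primer <- grepl("AAGCAGTGGTATCAACGCAGAGTAC$", s)
  has_tail <- grepl(strrep("A", 30L), s, fixed = TRUE)
  expect_true(all(ends_primer[fl] & has_tail[fl]))
  expect_true(all(!ends_primer[!reads$has_3p_primer]))
})
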