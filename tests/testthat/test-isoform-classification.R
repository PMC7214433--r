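ai <- function(id, exons, strand = "+", contig = "chr1", ...) {
  aligned_isoform(id, contig, strand, exons, ...)
}

test_that("alignment filter applies inclusive coverage/identity thresholds and target regions", {
  isoforms <- c(
    lapply(1:7, function(i) ai(sprintf("ok%d", i), rbind(c(0, 100)),
                               coverage = 0.99, identity = 0.95)),
    list(ai("low_cov", rbind(c(0, 100)), coverage = 0.989, identity = 1),
         ai("low_id", rbind(c(0, 100)), coverage = 1, identity = 0.949),
         ai("both_low", rbind(c(0, 100)), coverage = 0.5, identity = 0.5)))
  kept <- filter_alignments(isoforms)
  expect_length(kept, 7L)
  expect_true(all(grepl("^ok", vapply(kept, `[[`, "", "isoform_id"))))
  # target regions: exonic footprint must intersect
  tr <- data.frame(contig = "chr1", start = 500L, end = 600L)
  expect_length(filter_alignments(isoforms, target_regions = tr), 0L)
  tr2 <- data.frame(contig = "chr1", start = 50L, end = 60L)
  expect_length(filter_alignments(isoforms, target_regions = tr2), 7L)
  expect_error(filter_alignments(isoforms, min_coverage = 1.2), "\\[0, 1\\]")
})

test_that("reads collapse by junction chain with 5'/3' end variation ignored", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    sample_barcode = c("s1", "s2", "s1", "s1"),
    contig = "chr1", strand = "+",
    blocks = c("100-200;300-400",   # same chain, shorter 5' end
               "120-200;300-450",   # same chain, different ends
               "100-200;320-400",   # different acceptor -> new chain
               "700-800"),          # mono-exon
    coverage = 1, identity = 1, stringsAsFactors = FALSE)
  isoforms <- collapse_reads(reads)
  expect_length(isoforms, 3L)
  chains <- vapply(isoforms, function(i) capiso:::chain_key(junction_chain(i)), "")
  two <- isoforms[[which(chains == "chr1:+:200-300")]]
  expect_equal(unname(two$exons), rbind(c(100L, 200L), c(300L, 450L)))
  expect_equal(sum(two$fl_counts), 2L)
  expect_equal(two$fl_counts[["s1"]], 1L)
  expect_setequal(two$member_reads, c("r1", "r2"))
})

test_that("mono-exon reads collapse by single-linkage overlap on one strand", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:5),
    sample_barcode = "s1", contig = "chr1",
    strand = c("+", "+", "+", "-", "+"),
    blocks = c("100-200", "150-300", "290-400",  # one chained cluster
               "150-300",                        # minus strand: separate
               "1000-1100"),                     # disjoint: separate
    coverage = 1, identity = 1, stringsAsFactors = FALSE)
  isoforms <- collapse_reads(reads)
  expect_length(isoforms, 3L)
  sizes <- sort(vapply(isoforms, function(i) length(i$member_reads), 0L))
  expect_equal(sizes, c(1L, 1L, 3L))
})

test_that("collapsing a chimera-free FL pool recovers the expressed junction chains", {
  sim <- simulate_annotation(n_genes = 6L, seed = 31L)
  expr <- simulate_expression(sim$annotation, log10_range = 1, seed = 31L)
  reads <- simulate_long_reads(expr, sim$annotation, 20000L, fl_rate = 1,
                               chimera_rate = 0, seed = 31L)
  isoforms <- collapse_reads(reads)
  multi_chains <- vapply(Filter(function(i) nrow(i$exons) > 1L, isoforms),
                         function(i) capiso:::chain_key(junction_chain(i)), "")
  truth_multi <- unique(vapply(
    sim$annotation$transcripts[unique(reads$truth_transcript_id)],
    function(t) capiso:::chain_key(junction_chain(t)), ""))
  truth_multi <- truth_multi[nzchar(truth_multi)]
  expect_setequal(multi_chains, truth_multi)
})

test_that("structural categories follow the FSM/ISM/NIC/NNC decision order", {
  ann <- fixture_annotation()
  # chain identical to A1
  fsm <- classify_isoform(ai("q1", rbind(c(90, 200), c(300, 400), c(500, 610))), ann)
  expect_identical(fsm$category, "FSM")
  expect_identical(fsm$matched_transcript_id, "A1")
  expect_identical(fsm$matched_gene_id, "GA")
  expect_equal(fsm$n_novel_junctions, 0L)
  # chain equal to A3's single junction (400,500) -> FSM of A3, even though
  # it is also a sub-chain of A1 (FSM precedes ISM in the decision order)
  fsm3 <- classify_isoform(ai("q2", rbind(c(320, 400), c(500, 620))), ann)
  expect_identical(fsm3$category, "FSM")
  expect_identical(fsm3$matched_transcript_id, "A3")
  # consecutive prefix of A1's chain that matches no full chain -> ISM
  ism <- classify_isoform(ai("q3", rbind(c(100, 200), c(300, 620))), ann)
  expect_identical(ism$category, "ISM")
  expect_identical(ism$matched_transcript_id, "A1")
  expect_identical(ism$matched_gene_id, "GA")
  # chain equal to A2's (200,500) -> FSM of A2
  nic2 <- classify_isoform(ai("q4", rbind(c(100, 200), c(500, 620))), ann)
  expect_identical(nic2$category, "FSM")
  expect_identical(nic2$matched_transcript_id, "A2")
  # donor shifted +8 nt from any annotated donor -> NNC with one novel site
  nnc <- classify_isoform(ai("q5", rbind(c(100, 208), c(300, 400), c(500, 620))), ann)
  expect_identical(nnc$category, "NNC")
  expect_equal(nnc$n_novel_splice_sites, 1L)
  expect_gte(nnc$n_novel_junctions, 1L)
})

test_that("NIC splits into known-junction combinations vs known-site novel junctions", {
  ann <- annotation_set(list(
    tm("P1", rbind(c(0, 100), c(200, 300), c(400, 500), c(600, 700)),
       gene = "GP"),
    tm("P2", rbind(c(0, 100), c(450, 500), c(600, 700)), gene = "GP")))
  # chain (100,200-intron),(300,400),(500,600) = P1's; drop middle intron ->
  # exon (200,500) skips P1's intron (300,400): junctions (100,200) and
  # (500,600) both annotated, combination never seen consecutively in P1?
  # They ARE consecutive-with-gap -> not a sub-chain -> NIC combination.
  nic_comb <- classify_isoform(ai("c1", rbind(c(0, 100), c(200, 500), c(600, 700))), ann)
  expect_identical(nic_comb$category, "NIC")
  expect_identical(nic_comb$subcategory, "combination")
  # novel junction from two annotated sites: donor 300 (P1) paired with
  # acceptor 450 (P2): junction (300,450) unseen but both sites annotated
  nic_sites <- classify_isoform(
    ai("c2", rbind(c(0, 100), c(200, 300), c(450, 700))), ann)
  expect_identical(nic_sites$category, "NIC")
  expect_identical(nic_sites$subcategory, "novel_junction")
  expect_equal(nic_sites$n_novel_junctions, 1L)
  expect_equal(nic_sites$n_novel_splice_sites, 0L)
})

test_that("splice-site novelty is side-specific: donor at an acceptor-only position is novel", {
  ann <- annotation_set(list(
    tm("S1", rbind(c(0, 100), c(200, 300)), gene = "GS")))
  # annotated: donor 100, acceptor 200 (plus strand)
  # isoform with donor at 200 (the annotated acceptor position) -> novel donor
  iso <- ai("sx", rbind(c(150, 200), c(250, 300)))
  rec <- classify_isoform(iso, ann)
  expect_identical(rec$category, "NNC")
  expect_true(grepl("200:donor", rec$novel_splice_sites))
})

test_that("mono-exon isoforms classify by containment, gene overlap, or intergenic", {
  ann <- fixture_annotation()
  known <- classify_isoform(ai("m1", rbind(c(120, 180))), ann)
  expect_identical(known$category, "mono-exon-known")
  expect_identical(known$matched_gene_id, "GA")
  novel <- classify_isoform(ai("m2", rbind(c(150, 450))), ann)
  expect_identical(novel$category, "mono-exon-novel")
  expect_identical(novel$matched_gene_id, "GA")
  inter <- classify_isoform(ai("m3", rbind(c(5000, 5100))), ann)
  expect_identical(inter$category, "intergenic")
  expect_true(is.na(inter$matched_gene_id))
})

test_that("classification agrees with the brute-force oracle on random fixtures", {
  set.seed(99)
  n_agree <- 0L
  for (i in 1:300) {
    ref <- annotation_set(lapply(1:3, function(k)
      random_transcript(sprintf("R%d", k), gene = sprintf("g%d", k),
                        strand = "+", max_exons = 5L)))
    iso <- random_transcript("q", strand = "+", max_exons = 5L)
    if (nrow(iso$exons) < 2L) next
    got <- classify_isoform(ai("q", iso$exons), ref)$category
    want <- classify_oracle(iso, ref)
    expect_identical(got, want)
    n_agree <- n_agree + 1L
  }
  expect_gte(n_agree, 100L)
})

test_that("intron retention requires strict containment of an annotated intron", {
  ann <- fixture_annotation()
  # exon (100,600) spans GA's intron (200,300) with both flanks overlapped
  ir <- classify_isoform(ai("ir1", rbind(c(100, 600))), ann)
  expect_true(ir$intron_retention)
  expect_true(detect_intron_retention(ai("ir1", rbind(c(100, 600))), ann, "GA"))
  # exon exactly matching the intron boundaries does not overlap the flanks
  expect_false(detect_intron_retention(ai("ir2", rbind(c(200, 300))), ann, "GA"))
  # FSM of A1 cannot contain any intron of its own chain
  fsm <- classify_isoform(ai("ir3", rbind(c(100, 200), c(300, 400), c(500, 600))), ann)
  expect_identical(fsm$category, "FSM")
  expect_false(fsm$intron_retention)
})

test_that("generator-injected intron retention events are all flagged", {
  sim <- simulate_annotation(n_genes = 15L, seed = 41L)
  ann <- sim$annotation
  for (t in ann$transcripts) {
    principal_id <- grep("\\.T01$", ann$genes[[t$gene_id]], value = TRUE)
    if (t$transcript_id == principal_id) next
    p <- ann$transcripts[[principal_id]]
    # truth: does t's exon set strictly contain one of p's introns?
    pj <- junction_chain(p)$introns
    truth_ir <- nrow(pj) > 0L && any(vapply(seq_len(nrow(t$exons)), function(i)
      any(t$exons[i, 1] < pj[, 1] & pj[, 2] < t$exons[i, 2]), TRUE))
    ref <- subset_annotation(ann, setdiff(names(ann$transcripts),
                                          t$transcript_id))
    got <- detect_intron_retention(t, ref, t$gene_id)
    if (truth_ir) expect_true(got)
  }
})

test_that("recovery statistics stratify by probe representation and expression", {
  ann <- fixture_annotation()
  isoforms <- list(ai("i1", rbind(c(100, 200), c(300, 400), c(500, 600)),
                      fl_counts = c(s1 = 5L)),          # FSM of A1
                   ai("i2", rbind(c(150, 208), c(300, 400), c(500, 600)),
                      fl_counts = c(s1 = 2L)))          # NNC at GA
  records <- classify_isoforms(isoforms, ann)
  expr <- expression_profile(c(A1 = 9e5, A2 = 4e4, A3 = 4e4, B1 = 1e4, B2 = 1e4),
                             normalize = FALSE)
  rec <- recovery_statistics(records, ann, probe_tpm = c(GA = 5, GB = 0.5),
                             expression = expr)
  all_row <- rec[rec$stratum == "all", ]
  # GA detected (gene level), GB not; isoforms: only A1 FSM-detected
  expect_equal(all_row$gene_recovery, 0.5)
  expect_equal(all_row$isoform_recovery, 1 / 5)
  probe_row <- rec[rec$stratum == "probe_ge_min", ]
  expect_equal(probe_row$n_genes, 1L)       # only GA has probe_tpm >= 1
  expect_equal(probe_row$gene_recovery, 1.0)
  expect_equal(rec[rec$stratum == "expr_ge_min", ]$n_genes, 2L)
})

test_that("novelty summary counts distinct sites/junctions once", {
  ann <- fixture_annotation()
  isoforms <- list(
    ai("i1", rbind(c(100, 200), c(300, 400), c(500, 600))),  # FSM (A1)
    ai("i2", rbind(c(100, 200), c(300, 400), c(500, 600)))   # duplicate FSM
  )
  records <- classify_isoforms(isoforms, ann)
  nv <- novelty_summary(records, ann)
  expect_equal(nv$isoform_novelty, 0)
  expect_equal(nv$site_novelty, 0)
  expect_equal(nv$n_distinct_junctions, 2L)  # counted once despite 2 isoforms
  # one NNC adding 1 novel donor among the distinct sites
  isoforms3 <- c(isoforms, list(ai("i3", rbind(c(100, 208), c(300, 400), c(500, 600)))))
  rec3 <- classify_isoforms(isoforms3, ann)
  nv3 <- novelty_summary(rec3, ann)
  expect_equal(nv3$n_distinct_sites, 5L)     # 4 annotated + 1 novel donor
  expect_equal(nv3$site_novelty, 1 / 5)
  expect_equal(nv3$isoform_novelty, 1 / 3)
  # TSL confirmation: FSM-matched A1 has TSL 1 -> no TSL2-5 confirmations
  expect_equal(nv3$tsl25_confirmed, 0L)
})

test_that("novelty amplifies from sites to junctions to isoforms under site-level injection", {
  sim <- simulate_annotation(n_genes = 12L, seed = 51L)
  ann <- sim$annotation
  set.seed(52)
  # inject site-level novelty: shift one donor of some transcripts by 6 nt
  mutated <- lapply(ann$transcripts, function(t) {
    if (nrow(t$exons) < 3L || runif(1) > 0.4) return(t)
    i <- sample(nrow(t$exons) - 1L, 1L)
    ex <- t$exons
    if (ex[i + 1L, 1L] - (ex[i, 2L] + 6L) >= 30L) ex[i, 2L] <- ex[i, 2L] + 6L
    t$exons <- ex
    t
  })
  isoforms <- lapply(mutated, function(t)
    ai(paste0("o_", t$transcript_id), t$exons, t$strand, t$contig))
  records <- classify_isoforms(isoforms, ann)
  nv <- novelty_summary(records, ann)
  expect_gte(nv$junction_novelty, nv$site_novelty)
  expect_gte(nv$isoform_novelty, nv$junction_novelty)
  expect_gt(nv$isoform_novelty, 0)
})
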