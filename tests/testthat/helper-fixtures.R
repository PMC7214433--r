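# Shared fixture builders and independent brute-force oracles.

tm <- function(id, exons, strand = "+", gene = paste0("gene_", id),
               contig = "chr1", tags = character(), tsl = NA_integer_,
               coding = TRUE) {
  transcript_model(id, gene, contig, strand, exons, tags = tags, tsl = tsl,
                   coding = coding)
}

# two genes / five transcripts with hand-enumerable junction chains
fixture_annotation <- function() {
  annotation_set(list(
    # gene A, plus strand: principal + exon-skip + intron retention
    tm("A1", rbind(c(100, 200), c(300, 400), c(500, 600)), "+", "GA",
       tags = c("basic", "appris_principal"), tsl = 1L),
    tm("A2", rbind(c(100, 200), c(500, 600)), "+", "GA",
       tags = "basic", tsl = 2L),
    tm("A3", rbind(c(100, 400), c(500, 600)), "+", "GA",
       tags = "basic", tsl = 5L),
    # gene B, minus strand: principal + alt acceptor
    tm("B1", rbind(c(1000, 1150), c(1300, 1450)), "-", "GB",
       tags = c("basic", "appris_principal"), tsl = 1L),
    tm("B2", rbind(c(1000, 1150), c(1310, 1450)), "-", "GB",
       tags = "basic", tsl = 3L)))
}

# per-base set-intersection oracle for exonic overlap
overlap_oracle <- function(a, b) {
  if (a$contig != b$contig || a$strand != b$strand) return(0L)
  pa <- unlist(lapply(seq_len(nrow(a$exons)), function(i)
    seq.int(a$exons[i, 1], a$exons[i, 2] - 1L)))
  pb <- unlist(lapply(seq_len(nrow(b$exons)), function(i)
    seq.int(b$exons[i, 1], b$exons[i, 2] - 1L)))
  length(intersect(pa, pb))
}

# random small transcript on chr1 within [0, ~5000)
random_transcript <- function(id, gene = id, strand = NULL, max_exons = 4L) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  n <- sample.int(max_exons, 1L)
  lens <- sample(20:200, n, replace = TRUE)
  gaps <- if (n > 1L) sample(30:300, n - 1L, replace = TRUE) else integer()
  starts <- sample.int(1000L, 1L) + cumsum(c(0L, lens[-n] + gaps))
  tm(id, cbind(starts, starts + lens), strand, gene)
}

# brute-force structural classifier for multi-exon isoforms: enumerates all
# reference chains, all consecutive sub-chains, and the catalogs directly
classify_oracle <- function(iso, annotation) {
  ch <- junction_chain(iso)
  key <- function(m, cs)
    if (nrow(m) == 0L) character() else
      sprintf("%s|%s|%d|%d", cs$contig, cs$strand, m[, 1], m[, 2])
  iso_j <- key(ch$introns, ch)
  ref <- lapply(annotation$transcripts, junction_chain)
  ref_j <- lapply(ref, function(r) key(r$introns, r))
  if (length(iso_j) == 0L) return(NA_character_)  # mono-exon handled elsewhere
  if (any(vapply(ref_j, identical, TRUE, y = iso_j))) return("FSM")
  for (r in ref_j) {
    if (length(r) <= length(iso_j)) next
    for (s in seq_len(length(r) - length(iso_j) + 1L)) {
      if (identical(r[seq.int(s, s + length(iso_j) - 1L)], iso_j))
        return("ISM")
    }
  }
  all_j <- unique(unlist(ref_j))
  site <- function(m, cs) {
    if (nrow(m) == 0L) return(character())
    don <- if (cs$strand == "+") m[, 1] else m[, 2]
    acc <- if (cs$strand == "+") m[, 2] else m[, 1]
    c(sprintf("%s|%s|%d|D", cs$contig, cs$strand, don),
      sprintf("%s|%s|%d|A", cs$contig, cs$strand, acc))
  }
  all_s <- unique(unlist(lapply(ref, function(r) site(r$introns, r))))
  iso_s <- site(ch$introns, ch)
  if (all(iso_j %in% all_j)) return("NIC")
  if (all(iso_s %in% all_s)) return("NIC")
  "NNC"
}

small_pipeline_config <- function(seed = 7L) {
  run_config(seed = seed, n_genes = 10L, n_reads = 3000L, n_targets = 4L,
             saturation_iterations = 20L,
             saturation_depth_fractions = c(0.1, 0.5, 1))
}
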