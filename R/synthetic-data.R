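## Synthetic capture experiment generator with known ground truth.
##
## The generator emulates the statistical structure of a targeted full-length
## cDNA capture experiment: a multi-isoform annotation with canonical splice
## sites, expression spanning several orders of magnitude, overlap-dependent
## capture enrichment over constant off-target background, barcoded
## full-length reads with a controllable PCR-chimera rate, and Poisson
## short-read junction coverage.  Everything is deterministic under a seed.

#' Expression profile (TPM-like, sums to 1e6)
#'
#' @param x Named non-negative numeric vector (transcript_id -> abundance).
#' @param normalize Rescale to sum 1e6 (default TRUE).
#' @return Object of class `expression_profile` (a named numeric vector).
#' @export
expression_profile <- function(x, normalize = TRUE) {
  stopifnot(is.numeric(x), !is.null(names(x)))
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (normalize) {
    if (s <= 0) stop("total abundance is zero")
    x <- x / s * 1e6
  } else if (abs(s - 1e6) > 1e-9 * 1e6) {
    stop("abundances must sum to 1e6")
  }
  structure(x, class = "expression_profile")
}

#' Capture design: targeted genes and their probe-template ORFs
#'
#' @param targets Character vector of targeted gene ids.
#' @param template Named character vector gene_id -> transcript_id, the
#'   probe-source isoform ("ORF") for each target.
#' @param probe_tpm Named numeric vector gene_id -> probe representation
#'   (TPM-like abundance of that gene's probes in the probe set).
#' @param annotation Optional [annotation_set()] used to validate that each
#'   template belongs to its gene.
#' @return Object of class `capture_design`.
#' @export
capture_design <- function(targets, template, probe_tpm = NULL,
                           annotation = NULL) {
  stopifnot(all(targets %in% names(template)))
  if (!is.null(probe_tpm) && !all(names(probe_tpm) %in% targets))
    stop("probe_tpm keys must be a subset of targets")
  if (!is.null(annotation)) {
    for (g in targets) {
      tt <- template[[g]]
      tm <- annotation$transcripts[[tt]]
      if (is.null(tm) || tm$gene_id != g)
        stop("template ", tt, " does not belong to gene ", g)
    }
  }
  structure(list(targets = targets, template = template[targets],
                 probe_tpm = probe_tpm), class = "capture_design")
}

#' Capture efficiency model
#'
#' Retention is piecewise-linear in the exonic overlap (nt) between the
#' probe-template isoform and a transcript: background below `overlap_floor`,
#' full efficiency at or above `overlap_full`, linear in between.  The
#' default knee points encode the spike-in observation that capture
#' efficiency is flat for overlaps of 45 nt and above but collapses to
#' background at 35 nt.
#'
#' @param p_on Retention probability for fully-overlapping targets, in (0,1].
#' @param p_bg Off-target retention probability, in [0,1), `< p_on`.
#' @param overlap_full Overlap (nt) granting full efficiency (default 45).
#' @param overlap_floor Overlap (nt) below which efficiency is `p_bg`
#'   (default 35).
#' @return Object of class `capture_model`.
#' @export
capture_model <- function(p_on = 0.5, p_bg = 0.005,
                          overlap_full = 45L, overlap_floor = 35L) {
  stopifnot(p_on > 0, p_on <= 1, p_bg >= 0, p_bg < 1,
            overlap_floor < overlap_full)
  if (p_bg >= p_on) stop("p_bg must be smaller than p_on")
  structure(list(p_on = p_on, p_bg = p_bg,
                 overlap_full = as.integer(overlap_full),
                 overlap_floor = as.integer(overlap_floor)),
            class = "capture_model")
}

#' Per-transcript capture efficiency under a capture model
#'
#' @param model A [capture_model()].
#' @param overlap Integer vector of exonic overlaps (nt) with the probe
#'   template; use 0 for untargeted transcripts.
#' @param targeted Logical vector; untargeted transcripts get `p_bg`.
#' @return Numeric vector of retention efficiencies.
#' @export
capture_efficiency_curve <- function(model, overlap, targeted = TRUE) {
  frac <- pmin(1, pmax(0, (overlap - model$overlap_floor) /
                            (model$overlap_full - model$overlap_floor)))
  e <- model$p_bg + (model$p_on - model$p_bg) * frac
  targeted <- rep_len(targeted, length(e))
  e[!targeted] <- model$p_bg
  e
}

## ---------------------------------------------------------------------------
## Annotation + genome simulation

## constraint map: environment position(int key as char) -> base; plants bases
## needed for canonical splice dinucleotides / polyA motifs; a conflicting
## plant fails and the caller abandons that variant.
plant_bases <- function(env, pos, bases) {
  keys <- as.character(pos)
  old <- mget(keys, envir = env, ifnotfound = NA_character_)
  clash <- !is.na(unlist(old)) & unlist(old) != bases
  if (any(clash)) return(FALSE)
  for (i in seq_along(keys)) assign(keys[i], bases[i], envir = env)
  TRUE
}

## sense-strand GT..AG for one intron (start,end), genomic bases depend on strand
plant_intron <- function(env, strand, s, e) {
  if (strand == "+")
    plant_bases(env, c(s, s + 1L, e - 2L, e - 1L), c("G", "T", "A", "G"))
  else
    plant_bases(env, c(s, s + 1L, e - 2L, e - 1L), c("C", "T", "A", "C"))
}

plant_chain <- function(env, strand, exons) {
  n <- nrow(exons)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    if (!plant_intron(env, strand, exons[i, 2L], exons[i + 1L, 1L]))
      return(FALSE)
  }
  TRUE
}

#' Simulate a genome and multi-isoform annotation
#'
#' Each gene receives one principal transcript (tagged `appris_principal` and
#' `basic`) plus alternative isoforms derived by exon skipping, alternative
#' donors/acceptors (shifts of 3-30 nt), intron retention, and alternative
#' first/last exons.  All splice sites are canonical (sense-strand GT..AG) by
#' construction; a canonical polyA motif is planted upstream of a fraction of
#' transcript 3' ends.  Output is deterministic under `seed`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param isoforms_per_gene_range Length-2 integer range (min, max), isoforms
#'   per gene including the principal.
#' @param exons_per_transcript_range Range of exon counts for the principal.
#' @param exon_len_range,intron_len_range Ranges (nt) for exon/intron lengths.
#' @param polya_rate Fraction of transcripts with a planted AATAAA upstream of
#'   the 3' end.
#' @param genes_per_contig Genes placed per contig.
#' @param seed Integer RNG seed.
#' @return List with elements `genome` (a `DNAStringSet`) and `annotation`
#'   (an [annotation_set()]).
#' @export
simulate_annotation <- function(n_genes = 20L,
                                isoforms_per_gene_range = c(1L, 8L),
                                exons_per_transcript_range = c(3L, 9L),
                                exon_len_range = c(80L, 300L),
                                intron_len_range = c(80L, 400L),
                                polya_rate = 0.7,
                                genes_per_contig = 10L,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, all(isoforms_per_gene_range >= 1L),
            all(exons_per_transcript_range >= 1L),
            all(exon_len_range > 0L), all(intron_len_range > 40L))
  set.seed(seed)
  rng_int <- function(range) {
    if (range[1L] >= range[2L]) as.integer(range[1L])
    else sample(seq.int(range[1L], range[2L]), 1L)
  }
  n_contigs <- ceiling(n_genes / genes_per_contig)
  contigs <- sprintf("chr%d", seq_len(n_contigs))
  cursor <- setNames(rep(200L, n_contigs), contigs)
  plants <- setNames(lapply(contigs, function(x) new.env(parent = emptyenv())),
                     contigs)
  transcripts <- list()

  for (gi in seq_len(n_genes)) {
    gid <- sprintf("G%04d", gi)
    contig <- contigs[[((gi - 1L) %/% genes_per_contig) + 1L]]
    env <- plants[[contig]]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- rng_int(exons_per_transcript_range)
    lens <- vapply(seq_len(n_ex), function(i) rng_int(exon_len_range), 0L)
    gaps <- if (n_ex > 1L)
      vapply(seq_len(n_ex - 1L), function(i) rng_int(intron_len_range), 0L)
    else integer()
    starts <- cursor[[contig]] + cumsum(c(0L, lens[-n_ex] + gaps))
    principal <- cbind(starts, starts + lens)
    if (!plant_chain(env, strand, principal))
      stop("internal: could not plant principal splice sites for ", gid)
    n_iso <- rng_int(isoforms_per_gene_range)
    iso_exons <- list(principal)
    chain_seen <- paste(principal[-n_ex, 2L], principal[-1L, 1L],
                        sep = "-", collapse = "|")
    attempts <- 0L
    while (length(iso_exons) < n_iso && attempts < 50L) {
      attempts <- attempts + 1L
      ex <- derive_isoform_variant(principal, strand,
                                   intron_min = 40L, exon_min = 20L)
      if (is.null(ex)) next
      key <- if (nrow(ex) > 1L)
        paste(ex[-nrow(ex), 2L], ex[-1L, 1L], sep = "-", collapse = "|")
      else sprintf("mono:%d-%d", ex[1L, 1L], ex[1L, 2L])
      if (key %in% chain_seen) next
      if (!plant_chain(env, strand, ex)) next
      iso_exons[[length(iso_exons) + 1L]] <- ex
      chain_seen <- c(chain_seen, key)
    }
    for (k in seq_along(iso_exons)) {
      tid <- sprintf("%s.T%02d", gid, k)
      ex <- iso_exons[[k]]
      ## plant polyA motif in the last sense exon for a fraction of isoforms
      if (runif(1) < polya_rate) {
        off <- sample(5:20, 1L)  # offset of motif's last base from the 3' end
        if (strand == "+") {
          last <- ex[nrow(ex), ]
          if (last[2L] - last[1L] > off + 6L)
            plant_bases(env, seq.int(last[2L] - 1L - off - 5L, last[2L] - 1L - off),
                        c("A", "A", "T", "A", "A", "A"))
        } else {
          first <- ex[1L, ]
          if (first[2L] - first[1L] > off + 6L)
            plant_bases(env, seq.int(first[1L] + off + 5L, first[1L] + off,
                                     by = -1L),
                        c("T", "T", "A", "T", "T", "T"))
        }
      }
      transcripts[[tid]] <- transcript_model(
        tid, gid, contig, strand, ex,
        tags = if (k == 1L) c("basic", "appris_principal") else "basic",
        tsl = if (k == 1L) 1L else sample(1:5, 1L),
        coding = TRUE)
    }
    span_end <- max(vapply(iso_exons, function(e) max(e[, 2L]), 0L))
    cursor[[contig]] <- span_end + 500L
  }

  genome <- Biostrings::DNAStringSet(setNames(vapply(contigs, function(cn) {
    len <- cursor[[cn]] + 200L
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    env <- plants[[cn]]
    keys <- ls(env)
    if (length(keys) > 0L) {
      pos <- as.integer(keys)
      if (any(pos >= len)) stop("internal: planted base outside contig")
      bases[pos + 1L] <- unlist(mget(keys, envir = env), use.names = FALSE)
    }
    paste(bases, collapse = "")
  }, ""), contigs))
  list(genome = genome, annotation = annotation_set(transcripts))
}

## One structural variant of the principal isoform; NULL if not feasible.
derive_isoform_variant <- function(principal, strand, intron_min, exon_min) {
  n <- nrow(principal)
  moves <- c(if (n >= 3L) "skip",
             if (n >= 2L) c("alt5", "alt3", "retain", "alt_first", "alt_last"))
  if (is.null(moves)) return(NULL)
  move <- sample(moves, 1L)
  ex <- principal
  switch(move,
    skip = ex[-sample(2:(n - 1L), 1L), , drop = FALSE],
    retain = {                       # merge two exons across an intron
      i <- sample(seq_len(n - 1L), 1L)
      ex[i, 2L] <- ex[i + 1L, 2L]
      ex[-(i + 1L), , drop = FALSE]
    },
    alt5 = ,                         # shift an internal boundary (donor or
    alt3 = {                         # acceptor depending on strand)
      i <- sample(seq_len(n - 1L), 1L)
      delta <- sample(c(-(3:30), 3:30), 1L)
      side <- if (move == "alt5") "end" else "start"
      if (side == "end") {
        newv <- ex[i, 2L] + delta
        if (newv - ex[i, 1L] < exon_min || ex[i + 1L, 1L] - newv < intron_min)
          return(NULL)
        ex[i, 2L] <- newv
      } else {
        newv <- ex[i + 1L, 1L] + delta
        if (ex[i + 1L, 2L] - newv < exon_min || newv - ex[i, 2L] < intron_min)
          return(NULL)
        ex[i + 1L, 1L] <- newv
      }
      ex
    },
    alt_first = {                    # new leftmost exon inside the 1st intron
      gap_lo <- ex[1L, 2L] + intron_min
      gap_hi <- ex[2L, 1L] - intron_min
      if (gap_hi - gap_lo < exon_min + 10L) return(NULL)
      s <- sample(seq.int(gap_lo, gap_hi - exon_min), 1L)
      e <- min(gap_hi, s + exon_min + sample(0:40, 1L))
      rbind(c(s, e), ex[-1L, , drop = FALSE])
    },
    alt_last = {                     # new rightmost exon inside the last intron
      gap_lo <- ex[n - 1L, 2L] + intron_min
      gap_hi <- ex[n, 1L] - intron_min
      if (gap_hi - gap_lo < exon_min + 10L) return(NULL)
      s <- sample(seq.int(gap_lo, gap_hi - exon_min), 1L)
      e <- min(gap_hi, s + exon_min + sample(0:40, 1L))
      rbind(ex[-n, , drop = FALSE], c(s, e))
    })
}

## ---------------------------------------------------------------------------
## Expression

#' Simulate a wide-dynamic-range expression profile
#'
#' Per-gene abundances are drawn log-uniform over `log10_range` orders of
#' magnitude (the dynamic range reported for the human transcriptome is at
#' least six); each gene's abundance is split across its isoforms by a
#' symmetric Dirichlet with concentration 1, and the profile is normalised to
#' one million (TPM-like).
#'
#' @param annotation An [annotation_set()].
#' @param log10_range Orders of magnitude spanned (> 0; default 6).
#' @param seed Integer RNG seed.
#' @return An [expression_profile()].
#' @export
simulate_expression <- function(annotation, log10_range = 6, seed = 1L) {
  if (log10_range <= 0) stop("log10_range must be positive")
  if (length(annotation$transcripts) == 0L) stop("empty annotation")
  set.seed(seed)
  ab <- unlist(lapply(names(annotation$genes), function(g) {
    tids <- annotation$genes[[g]]
    gene_ab <- 10^runif(1L, 0, log10_range)
    w <- rgamma(length(tids), shape = 1)        # symmetric Dirichlet(1)
    setNames(gene_ab * w / sum(w), tids)
  }))
  expression_profile(ab)
}

#' Apply overlap-dependent capture to an expression profile
#'
#' For each transcript of a targeted gene the retention efficiency follows
#' the piecewise-linear [capture_model()] in its exonic overlap with the
#' gene's probe-template isoform; untargeted transcripts retain at the
#' background rate.  Post-capture abundance is proportional to pre-capture
#' abundance times efficiency, renormalised to 1e6.  The baseline model is
#' deterministic; `seed` is reserved for optional noise extensions.
#'
#' @param profile Pre-capture [expression_profile()].
#' @param design A [capture_design()].
#' @param model A [capture_model()].
#' @param annotation The [annotation_set()] the profile refers to.
#' @param seed Unused by the deterministic baseline model.
#' @return List with `profile` (post-capture [expression_profile()]) and
#'   `efficiency` (named per-transcript retention vector).
#' @export
simulate_capture <- function(profile, design, model, annotation, seed = NULL) {
  tids <- names(profile)
  eff <- setNames(rep(model$p_bg, length(tids)), tids)
  for (g in design$targets) {
    templ_id <- design$template[[g]]
    templ <- annotation$transcripts[[templ_id]]
    if (is.null(templ)) stop("template transcript ", templ_id,
                             " absent from annotation")
    members <- intersect(annotation$genes[[g]], tids)
    ov <- vapply(members, function(id)
      exonic_overlap(templ, annotation$transcripts[[id]]), 0L)
    eff[members] <- capture_efficiency_curve(model, ov)
  }
  post <- as.numeric(profile) * eff
  list(profile = expression_profile(setNames(post, tids)), efficiency = eff)
}

## ---------------------------------------------------------------------------
## Long reads

encode_blocks <- function(exons) {
  paste(sprintf("%d-%d", exons[, 1L], exons[, 2L]), collapse = ";")
}

decode_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  as_exon_matrix(do.call(rbind, lapply(parts, as.integer)))
}

#' Default dual-barcode pairing table
#'
#' @param n Number of barcode pairs (default 96, the standard plate format).
#' @return data.frame with columns `barcode_5p`, `barcode_3p`, `pair_id`.
#' @export
dual_barcode_pair_table <- function(n = 96L) {
  pid <- sprintf("db%03d", seq_len(n))
  data.frame(barcode_5p = paste0(pid, ".5p"),
             barcode_3p = paste0(pid, ".3p"),
             pair_id = pid, stringsAsFactors = FALSE)
}

#' Simulate barcoded long reads with PCR chimeras
#'
#' Source transcripts are drawn proportional to abundance.  With probability
#' `chimera_rate` a read is a PCR chimera joining the 5' portion of molecule A
#' to the 3' portion of an independently drawn molecule B, so its dual inner
#' barcodes mismatch; alignment blocks are those of the 5' parent molecule.
#' With probability `fl_rate` a read carries both primers and the polyA tail
#' (the full-length definition); otherwise exactly one of the three elements
#' is dropped uniformly at random.  A read missing its 3' primer also loses
#' its sample barcode (which sits inside that primer); a missing primer hides
#' the corresponding inner barcode.
#'
#' @param profile [expression_profile()] to sample from.
#' @param annotation [annotation_set()] supplying exon structures.
#' @param n_reads Number of reads (>= 1).
#' @param fl_rate Probability a read is full length, in \[0,1\].
#' @param chimera_rate Probability a read is a PCR chimera, in \[0,1\].
#' @param sample_barcodes Character vector of sample barcodes (reads are
#'   assigned uniformly).
#' @param dual_barcode_pairs Pairing data.frame as from
#'   [dual_barcode_pair_table()], or `NULL` to disable dual barcoding.
#' @param seed Integer RNG seed.
#' @return data.frame of class `long_read_set`: one row per read with primer
#'   and polyA flags, barcodes, encoded alignment blocks, and truth columns
#'   (`truth_transcript_id`, `truth_3p_transcript_id`, `truth_chimera`).
#'   The pairing table is attached as attribute `pairs`.
#' @export
simulate_long_reads <- function(profile, annotation, n_reads,
                                fl_rate = 0.8, chimera_rate = 0.02,
                                sample_barcodes = sprintf("bc%02d", 1:7),
                                dual_barcode_pairs = dual_barcode_pair_table(),
                                seed = 1L) {
  stopifnot(n_reads >= 1L, fl_rate >= 0, fl_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  if (!is.null(dual_barcode_pairs) && nrow(dual_barcode_pairs) == 0L)
    stop("dual barcoding requested with an empty pairing table")
  if (length(sample_barcodes) == 0L) stop("no sample barcodes given")
  set.seed(seed)
  tids <- names(profile)
  prob <- as.numeric(profile)
  tx_a <- sample(tids, n_reads, replace = TRUE, prob = prob)
  chim <- runif(n_reads) < chimera_rate
  tx_b <- tx_a
  if (any(chim)) tx_b[chim] <- sample(tids, sum(chim), replace = TRUE, prob = prob)
  pair_a <- pair_b <- rep(NA_character_, n_reads)
  if (!is.null(dual_barcode_pairs)) {
    pair_a <- sample(dual_barcode_pairs$pair_id, n_reads, replace = TRUE)
    pair_b <- pair_a
    if (any(chim))
      pair_b[chim] <- sample(dual_barcode_pairs$pair_id, sum(chim), replace = TRUE)
  }
  fl <- runif(n_reads) < fl_rate
  dropped <- ifelse(fl, 0L, sample(1:3, n_reads, replace = TRUE))
  has5 <- dropped != 1L
  has3 <- dropped != 2L
  haspa <- dropped != 3L
  sb <- sample(sample_barcodes, n_reads, replace = TRUE)
  sb[!has3] <- NA_character_
  b5 <- b3 <- rep(NA_character_, n_reads)
  if (!is.null(dual_barcode_pairs)) {
    idx_a <- match(pair_a, dual_barcode_pairs$pair_id)
    idx_b <- match(pair_b, dual_barcode_pairs$pair_id)
    b5 <- ifelse(has5, dual_barcode_pairs$barcode_5p[idx_a], NA_character_)
    b3 <- ifelse(has3, dual_barcode_pairs$barcode_3p[idx_b], NA_character_)
  }
  ## block structure comes from the 5' parent molecule
  tx_tab <- annotation$transcripts[tx_a]
  reads <- data.frame(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    sample_barcode = sb,
    has_5p_primer = has5, has_3p_primer = has3, has_polyA = haspa,
    inner_5p_barcode = b5, inner_3p_barcode = b3,
    contig = vapply(tx_tab, `[[`, "", "contig"),
    strand = vapply(tx_tab, `[[`, "", "strand"),
    blocks = vapply(tx_tab, function(t) encode_blocks(t$exons), ""),
    coverage = 1, identity = 1,
    truth_transcript_id = tx_a,
    truth_3p_transcript_id = tx_b,
    truth_chimera = chim,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(reads, "pairs") <- dual_barcode_pairs
  class(reads) <- c("long_read_set", "data.frame")
  reads
}

#' Simulate short-read junction counts
#'
#' The count for junction j is Poisson with mean `mean_depth` times the
#' relative abundance mass of the transcripts containing j; junctions present
#' in no expressed transcript get count 0.
#'
#' @param profile [expression_profile()].
#' @param annotation [annotation_set()].
#' @param mean_depth Expected read count at a junction carried by the whole
#'   library (> 0).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `count` (one row per annotated junction).
#' @export
simulate_short_read_junction_counts <- function(profile, annotation,
                                                mean_depth = 5e5, seed = 1L) {
  stopifnot(mean_depth > 0)
  set.seed(seed)
  mass <- setNames(numeric(length(annotation$junction_catalog)),
                   annotation$junction_catalog)
  for (t in annotation$transcripts) {
    keys <- junction_keys(junction_chain(t))
    ab <- profile[[t$transcript_id]]
    if (!is.null(ab) && length(keys) > 0L)
      mass[keys] <- mass[keys] + ab / 1e6
  }
  parts <- do.call(rbind, strsplit(names(mass), ":", fixed = TRUE))
  se <- do.call(rbind, strsplit(parts[, 3L], "-", fixed = TRUE))
  data.frame(contig = parts[, 1L],
             start = as.integer(se[, 1L]), end = as.integer(se[, 2L]),
             strand = parts[, 2L],
             count = rpois(length(mass), mean_depth * unname(mass)),
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---------------------------------------------------------------------------
## Auxiliary simulated evidence tracks

#' Simulate CAGE peaks at annotated transcription start sites
#'
#' One peak per distinct annotated 5' end, centered at the TSS up to
#' `jitter` nt away, with half-width `halfwidth`.
#'
#' @param annotation [annotation_set()].
#' @param halfwidth Peak half-width (nt).
#' @param jitter Maximum |center - TSS| displacement (nt).
#' @param seed Integer RNG seed.
#' @return data.frame with 0-based half-open columns `contig`, `start`,
#'   `end`, `name`, `strand`.
#' @export
simulate_cage_peaks <- function(annotation, halfwidth = 25L, jitter = 5L,
                                seed = 1L) {
  set.seed(seed)
  tss <- unique(do.call(rbind, lapply(annotation$transcripts, function(t)
    data.frame(contig = t$contig, pos = five_prime_pos(t), strand = t$strand,
               stringsAsFactors = FALSE))))
  center <- tss$pos + sample(seq.int(-jitter, jitter), nrow(tss), replace = TRUE)
  data.frame(contig = tss$contig,
             start = pmax(0L, center - halfwidth),
             end = center + halfwidth + 1L,
             name = sprintf("peak%04d", seq_len(nrow(tss))),
             strand = tss$strand, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a per-base conservation track over splice sites
#'
#' Emits elevated scores over every annotated splice-site trinucleotide
#' (donor: last exonic base + first two intronic; acceptor: last two intronic
#' + first exonic), mimicking the elevated phyloP conservation of splice
#' sites; other positions are uncovered.
#'
#' @param annotation [annotation_set()].
#' @param mean_score Mean of the emitted scores.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `contig`, `start`, `end`, `score`
#'   (0-based half-open single-base intervals).
#' @export
simulate_conservation_track <- function(annotation, mean_score = 3,
                                        seed = 1L) {
  set.seed(seed)
  pos <- unique(do.call(rbind, lapply(annotation$transcripts, function(t) {
    ch <- junction_chain(t)
    if (nrow(ch$introns) == 0L) return(NULL)
    s <- ch$introns[, 1L]; e <- ch$introns[, 2L]
    data.frame(contig = t$contig,
               p = c(s - 1L, s, s + 1L, e - 2L, e - 1L, e),
               stringsAsFactors = FALSE)
  })))
  pos <- pos[order(pos$contig, pos$p), , drop = FALSE]
  data.frame(contig = pos$contig, start = pos$p, end = pos$p + 1L,
             score = round(mean_score + runif(nrow(pos), -1, 1), 3),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a bedGraph track
#' @param track data.frame with `contig`, `start`, `end`, `score` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$contig,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write CAGE-style peaks as BED
#' @param peaks data.frame as from [simulate_cage_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(peaks, path) {
  gr <- GenomicRanges::GRanges(peaks$contig,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = if ("strand" %in% names(peaks))
                                 peaks$strand else "*")
  gr$name <- peaks$name
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED file of peaks
#' @param path BED file.
#' @return data.frame with 0-based half-open `contig`, `start`, `end`,
#'   `name`, `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("peak%04d", seq_along(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Emit literal read sequences as FASTA
#'
#' Writes, for each read, the concatenation of the elements it carries:
#' 5' primer (with inner 5' barcode), the sense cDNA sequence of its source
#' transcript, a 30-nt polyA tail, and the 3' primer (with sample and inner
#' 3' barcodes).  Intended for interface-level tests; classification operates
#' on exon-block structure.
#'
#' @param reads A `long_read_set`.
#' @param genome Genome `DNAStringSet`.
#' @param annotation [annotation_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_read_fasta <- function(reads, genome, annotation, path) {
  ## deterministic id -> DNA mapping so barcode labels become literal 16-mers
  id_to_dna <- function(id, len = 16L) {
    if (is.na(id)) return("")
    codes <- utf8ToInt(id)
    idx <- (cumsum(codes * seq_along(codes)) + codes) %% 4L + 1L
    paste(rep_len(c("A", "C", "G", "T")[idx], len), collapse = "")
  }
  seqs <- vapply(seq_len(nrow(reads)), function(i) {
    t <- annotation$transcripts[[reads$truth_transcript_id[i]]]
    body <- paste(vapply(seq_len(nrow(t$exons)), function(j)
      genome_subseq(genome, t$contig, t$exons[j, 1L], t$exons[j, 2L]), ""),
      collapse = "")
    if (t$strand == "-") body <- revcomp(body)
    paste0(
      if (reads$has_5p_primer[i])
        paste0("AAGCAGTGGTATCAACGCAGAGTACATGGG",
               id_to_dna(reads$inner_5p_barcode[i]))
      else "",
      body,
      if (reads$has_polyA[i]) strrep("A", 30L) else "",
      if (reads$has_3p_primer[i])
        paste0(id_to_dna(reads$sample_barcode[i]),
               id_to_dna(reads$inner_3p_barcode[i]),
               "AAGCAGTGGTATCAACGCAGAGTAC")
      else "")
  }, "")
  writeLines(paste0(">", reads$read_id, "\n", seqs), path)
  invisible(path)
}
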