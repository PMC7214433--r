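## Functional feature annotation of isoforms (CAGE 5' support, canonical
## polyA motif upstream of the 3' end, splice-site trinucleotide
## conservation) and the orthogonal short-read novel-junction validation
## filter.

POLYA_MOTIFS <- c("AATAAA", "ATTAAA")

#' CAGE support of an isoform 5' end
#'
#' Finds the peak whose center is closest to the strand-aware 5' end and
#' reports (i) the signed distance to that center (negative when the 5' end
#' lies upstream of the center in transcript orientation) and (ii) whether
#' the 5' end falls inside any peak interval (half-open).
#'
#' @param iso [aligned_isoform()] or [transcript_model()].
#' @param peaks data.frame of peaks (`contig`, `start`, `end`; 0-based
#'   half-open), e.g. from [simulate_cage_peaks()] or [read_bed6()].
#' @return List with `cage_distance` (NA when no peak shares the contig) and
#'   `within_cage`.
#' @export
cage_annotate <- function(iso, peaks) {
  pos <- five_prime_pos(iso)
  p <- peaks[peaks$contig == iso$contig, , drop = FALSE]
  if (nrow(p) == 0L)
    return(list(cage_distance = NA_integer_, within_cage = FALSE))
  centers <- (p$start + p$end - 1L) %/% 2L   # central base of the interval
  d_gen <- pos - centers
  d_tx <- if (iso$strand == "+") d_gen else -d_gen
  i <- which.min(abs(d_tx))
  list(cage_distance = unname(d_tx[i]),
       within_cage = any(p$start <= pos & pos < p$end))
}

#' Scan for a canonical polyA motif upstream of the 3' end
#'
#' Scans the transcript-sense genomic window whose 3'-most base lies 5 nt
#' and whose 5'-most base lies 25 nt upstream of the 3' end for the
#' canonical hexamers AATAAA / ATTAAA (sense strand; reverse-complement
#' lookup on the minus strand).  A motif counts only if it lies entirely
#' within the window; the match nearest the 3' end is reported.  Offsets are
#' measured from the 3' end to the motif's last base (`offset_end`) and
#' first base (`offset_start`), to support either reading of the window
#' convention.
#'
#' @param iso [aligned_isoform()] or [transcript_model()].
#' @param genome Genome `DNAStringSet`.
#' @param window Length-2 integer: closest and farthest offsets (nt upstream
#'   of the 3' end) that the motif may occupy (default `c(5, 25)`).
#' @return List: `found`, `motif` (NA when absent), `offset_end`,
#'   `offset_start`.
#' @export
polya_motif_scan <- function(iso, genome, window = c(5L, 25L)) {
  lo <- window[1L]; hi <- window[2L]
  pos3 <- three_prime_pos(iso)
  if (iso$strand == "+") {
    from <- max(0L, pos3 - hi); to <- pos3 - lo + 1L     # [from, to)
    if (to <= from) return(list(found = FALSE, motif = NA_character_,
                                offset_end = NA_integer_, offset_start = NA_integer_))
    win <- genome_subseq(genome, iso$contig, from, to)
  } else {
    from <- pos3 + lo; to <- min(length(genome[[iso$contig]]), pos3 + hi + 1L)
    if (to <= from) return(list(found = FALSE, motif = NA_character_,
                                offset_end = NA_integer_, offset_start = NA_integer_))
    win <- revcomp(genome_subseq(genome, iso$contig, from, to))
  }
  ## win is the sense-strand window, 5'->3'; its last base is `lo` nt
  ## upstream of the 3' end
  best <- NULL
  for (m in POLYA_MOTIFS) {
    hits <- gregexpr(m, win, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    last_base <- hits + 5L                    # 1-based position in win
    off_end <- nchar(win) - last_base + lo    # nt upstream of the 3' end
    cand <- min(off_end)
    if (is.null(best) || cand < best$offset_end)
      best <- list(found = TRUE, motif = m, offset_end = cand,
                   offset_start = cand + 5L)
  }
  if (is.null(best))
    best <- list(found = FALSE, motif = NA_character_,
                 offset_end = NA_integer_, offset_start = NA_integer_)
  best
}

#' Splice-site trinucleotide conservation and dinucleotides
#'
#' For each junction the donor trinucleotide is the last exonic base plus
#' the first two intronic bases, and the acceptor trinucleotide the last two
#' intronic bases plus the first exonic base (strand-aware).  Per-base
#' conservation scores are fetched from the track; positions the track does
#' not cover stay `NA` (0 is a meaningful conservation value and is never
#' substituted).
#'
#' @param iso [aligned_isoform()] or [transcript_model()].
#' @param track A [read_track()] score track, or NULL.
#' @param genome Optional genome `DNAStringSet`; enables dinucleotide
#'   reporting.
#' @return data.frame with one row per junction: intron coordinates, donor
#'   and acceptor score triples (`donor_s1..3`, `acceptor_s1..3`, in
#'   transcript-sense order), mean scores, and dinucleotides when a genome is
#'   given.
#' @export
junction_conservation <- function(iso, track = NULL, genome = NULL) {
  chain <- junction_chain(iso)
  n <- nrow(chain$introns)
  if (n == 0L) return(NULL)
  s <- chain$introns[, 1L]; e <- chain$introns[, 2L]
  if (chain$strand == "+") {
    donor_pos <- cbind(s - 1L, s, s + 1L)
    acceptor_pos <- cbind(e - 2L, e - 1L, e)
  } else {
    donor_pos <- cbind(e, e - 1L, e - 2L)
    acceptor_pos <- cbind(s + 1L, s, s - 1L)
  }
  fetch <- function(posmat) {
    if (is.null(track)) return(matrix(NA_real_, n, 3L))
    matrix(track_value(track, chain$contig, as.vector(posmat)), n, 3L)
  }
  ds <- fetch(donor_pos); as_ <- fetch(acceptor_pos)
  out <- data.frame(contig = chain$contig, strand = chain$strand,
                    intron_start = s, intron_end = e,
                    donor_s1 = ds[, 1L], donor_s2 = ds[, 2L], donor_s3 = ds[, 3L],
                    acceptor_s1 = as_[, 1L], acceptor_s2 = as_[, 2L],
                    acceptor_s3 = as_[, 3L],
                    donor_mean = rowMeans(ds), acceptor_mean = rowMeans(as_),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(genome)) {
    din <- splice_dinucleotides(chain, genome)
    out$donor_dinucleotide <- din$donor
    out$acceptor_dinucleotide <- din$acceptor
  }
  out
}

#' Validate novel isoforms against short-read junction support
#'
#' An isoform is validated iff every one of its novel junctions is supported
#' by at least `min_support` short reads (inclusive); isoforms with no novel
#' junctions are validated vacuously.  Junctions absent from the count table
#' count as 0.
#'
#' @param records Classification data.frame from [classify_isoforms()].
#' @param junction_counts data.frame (`contig`, `start`, `end`, `strand`,
#'   `count`), e.g. from [simulate_short_read_junction_counts()].
#' @param min_support Minimum supporting short reads per novel junction.
#' @return `records` with a logical `validated` column added; the attribute
#'   `filtered` holds the row indices of validated isoforms (novel isoforms
#'   failing validation are the ones dropped).
#' @export
validate_novel_isoforms <- function(records, junction_counts,
                                    min_support = 3L) {
  counts <- setNames(junction_counts$count,
                     sprintf("%s:%s:%d-%d", junction_counts$contig,
                             junction_counts$strand, junction_counts$start,
                             junction_counts$end))
  records$validated <- vapply(records$novel_junctions, function(nj) {
    if (!nzchar(nj)) return(TRUE)
    keys <- strsplit(nj, ";", fixed = TRUE)[[1L]]
    support <- counts[keys]
    support[is.na(support)] <- 0L
    all(support >= min_support)
  }, TRUE, USE.NAMES = FALSE)
  attr(records, "filtered") <- which(records$validated)
  records
}

#' Annotate a set of isoforms with functional features
#'
#' Driver combining [cage_annotate()], [polya_motif_scan()] and
#' [junction_conservation()] into one feature table.
#'
#' @param isoforms List of [aligned_isoform()] objects.
#' @param peaks Optional CAGE peak data.frame.
#' @param genome Optional genome `DNAStringSet`.
#' @param track Optional [read_track()] conservation track.
#' @param polya_window PolyA scan window (see [polya_motif_scan()]).
#' @return data.frame with one row per isoform.
#' @export
annotate_features <- function(isoforms, peaks = NULL, genome = NULL,
                              track = NULL, polya_window = c(5L, 25L)) {
  do.call(rbind, lapply(isoforms, function(iso) {
    cage <- if (!is.null(peaks)) cage_annotate(iso, peaks)
    else list(cage_distance = NA_integer_, within_cage = NA)
    pa <- if (!is.null(genome)) polya_motif_scan(iso, genome, polya_window)
    else list(found = NA, motif = NA_character_,
              offset_end = NA_integer_, offset_start = NA_integer_)
    jc <- if (!is.null(track) || !is.null(genome))
      junction_conservation(iso, track, genome) else NULL
    data.frame(isoform_id = iso$isoform_id,
               cage_distance = cage$cage_distance,
               within_cage = cage$within_cage,
               polya_motif_found = pa$found, polya_motif = pa$motif,
               polya_motif_offset = pa$offset_end,
               polya_motif_offset_start = pa$offset_start,
               donor_mean_score = if (!is.null(jc)) mean(jc$donor_mean) else NA_real_,
               acceptor_mean_score = if (!is.null(jc)) mean(jc$acceptor_mean) else NA_real_,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
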