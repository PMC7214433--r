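## Capture-coverage estimation: what fraction of annotated isoforms a
## one-ORF-per-gene probe design can capture, given the empirical observation
## that >= 50 bp of sequence overlap with the probe template suffices.

#' Exonic overlap between two transcripts (nt)
#'
#' Total base pairs in the intersection of the two transcripts' exon-interval
#' unions; 0 when the transcripts sit on different contigs or strands (capture
#' hybridisation is sequence-specific).
#'
#' @param a,b [transcript_model()] objects (or aligned isoforms).
#' @param span If `TRUE`, intersect whole genomic spans (first exon start to
#'   last exon end) instead of exon unions; the alternative reading of
#'   "intersection of genomic ranges".
#' @return Integer overlap in nt.
#' @export
exonic_overlap <- function(a, b, span = FALSE) {
  if (a$contig != b$contig || a$strand != b$strand) return(0L)
  if (span) {
    lo <- max(a$exons[1L, 1L], b$exons[1L, 1L])
    hi <- min(a$exons[nrow(a$exons), 2L], b$exons[nrow(b$exons), 2L])
    return(max(0L, hi - lo))
  }
  ia <- IRanges::IRanges(a$exons[, 1L] + 1L, a$exons[, 2L])
  ib <- IRanges::IRanges(b$exons[, 1L] + 1L, b$exons[, 2L])
  sum(IRanges::width(IRanges::intersect(ia, ib)))
}

#' Select one representative (probe-template) transcript per gene
#'
#' @param annotation An [annotation_set()].
#' @param mode `"appris"` (the APPRIS-principal-tagged transcript),
#'   `"random"` (uniform over the gene's transcripts, deterministic under
#'   `seed`), or `"specified"` (taken from `overrides`).
#' @param seed RNG seed for `mode = "random"`.
#' @param overrides Named character vector gene_id -> transcript_id, required
#'   for `mode = "specified"`.
#' @param untagged_policy What to do in appris mode for genes with no tagged
#'   transcript: `"skip"` (drop the gene, with a warning), `"longest"`
#'   (fall back to the longest transcript), or `"error"`.
#' @return Named character vector gene_id -> transcript_id.  Skipped genes
#'   are recorded in attribute `skipped`.
#' @export
select_representative <- function(annotation,
                                  mode = c("appris", "random", "specified"),
                                  seed = 1L, overrides = NULL,
                                  untagged_policy = c("skip", "longest", "error")) {
  mode <- match.arg(mode)
  untagged_policy <- match.arg(untagged_policy)
  genes <- annotation$genes
  if (mode == "specified") {
    if (is.null(overrides) || !all(names(genes) %in% names(overrides)))
      stop("mode 'specified' requires an override for every gene")
    return(vapply(names(genes), function(g) overrides[[g]], ""))
  }
  if (mode == "random") set.seed(seed)
  skipped <- character()
  reps <- vapply(names(genes), function(g) {
    tids <- genes[[g]]
    if (mode == "random")
      return(if (length(tids) == 1L) tids else sample(tids, 1L))
    tagged <- tids[vapply(annotation$transcripts[tids], function(t)
      "appris_principal" %in% t$tags, TRUE)]
    if (length(tagged) >= 1L) return(tagged[1L])
    switch(untagged_policy,
           error = stop("gene ", g, " has no appris_principal transcript"),
           longest = tids[which.max(vapply(annotation$transcripts[tids],
                                           exonic_length, 0L))],
           skip = { skipped <<- c(skipped, g); NA_character_ })
  }, "")
  if (length(skipped) > 0L) {
    warning(length(skipped), " gene(s) without appris_principal tag skipped")
    reps <- reps[!is.na(reps)]
  }
  attr(reps, "skipped") <- skipped
  reps
}

#' Estimate capture coverage of an annotation by one probe template per gene
#'
#' An isoform counts as covered iff its exonic overlap with its gene's
#' representative is at least `min_overlap` nt (default 50, the empirically
#' sufficient overlap); the representative always covers itself, even when
#' shorter than `min_overlap` (a probe trivially captures its own template).
#'
#' @param annotation An [annotation_set()].  Apply any coding/basic filtering
#'   before calling (see [filter_basic_coding()]).
#' @param representatives Named vector gene_id -> transcript_id, as from
#'   [select_representative()]; genes absent from it are excluded.
#' @param min_overlap Coverage threshold in nt (>= 1).
#' @param span Use genomic-span overlap instead of exonic overlap (the
#'   alternative reading; both are reported by the pipeline).
#' @return Object of class `coverage_report`: n_genes, n_isoforms,
#'   n_covered, fraction_covered, per_gene data.frame, min_overlap, mode.
#' @export
coverage_estimate <- function(annotation, representatives, min_overlap = 50L,
                              span = FALSE) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  gids <- intersect(names(annotation$genes), names(representatives))
  per_gene <- do.call(rbind, lapply(gids, function(g) {
    rep_id <- representatives[[g]]
    rep_t <- annotation$transcripts[[rep_id]]
    tids <- annotation$genes[[g]]
    covered <- vapply(tids, function(id) {
      id == rep_id ||
        exonic_overlap(rep_t, annotation$transcripts[[id]], span = span) >=
          min_overlap
    }, TRUE)
    data.frame(gene_id = g, representative_id = rep_id,
               n_covered = sum(covered), n_isoforms = length(tids),
               stringsAsFactors = FALSE)
  }))
  n_iso <- sum(per_gene$n_isoforms)
  n_cov <- sum(per_gene$n_covered)
  structure(list(n_genes = length(gids), n_isoforms = n_iso,
                 n_covered = n_cov,
                 fraction_covered = if (n_iso > 0L) n_cov / n_iso else NaN,
                 per_gene = per_gene, min_overlap = as.integer(min_overlap),
                 mode = if (span) "span" else "exonic"),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d genes, %d isoforms, %d covered (%.2f%%), min_overlap=%d nt (%s overlap)\n",
              x$n_genes, x$n_isoforms, x$n_covered,
              100 * x$fraction_covered, x$min_overlap, x$mode))
  invisible(x)
}

#' Restrict an annotation to coding transcripts with the `basic` tag
#'
#' The filtering applied before coverage estimation: only protein-coding
#' transcripts carrying the GENCODE `basic` tag are considered.
#'
#' @param annotation An [annotation_set()].
#' @return Filtered [annotation_set()].
#' @export
filter_basic_coding <- function(annotation) {
  keep <- vapply(annotation$transcripts, function(t)
    t$coding && "basic" %in% t$tags, TRUE)
  if (!any(keep)) stop("no coding transcripts with the 'basic' tag")
  subset_annotation(annotation, names(annotation$transcripts)[keep])
}
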