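## Core genomic data types and format IO.
## All internal coordinates are 0-based half-open; GTF converts on read/write.

#' Construct a transcript model
#'
#' The unit of classification and overlap analysis: one annotated or observed
#' transcript, as a set of ordered exon intervals on a contig.
#'
#' @param transcript_id,gene_id Identifier strings.
#' @param contig Contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column integer matrix (`start`, `end`) of exon intervals,
#'   0-based half-open, ascending and non-overlapping.  A two-column
#'   data.frame or a list of length-2 vectors is accepted and coerced.
#' @param tags Character vector; recognised tags are `"basic"` and
#'   `"appris_principal"`.
#' @param tsl Transcript support level, integer 1-5, or `NA` when absent.
#' @param coding Logical; is the transcript protein-coding?
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             tags = character(), tsl = NA_integer_,
                             coding = TRUE) {
  exons <- as_exon_matrix(exons)
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"))
  if (nrow(exons) < 1L)
    stop("transcript '", transcript_id, "' has no exons")
  if (any(exons[, 1L] >= exons[, 2L]))
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  if (nrow(exons) > 1L) {
    if (is.unsorted(exons[, 1L], strictly = TRUE))
      stop("exons of '", transcript_id, "' are not sorted ascending")
    if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
      stop("exons of '", transcript_id, "' overlap")
  }
  tsl <- as.integer(tsl)
  if (!is.na(tsl) && (tsl < 1L || tsl > 5L))
    stop("tsl must be in 1..5 or NA")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons,
                 tags = unique(tags), tsl = tsl, coding = isTRUE(coding)),
            class = "transcript_model")
}

as_exon_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  dimnames(x) <- list(NULL, c("start", "end"))
  x
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s) [%d, %d)\n",
              x$transcript_id, x$gene_id, x$contig, x$strand, nrow(x$exons),
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L]))
  invisible(x)
}

exonic_length <- function(t) sum(t$exons[, 2L] - t$exons[, 1L])

tx_start <- function(t) t$exons[1L, 1L]
tx_end <- function(t) t$exons[nrow(t$exons), 2L]

## strand-aware 5' end position (0-based, the base itself)
five_prime_pos <- function(t) if (t$strand == "+") tx_start(t) else tx_end(t) - 1L
three_prime_pos <- function(t) if (t$strand == "+") tx_end(t) - 1L else tx_start(t)

#' Junction chain of a transcript
#'
#' The ordered intron coordinates of a transcript; the identity key for
#' read collapsing and full-splice-match comparison.  Introns are stored in
#' ascending genomic order on both strands; strand is metadata.
#'
#' @param t A [transcript_model()] (or aligned isoform with `contig`,
#'   `strand` and `exons` fields).
#' @return Object of class `junction_chain` with fields `contig`, `strand`
#'   and `introns` (two-column matrix, possibly zero-row for mono-exonic
#'   transcripts).
#' @export
junction_chain <- function(t) {
  n <- nrow(t$exons)
  introns <- if (n < 2L) {
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
  }
  structure(list(contig = t$contig, strand = t$strand, introns = introns),
            class = "junction_chain")
}

junction_keys <- function(chain) {
  if (nrow(chain$introns) == 0L) return(character())
  sprintf("%s:%s:%d-%d", chain$contig, chain$strand,
          chain$introns[, 1L], chain$introns[, 2L])
}

chain_key <- function(chain) {
  paste(junction_keys(chain), collapse = "|")
}

## donor = intron boundary on the 5' (transcript sense) side
splice_site_keys <- function(chain) {
  if (nrow(chain$introns) == 0L) return(character())
  s <- chain$introns[, 1L]; e <- chain$introns[, 2L]
  if (chain$strand == "+") {
    c(sprintf("%s:+:%d:donor", chain$contig, s),
      sprintf("%s:+:%d:acceptor", chain$contig, e))
  } else {
    c(sprintf("%s:-:%d:donor", chain$contig, e),
      sprintf("%s:-:%d:acceptor", chain$contig, s))
  }
}

#' Assemble an annotation set from transcript models
#'
#' Builds the reference container used throughout: transcripts, the
#' gene-to-transcript map, and catalogs of all annotated introns (junctions)
#' and splice sites, against which junction and splice-site novelty is judged.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @return Object of class `annotation_set` with fields `transcripts` (named
#'   list), `genes` (named list of transcript ids), `junction_catalog` and
#'   `splice_site_catalog` (character key vectors).
#' @export
annotation_set <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_id in annotation")
  names(transcripts) <- ids
  gids <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- split(ids, gids)
  chains <- lapply(transcripts, junction_chain)
  jc <- unique(unlist(lapply(chains, junction_keys), use.names = FALSE))
  sc <- unique(unlist(lapply(chains, splice_site_keys), use.names = FALSE))
  structure(list(transcripts = transcripts, genes = genes,
                 junction_catalog = if (is.null(jc)) character() else jc,
                 splice_site_catalog = if (is.null(sc)) character() else sc),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d gene(s), %d transcript(s), %d junction(s), %d splice site(s)\n",
              length(x$genes), length(x$transcripts),
              length(x$junction_catalog), length(x$splice_site_catalog)))
  invisible(x)
}

#' Subset an annotation set by transcript id
#'
#' Catalogs are rebuilt so they remain exactly the union over the retained
#' transcripts.
#'
#' @param annotation An [annotation_set()].
#' @param transcript_ids Ids to keep.
#' @return A new `annotation_set`.
#' @export
subset_annotation <- function(annotation, transcript_ids) {
  annotation_set(annotation$transcripts[transcript_ids])
}

## ---------------------------------------------------------------------------
## GTF

GTF_COLS <- c("contig", "source", "type", "start", "end", "score", "strand",
              "frame", "attributes")

parse_gtf_attributes <- function(attr) {
  ## key "value"; pairs -- repeated keys allowed (GENCODE `tag`)
  m <- gregexpr('(\\w+)\\s+"([^"]*)"', attr, perl = TRUE)
  lapply(regmatches(attr, m), function(pairs) {
    keys <- sub('^(\\w+)\\s+.*$', "\\1", pairs)
    vals <- sub('^\\w+\\s+"([^"]*)"$', "\\1", pairs)
    setNames(vals, keys)
  })
}

#' Read a GENCODE-style GTF into an annotation set
#'
#' Exon features are assembled into transcript models.  1-based closed GTF
#' coordinates are converted to the internal 0-based half-open convention.
#' Repeated `tag "..."` attributes and comma-separated tag lists are both
#' accepted; any `appris_principal*` tag is normalised to `appris_principal`.
#' `transcript_support_level` values outside 1-5 (e.g. `NA`) parse as absent.
#' Coding status is taken from `transcript_type`/`transcript_biotype`
#' (`protein_coding`), defaulting to `TRUE` when the attribute is missing.
#'
#' @param path GTF file path.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop("malformed GTF line ", lineno[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, got ", nf[nf != 9L][1L])
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- GTF_COLS
  tab$line <- lineno
  tab <- tab[tab$type == "exon", , drop = FALSE]
  if (nrow(tab) == 0L) stop("no exon features in ", path)
  attrs <- parse_gtf_attributes(tab$attributes)
  tid <- vapply(attrs, function(a) {
    if ("transcript_id" %in% names(a)) unname(a[["transcript_id"]]) else NA_character_
  }, "")
  if (anyNA(tid))
    stop("exon without transcript_id at line ", tab$line[which(is.na(tid))[1L]])
  start0 <- as.integer(tab$start) - 1L   # 1-based closed -> 0-based half-open
  end0 <- as.integer(tab$end)
  if (anyNA(start0) || anyNA(end0))
    stop("malformed GTF line ", tab$line[which(is.na(start0) | is.na(end0))[1L]],
         ": non-numeric coordinates")
  groups <- split(seq_len(nrow(tab)), tid)
  transcripts <- lapply(names(groups), function(id) {
    i <- groups[[id]]
    a <- do.call(c, attrs[i])
    gene <- if ("gene_id" %in% names(a)) unname(a[names(a) == "gene_id"][1L]) else
      stop("exon without gene_id for transcript ", id)
    tags <- unlist(strsplit(unname(a[names(a) == "tag"]), ",", fixed = TRUE))
    tags <- trimws(tags)
    norm <- unique(c(if ("basic" %in% tags) "basic",
                     if (any(grepl("^appris_principal", tags))) "appris_principal"))
    tslv <- suppressWarnings(as.integer(unname(a[names(a) == "transcript_support_level"])[1L]))
    if (length(tslv) == 0L || is.na(tslv) || tslv < 1L || tslv > 5L)
      tslv <- NA_integer_
    btype <- unname(a[names(a) %in% c("transcript_type", "transcript_biotype")])[1L]
    ord <- order(start0[i])
    transcript_model(id, gene,
                     contig = tab$contig[i][1L], strand = tab$strand[i][1L],
                     exons = cbind(start0[i][ord], end0[i][ord]),
                     tags = if (is.null(norm)) character() else norm,
                     tsl = tslv,
                     coding = if (is.na(btype) || length(btype) == 0L) TRUE
                              else identical(btype, "protein_coding"))
  })
  annotation_set(transcripts)
}

#' Write an annotation set as GTF
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons become 1-based
#' closed GTF records; tags, TSL and coding status round-trip.
#'
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  out <- unlist(lapply(annotation$transcripts, function(t) {
    attr_tail <- paste0(
      if ("basic" %in% t$tags) ' tag "basic";' else "",
      if ("appris_principal" %in% t$tags) ' tag "appris_principal_1";' else "",
      if (!is.na(t$tsl)) sprintf(' transcript_support_level "%d";', t$tsl) else "",
      sprintf(' transcript_type "%s";',
              if (t$coding) "protein_coding" else "processed_transcript"))
    sprintf('%s\tcapiso\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";%s',
            t$contig, t$exons[, 1L] + 1L, t$exons[, 2L], t$strand,
            t$gene_id, t$transcript_id, attr_tail)
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## BED12

#' Write transcript models or aligned isoforms as BED12
#'
#' Exon structure is encoded in the block fields.  Coordinates, strand and
#' ids round-trip exactly through [read_bed12()].
#'
#' @param models List of [transcript_model()] or [aligned_isoform()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, "", "contig"),
    ranges = IRanges::IRanges(
      start = vapply(models, function(m) m$exons[1L, 1L], 0L) + 1L,
      end = vapply(models, function(m) m$exons[nrow(m$exons), 2L], 0L)),
    strand = vapply(models, `[[`, "", "strand"))
  gr$name <- vapply(models, function(m) {
    if (!is.null(m$transcript_id)) m$transcript_id else m$isoform_id
  }, "")
  gr$blocks <- IRanges::IRangesList(lapply(models, function(m) {
    IRanges::IRanges(start = m$exons[, 1L] - m$exons[1L, 1L] + 1L,
                     end = m$exons[, 2L] - m$exons[1L, 1L])
  }))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED12 file as transcript models
#'
#' @param path BED12 file.
#' @param gene_ids Optional named character vector mapping record name to
#'   gene id; defaults to the record name itself.
#' @return List of [transcript_model()] objects (gene_id = record name unless
#'   supplied).
#' @export
read_bed12 <- function(path, gene_ids = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    g <- gr[i]
    name <- g$name
    offset <- GenomicRanges::start(g) - 1L  # chromStart, 0-based
    bl <- g$blocks[[1L]]
    if (length(bl) > 0L) {
      exons <- cbind(offset + IRanges::start(bl) - 1L, offset + IRanges::end(bl))
      if (max(exons[, 2L]) != GenomicRanges::end(g))
        stop("BED12 record '", name, "': blocks inconsistent with chromEnd")
    } else {
      exons <- cbind(offset, GenomicRanges::end(g))
    }
    transcript_model(name,
                     gene_id = if (!is.null(gene_ids) && name %in% names(gene_ids))
                       unname(gene_ids[[name]]) else name,
                     contig = as.character(GenomicRanges::seqnames(g)),
                     strand = as.character(GenomicRanges::strand(g)),
                     exons = exons)
  })
}

## ---------------------------------------------------------------------------
## bedGraph score track

#' Read a bedGraph per-base score track
#'
#' @param path bedGraph file (0-based half-open intervals on disk).
#' @return Object of class `score_track`; query it with [track_value()].
#'   Overlapping intervals with conflicting values are an error.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov) > 0L) {
    bad <- gr$score[S4Vectors::queryHits(ov)] != gr$score[S4Vectors::subjectHits(ov)]
    if (any(bad))
      stop("bedGraph has overlapping intervals with conflicting values")
  }
  structure(list(gr = gr), class = "score_track")
}

#' Look up per-base track scores
#'
#' @param track A [read_track()] result.
#' @param contig Contig name (scalar or vector recycled against `pos`).
#' @param pos 0-based positions.
#' @return Numeric vector; positions not covered by any interval are `NA`.
#'   At an abutting-interval boundary the right-hand interval's value applies
#'   (half-open convention).
#' @export
track_value <- function(track, contig, pos) {
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n)
  out <- rep(NA_real_, n)
  known <- contig %in% GenomeInfoDb::seqlevels(track$gr)
  if (any(known)) {
    q <- GenomicRanges::GRanges(contig[known],
                                IRanges::IRanges(start = pos[known] + 1L,
                                                 width = 1L))
    hit <- GenomicRanges::findOverlaps(q, track$gr, select = "first")
    out[known] <- ifelse(is.na(hit), NA_real_, track$gr$score[hit])
  }
  out
}

## ---------------------------------------------------------------------------
## FASTA genome

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet] (uppercased), the genome
#'   container used throughout.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate contig names in ", path)
  if (any(Biostrings::width(g) == 0L)) stop("empty contig sequence in ", path)
  Biostrings::DNAStringSet(toupper(g))
}

#' Write a genome FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

## 0-based half-open genomic subsequence as a character scalar
genome_subseq <- function(genome, contig, start, end) {
  as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## ---------------------------------------------------------------------------
## TSV tables

#' Read a TSV table (header row, `#` comment lines)
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a TSV table
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
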