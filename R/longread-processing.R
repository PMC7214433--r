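## Full-length read classification, demultiplexing, and PCR-chimera
## detection via dual-barcode concordance.

#' Classify reads as full length
#'
#' A full-length (FL) read contains the 5' primer, the 3' primer, and the
#' polyA tail preceding the 3' primer.
#'
#' @param reads A `long_read_set` data.frame (columns `has_5p_primer`,
#'   `has_3p_primer`, `has_polyA`).
#' @return Logical vector, one element per read.
#' @export
classify_full_length <- function(reads) {
  reads$has_5p_primer & reads$has_3p_primer & reads$has_polyA
}

#' Demultiplex full-length reads by sample barcode
#'
#' Only FL reads are assigned; reads whose barcode is not in
#' `sample_barcodes` (or missing) go to the `"unassigned"` bin.
#'
#' @param reads A `long_read_set`.
#' @param sample_barcodes Unique barcode strings.
#' @return Named list of data.frames (one per barcode, plus `unassigned`),
#'   partitioning the FL reads.
#' @export
demultiplex <- function(reads, sample_barcodes) {
  if (anyDuplicated(sample_barcodes)) stop("duplicate sample barcodes")
  fl <- reads[classify_full_length(reads), , drop = FALSE]
  bin <- ifelse(!is.na(fl$sample_barcode) &
                  fl$sample_barcode %in% sample_barcodes,
                fl$sample_barcode, "unassigned")
  out <- lapply(c(sample_barcodes, "unassigned"), function(b)
    fl[bin == b, , drop = FALSE])
  names(out) <- c(sample_barcodes, "unassigned")
  out
}

#' Dual-barcode concordance of reads
#'
#' A read is `concordant` when its inner 5' and 3' barcodes form a known
#' matching pair, `discordant` when both are present but mismatched (the
#' signature of a PCR chimera: barcode swaps occur only through chimeric
#' products), and `unresolved` when either barcode is absent.
#'
#' @param reads A `long_read_set` (columns `inner_5p_barcode`,
#'   `inner_3p_barcode`).
#' @param pairs Pairing data.frame (`barcode_5p`, `barcode_3p`, `pair_id`);
#'   defaults to the table attached to `reads`.
#' @return Character vector in `{"concordant","discordant","unresolved"}`.
#' @export
dual_barcode_concordance <- function(reads, pairs = attr(reads, "pairs")) {
  if (is.null(pairs)) stop("no barcode pairing table available")
  p5 <- match(reads$inner_5p_barcode, pairs$barcode_5p)
  p3 <- match(reads$inner_3p_barcode, pairs$barcode_3p)
  out <- rep("unresolved", nrow(reads))
  resolved <- !is.na(p5) & !is.na(p3)
  out[resolved] <- ifelse(pairs$pair_id[p5[resolved]] ==
                            pairs$pair_id[p3[resolved]],
                          "concordant", "discordant")
  out
}

#' Read-level chimera rate estimate
#'
#' The fraction of resolved reads that are discordant, with its binomial
#' standard error; a consistent estimator of the simulation chimera rate.
#'
#' @param concordance Output of [dual_barcode_concordance()].
#' @return List with `rate`, `se`, `n_resolved`.
#' @export
chimera_rate_estimate <- function(concordance) {
  n <- sum(concordance != "unresolved")
  k <- sum(concordance == "discordant")
  rate <- if (n > 0L) k / n else NaN
  list(rate = rate, se = if (n > 0L) sqrt(rate * (1 - rate) / n) else NaN,
       n_resolved = n)
}

#' Call per-isoform chimera status by majority vote
#'
#' An isoform is called non-chimeric iff strictly more than half of its
#' resolved member reads are concordant ("a majority", read strictly: a tie
#' is called chimeric, the conservative choice for novel-isoform claims).
#' Unresolved reads are excluded from the vote denominator.  Isoforms with
#' zero resolved reads receive no call and are counted separately.
#'
#' @param isoforms List of [aligned_isoform()] objects (with `member_reads`).
#' @param reads The `long_read_set` the members refer to.
#' @param novel Optional named logical vector isoform_id -> is-novel, used to
#'   additionally report the non-chimeric rate among novel isoforms.
#' @param pairs Barcode pairing table (defaults to the one on `reads`).
#' @return Object of class `chimera_report`: read tallies, `per_isoform`
#'   data.frame with call in `{"non-chimeric","chimeric"}` (`NA` when
#'   uncalled), `nonchimeric_rate_all`, `nonchimeric_rate_novel`.
#' @export
call_isoform_chimeras <- function(isoforms, reads, novel = NULL,
                                  pairs = attr(reads, "pairs")) {
  conc <- dual_barcode_concordance(reads, pairs)
  names(conc) <- reads$read_id
  per <- do.call(rbind, lapply(isoforms, function(iso) {
    labels <- conc[iso$member_reads]
    n_c <- sum(labels == "concordant", na.rm = TRUE)
    n_d <- sum(labels == "discordant", na.rm = TRUE)
    call <- if (n_c + n_d == 0L) NA_character_
            else if (n_c > (n_c + n_d) / 2) "non-chimeric" else "chimeric"
    data.frame(isoform_id = iso$isoform_id, n_concordant = n_c,
               n_discordant = n_d, call = call, stringsAsFactors = FALSE)
  }))
  called <- per[!is.na(per$call), , drop = FALSE]
  rate_all <- if (nrow(called) > 0L)
    mean(called$call == "non-chimeric") else NaN
  rate_novel <- NA_real_
  if (!is.null(novel)) {
    nov <- called[called$isoform_id %in% names(novel)[novel], , drop = FALSE]
    rate_novel <- if (nrow(nov) > 0L) mean(nov$call == "non-chimeric") else NaN
  }
  structure(list(n_reads = nrow(reads),
                 n_concordant = sum(conc == "concordant"),
                 n_discordant = sum(conc == "discordant"),
                 per_isoform = per,
                 n_uncalled = sum(is.na(per$call)),
                 nonchimeric_rate_all = rate_all,
                 nonchimeric_rate_novel = rate_novel),
            class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("<chimera_report> %d reads (%d concordant / %d discordant); %d isoforms called, non-chimeric rate %.3f\n",
              x$n_reads, x$n_concordant, x$n_discordant,
              nrow(x$per_isoform) - x$n_uncalled, x$nonchimeric_rate_all))
  invisible(x)
}
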