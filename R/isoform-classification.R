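## Collapse of aligned full-length reads into isoforms and SQANTI-style
## structural classification against a reference annotation.
##
## Multi-exon categories, in decision order:
##   FSM  - junction chain identical to a reference transcript's chain
##   ISM  - chain equal to a consecutive sub-chain of a reference chain
##   NIC  - all junctions annotated (subcategory "combination"), or all
##          splice sites annotated but >= 1 junction novel (subcategory
##          "novel_junction")
##   NNC  - at least one novel splice site
## Mono-exon reads are classified by containment in a reference exon
## (mono-exon-known), overlap with a gene footprint (mono-exon-novel), or
## neither (intergenic).

#' Construct an aligned isoform
#'
#' @param isoform_id Identifier.
#' @param contig,strand Location.
#' @param exons Exon intervals (0-based half-open), as for
#'   [transcript_model()].
#' @param fl_counts Named integer vector sample -> full-length read count.
#' @param member_reads Character vector of member read ids.
#' @param coverage,identity Alignment query coverage and identity in \[0,1\].
#' @return Object of class `aligned_isoform`.
#' @export
aligned_isoform <- function(isoform_id, contig, strand, exons,
                            fl_counts = integer(), member_reads = character(),
                            coverage = 1, identity = 1) {
  exons <- as_exon_matrix(exons)
  stopifnot(nrow(exons) >= 1L, all(exons[, 1L] < exons[, 2L]),
            all(fl_counts >= 0))
  structure(list(isoform_id = isoform_id, contig = contig, strand = strand,
                 exons = exons, fl_counts = fl_counts,
                 member_reads = member_reads,
                 coverage = coverage, identity = identity),
            class = "aligned_isoform")
}

#' Filter aligned isoforms on alignment quality and target region
#'
#' Keeps isoforms with alignment coverage and identity at or above the
#' thresholds (inclusive, default >= 99% coverage and >= 95% identity) whose
#' exonic footprint intersects the target regions, when given.
#'
#' @param isoforms List of [aligned_isoform()].
#' @param min_coverage,min_identity Thresholds in \[0,1\].
#' @param target_regions Optional data.frame (`contig`, `start`, `end`;
#'   0-based half-open) of targeted probe regions.
#' @return Filtered list.
#' @export
filter_alignments <- function(isoforms, min_coverage = 0.99,
                              min_identity = 0.95, target_regions = NULL) {
  if (min_coverage < 0 || min_coverage > 1 || min_identity < 0 || min_identity > 1)
    stop("thresholds must be in [0, 1]")
  keep <- vapply(isoforms, function(iso) {
    ok <- iso$coverage >= min_coverage && iso$identity >= min_identity
    if (ok && !is.null(target_regions)) {
      tr <- target_regions[target_regions$contig == iso$contig, , drop = FALSE]
      ok <- nrow(tr) > 0L && any(vapply(seq_len(nrow(tr)), function(i)
        any(iso$exons[, 1L] < tr$end[i] & iso$exons[, 2L] > tr$start[i]),
        TRUE))
    }
    ok
  }, TRUE)
  isoforms[keep]
}

#' Collapse aligned full-length reads into distinct isoforms
#'
#' Multi-exon reads are grouped by identical junction chain (contig, strand,
#' intron coordinates); the representative exon structure is the chain
#' bounded by the 5'-most start and 3'-most end among members (5'/3' end
#' variation within a chain is ignored).  Mono-exon reads are grouped by
#' single-linkage interval overlap on the same contig and strand.
#' Full-length counts are tallied per sample barcode.
#'
#' @param reads A `long_read_set` restricted to aligned FL reads (columns
#'   `contig`, `strand`, `blocks`, `sample_barcode`, `read_id`).
#' @return List of [aligned_isoform()] objects.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L) return(list())
  exon_list <- lapply(reads$blocks, decode_blocks)
  n_ex <- vapply(exon_list, nrow, 0L)
  multi <- which(n_ex > 1L)
  mono <- which(n_ex == 1L)
  out <- list()
  tally <- function(idx) {
    tab <- table(reads$sample_barcode[idx], useNA = "no")
    setNames(as.integer(tab), names(tab))
  }
  if (length(multi) > 0L) {
    keys <- vapply(multi, function(i) {
      ex <- exon_list[[i]]
      paste(reads$contig[i], reads$strand[i],
            paste(ex[-nrow(ex), 2L], ex[-1L, 1L], sep = "-", collapse = "|"),
            sep = ":")
    }, "")
    for (grp in split(multi, keys)) {
      i0 <- grp[[1L]]
      ex <- exon_list[[i0]]
      ex[1L, 1L] <- min(vapply(grp, function(i) exon_list[[i]][1L, 1L], 0L))
      n <- nrow(ex)
      ex[n, 2L] <- max(vapply(grp, function(i) {
        e <- exon_list[[i]]; e[nrow(e), 2L]
      }, 0L))
      out[[length(out) + 1L]] <- aligned_isoform(
        "", reads$contig[i0], reads$strand[i0], ex,
        fl_counts = tally(grp), member_reads = reads$read_id[grp],
        coverage = mean(reads$coverage[grp]),
        identity = mean(reads$identity[grp]))
    }
  }
  if (length(mono) > 0L) {
    loc <- paste(reads$contig[mono], reads$strand[mono])
    for (grp0 in split(mono, loc)) {
      s <- vapply(grp0, function(i) exon_list[[i]][1L, 1L], 0L)
      e <- vapply(grp0, function(i) exon_list[[i]][1L, 2L], 0L)
      ord <- order(s)
      grp0 <- grp0[ord]; s <- s[ord]; e <- e[ord]
      cluster <- cumsum(c(1L, as.integer(s[-1L] >= cummax(e)[-length(e)])))
      for (cl in split(seq_along(grp0), cluster)) {
        idx <- grp0[cl]
        out[[length(out) + 1L]] <- aligned_isoform(
          "", reads$contig[idx[1L]], reads$strand[idx[1L]],
          cbind(min(s[cl]), max(e[cl])),
          fl_counts = tally(idx), member_reads = reads$read_id[idx],
          coverage = mean(reads$coverage[idx]),
          identity = mean(reads$identity[idx]))
      }
    }
  }
  ## deterministic ids: order by contig, start, chain
  ord <- order(vapply(out, `[[`, "", "contig"),
               vapply(out, function(x) x$exons[1L, 1L], 0L),
               vapply(out, function(x) chain_key(junction_chain(x)), ""))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$isoform_id <- sprintf("iso%05d", i)
  out
}

## ---------------------------------------------------------------------------
## Classification

classification_index <- function(annotation) {
  tx <- annotation$transcripts
  chains <- lapply(tx, junction_chain)
  ckeys <- vapply(chains, chain_key, "")
  multi <- ckeys != ""
  chain_map <- split(names(tx)[multi], ckeys[multi])
  padded <- paste0("|", ckeys[multi], "|")
  names(padded) <- names(tx)[multi]
  gene_info <- lapply(names(annotation$genes), function(g) {
    tids <- annotation$genes[[g]]
    exo <- do.call(rbind, lapply(tx[tids], `[[`, "exons"))
    introns <- do.call(rbind, lapply(tids, function(id) {
      ch <- chains[[id]]
      if (nrow(ch$introns) == 0L) NULL else ch$introns
    }))
    list(gene_id = g, contig = tx[[tids[1L]]]$contig,
         strand = tx[[tids[1L]]]$strand,
         footprint = c(min(exo[, 1L]), max(exo[, 2L])),
         exons = exo,
         exon_union = IRanges::reduce(IRanges::IRanges(exo[, 1L] + 1L, exo[, 2L])),
         introns = introns,
         jkeys = unique(unlist(lapply(chains[tids], junction_keys),
                               use.names = FALSE)))
  })
  names(gene_info) <- names(annotation$genes)
  list(chain_map = chain_map, padded = padded, gene_info = gene_info,
       junction_catalog = annotation$junction_catalog,
       splice_site_catalog = annotation$splice_site_catalog)
}

## genes on the same contig/strand whose footprint overlaps the isoform span
candidate_genes <- function(index, iso) {
  lo <- iso$exons[1L, 1L]; hi <- iso$exons[nrow(iso$exons), 2L]
  Filter(function(gi) gi$contig == iso$contig && gi$strand == iso$strand &&
           gi$footprint[1L] < hi && gi$footprint[2L] > lo,
         index$gene_info)
}

gene_exonic_overlap <- function(gi, iso) {
  ia <- IRanges::IRanges(iso$exons[, 1L] + 1L, iso$exons[, 2L])
  sum(IRanges::width(IRanges::intersect(ia, gi$exon_union)))
}

## max shared junctions, then max exonic overlap, then lexicographic gene id
assign_gene <- function(index, iso, jkeys) {
  cand <- candidate_genes(index, iso)
  if (length(cand) == 0L) return(NA_character_)
  shared <- vapply(cand, function(gi) sum(jkeys %in% gi$jkeys), 0L)
  ov <- vapply(cand, gene_exonic_overlap, 0L, iso = iso)
  ids <- vapply(cand, `[[`, "", "gene_id")
  ord <- order(-shared, -ov, ids)
  ids[ord[1L]]
}

#' Classify one aligned isoform against a reference annotation
#'
#' See the category definitions at the top of this file.  The matched gene is
#' the reference gene sharing the most junctions with the isoform, ties
#' broken by exonic overlap then lexicographic gene id.  Splice-site novelty
#' is position-, side- and strand-specific: a donor at a position annotated
#' only as an acceptor is novel.
#'
#' @param iso An [aligned_isoform()] (or [transcript_model()]).
#' @param annotation An [annotation_set()].
#' @param genome Optional genome `DNAStringSet`; enables the `all_canonical`
#'   splice-dinucleotide flag (canonical set GT-AG, GC-AG, AT-AC).
#' @param index Prebuilt [classification_index] (internal); computed from
#'   `annotation` when missing.  Pass one when classifying many isoforms.
#' @return A one-row data.frame (`classification_record`): `isoform_id`,
#'   `category`, `subcategory`, matched ids, junction/splice-site inventories
#'   and novelty, `intron_retention`, `all_canonical`, `fl_total`.
#' @export
classify_isoform <- function(iso, annotation, genome = NULL, index = NULL) {
  if (is.null(index)) index <- classification_index(annotation)
  chain <- junction_chain(iso)
  jkeys <- junction_keys(chain)
  skeys <- splice_site_keys(chain)
  novel_j <- jkeys[!jkeys %in% index$junction_catalog]
  novel_s <- skeys[!skeys %in% index$splice_site_catalog]
  matched_tx <- NA_character_
  subcat <- NA_character_

  if (nrow(chain$introns) > 0L) {
    key <- chain_key(chain)
    if (!is.null(index$chain_map[[key]])) {
      category <- "FSM"
      matched_tx <- sort(index$chain_map[[key]])[1L]
      gene <- annotation$transcripts[[matched_tx]]$gene_id
    } else {
      hit <- names(index$padded)[grepl(paste0("|", key, "|"),
                                       index$padded, fixed = TRUE)]
      if (length(hit) > 0L) {
        category <- "ISM"
        matched_tx <- sort(hit)[1L]
        gene <- annotation$transcripts[[matched_tx]]$gene_id
      } else if (length(novel_j) == 0L) {
        category <- "NIC"; subcat <- "combination"
        gene <- assign_gene(index, iso, jkeys)
      } else if (length(novel_s) == 0L) {
        category <- "NIC"; subcat <- "novel_junction"
        gene <- assign_gene(index, iso, jkeys)
      } else {
        category <- "NNC"
        gene <- assign_gene(index, iso, jkeys)
      }
    }
  } else {
    ## mono-exon: containment in a reference exon, else gene overlap
    s <- iso$exons[1L, 1L]; e <- iso$exons[1L, 2L]
    cand <- candidate_genes(index, iso)
    contained <- Filter(function(gi)
      any(gi$exons[, 1L] <= s & e <= gi$exons[, 2L]), cand)
    if (length(contained) > 0L) {
      category <- "mono-exon-known"
      ids <- sort(vapply(contained, `[[`, "", "gene_id"))
      gene <- ids[1L]
      tin <- Filter(function(id) {
        t <- annotation$transcripts[[id]]
        any(t$exons[, 1L] <= s & e <= t$exons[, 2L])
      }, annotation$genes[[gene]])
      matched_tx <- sort(unlist(tin))[1L]
    } else if (length(cand) > 0L) {
      category <- "mono-exon-novel"
      gene <- assign_gene(index, iso, jkeys)
    } else {
      category <- "intergenic"
      gene <- NA_character_
    }
  }

  ir <- if (!is.na(gene))
    detect_intron_retention(iso, annotation, gene, index = index) else FALSE
  canon <- if (!is.null(genome) && nrow(chain$introns) > 0L) {
    dints <- splice_dinucleotides(chain, genome)
    all(paste(dints$donor, dints$acceptor, sep = "-") %in%
          c("GT-AG", "GC-AG", "AT-AC"))
  } else NA
  data.frame(
    isoform_id = if (!is.null(iso$isoform_id)) iso$isoform_id else iso$transcript_id,
    category = category, subcategory = subcat,
    matched_transcript_id = matched_tx, matched_gene_id = gene,
    n_junctions = length(jkeys),
    junctions = paste(jkeys, collapse = ";"),
    splice_sites = paste(skeys, collapse = ";"),
    novel_junctions = paste(novel_j, collapse = ";"),
    novel_splice_sites = paste(novel_s, collapse = ";"),
    n_novel_junctions = length(novel_j),
    n_novel_splice_sites = length(novel_s),
    intron_retention = ir,
    all_canonical = canon,
    fl_total = if (!is.null(iso$fl_counts)) sum(iso$fl_counts) else NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a set of aligned isoforms
#'
#' Vectorised driver over [classify_isoform()]; asserts the category
#' partition invariant (every isoform gets exactly one category; FSM implies
#' zero novel junctions).
#'
#' @inheritParams classify_isoform
#' @param isoforms List of [aligned_isoform()] objects.
#' @return data.frame with one `classification_record` row per isoform.
#' @export
classify_isoforms <- function(isoforms, annotation, genome = NULL) {
  index <- classification_index(annotation)
  rec <- do.call(rbind, lapply(isoforms, classify_isoform,
                               annotation = annotation, genome = genome,
                               index = index))
  stopifnot(!anyNA(rec$category),
            all(rec$n_novel_junctions[rec$category == "FSM"] == 0L))
  rec
}

## sense donor/acceptor dinucleotides of every intron in a chain
splice_dinucleotides <- function(chain, genome) {
  if (nrow(chain$introns) == 0L)
    return(data.frame(donor = character(), acceptor = character()))
  s <- chain$introns[, 1L]; e <- chain$introns[, 2L]
  left <- vapply(seq_along(s), function(i)
    genome_subseq(genome, chain$contig, s[i], s[i] + 2L), "")
  right <- vapply(seq_along(e), function(i)
    genome_subseq(genome, chain$contig, e[i] - 2L, e[i]), "")
  if (chain$strand == "+") data.frame(donor = left, acceptor = right,
                                      stringsAsFactors = FALSE)
  else data.frame(donor = vapply(right, revcomp, ""),
                  acceptor = vapply(left, revcomp, ""),
                  stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect intron retention
#'
#' TRUE iff some exon of the isoform completely contains an annotated intron
#' of the matched gene (strict containment, so both flanking reference exons
#' are overlapped by that exon).
#'
#' @param iso [aligned_isoform()] or [transcript_model()].
#' @param annotation [annotation_set()].
#' @param gene_id Matched gene.
#' @param index Optional prebuilt classification index.
#' @return Logical scalar.
#' @export
detect_intron_retention <- function(iso, annotation, gene_id, index = NULL) {
  introns <- if (!is.null(index)) index$gene_info[[gene_id]]$introns
  else do.call(rbind, lapply(annotation$genes[[gene_id]], function(id) {
    ch <- junction_chain(annotation$transcripts[[id]])
    if (nrow(ch$introns) == 0L) NULL else ch$introns
  }))
  if (is.null(introns) || nrow(introns) == 0L) return(FALSE)
  any(vapply(seq_len(nrow(iso$exons)), function(i)
    any(iso$exons[i, 1L] < introns[, 1L] & introns[, 2L] < iso$exons[i, 2L]),
    TRUE))
}

#' Gene- and isoform-level recovery statistics
#'
#' A gene is detected iff at least one full-length read is assigned to the
#' locus; a reference isoform is detected iff some observed isoform is an FSM
#' of it.  Fractions are reported for all genes, genes with probe
#' representation at or above `probe_min` TPM, genes with expression at or
#' above `expr_min` TPM, and the intersection of both.
#'
#' @param records Classification data.frame from [classify_isoforms()].
#' @param annotation Reference [annotation_set()].
#' @param probe_tpm Named numeric gene_id -> probe representation (TPM).
#' @param expression Optional [expression_profile()]; gene expression is the
#'   sum over member transcripts.
#' @param probe_min,expr_min Stratification thresholds (TPM).
#' @return data.frame with one row per stratum: counts and recovery
#'   fractions for genes and isoforms.
#' @export
recovery_statistics <- function(records, annotation, probe_tpm = NULL,
                                expression = NULL, probe_min = 1.0,
                                expr_min = 10.0) {
  gids <- names(annotation$genes)
  det_rec <- records[!is.na(records$matched_gene_id) &
                       (is.na(records$fl_total) | records$fl_total >= 1L), ,
                     drop = FALSE]
  gene_detected <- setNames(gids %in% det_rec$matched_gene_id, gids)
  fsm_tx <- unique(det_rec$matched_transcript_id[det_rec$category == "FSM"])
  gene_expr <- if (!is.null(expression)) {
    vapply(gids, function(g)
      sum(expression[intersect(annotation$genes[[g]], names(expression))]), 0)
  } else setNames(rep(NA_real_, length(gids)), gids)
  pt <- setNames(rep(0, length(gids)), gids)
  if (!is.null(probe_tpm)) pt[names(probe_tpm)] <- probe_tpm
  strata <- list(
    all = rep(TRUE, length(gids)),
    probe_ge_min = pt >= probe_min,
    expr_ge_min = !is.na(gene_expr) & gene_expr >= expr_min,
    probe_and_expr = pt >= probe_min & !is.na(gene_expr) & gene_expr >= expr_min)
  do.call(rbind, lapply(names(strata), function(sname) {
    sel <- strata[[sname]]
    sg <- gids[sel]
    stids <- unlist(annotation$genes[sg], use.names = FALSE)
    data.frame(stratum = sname, n_genes = length(sg),
               gene_recovery = if (length(sg) > 0L)
                 mean(gene_detected[sg]) else NaN,
               n_isoforms = length(stids),
               isoform_recovery = if (length(stids) > 0L)
                 mean(stids %in% fsm_tx) else NaN,
               stringsAsFactors = FALSE)
  }))
}

#' Novelty proportions and category summary
#'
#' Distinct splice sites and junctions are counted once across the observed
#' isoform set; isoform novelty means category outside
#' FSM/ISM/mono-exon-known.  TSL confirmation counts distinct FSM-matched
#' reference transcripts with TSL 2-5 (and TSL 5 alone).
#'
#' @param records Classification data.frame from [classify_isoforms()].
#' @param annotation Reference [annotation_set()] (for TSL lookup).
#' @return List: `site_novelty`, `junction_novelty`, `isoform_novelty`
#'   fractions; `n_distinct_sites`, `n_distinct_junctions`, `n_isoforms`;
#'   `category_proportions` (named); `subcategory_proportions` for novel
#'   isoforms; `intron_retention_fraction` among novel isoforms;
#'   `tsl25_confirmed`, `tsl5_confirmed`.
#' @export
novelty_summary <- function(records, annotation = NULL) {
  split_keys <- function(x) unlist(strsplit(x[nzchar(x)], ";", fixed = TRUE))
  all_j <- unique(split_keys(records$junctions))
  nov_j <- unique(split_keys(records$novel_junctions))
  all_s <- unique(split_keys(records$splice_sites))
  nov_s <- unique(split_keys(records$novel_splice_sites))
  known_cat <- c("FSM", "ISM", "mono-exon-known")
  is_novel <- !records$category %in% known_cat & records$category != "intergenic"
  cat_prop <- prop.table(table(records$category))
  novel_rec <- records[is_novel, , drop = FALSE]
  sub_prop <- if (nrow(novel_rec) > 0L)
    prop.table(table(ifelse(novel_rec$intron_retention, "intron_retention",
                            ifelse(novel_rec$category == "NNC", "novel_sites",
                                   "known_elements"))))
  else table(character())
  tsl25 <- tsl5 <- NA_integer_
  if (!is.null(annotation)) {
    fsm_tx <- unique(records$matched_transcript_id[records$category == "FSM"])
    tsl <- vapply(annotation$transcripts[fsm_tx], `[[`, 0L, "tsl")
    tsl25 <- sum(!is.na(tsl) & tsl >= 2L)
    tsl5 <- sum(!is.na(tsl) & tsl == 5L)
  }
  list(site_novelty = if (length(all_s) > 0L) length(nov_s) / length(all_s) else NaN,
       junction_novelty = if (length(all_j) > 0L) length(nov_j) / length(all_j) else NaN,
       isoform_novelty = mean(is_novel),
       n_distinct_sites = length(all_s), n_distinct_junctions = length(all_j),
       n_isoforms = nrow(records),
       category_proportions = cat_prop,
       subcategory_proportions = sub_prop,
       intron_retention_fraction = if (nrow(novel_rec) > 0L)
         mean(novel_rec$intron_retention) else NaN,
       tsl25_confirmed = tsl25, tsl5_confirmed = tsl5)
}
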