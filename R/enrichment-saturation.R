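## Enrichment statistics (on-target rate, fold enrichment, capture
## efficiency, rank abundance) and saturation-discovery curves.

#' Per-gene abundance fractions
#'
#' Sums a transcript-level source (TPM profile or FL counts) over each
#' gene's member transcripts and normalises by the total, giving the
#' fraction of total transcriptional abundance (or of full-length reads)
#' attributable to each gene.
#'
#' @param source Named numeric vector transcript_id -> abundance
#'   ([expression_profile()] or FL counts).
#' @param annotation An [annotation_set()].
#' @return Named numeric vector gene_id -> fraction (sums to 1).
#' @export
gene_abundance_fractions <- function(source, annotation) {
  total <- sum(source)
  if (total <= 0) stop("total abundance is zero")
  tx2gene <- setNames(
    rep(names(annotation$genes), lengths(annotation$genes)),
    unlist(annotation$genes, use.names = FALSE))
  g <- tx2gene[names(source)]
  if (anyNA(g)) stop("source contains transcripts absent from the annotation")
  frac <- tapply(as.numeric(source), g, sum) / total
  out <- setNames(rep(0, length(annotation$genes)), names(annotation$genes))
  out[names(frac)] <- frac
  out
}

#' On-target rate
#'
#' The fraction of total abundance attributable to the targeted genes.
#'
#' @param fractions Per-gene fractions from [gene_abundance_fractions()].
#' @param targets Character vector of targeted gene ids.
#' @return Numeric scalar in \[0,1\].
#' @export
on_target_rate <- function(fractions, targets) {
  unknown <- setdiff(targets, names(fractions))
  if (length(unknown) > 0L)
    warning(length(unknown), " target gene(s) absent from the annotation")
  sum(fractions[intersect(targets, names(fractions))])
}

#' Fold enrichment
#'
#' Capturant on-target rate divided by input on-target rate.
#'
#' @param input_rate,capturant_rate On-target rates in \[0,1\].
#' @return Numeric scalar; `NA` with a warning when `input_rate` is 0.
#' @export
fold_enrichment <- function(input_rate, capturant_rate) {
  if (input_rate == 0) {
    warning("input on-target rate is 0; fold enrichment undefined")
    return(NA_real_)
  }
  capturant_rate / input_rate
}

#' Per-isoform capture efficiency
#'
#' Elementwise capturant depth divided by input depth; isoforms with zero
#' input depth get `NA`.  When a [capture_design()] and annotation are
#' supplied, efficiencies are additionally summarised by exonic overlap (nt)
#' with the gene's probe template.
#'
#' @param input_depth,capturant_depth Named numeric vectors (isoform ->
#'   depth), identically keyed.
#' @param design Optional [capture_design()].
#' @param annotation Optional [annotation_set()] (required with `design`).
#' @return List with `efficiency` (named vector) and, with a design,
#'   `by_overlap` (data.frame: isoform, gene, targeted, overlap_nt,
#'   efficiency).
#' @export
capture_efficiency <- function(input_depth, capturant_depth, design = NULL,
                               annotation = NULL) {
  stopifnot(identical(names(input_depth), names(capturant_depth)))
  eff <- ifelse(input_depth > 0, capturant_depth / input_depth, NA_real_)
  names(eff) <- names(input_depth)
  out <- list(efficiency = eff)
  if (!is.null(design)) {
    stopifnot(!is.null(annotation))
    rows <- lapply(names(eff), function(id) {
      t <- annotation$transcripts[[id]]
      if (is.null(t)) return(NULL)
      g <- t$gene_id
      targeted <- g %in% design$targets
      ov <- if (targeted)
        exonic_overlap(annotation$transcripts[[design$template[[g]]]], t)
      else 0L
      data.frame(isoform_id = id, gene_id = g, targeted = targeted,
                 overlap_nt = ov, efficiency = eff[[id]],
                 stringsAsFactors = FALSE)
    })
    out$by_overlap <- do.call(rbind, rows)
  }
  out
}

#' Saturation-discovery curve by subsampling
#'
#' Full-length reads are subsampled without replacement at each depth; the
#' number of unique genes and unique isoforms detected is averaged over
#' `n_iterations` random subsamples per depth.  Within an iteration, depths
#' are nested (a single random permutation is truncated at each depth), so
#' per-iteration counts are non-decreasing in depth while each depth's
#' marginal sample remains a uniform without-replacement draw.
#'
#' @param read_assignments data.frame with columns `read_id`, `gene_id`,
#'   `isoform_id` (one row per full-length read).
#' @param depths Integer vector of sampling depths (each <= total reads).
#' @param n_iterations Number of subsampling iterations per depth
#'   (default 100).
#' @param seed Integer RNG seed.
#' @param fsm_only Restrict the isoform count to reads whose isoform exactly
#'   matches the reference (requires a logical `fsm` column).
#' @return Object of class `saturation_curve`: data.frame `curve` with
#'   columns `depth`, `mean_unique_genes`, `mean_unique_isoforms`,
#'   `se_unique_genes`, `se_unique_isoforms`; plus `n_iterations`, `seed`.
#' @export
discovery_curve <- function(read_assignments, depths, n_iterations = 100L,
                            seed = 1L, fsm_only = FALSE) {
  n <- nrow(read_assignments)
  if (any(depths > n)) stop("depth exceeds the total number of reads")
  stopifnot(n_iterations >= 1L)
  set.seed(seed)
  depths <- as.integer(depths)
  gene <- read_assignments$gene_id
  iso <- read_assignments$isoform_id
  if (fsm_only) {
    if (is.null(read_assignments$fsm)) stop("fsm_only requires an 'fsm' column")
    iso[!read_assignments$fsm] <- NA_character_
  }
  g_mat <- matrix(0, n_iterations, length(depths))
  i_mat <- matrix(0, n_iterations, length(depths))
  for (it in seq_len(n_iterations)) {
    perm <- sample.int(n)
    for (d in seq_along(depths)) {
      idx <- perm[seq_len(depths[d])]
      g_mat[it, d] <- length(unique(gene[idx]))
      u <- unique(iso[idx])
      i_mat[it, d] <- sum(!is.na(u))
    }
  }
  curve <- data.frame(
    depth = depths,
    mean_unique_genes = colMeans(g_mat),
    mean_unique_isoforms = colMeans(i_mat),
    se_unique_genes = apply(g_mat, 2L, sd) / sqrt(n_iterations),
    se_unique_isoforms = apply(i_mat, 2L, sd) / sqrt(n_iterations))
  structure(list(curve = curve, n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)), class = "saturation_curve")
}

#' Expected unique categories under without-replacement subsampling
#'
#' The hypergeometric closed form E\[unique\] = sum_i (1 - C(N-n_i, d) /
#' C(N, d)) for category sizes n_i, pool size N and depth d; the analytic
#' oracle for [discovery_curve()].
#'
#' @param category_sizes Integer vector of per-category read counts.
#' @param depth Sampling depth.
#' @return Expected number of distinct categories observed.
#' @export
expected_unique_categories <- function(category_sizes, depth) {
  N <- sum(category_sizes)
  ## exp/lchoose for numerical stability at large N
  sum(1 - exp(lchoose(N - category_sizes, depth) - lchoose(N, depth)))
}

#' Rank-abundance table
#'
#' Genes ordered by descending abundance fraction (ties broken
#' lexicographically by gene id), flagged targeted/untargeted; the standard
#' display is the top 50 genes.
#'
#' @param fractions Per-gene fractions from [gene_abundance_fractions()].
#' @param targets Targeted gene ids.
#' @param top_n Number of rows to return (all genes when larger).
#' @return data.frame: `rank`, `gene_id`, `fraction`, `targeted`.
#' @export
rank_abundance_table <- function(fractions, targets, top_n = 50L) {
  ord <- order(-fractions, names(fractions))
  ids <- names(fractions)[ord]
  k <- min(top_n, length(ids))
  data.frame(rank = seq_len(k), gene_id = ids[seq_len(k)],
             fraction = unname(fractions[ord][seq_len(k)]),
             targeted = ids[seq_len(k)] %in% targets,
             stringsAsFactors = FALSE)
}

#' Enrichment report for an input/capturant pair
#'
#' @param input,capturant Named transcript-level abundance vectors.
#' @param annotation [annotation_set()].
#' @param targets Targeted gene ids.
#' @return Object of class `enrichment_report`: `on_target_input`,
#'   `on_target_capturant`, `fold_enrichment`, `per_gene_fraction`
#'   (capturant), `per_isoform_efficiency`.
#' @export
enrichment_report <- function(input, capturant, annotation, targets) {
  fi <- gene_abundance_fractions(input, annotation)
  fc <- gene_abundance_fractions(capturant, annotation)
  ri <- on_target_rate(fi, targets)
  rc <- on_target_rate(fc, targets)
  structure(list(on_target_input = ri, on_target_capturant = rc,
                 fold_enrichment = fold_enrichment(ri, rc),
                 per_gene_fraction = fc,
                 per_isoform_efficiency =
                   capture_efficiency(input, capturant)$efficiency),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> on-target %.2f%% -> %.2f%% (%.1f-fold)\n",
              100 * x$on_target_input, 100 * x$on_target_capturant,
              x$fold_enrichment))
  invisible(x)
}
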