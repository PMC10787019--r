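#' Parameters for chromosome-enriched K-mer selection
#'
#' The two selection conditions are (1) a minimum global occurrence count
#' and (2) an enrichment fold of the best chromosome over a baseline taken
#' across the remaining chromosomes. The canonical thresholds for a
#' multi-gigabase assembly are `min_global = 1000` and `fold = 2`;
#' `min_global` scales with assembly size and should be lowered for small
#' or simulated genomes (roughly in proportion to the copy number of the
#' discriminating repeat families).
#'
#' @param min_global Minimum genome-wide count (condition 1).
#' @param fold Required enrichment fold (> 1; condition 2).
#' @param baseline `"max_other"` (strict: the K-mer is effectively private
#'   to one chromosome) or `"mean_other"` (mean over all remaining
#'   chromosomes; admits repeat families shared by a few homologous
#'   chromosomes, which is what polyploid co-clustering relies on).
#' @param normalize `"density"` (count / (L - k + 1)) or `"raw"`.
#' @return List of class `enrichment_params`.
#' @export
enrichment_params <- function(min_global = 1000, fold = 2,
                              baseline = c("max_other", "mean_other"),
                              normalize = c("density", "raw")) {
  stopifnot(min_global >= 1, fold > 1)
  structure(list(min_global = min_global, fold = fold,
                 baseline = match.arg(baseline),
                 normalize = match.arg(normalize)),
            class = "enrichment_params")
}

#' Select chromosome-enriched K-mers
#'
#' A K-mer is kept iff its global count is at least `min_global` and its
#' value (density or raw count) on its best chromosome is at least
#' `fold` times the baseline over the remaining chromosomes. Each kept
#' K-mer is assigned to its argmax chromosome (ties broken by
#' lexicographic chromosome id). The achieved fold is `Inf` when the
#' baseline is zero.
#'
#' @param table A `kmer_table` from [count_kmers_assembly()] with at least
#'   two chromosomes.
#' @param params An [enrichment_params()].
#' @return List of class `enriched_kmers` with elements `entries`
#'   (data.table `kmer`, `chrom`, `global`, `fold`) and `params`.
#' @export
select_enriched <- function(table, params = enrichment_params()) {
  stopifnot(inherits(table, "kmer_table"))
  chroms <- names(table$chrom_lengths)
  n_chrom <- length(chroms)
  if (n_chrom < 2L) stop("enrichment undefined for a single chromosome")
  eff_len <- table$chrom_lengths - table$k + 1
  cnt <- data.table::copy(table$counts)
  cnt[, global := sum(count), by = kmer]
  cnt <- cnt[global >= params$min_global]
  if (nrow(cnt) == 0L) {
    return(structure(list(entries = data.table::data.table(
      kmer = character(0), chrom = character(0), global = numeric(0),
      fold = numeric(0)), params = params), class = "enriched_kmers"))
  }
  if (params$normalize == "density") {
    cnt[, value := count / eff_len[chrom]]
  } else {
    cnt[, value := as.numeric(count)]
  }
  # per kmer: argmax chromosome, best value, runner-up, sum of others
  data.table::setorder(cnt, kmer, -value, chrom)
  agg <- cnt[, list(
    chrom = chrom[1L],
    best = value[1L],
    second = if (.N > 1L) value[2L] else 0,
    sum_other = sum(value) - value[1L],
    global = global[1L]), by = kmer]
  base <- if (params$baseline == "max_other") {
    agg$second
  } else {
    agg$sum_other / (n_chrom - 1L)
  }
  fold_achieved <- ifelse(base > 0, agg$best / base,
                          ifelse(agg$best > 0, Inf, 0))
  keep <- fold_achieved >= params$fold
  entries <- data.table::data.table(
    kmer = agg$kmer[keep], chrom = agg$chrom[keep],
    global = agg$global[keep], fold = fold_achieved[keep])
  data.table::setorder(entries, kmer)
  structure(list(entries = entries, params = params),
            class = "enriched_kmers")
}

#' @export
print.enriched_kmers <- function(x, ...) {
  cat("enriched_kmers:", nrow(x$entries), "K-mers (min_global =",
      x$params$min_global, ", fold =", x$params$fold, ", baseline =",
      x$params$baseline, ", normalize =", x$params$normalize, ")\n")
  invisible(x)
}

#' Build the chromosome x enriched-K-mer profile matrix
#'
#' Rows follow the genome (table) chromosome order; columns are the
#' selected K-mers in lexicographic order. Values are densities or raw
#' counts per the enrichment params.
#'
#' @param table The `kmer_table` the selection was made from.
#' @param enriched An [select_enriched()] result (non-empty).
#' @return Numeric matrix, chromosomes x K-mers.
#' @export
build_profile_matrix <- function(table, enriched) {
  stopifnot(inherits(enriched, "enriched_kmers"))
  if (nrow(enriched$entries) == 0L) {
    stop("insufficient markers: empty enriched K-mer set")
  }
  kmers <- sort(enriched$entries$kmer)
  chroms <- names(table$chrom_lengths)
  sel <- table$counts[table$counts$kmer %in% kmers]
  mat <- matrix(0, nrow = length(chroms), ncol = length(kmers),
                dimnames = list(chroms, kmers))
  mat[cbind(match(sel$chrom, chroms), match(sel$kmer, kmers))] <- sel$count
  if (enriched$params$normalize == "density") {
    eff_len <- table$chrom_lengths - table$k + 1
    mat <- mat / eff_len[chroms]
  }
  mat
}
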