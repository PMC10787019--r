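#' Canonical K-mer count table
#'
#' Internal constructor. Counts are stored sparsely as a data.table with
#' columns `kmer` (canonical form: lexicographic minimum of the K-mer and
#' its reverse complement), `chrom`, `count`.
#'
#' @param k K-mer length (odd).
#' @param counts data.table(kmer, chrom, count).
#' @param chrom_lengths Named numeric vector of chromosome lengths (`NA`
#'   for read tables).
#' @param source `"assembly"` or `"reads"`.
#' @return Object of class `kmer_table`.
#' @keywords internal
kmer_table <- function(k, counts, chrom_lengths, source) {
  structure(list(k = as.integer(k), counts = counts,
                 chrom_lengths = chrom_lengths, source = source),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: k =", x$k, "| source =", x$source, "|",
      length(unique(x$counts$kmer)), "distinct canonical K-mers over",
      length(x$chrom_lengths), "chromosome(s)\n")
  invisible(x)
}

check_k <- function(k) {
  if (k %% 2L == 0L) {
    stop("k must be odd: palindromic canonicalization undefined for even k")
  }
  if (k < 3L || k > 31L) stop("k out of supported range [3, 31]")
  invisible(as.integer(k))
}

#' Count canonical K-mers per chromosome of an assembly
#'
#' Every length-k window of every chromosome is counted once under
#' canonicalization (lexicographic min of the window and its reverse
#' complement). Windows containing `N` contribute nothing; chromosomes
#' shorter than k contribute zero.
#'
#' @param genome A [genome_map()] or named character vector of sequences.
#' @param k Odd K-mer length in `[3, 31]` (13 is the conventional choice
#'   for chromosome-enrichment screens).
#' @return A `kmer_table` with `source = "assembly"`.
#' @export
count_kmers_assembly <- function(genome, k = 13L) {
  k <- check_k(k)
  seqs <- if (inherits(genome, "genome_map")) genome$seqs else genome
  stopifnot(!is.null(names(seqs)))
  parts <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    res <- .cpp_count_kmers(seqs[[i]], k)
    if (length(res$kmer)) {
      parts[[i]] <- data.table::data.table(
        kmer = res$kmer, chrom = names(seqs)[i], count = res$count)
    }
  }
  counts <- data.table::rbindlist(parts)
  data.table::setorder(counts, kmer, chrom)
  kmer_table(k, counts, stats::setNames(nchar(seqs), names(seqs)),
             "assembly")
}

#' Count canonical K-mers in read sets
#'
#' Aggregates global counts over one or more FASTQ files (or an in-memory
#' read data.frame) into a single pseudo-chromosome `"reads"`.
#'
#' @param fastq FASTQ path(s), or a data.frame with a `seq` column.
#' @param k Odd K-mer length (21 is the smudge-analysis convention).
#' @param min_count_keep Drop K-mers with final count below this.
#' @return A `kmer_table` with `source = "reads"`.
#' @export
count_kmers_reads <- function(fastq, k = 21L, min_count_keep = 1L) {
  k <- check_k(k)
  stopifnot(min_count_keep >= 1L)
  if (is.character(fastq)) {
    seqs <- unlist(lapply(fastq, function(p) read_fastq(p)$seq))
  } else {
    seqs <- fastq$seq
  }
  res <- .cpp_count_kmers_batch(seqs, k)
  counts <- data.table::data.table(kmer = res$kmer, chrom = "reads",
                                   count = res$count)
  counts <- counts[count >= min_count_keep]
  data.table::setorder(counts, kmer)
  kmer_table(k, counts, c(reads = NA_real_), "reads")
}

#' Per-base density of a K-mer on a chromosome
#'
#' `count / (L - k + 1)`; zero when the K-mer is absent from that
#' chromosome.
#'
#' @param table A `kmer_table` from [count_kmers_assembly()].
#' @param kmer Canonical K-mer string.
#' @param chrom Chromosome id.
#' @return Numeric density per effective window.
#' @export
kmer_density <- function(table, kmer, chrom) {
  if (!chrom %in% names(table$chrom_lengths)) {
    stop("unknown chromosome: ", chrom)
  }
  L <- table$chrom_lengths[[chrom]]
  if (is.na(L)) stop("density undefined for read tables")
  km <- kmer; ch <- chrom
  cnt <- table$counts[table$counts$kmer == km & table$counts$chrom == ch]$count
  if (length(cnt) == 0L) return(0)
  sum(cnt) / (L - table$k + 1)
}

#' Global (genome-wide) counts of a K-mer table
#'
#' @param table A `kmer_table`.
#' @return data.table with columns `kmer`, `global`.
#' @export
kmer_global_counts <- function(table) {
  table$counts[, list(global = sum(count)), by = kmer]
}

#' Dump a K-mer table to sorted TSV
#'
#' @param table A `kmer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  out <- data.table::copy(table$counts)
  data.table::setorder(out, kmer, chrom)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
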