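#' Simulate short reads from a genome
#'
#' Uniform start positions per chromosome, both strands equally likely,
#' i.i.d. substitution errors. The expected read count per chromosome is
#' `coverage * chrom_len / read_len`, realized by rounding. Defaults match
#' a typical 150-bp Illumina run.
#'
#' @param genome A [genome_map()] or named character vector of sequences.
#' @param coverage Fold coverage per haplotype (per chromosome).
#' @param read_len Read length in bp (>= 21).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path; when given the reads are also
#'   written with constant quality `"I"`.
#' @return data.frame with columns `id`, `seq`, `qual` (invisibly when
#'   `path` is given).
#' @export
simulate_reads <- function(genome, coverage = 25, read_len = 150L,
                           error_rate = 0, seed = 1L, path = NULL) {
  seqs <- if (inherits(genome, "genome_map")) genome$seqs else genome
  stopifnot(coverage > 0, read_len >= 21L)
  if (any(nchar(seqs) < read_len)) {
    stop("read_len exceeds the length of chromosome ",
         names(seqs)[which(nchar(seqs) < read_len)[1L]])
  }
  set.seed(seed)
  out <- vector("list", length(seqs))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- nchar(s)
    n_reads <- as.integer(round(coverage * L / read_len))
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    rd <- substring(s, starts, starts + read_len - 1L)
    flip <- stats::runif(n_reads) < 0.5
    rd[flip] <- .cpp_revcomp(rd[flip])
    if (error_rate > 0) {
      nerr <- stats::rbinom(n_reads, read_len, error_rate)
      hit <- which(nerr > 0L)
      for (j in hit) {
        p <- sample.int(read_len, nerr[j])
        ch <- strsplit(rd[j], "", fixed = TRUE)[[1]]
        for (q in p) ch[q] <- sample(setdiff(bases, ch[q]), 1L)
        rd[j] <- paste0(ch, collapse = "")
      }
    }
    out[[i]] <- data.frame(
      id = sprintf("%s_read%d", names(seqs)[i], seq_len(n_reads)),
      seq = rd, qual = strrep("I", read_len), stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}
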