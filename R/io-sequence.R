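#' Read a FASTA file
#'
#' Strict FASTA reader for assembly-sized inputs. Sequences are uppercased;
#' the record id is the first whitespace-delimited token of the header.
#' Characters outside `{A,C,G,T,N}` are rejected with the offending
#' position, and duplicate ids are an error.
#'
#' @param path Path to a FASTA file. Multi-line (wrapped) records are
#'   supported.
#' @return Named character vector of sequences; names are record ids, in
#'   file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("FASTA must start with a '>' header: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste0(x, collapse = "")), character(1))
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    stop("FASTA record with empty sequence in: ", path)
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ line count not a multiple of 4: ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  idx <- seq_len(n)
  ids <- lines[4L * idx - 3L]
  if (any(!startsWith(ids, "@"))) {
    stop("malformed FASTQ header at record ", which(!startsWith(ids, "@"))[1L])
  }
  seqs <- toupper(lines[4L * idx - 2L])
  quals <- lines[4L * idx]
  if (any(nchar(seqs) != nchar(quals))) {
    stop("FASTQ sequence/quality length mismatch at record ",
         which(nchar(seqs) != nchar(quals))[1L])
  }
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual` (as returned
#'   by [simulate_reads()] or [read_fastq()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) > 0 && any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch at record ",
         which(nchar(reads$seq) != nchar(reads$qual))[1L])
  }
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(4L * nrow(reads))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param seqs Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) .cpp_revcomp(seqs)
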