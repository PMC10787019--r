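# Independent brute-force oracles. These deliberately avoid the package's
# C++ counting path and data.table aggregation: plain substring
# enumeration, Biostrings reverse complements and straight-line predicate
# evaluation.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# canonical K-mer counts per chromosome by full window enumeration
oracle_count_kmers <- function(seqs, k) {
  parts <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(s, starts, starts + k - 1L)
    km <- km[!grepl("[^ACGT]", km)]
    if (length(km) == 0L) next
    rc <- oracle_revcomp(km)
    can <- ifelse(km <= rc, km, rc)
    tb <- table(can)
    parts[[nm]] <- data.frame(kmer = names(tb), chrom = nm,
                              count = as.numeric(tb),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$kmer, out$chrom), ]
  rownames(out) <- NULL
  out
}

# exhaustive enrichment scan over every distinct K-mer
oracle_select_enriched <- function(seqs, k, min_global, fold,
                                   baseline = "max_other",
                                   normalize = "density") {
  cnt <- oracle_count_kmers(seqs, k)
  eff <- nchar(seqs) - k + 1
  chroms <- names(seqs)
  global_tab <- tapply(cnt$count, cnt$kmer, sum)
  cands <- names(global_tab)[global_tab >= min_global]
  cnt <- cnt[cnt$kmer %in% cands, , drop = FALSE]
  rows_by_kmer <- split(cnt[, c("chrom", "count")], cnt$kmer)
  res <- list()
  for (km in names(rows_by_kmer)) {
    rows <- rows_by_kmer[[km]]
    v <- setNames(rep(0, length(chroms)), chroms)
    v[rows$chrom] <- rows$count
    g <- sum(v)
    if (g < min_global) next
    val <- if (normalize == "density") v / eff[chroms] else v
    best_chrom <- names(val)[order(-val, names(val))][1]
    best <- val[[best_chrom]]
    others <- val[setdiff(chroms, best_chrom)]
    base <- if (baseline == "max_other") max(others) else mean(others)
    achieved <- if (base > 0) best / base else if (best > 0) Inf else 0
    if (achieved >= fold) {
      res[[length(res) + 1L]] <- data.frame(
        kmer = km, chrom = best_chrom, global = g, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(kmer = character(0), chrom = character(0),
                      global = numeric(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$kmer), ]
  rownames(out) <- NULL
  out
}

# naive O(n^3) average-linkage (UPGMA) producing cophenetic distances
oracle_upgma_cophenetic <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  clusters <- as.list(labs)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  active <- rep(TRUE, length(clusters))
  cd <- function(a, b) mean(d[a, b])
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dd <- cd(clusters[[i]], clusters[[j]])
        if (dd < bd - 1e-12) { bd <- dd; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bd; coph[b, a] <- bd
    clusters[[best[1]]] <- c(a, b)
    active[best[2]] <- FALSE
  }
  coph
}

# six-predicate filter oracle: survivors pass all predicates; proximity is
# evaluated against every record of the input set
oracle_filter <- function(vs, params) {
  rec <- vs$records
  n <- nrow(rec)
  ns <- ncol(vs$gt)
  pass <- logical(n)
  for (i in seq_len(n)) {
    d <- rec$depth[i]
    ok_depth <- !is.na(d) && d >= params$depth_min && d <= params$depth_max
    ok_allelic <- length(strsplit(rec$alt[i], ",")[[1]]) == 1L
    miss <- if (ns > 0) mean(vs$gt[i, ] %in% c("./.", ".|.", ".")) else 0
    ok_miss <- miss <= params$max_missing
    ok_rep <- !interval_contains(params$repeat_mask, rec$chrom[i],
                                 rec$pos[i])
    near <- which(rec$chrom == rec$chrom[i] &
                    abs(rec$pos - rec$pos[i]) < params$min_spacing)
    ok_prox <- length(setdiff(near, i)) == 0L
    pass[i] <- ok_depth && ok_allelic && ok_miss && ok_rep && ok_prox
  }
  pass
}

# gene clusters by window enumeration: every maximal window of >= min_size
# consecutive family genes whose successive gaps are all <= max_gap
oracle_clusters <- function(features, family_ids, min_size = 3,
                            max_gap = 8e5, gap_mode = "end_to_start") {
  out <- list()
  for (ch in unique(features$chrom)) {
    fam <- features[features$chrom == ch &
                      features$feature_id %in% family_ids, ]
    fam <- fam[order(fam$start, fam$end), ]
    m <- nrow(fam)
    if (m < min_size) next
    ok_link <- function(i, j) {
      gaps <- vapply(i:(j - 1L), function(x) {
        if (gap_mode == "end_to_start") {
          max(fam$start[x + 1L] - fam$end[x] - 1L, 0L)
        } else {
          fam$start[x + 1L] - fam$start[x]
        }
      }, numeric(1))
      all(gaps <= max_gap)
    }
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (j - i + 1L < min_size) next
        if (!ok_link(i, j)) next
        left_ext <- i > 1L && ok_link(i - 1L, j)
        right_ext <- j < m && ok_link(i, j + 1L)
        if (!left_ext && !right_ext) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = fam$start[i], end = fam$end[j],
            n_members = j - i + 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0)))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

# random gene-annotation fixture for cluster testing
random_gff_fixture <- function(seed, n_genes = 40, n_chrom = 2,
                               span = 5e6) {
  set.seed(seed)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n_genes, replace = TRUE)
  start <- sample.int(span, n_genes)
  len <- sample(500:10000, n_genes, replace = TRUE)
  f <- data.frame(chrom = chrom, start = start, end = start + len,
                  strand = sample(c("+", "-"), n_genes, replace = TRUE),
                  feature_id = sprintf("gene%03d_s%d", seq_len(n_genes), seed),
                  feature_type = "gene", stringsAsFactors = FALSE)
  fam <- sample(f$feature_id, max(3, rbinom(1, n_genes, 0.4)))
  list(features = f, family_ids = fam)
}

make_kmer_table <- function(k, counts, chrom_lengths, source = "assembly") {
  tetrasig:::kmer_table(k, data.table::as.data.table(counts),
                        chrom_lengths, source)
}
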