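#' Simulation configuration for polyploid genomes
#'
#' Describes the stated world the downstream signature analyses assume:
#' an auto-tetraploid (four haplotypes per homologous group recently
#' diverged from one group ancestor, with a group-private repeat family
#' shared by all four haplotypes), an allo-tetraploid (two anciently
#' diverged subgenomes, each carrying a subgenome-private repeat family
#' shared across all of its chromosomes), or a diploid (two haplotypes per
#' group, group-private repeats).
#'
#' @param mode `"auto"`, `"allo"` or `"diploid"`.
#' @param n_groups Number of homologous groups (monoploid chromosomes).
#' @param chrom_len Chromosome length in bp.
#' @param n_haplotypes Haplotypes per group: 4 for tetraploid modes, 2 for
#'   diploid.
#' @param d_hap Per-base substitution probability between a haplotype and
#'   its (sub)genome ancestor.
#' @param d_sub Per-base substitution probability between the two subgenome
#'   ancestors (allo mode only); must exceed `d_hap`.
#' @param repeat_len Repeat motif length in bp.
#' @param repeat_copies Copies of the motif placed per chromosome.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mode = c("auto", "allo", "diploid"), n_groups = 3L,
                       chrom_len = 50000L, n_haplotypes = NULL,
                       d_hap = 0.005, d_sub = 0.05, repeat_len = 200L,
                       repeat_copies = 150L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(n_haplotypes)) {
    n_haplotypes <- if (mode == "diploid") 2L else 4L
  }
  cfg <- list(mode = mode, n_groups = as.integer(n_groups),
              chrom_len = as.integer(chrom_len),
              n_haplotypes = as.integer(n_haplotypes),
              d_hap = d_hap, d_sub = d_sub,
              repeat_len = as.integer(repeat_len),
              repeat_copies = as.integer(repeat_copies),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_groups < 1L) stop("n_groups must be >= 1")
  if (cfg$mode == "diploid" && cfg$n_haplotypes != 2L) {
    stop("diploid mode requires n_haplotypes = 2")
  }
  if (cfg$mode %in% c("auto", "allo") && cfg$n_haplotypes != 4L) {
    stop("tetraploid modes require n_haplotypes = 4")
  }
  if (cfg$mode == "allo" &&
      !(cfg$d_hap >= 0 && cfg$d_hap < cfg$d_sub && cfg$d_sub <= 0.2)) {
    stop("allo mode requires 0 <= d_hap < d_sub <= 0.2")
  }
  if (cfg$d_hap < 0 || cfg$d_hap > 0.2) stop("d_hap out of range [0, 0.2]")
  if (cfg$chrom_len < 10L * cfg$repeat_len) {
    stop("chrom_len must be >= 10 * repeat_len")
  }
  if (cfg$repeat_copies * cfg$repeat_len >= cfg$chrom_len) {
    stop("repeat copies do not fit in chrom_len")
  }
  invisible(cfg)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-substitute a sequence at per-base rate d (substitutions only; each
# hit base moves to one of the three other bases uniformly).
mutate_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  n <- nchar(seq)
  hits <- which(stats::runif(n) < d)
  if (length(hits) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hits) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste0(chars, collapse = "")
}

# Overwrite `copies` non-overlapping windows of `seq` with `motif`,
# at random offsets (random composition of the residual gap).
plant_repeats <- function(seq, motif, copies) {
  L <- nchar(seq)
  rl <- nchar(motif)
  free <- L - copies * rl
  cuts <- sort(sample.int(free + 1L, copies, replace = TRUE) - 1L)
  starts <- cuts + (seq_len(copies) - 1L) * rl + 1L
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mchars <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (s in starts) chars[s:(s + rl - 1L)] <- mchars
  paste0(chars, collapse = "")
}

#' Simulate a polyploid genome with a haplotype map
#'
#' Generates one chromosome per (group, haplotype) according to the mode in
#' `config` (see [sim_config()]). Chromosomes are named `g<group>_h<hap>`;
#' the label map records group, haplotype index and (allo mode) subgenome.
#'
#' @param config A [sim_config()].
#' @return A list of class `genome_map` with elements `seqs` (named
#'   character vector), `labels` (data.frame `chrom`, `group`, `haplotype`,
#'   `subgenome`) and `truth` (the config and mode).
#' @export
simulate_polyploid_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  seqs <- character(0)
  labels <- list()
  if (config$mode == "allo") {
    motif_a <- random_dna(config$repeat_len)
    motif_b <- random_dna(config$repeat_len)
  }
  for (g in seq_len(config$n_groups)) {
    anc <- random_dna(config$chrom_len)
    if (config$mode %in% c("auto", "diploid")) {
      motif <- random_dna(config$repeat_len)
      anc <- plant_repeats(anc, motif, config$repeat_copies)
      for (h in seq_len(config$n_haplotypes)) {
        id <- sprintf("g%d_h%d", g, h)
        seqs[id] <- mutate_seq(anc, config$d_hap)
        labels[[id]] <- data.frame(chrom = id, group = sprintf("g%d", g),
                                   haplotype = h, subgenome = NA_character_,
                                   stringsAsFactors = FALSE)
      }
    } else {
      anc_a <- plant_repeats(mutate_seq(anc, config$d_sub / 2), motif_a,
                             config$repeat_copies)
      anc_b <- plant_repeats(mutate_seq(anc, config$d_sub / 2), motif_b,
                             config$repeat_copies)
      for (h in 1:2) {
        id <- sprintf("g%d_h%d", g, h)
        seqs[id] <- mutate_seq(anc_a, config$d_hap)
        labels[[id]] <- data.frame(chrom = id, group = sprintf("g%d", g),
                                   haplotype = h, subgenome = "A",
                                   stringsAsFactors = FALSE)
      }
      for (h in 3:4) {
        id <- sprintf("g%d_h%d", g, h)
        seqs[id] <- mutate_seq(anc_b, config$d_hap)
        labels[[id]] <- data.frame(chrom = id, group = sprintf("g%d", g),
                                   haplotype = h, subgenome = "B",
                                   stringsAsFactors = FALSE)
      }
    }
  }
  genome_map(seqs, do.call(rbind, labels),
             truth = list(mode = config$mode, config = config))
}

#' Genome map: sequences plus chromosome labels
#'
#' @param seqs Named character vector of chromosome sequences.
#' @param labels data.frame with columns `chrom`, `group`, `haplotype`
#'   and optionally `subgenome`.
#' @param truth Optional truth record from a simulator.
#' @return A list of class `genome_map`.
#' @export
genome_map <- function(seqs, labels, truth = NULL) {
  stopifnot(!is.null(names(seqs)))
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "group") %in% names(labels)))
  if (!setequal(labels$chrom, names(seqs)) ||
      anyDuplicated(labels$chrom)) {
    stop("labels must cover every chromosome exactly once")
  }
  if (!"subgenome" %in% names(labels)) labels$subgenome <- NA_character_
  rownames(labels) <- NULL
  structure(list(seqs = seqs, labels = labels, truth = truth),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", length(x$seqs), "chromosomes,",
      length(unique(x$labels$group)), "groups;",
      "total", sum(nchar(x$seqs)), "bp\n")
  invisible(x)
}
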