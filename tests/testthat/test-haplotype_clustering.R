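mat_from_rows <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("c", seq_along(rows))
  colnames(m) <- paste0("k", seq_len(ncol(m)))
  m
}

# block distance matrix: within-block w, between-block b
block_dist <- function(blocks, w = 0.1, b = 0.9, jitter = 0, seed = 1) {
  labs <- unlist(blocks)
  n <- length(labs)
  d <- matrix(b, n, n, dimnames = list(labs, labs))
  for (bl in blocks) d[bl, bl] <- w
  if (jitter > 0) {
    set.seed(seed)
    j <- matrix(runif(n * n, 0, jitter), n)
    j <- (j + t(j)) / 2
    d <- d + j
  }
  diag(d) <- 0
  d
}

test_that("chromosome_distance matches hand-computed values", {
  m <- mat_from_rows(c(1, 2, 0), c(0, 2, 2), c(1, 2, 0))
  d <- chromosome_distance(m, "braycurtis")
  expect_equal(d["c1", "c2"], 3 / 7)  # (|1-0|+|2-2|+|0-2|) / (3+4)
  expect_equal(d["c1", "c3"], 0)      # identical rows
  dj <- chromosome_distance(mat_from_rows(c(1, 1, 0, 0), c(0, 0, 3, 9)),
                            "jaccard_presence")
  expect_equal(dj["c1", "c2"], 1)     # disjoint presence
  m2 <- mat_from_rows(c(0, 0, 0), c(1, 2, 3))
  expect_error(chromosome_distance(m2), "all-zero.*c1")
  expect_true(isSymmetric(chromosome_distance(
    mat_from_rows(c(1, 2, 3), c(3, 1, 2), c(9, 1, 1)),
    "one_minus_spearman")))
})

test_that("UPGMA recovers nearest-pair topology and cophenetic heights", {
  labs <- c("a", "b", "c")
  d <- matrix(0.9, 3, 3, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 0.1
  diag(d) <- 0
  tree <- cluster_chromosomes(d)
  # ((a,b),c): a-b cophenetic below a-c = b-c
  expect_equal(tree$cophenetic["a", "b"], 0.1)
  expect_equal(tree$cophenetic["a", "c"], tree$cophenetic["b", "c"])
  expect_gt(tree$cophenetic["a", "c"], 0.1)

  d4 <- block_dist(list(c("a", "b"), c("x", "y")))
  cl <- cutree(cluster_chromosomes(d4)$hclust, k = 2)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["x"]], cl[["y"]])
  expect_false(cl[["a"]] == cl[["x"]])

  expect_error(cluster_chromosomes(matrix(0, 1, 1,
                                          dimnames = list("a", "a"))))
})

test_that("cophenetic distances equal a brute-force UPGMA oracle", {
  set.seed(21)
  labs <- paste0("L", 1:8)
  m <- matrix(runif(64), 8, 8, dimnames = list(labs, labs))
  d <- (m + t(m)) / 2
  diag(d) <- 0
  tree <- cluster_chromosomes(d)
  want <- oracle_upgma_cophenetic(d)
  expect_equal(tree$cophenetic[labs, labs], want[labs, labs],
               tolerance = 1e-10)
})

test_that("classify_origin calls auto for co-clustering groups", {
  d <- block_dist(list(paste0("g1_h", 1:4), paste0("g2_h", 1:4)),
                  jitter = 0.05, seed = 2)
  labels <- data.frame(chrom = rownames(d),
                       group = sub("_h[0-9]", "", rownames(d)))
  call <- classify_origin(cluster_chromosomes(d), labels,
                          n_permutations = 500, seed = 1)
  expect_identical(call$verdict, "auto")
  expect_equal(call$S, 1)
  expect_true(all(call$per_group))
})

test_that("classify_origin calls allo for subgenome-wise clustering", {
  # 2 groups x 4 haplotypes; haplotypes 1-2 of each group form subgenome A
  subA <- c("g1_h1", "g1_h2", "g2_h1", "g2_h2")
  subB <- c("g1_h3", "g1_h4", "g2_h3", "g2_h4")
  d <- block_dist(list(subA, subB), jitter = 0.05, seed = 3)
  labels <- data.frame(chrom = rownames(d),
                       group = sub("_h[0-9]", "", rownames(d)))
  call <- classify_origin(cluster_chromosomes(d), labels,
                          n_permutations = 200, seed = 1)
  expect_identical(call$verdict, "allo")
  expect_equal(call$S, 0)
  expect_equal(call$subgenome_score, 1)
})

test_that("classify_origin validates labels", {
  d <- block_dist(list(c("a", "b"), c("x", "y")))
  tree <- cluster_chromosomes(d)
  expect_error(classify_origin(tree, data.frame(chrom = c("a", "b", "x"),
                                                group = c("g", "g", "h"))),
               "unlabeled leaf: y")
  expect_error(classify_origin(
    tree, data.frame(chrom = c("a", "b", "x", "y"),
                     group = c("g", "g", "h", "i"))), "size 1")
})

test_that("S is invariant to leaf order and group relabeling", {
  d <- block_dist(list(paste0("g1_h", 1:4), paste0("g2_h", 1:4)),
                  jitter = 0.08, seed = 5)
  labels <- data.frame(chrom = rownames(d),
                       group = sub("_h[0-9]", "", rownames(d)))
  base <- classify_origin(cluster_chromosomes(d), labels,
                          n_permutations = 10, seed = 1)
  set.seed(9)
  perm <- sample(rownames(d))
  call2 <- classify_origin(cluster_chromosomes(d[perm, perm]),
                           labels[sample(nrow(labels)), ],
                           n_permutations = 10, seed = 1)
  labels3 <- transform(labels, group = ifelse(group == "g1", "zzz", "aaa"))
  call3 <- classify_origin(cluster_chromosomes(d), labels3,
                           n_permutations = 10, seed = 1)
  expect_equal(call2$S, base$S)
  expect_equal(call3$S, base$S)
})

test_that("permutation p agrees with an independent shuffler", {
  set.seed(31)
  labs <- paste0("L", 1:8)
  m <- matrix(runif(64), 8, 8, dimnames = list(labs, labs))
  d <- (m + t(m)) / 2
  diag(d) <- 0
  labels <- data.frame(chrom = labs, group = rep(c("p", "q"), each = 4))
  tree <- cluster_chromosomes(d)
  call <- classify_origin(tree, labels, n_permutations = 1000, seed = 7)

  # independent shuffler: recompute S from scratch per shuffle
  clade_sets <- tetrasig:::clade_leaf_sets(tree$hclust)
  keys <- vapply(clade_sets, paste, character(1), collapse = "\r")
  S_of <- function(assign) {
    mean(vapply(split(labs, assign), function(g)
      paste(sort(g), collapse = "\r") %in% keys, logical(1)))
  }
  obs <- S_of(setNames(labels$group, labels$chrom)[labs])
  set.seed(123)
  null_S <- replicate(2000, S_of(sample(labels$group)))
  p_oracle <- mean(null_S >= obs)
  se <- sqrt(max(p_oracle * (1 - p_oracle), 1e-4) / 1000)
  expect_lt(abs(call$permutation_p - p_oracle), 4 * se + 0.02)
})
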