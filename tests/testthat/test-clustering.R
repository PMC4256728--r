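test_that("identical and reverse-complement reads form single edges", {
  set.seed(1)
  a <- random_dna(100)
  e1 <- build_similarity_graph(c(x = a, y = a))
  expect_equal(nrow(e1), 1)
  expect_equal(e1$identity, 100)
  expect_equal(e1$overlap_fraction, 1)
  e2 <- build_similarity_graph(c(x = a, y = revcomp1(a)))
  expect_equal(nrow(e2), 1)
  expect_equal(e2$orient, "diff")
  expect_equal(e2$identity, 100)
})

test_that("edges connect template reads only, matching a brute-force aligner", {
  set.seed(2)
  template <- random_dna(400)
  tmpl_reads <- sample_reads(template, 30, divergence = 0.02, prefix = "t",
                             seed = 3)
  rnd_reads <- setNames(replicate(20, random_dna(100)),
                        sprintf("r%03d", 1:20))
  reads <- c(tmpl_reads, rnd_reads)
  edges <- build_similarity_graph(reads)
  expect_gt(nrow(edges), 0)
  expect_true(all(grepl("^t", edges$read_a)))
  expect_true(all(grepl("^t", edges$read_b)))

  # independent oracle: all-pairs gapped local alignment on both strands
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  oracle_edge <- function(x, y) {
    best <- NULL
    for (yy in c(y, revcomp1(y))) {
      a <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(x), Biostrings::DNAString(yy), type = "local",
        substitutionMatrix = submat, gapOpening = 100, gapExtension = 100)
    ov <- nchar(gsub("-", "", as.character(Biostrings::pattern(a)),
                     fixed = TRUE))
      cand <- c(identity = Biostrings::pid(a), ovf = ov / 100)
      if (is.null(best) || cand["identity"] * cand["ovf"] >
          best["identity"] * best["ovf"]) best <- cand
    }
    best
  }
  ids <- names(reads)
  got <- paste(edges$read_a, edges$read_b)
  n_checked <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in (i + 1L):length(ids)) {
      # the oracle trims terminal mismatches, so only pairs clearly away
      # from the 90%/0.55 decision boundary are required to agree
      o <- oracle_edge(reads[[ids[i]]], reads[[ids[j]]])
      key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
      if (o["identity"] >= 93 && o["ovf"] >= 0.62) {
        expect_true(key %in% got, label = key)
        n_checked <- n_checked + 1L
      } else if (o["identity"] < 85 || o["ovf"] < 0.45) {
        expect_false(key %in% got, label = key)
      }
    }
  }
  expect_gt(n_checked, 10)
})

test_that("an empty edge set yields all singleton clusters", {
  reads <- setNames(replicate(10, random_dna(100)), sprintf("s%02d", 1:10))
  edges <- build_similarity_graph(reads)[0, ]
  cl <- partition_graph(edges, reads)
  expect_equal(nrow(cl$clusters), 10)
  expect_true(all(cl$clusters$n_reads == 1))
  expect_equal(sum(cl$clusters$detailed), 0)
  expect_equal(sum(cl$clusters$genome_proportion), 100)
})

test_that("planted families partition into the right clusters", {
  set.seed(4)
  t1 <- random_dna(300); t2 <- random_dna(300)
  r1 <- sample_reads(t1, 45, divergence = 0.01, prefix = "a", seed = 5)
  r2 <- sample_reads(t2, 30, divergence = 0.01, prefix = "b", seed = 6)
  reads <- c(r1, r2)
  edges <- build_similarity_graph(reads)
  cl <- partition_graph(edges, reads)
  det <- cl$clusters[cl$clusters$detailed, ]
  expect_equal(nrow(det), 2)
  expect_equal(det$cluster_id, c("CL1", "CL2"))
  expect_equal(det$n_reads, c(45, 30))
  expect_setequal(cluster_members(cl, "CL1"), names(r1))
  expect_setequal(cluster_members(cl, "CL2"), names(r2))
  # ranks: CL1 is the larger cluster; GP is percent of analyzed reads
  expect_equal(det$genome_proportion, c(100 * 45 / 75, 100 * 30 / 75))
})

test_that("partitioning agrees with a brute-force union-find oracle", {
  set.seed(7)
  for (trial in 1:5) {
    ids <- sprintf("n%02d", 1:30)
    n_edges <- sample(5:40, 1)
    edges <- data.frame(
      read_a = sample(ids, n_edges, replace = TRUE),
      read_b = sample(ids, n_edges, replace = TRUE),
      stringsAsFactors = FALSE)
    edges <- edges[edges$read_a != edges$read_b, ]
    reads <- setNames(rep("ACGT", 30), ids)
    cl <- partition_graph(edges, reads)
    oracle <- uf_components(ids, edges)
    # same partition: cluster labels must be a bijection of oracle roots
    expect_equal(length(unique(cl$membership)), length(unique(oracle)))
    tab <- table(cl$membership, oracle)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("clusters below the detail threshold are excluded from the report", {
  ids <- c(sprintf("big%05d", 1:120), sprintf("tiny%d", 1:4),
           sprintf("bg%05d", 1:876))
  reads <- setNames(rep("ACGTACGT", 1000), ids)
  edges <- data.frame(
    read_a = c(sprintf("big%05d", 1:119), sprintf("tiny%d", 1:3)),
    read_b = c(sprintf("big%05d", 2:120), sprintf("tiny%d", 2:4)),
    stringsAsFactors = FALSE)
  cfg <- clustering_config(detail_threshold = 0.005)  # 0.5% of 1000 = 5 reads
  cl <- partition_graph(edges, reads, cfg)
  det <- cl$clusters[cl$clusters$detailed, ]
  expect_equal(det$n_reads, 120)
  tiny <- cl$clusters[cl$clusters$n_reads == 4, ]
  expect_false(tiny$detailed)
  expect_equal(sum(cl$clusters$genome_proportion), 100)
})

test_that("raising min_identity never increases the edge count", {
  set.seed(8)
  template <- random_dna(500)
  reads <- sample_reads(template, 40, divergence = 0.05, prefix = "m",
                        seed = 9)
  counts <- vapply(c(80, 90, 95, 99), function(mi) {
    nrow(build_similarity_graph(reads, clustering_config(min_identity = mi)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contig assembly reconstructs templates from tiling reads", {
  set.seed(10)
  # identical reads -> one contig equal to the read
  a <- random_dna(100)
  asm <- assemble_cluster_contigs(c("x", "y", "z"),
                                  c(x = a, y = a, z = a))
  expect_equal(length(asm$contigs), 1)
  expect_equal(unname(asm$contigs[1]), a)
  # error-free 50 bp tiling of a 500 bp template -> contig holds the template
  template <- random_dna(500)
  reads <- tiling_reads(template, 100, 50)
  asm2 <- assemble_cluster_contigs(names(reads), reads)
  expect_equal(length(asm2$contigs), 1)
  expect_true(grepl(template, asm2$contigs[[1]], fixed = TRUE))
  expect_true(all(nchar(asm2$contigs) >= 100))
})

test_that("satellite read layouts yield a contig with the monomer period", {
  set.seed(11)
  mono <- random_dna(120)
  arr <- tandem_array(mono, 30, 0.005)
  reads <- sample_reads(arr, 120, divergence = 0, prefix = "s", seed = 12)
  asm <- assemble_cluster_contigs(names(reads), reads)
  expect_gte(max(nchar(asm$contigs)), 120)
  prof <- find_satellite_monomer(asm$contigs[[which.max(nchar(asm$contigs))]])
  expect_equal(prof$period, 120)
})

test_that("total repeat fraction adds detailed clusters and nothing else", {
  df <- data.frame(cluster_id = c("CL1", "CL2", "CL3"),
                   n_reads = c(50, 10, 1),
                   genome_proportion = c(50, 10, 1),
                   detailed = c(TRUE, TRUE, FALSE))
  expect_equal(total_repeat_fraction(df), 60)
  expect_equal(total_repeat_fraction(df[0, ]), 0)
})
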