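random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Additive distance matrix from a random unrooted tree with positive lengths.
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 0.5))
  tr$tip.label <- sort(tr$tip.label)[order(seq_len(n_taxa))]
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
  list(tree = tr, dm = dm)
}

test_that("p-distances follow the pairwise-deletion definition", {
  aln <- c(a = "AC", b = "AD", c = "AC")
  d <- pairwise_distances(aln)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  # gapped columns are excluded pairwise
  aln2 <- c(a = "A-CD", b = "AGCD", c = "AGCC")
  d2 <- pairwise_distances(aln2)
  expect_equal(d2["a", "b"], 0)        # columns 1,3,4 compared; all equal
  expect_equal(d2["b", "c"], 0.25)
  expect_error(pairwise_distances(c(a = "--A", b = "A--", c = "AAA")),
               "no comparable")
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- build_nj_tree(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["x"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(bl["y"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(bl["z"]), (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers additive 4- and 5-taxon trees exactly", {
  skip_if_not_installed("phangorn")
  for (n in c(4, 5)) {
    for (seed in 1:6) {
      fx <- random_additive(n, seed = 100 * n + seed)
      tr <- build_nj_tree(fx$dm)
      expect_equal(phangorn::RF.dist(tr, fx$tree), 0)
      # exact branch lengths: patristic distances reproduce the input
      got <- ape::cophenetic.phylo(tr)
      expect_equal(got[rownames(fx$dm), colnames(fx$dm)], fx$dm,
                   tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with brute-force least squares over all topologies", {
  skip_if_not_installed("phangorn")
  fx <- random_additive(5, seed = 777)
  nj_tr <- build_nj_tree(fx$dm)
  all_top <- phangorn::allTrees(5, rooted = FALSE,
                                tip.label = rownames(fx$dm))
  sse <- vapply(all_top, function(tp) {
    fit <- phangorn::nnls.tree(as.dist(fx$dm), tp, method = "unrooted")
    sum((ape::cophenetic.phylo(fit)[rownames(fx$dm), colnames(fx$dm)] -
           fx$dm)^2)
  }, numeric(1))
  best <- all_top[[which.min(sse)]]
  expect_equal(phangorn::RF.dist(nj_tr, best), 0)
})

test_that("the NJ tree is invariant to taxon input order", {
  skip_if_not_installed("phangorn")
  fx <- random_additive(6, seed = 888)
  perm <- c(4, 1, 6, 3, 5, 2)
  dm2 <- fx$dm[perm, perm]
  t1 <- build_nj_tree(fx$dm)
  t2 <- build_nj_tree(dm2)
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3, 3,
                                    dimnames = list(letters[1:3],
                                                    letters[1:3]))),
               "symmetric")
})

test_that("bootstrap gives full support on unambiguous alignments", {
  block_a <- strrep("A", 30); block_b <- strrep("C", 30)
  aln <- c(t1 = paste0(block_a, block_a), t2 = paste0(block_a, block_b),
           t3 = paste0(block_b, block_a), t4 = paste0(block_b, block_b))
  # two clean clades: {t1,t2} vs {t3,t4} differ in the first block
  aln2 <- c(u1 = strrep("AD", 50), u2 = strrep("AD", 50),
            u3 = strrep("CE", 50), u4 = strrep("CE", 50))
  tr2 <- bootstrap_support(sub_al <- aln2, n_replicates = 50, seed = 1)
  expect_true(all(tr2$node.label >= 95))
  tr0 <- bootstrap_support(aln2, n_replicates = 0)
  expect_null(tr0$node.label)
})

test_that("separated clades earn high bootstrap support", {
  set.seed(90)
  base1 <- random_peptide(200)
  base2 <- random_peptide(200)
  mut <- function(x, k) {
    b <- strsplit(x, "")[[1]]
    i <- sample(length(b), k)
    b[i] <- vapply(b[i], function(cur)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], cur), 1),
      character(1))
    paste(b, collapse = "")
  }
  aln <- c(a1 = base1, a2 = mut(base1, 2), b1 = base2, b2 = mut(base2, 2))
  tr <- bootstrap_support(aln, n_replicates = 100, seed = 2)
  supports <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(supports >= 95))
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100, na.rm = TRUE))
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  set.seed(91)
  aln <- setNames(replicate(5, random_peptide(60)), paste0("s", 1:5))
  t1 <- bootstrap_support(aln, n_replicates = 30, seed = 7)
  t2 <- bootstrap_support(aln, n_replicates = 30, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
})

test_that("RT representatives are picked by reference similarity", {
  set.seed(92)
  rt_pep <- random_peptide(120)
  refs <- c(RT_ref = rt_pep)
  # encode the peptide (no stops by construction of the alphabet)
  codons <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
              I="ATT", K="AAA", L="CTT", M="ATG", N="AAT", P="CCT", Q="CAA",
              R="CGT", S="TCT", T="ACT", V="GTT", W="TGG", Y="TAT")
  dna <- paste(codons[strsplit(rt_pep, "")[[1]]], collapse = "")
  good_contig <- paste0(random_dna(90), dna, random_dna(90))
  weak_contig <- random_dna(500)
  sat_contig <- tandem_array(random_dna(153), 10, 0.01)
  sel <- select_rt_representative(
    list(famA = c(ctg1 = weak_contig, ctg2 = good_contig),
         famSat = c(ctg1 = sat_contig)),
    refs, min_score = 100)
  expect_equal(sel$representatives$family_id, "famA")
  expect_equal(sel$representatives$contig_id, "ctg2")
  expect_equal(sel$dropped, "famSat")
  expect_true(grepl(substr(rt_pep, 10, 40), sel$peptides[["famA"]],
                    fixed = TRUE))
})

test_that("center-star alignment is deterministic and length-consistent", {
  set.seed(93)
  base <- random_peptide(80)
  mut_ins <- function(x, at, ins) {
    paste0(substr(x, 1, at), ins, substr(x, at + 1, nchar(x)))
  }
  peps <- c(p1 = base,
            p2 = mut_ins(base, 40, "WWW"),
            p3 = substr(base, 6, 80))
  aln <- align_rt_peptides(peps)
  expect_equal(length(unique(nchar(aln))), 1L)
  expect_identical(align_rt_peptides(peps), aln)
  expect_equal(gsub("-", "", aln[["p2"]], fixed = TRUE), peps[["p2"]])
  d <- pairwise_distances(aln)
  expect_lt(d["p1", "p3"], 0.05)
})

test_that("clade assignment follows the nearest reference leaf", {
  dm <- matrix(0, 4, 4,
               dimnames = list(c("fam1", "fam2", "refA", "refB"),
                               c("fam1", "fam2", "refA", "refB")))
  d <- function(i, j, v) dm[i, j] <<- dm[j, i] <<- v
  d("fam1", "refA", 0.1); d("fam1", "refB", 0.9); d("fam1", "fam2", 0.8)
  d("fam2", "refA", 0.9); d("fam2", "refB", 0.1); d("refA", "refB", 0.9)
  tr <- build_nj_tree(dm)
  cl <- assign_clades(tr, c(refA = "SIRE1/Maximus", refB = "Tekay"))
  expect_equal(unname(cl["fam1"]), "SIRE1/Maximus")
  expect_equal(unname(cl["fam2"]), "Tekay")
})
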