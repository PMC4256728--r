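# Two planted families clustered from raw reads; the larger ranks CL1.
make_two_cluster_fixture <- function() {
  set.seed(50)
  fa <- random_dna(300); fb <- random_dna(300)
  ra <- sample_reads(fa, 40, divergence = 0.005, prefix = "a", seed = 51)
  rb <- sample_reads(fb, 25, divergence = 0.005, prefix = "b", seed = 52)
  reads <- c(ra, rb)
  cl <- partition_graph(build_similarity_graph(reads), reads)
  list(reads = reads, cl = cl, fa = fa, fb = fb)
}

substitute_at <- function(x, pos) {
  for (p in pos) {
    cur <- substr(x, p, p)
    substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  x
}

test_that("ChIP reads map under the 3-mismatch/2-gap contract", {
  fx <- make_two_cluster_fixture()
  exact <- unname(fx$reads[["a0001"]])
  three_subs <- substitute_at(exact, c(10, 40, 70))
  four_subs <- substitute_at(exact, c(10, 40, 70, 90))
  two_gaps <- paste0(substr(exact, 1, 30), substr(exact, 33, 100))   # 98 bp
  three_gaps <- paste0(substr(exact, 1, 30), substr(exact, 34, 100)) # 97 bp
  chip <- c(q_exact = exact, q3 = three_subs, q4 = four_subs,
            q_gap2 = two_gaps, q_gap3 = three_gaps)
  asn <- map_reads_to_clusters(chip, fx$cl, fx$reads)
  expect_equal(asn$distance[asn$read_id == "q_exact"], 0)
  expect_equal(asn$cluster_id[asn$read_id == "q_exact"], "CL1")
  expect_equal(asn$distance[asn$read_id == "q3"], 3)
  expect_false("q4" %in% asn$read_id)        # 4 substitutions: rejected
  expect_equal(asn$distance[asn$read_id == "q_gap2"], 2)  # 2 gaps allowed
  expect_false("q_gap3" %in% asn$read_id)    # 3 gaps exceed the gap budget
})

test_that("reverse-complement ChIP reads map like their forward mates", {
  fx <- make_two_cluster_fixture()
  exact <- unname(fx$reads[["a0002"]])
  asn <- map_reads_to_clusters(c(q = revcomp1(exact)), fx$cl, fx$reads)
  expect_equal(asn$cluster_id, unname(fx$cl$membership[["a0002"]]))
  expect_equal(asn$distance, 0)
})

test_that("a closer cluster wins; distance ties go to the larger cluster", {
  seqA <- random_dna(100); seqB <- random_dna(100)
  genomic <- c(a1 = seqA, a2 = seqA, a3 = seqA, b1 = seqB, b2 = seqB)
  cl <- partition_graph(build_similarity_graph(genomic), genomic)
  expect_equal(unname(cl$membership[c("a1", "b1")]), c("CL1", "CL2"))
  near_b <- substitute_at(seqB, 50)        # distance 1 to B, far from A
  asn <- map_reads_to_clusters(c(q = near_b), cl, genomic)
  expect_equal(asn$cluster_id, "CL2")
  expect_equal(asn$distance, 1)
  # equal best distance in two clusters: the larger cluster (lower rank) wins
  g3 <- c(x1 = seqB, x2 = seqB, x3 = seqB, y1 = seqB, y2 = seqB)
  edges3 <- build_similarity_graph(g3)
  edges3 <- edges3[(edges3$read_a %in% c("x1", "x2", "x3")) ==
                   (edges3$read_b %in% c("x1", "x2", "x3")), ]
  cl3 <- partition_graph(edges3, g3)   # forced split: CL1={x*}, CL2={y*}
  q_tie <- substitute_at(seqB, 7)      # distance 1 to members of both
  asn3 <- map_reads_to_clusters(c(q = q_tie), cl3, g3)
  expect_equal(asn3$cluster_id, "CL1")
  expect_equal(asn3$distance, 1)
})

test_that("equal ChIP and input sets give normalized fold 1 everywhere", {
  asn <- data.frame(read_id = sprintf("r%02d", 1:30),
                    cluster_id = rep(c("CL1", "CL2", "CL3"), each = 10),
                    distance = 0, stringsAsFactors = FALSE)
  en <- compute_enrichment(asn, asn, 100, 100, c("CL2", "CL3"))
  expect_true(all(en$normalized_fold == 1))
  expect_true(all(en$fold == 1))
})

test_that("clusters absent from the ChIP set report fold zero", {
  chip <- data.frame(read_id = "c1", cluster_id = "CL1", distance = 0)
  input <- data.frame(read_id = c("i1", "i2"),
                      cluster_id = c("CL1", "CL2"), distance = 0)
  en <- compute_enrichment(chip, input, 10, 10, "CL1")
  expect_equal(en$fold[en$cluster_id == "CL2"], 0)
  expect_error(compute_enrichment(chip, input, 10, 10, "CL9"),
               "negative-control")
})

test_that("simulated centromeric enrichment is recovered end to end", {
  fams <- list(
    repeat_family_spec("cen", "satellite", 0.04, monomer_length = 153,
                       divergence = 0.005),
    repeat_family_spec("neu1", "LTR_copia", 0.05, template_length = 800,
                       divergence = 0.005),
    repeat_family_spec("neu2", "rDNA", 0.05, template_length = 800,
                       divergence = 0.005))
  g <- simulate_genome(genome_spec("A", 150000, fams, seed = 61))
  rd <- simulate_reads(g, read_sim_spec(1000, seed = 62, error_rate = 0.001))
  reads <- pool_mates(rd)
  cl <- partition_graph(build_similarity_graph(reads), reads)
  labels <- pooled_truth_labels(rd)
  det <- cl$clusters[cl$clusters$detailed & cl$clusters$n_reads >= 10, ]
  labs <- vapply(det$cluster_id, cluster_truth_label, character(1),
                 clustering = cl, labels = labels)
  cen_cl <- det$cluster_id[labs == "cen"][1]
  negs <- det$cluster_id[labs %in% c("neu1", "neu2")]
  cs <- read_sim_spec(700, seed = 63, error_rate = 0.001,
                      chip_target_family = "cen", chip_enrichment_fold = 5)
  sim <- simulate_chip_reads(g, cs)
  chip <- as.character(sim$chip$r1); input <- as.character(sim$input$r1)
  ac <- map_reads_to_clusters(chip, cl, reads)
  ai <- map_reads_to_clusters(input, cl, reads)
  en <- compute_enrichment(ac, ai, length(chip), length(input), negs)
  row <- en[en$cluster_id == cen_cl, ]
  expect_lt(abs(row$normalized_fold - 5), 3 * row$se_normalized_fold)
})

test_that("satellite variant share is zero without supporting ChIP reads", {
  set.seed(64)
  mono <- random_dna(153)
  arr <- tandem_array(mono, 30, 0)
  prof <- find_satellite_monomer(arr)
  variants <- data.frame(variant_length = 102, n_support = 10,
                         family_fraction = 1, read_share = 0.5,
                         del_start = 40,
                         deleted_segment = substr(mono, 40, 90))
  clean <- sample_reads(arr, 30, prefix = "c", seed = 65)
  share <- chip_satellite_variant_share(prof, variants, clean)
  expect_equal(share$chip_percent, 0)
  expect_error(chip_satellite_variant_share(prof, variants[0, ], clean),
               "variant")
  expect_error(chip_satellite_variant_share(prof, variants, character(0)),
               "ChIP")
})

test_that("planted variant junctions surface in the ChIP share", {
  set.seed(66)
  mono <- random_dna(153)
  del_start <- 40
  varm <- paste0(substr(mono, 1, del_start - 1), substr(mono, del_start + 51, 153))
  ctx <- paste0(strrep(mono, 2), varm, strrep(mono, 2))
  junction1 <- nchar(strrep(mono, 2)) + del_start - 1
  jr <- vapply(1:8, function(i) {
    st <- junction1 - 60 + i * 3
    substr(ctx, st, st + 99)
  }, character(1))
  names(jr) <- paste0("j", 1:8)
  clean <- sample_reads(strrep(mono, 6), 72, prefix = "c", seed = 67)
  prof <- find_satellite_monomer(strrep(mono, 30))
  variants <- data.frame(variant_length = 102, n_support = 8,
                         family_fraction = 1, read_share = 10,
                         del_start = del_start,
                         deleted_segment = substr(mono, del_start, del_start + 50))
  share <- chip_satellite_variant_share(prof, variants, c(jr, clean),
                                        genomic_family_reads = clean)
  expect_gt(share$chip_n_support, 5)
  expect_equal(share$genomic_n_support, 0)
  expect_gt(share$chip_percent, share$genomic_percent)
})
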