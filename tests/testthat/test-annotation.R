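mutate_frac <- function(x, frac, seed = 1) {
  set.seed(seed)
  b <- strsplit(x, "")[[1]]
  hit <- sample(seq_along(b), round(frac * length(b)))
  b[hit] <- vapply(b[hit], function(cur)
    sample(setdiff(c("A", "C", "G", "T"), cur), 1L), character(1))
  paste(b, collapse = "")
}

test_that("a contig identical to a library element takes its superfamily", {
  set.seed(20)
  lib <- c("copiaX#Ty1/Copia" = random_dna(800),
           "gypsyY#Ty3/Gypsy" = random_dna(800))
  ann <- annotate_cluster(c(ctg1 = lib[[1]]), lib)
  expect_equal(ann$superfamily, "Ty1/Copia")
  expect_true(ann$contig_hits$passing[1])
  expect_equal(ann$contig_hits$identity[1], 100)
})

test_that("hits below the identity screen leave the cluster Unclassified", {
  set.seed(21)
  lib <- c("copiaX#Ty1/Copia" = random_dna(800))
  far <- mutate_frac(lib[[1]], 0.40, seed = 22)   # ~60% identity, under 70
  ann <- annotate_cluster(c(ctg1 = far), lib)
  expect_equal(ann$superfamily, "Unclassified")
})

test_that("cluster superfamily is the plurality of contig-assigned reads", {
  set.seed(23)
  lib <- c("copiaX#Ty1/Copia" = random_dna(600),
           "gypsyY#Ty3/Gypsy" = random_dna(600))
  contigs <- c(ctg1 = lib[[2]], ctg2 = lib[[1]])
  ann <- annotate_cluster(contigs, lib,
                          reads_per_contig = c(ctg1 = 60, ctg2 = 40))
  expect_equal(ann$superfamily, "Ty3/Gypsy")
  tie <- annotate_cluster(contigs, lib,
                          reads_per_contig = c(ctg1 = 50, ctg2 = 50))
  expect_equal(tie$superfamily, "Unclassified")
})

test_that("satellite structure rescues clusters with no library hit", {
  set.seed(24)
  lib <- c("copiaX#Ty1/Copia" = random_dna(600))
  arr <- tandem_array(random_dna(153), 20, 0.01)
  ann <- annotate_cluster(c(ctg1 = arr), lib)
  expect_equal(ann$superfamily, "Satellite")
})

test_that("organelle elimination removes hit clusters, strict thresholds", {
  set.seed(25)
  plastid <- random_dna(2000)
  org_lib <- c("plastid#Organelle" = plastid)
  ctg_org <- substr(plastid, 100, 900)
  ctg_nuc <- random_dna(800)
  clusters <- data.frame(cluster_id = c("CL1", "CL2"),
                         n_reads = c(50, 40),
                         genome_proportion = c(5, 4),
                         detailed = TRUE, stringsAsFactors = FALSE)
  contigs <- list(CL1 = c(ctg1 = ctg_nuc), CL2 = c(ctg1 = ctg_org))
  el <- eliminate_organelle_clusters(clusters, contigs, org_lib)
  expect_equal(el$clusters$cluster_id, "CL1")
  expect_equal(el$removed$cluster_id, "CL2")
  # surviving cluster rows are untouched
  expect_equal(el$clusters[1, ], clusters[1, ])

  # strict '>' screen: a hit at exactly the threshold is NOT removed
  mid <- mutate_frac(ctg_org, 0.2, seed = 26)
  contigs2 <- list(CL2 = c(ctg1 = mid))
  clusters2 <- clusters[2, , drop = FALSE]
  h_ident <- suppressWarnings(
    annotate_cluster(c(ctg1 = mid), org_lib)$contig_hits$identity[1])
  at_thr <- eliminate_organelle_clusters(
    clusters2, contigs2, org_lib,
    annotation_config(min_identity = h_ident, min_coverage = 10))
  expect_equal(nrow(at_thr$removed), 0)
  below_thr <- eliminate_organelle_clusters(
    clusters2, contigs2, org_lib,
    annotation_config(min_identity = h_ident - 0.5, min_coverage = 10))
  expect_equal(below_thr$removed$cluster_id, "CL2")
})

test_that("superfamily summary reproduces published table arithmetic", {
  rows <- data.frame(
    superfamily = c("Ty1/Copia", "Ty3/Gypsy", "Unclassified LTR", "LINE/SINE",
                    "hAT", "Mutator", "RC/Helitron", "En-Spm", "PIF-Harbinger",
                    "Tc1-Mariner", "Other", "rDNA", "Satellite",
                    "Unclassified"),
    cl = c(39.57, 29.11, 0.28, 0.12,
           0.03, 0.57, 0.02, 3.64, 0.09, 0.01, 0.02, 0.43, 0.60, 1.05),
    ca = c(31.12, 32.56, 0.12, 0.03,
           0.06, 0.37, 0.04, 2.42, 0.24, 0.14, 0.03, 0.56, 4.89, 0.30))
  s <- summarize_superfamilies(rows)
  get <- function(fam, col) s[[col]][s$repeat_family == fam]
  expect_equal(get("Retrotransposon", "cl"), 69.08)
  expect_equal(get("Retrotransposon", "ca"), 63.83)
  expect_equal(get("Transposon", "cl"), 4.38)
  expect_equal(get("Transposon", "ca"), 3.30)
  expect_equal(get("Total", "cl"), 75.54)
  expect_equal(get("Total", "ca"), 72.88)
  # subtotals are exact sums of their member rows
  expect_equal(get("Retrotransposon", "cl"),
               sum(rows$cl[1:4]))
  expect_equal(get("Total", "cl"),
               get("Retrotransposon", "cl") + get("Transposon", "cl") +
                 get("rDNA", "cl") + get("Satellite", "cl") +
                 get("Unclassified", "cl"))
})

test_that("an empty cluster set summarizes to all zeros", {
  s <- summarize_superfamilies(
    data.frame(superfamily = character(), gp = numeric()))
  expect_true(all(s$gp == 0))
  expect_equal(s$gp[s$repeat_family == "Total"], 0)
})

test_that("per-read reference annotation screens identity and coverage", {
  set.seed(27)
  lib <- c("famA#Ty1/Copia" = random_dna(1000),
           "famB#Ty3/Gypsy" = random_dna(1000))
  exact <- substr(lib[[1]], 101, 200)
  # best hit covers only 45% of the read: 45 library bases + 55 random
  partial <- paste0(substr(lib[[1]], 301, 345), random_dna(55))
  diverged <- mutate_frac(substr(lib[[2]], 201, 300), 0.35, seed = 28)
  reads <- c(hit = exact, part = partial, far = diverged)
  ann <- annotate_reads_by_reference(reads, lib)
  expect_equal(ann$assignments$read_id, "hit")
  expect_equal(ann$assignments$family, "famA")
  expect_equal(ann$counts$n_reads[ann$counts$family == "famA"], 1L)
})

test_that("planted half-library read sets annotate at about 50%", {
  set.seed(29)
  lib <- c("famA#Ty1/Copia" = random_dna(1000))
  from_lib <- sample_reads(lib[[1]], 50, divergence = 0.03, prefix = "L",
                           seed = 30)
  random <- setNames(replicate(50, random_dna(100)), sprintf("R%03d", 1:50))
  ann <- annotate_reads_by_reference(c(from_lib, random), lib)
  captured <- ann$counts$percent_reads[ann$counts$family == "famA"]
  expect_gt(captured, 40)
  expect_lt(captured, 60)
  expect_true(all(grepl("^L", ann$assignments$read_id)))
  # counts are invariant to read order
  ann2 <- annotate_reads_by_reference(rev(c(from_lib, random)), lib)
  expect_equal(ann2$counts, ann$counts)
})
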