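#' ChIP read-mapping configuration
#'
#' The matching contract for assigning ChIP-seq reads to genomic repeat
#' clusters: an alignment may contain at most `max_mismatches` edited
#' positions in total, of which at most `max_gaps` may be gap (indel)
#' positions.
#'
#' @param max_mismatches Maximum edited positions (default 3).
#' @param max_gaps Maximum gap positions among them (default 2).
#' @param kmer_length Seed length for candidate detection (default 17; reads
#'   within 3 edits of a 100 bp read are guaranteed to share a 17-mer).
#' @param min_seed_support Minimum shared seed k-mers before a candidate pair
#'   is alignment-verified. Two 100 bp reads within 3 edits share at least
#'   `100 - 17 + 1 - 3*17 = 33` 17-mers, so the default 20 cannot lose true
#'   hits while discarding the bulk of phase-shifted tandem-repeat pairings.
#' @param max_candidates Per ChIP read, at most this many top-support
#'   genomic-read candidates are verified (default 100).
#' @return A list of class `chip_map_config`.
#' @export
chip_map_config <- function(max_mismatches = 3L, max_gaps = 2L,
                            kmer_length = 17L, min_seed_support = 20L,
                            max_candidates = 100L) {
  stopifnot(max_gaps <= max_mismatches, max_mismatches >= 0)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_gaps = as.integer(max_gaps),
                 kmer_length = as.integer(kmer_length),
                 min_seed_support = as.integer(min_seed_support),
                 max_candidates = as.integer(max_candidates)),
            class = "chip_map_config")
}

cluster_rank <- function(cluster_id) {
  as.integer(sub("^CL", "", cluster_id))
}

#' Map ChIP-seq reads onto genomic repeat clusters
#'
#' Each ChIP read is compared (both strands) against the genomic reads that
#' share a seed k-mer with it; a hit is an edit alignment with at most
#' `max_mismatches` total edited positions, of which at most `max_gaps` are
#' gaps. The read is assigned to the single cluster containing its
#' best-scoring (lowest-distance) genomic read; distance ties across clusters
#' go to the lower-ranked (larger) cluster. Unmatched reads stay unassigned.
#'
#' @param chip_reads Named character vector or `DNAStringSet`.
#' @param clustering A [partition_graph()] result over the genomic reads.
#' @param genomic_reads The genomic read set the clustering was built from.
#' @param config A [chip_map_config()].
#' @return A data.frame: `read_id`, `cluster_id`, `distance` (assigned reads
#'   only; deterministic and order-independent).
#' @export
map_reads_to_clusters <- function(chip_reads, clustering, genomic_reads,
                                  config = chip_map_config()) {
  stopifnot(inherits(clustering, "repeat_clustering"))
  q <- as_read_chr(chip_reads)
  s <- as_read_chr(genomic_reads)
  empty <- data.frame(read_id = character(), cluster_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (length(q) == 0L) return(empty)
  cand <- seeded_candidates(q, s, config$kmer_length)
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[, .(support = sum(support)), by = .(query, subject, orient)]
  cand <- cand[support >= config$min_seed_support]
  if (nrow(cand) == 0L) return(empty)
  setorder(cand, query, -support)
  cand[, crank := seq_len(.N), by = query]
  cand <- cand[crank <= config$max_candidates, .(query, subject, orient)]
  membership <- clustering$membership
  rc_cache <- new.env(parent = emptyenv())
  rc_of <- function(id) {
    if (is.null(rc_cache[[id]])) rc_cache[[id]] <- revcomp_chr(q[[id]])
    rc_cache[[id]]
  }
  rows <- list()
  for (qid in unique(cand$query)) {
    sub <- cand[query == qid]
    best_d <- config$max_mismatches + 1L
    best_clusters <- character(0)
    for (orn in unique(sub$orient)) {
      targets <- sub[orient == orn, subject]
      qs <- if (orn == "same") q[[qid]] else rc_of(qid)
      d <- adist(qs, s[targets], counts = TRUE)
      cnt <- attr(d, "counts")
      gaps <- cnt[1L, , "ins"] + cnt[1L, , "del"]
      total <- gaps + cnt[1L, , "sub"]
      ok <- total <= config$max_mismatches & gaps <= config$max_gaps
      if (!any(ok)) next
      dmin <- min(total[ok])
      if (dmin <= best_d) {
        hits <- targets[ok & total == dmin]
        cls <- unique(unname(membership[hits]))
        if (dmin < best_d) {
          best_d <- dmin
          best_clusters <- cls
        } else {
          best_clusters <- unique(c(best_clusters, cls))
        }
      }
    }
    if (length(best_clusters)) {
      win <- best_clusters[which.min(cluster_rank(best_clusters))]
      rows[[qid]] <- data.frame(read_id = qid, cluster_id = win,
                                distance = best_d, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Input-normalized ChIP enrichment per cluster
#'
#' Per-cluster read fractions in the ChIP and input sets give a raw fold
#' (ChIP fraction over input fraction); dividing by the pooled fold of the
#' negative-control clusters (their summed ChIP fraction over their summed
#' input fraction, i.e. the input-weighted mean control fold, which avoids
#' the small-count skew of averaging per-cluster ratios) yields the
#' normalized fold. Binomial standard errors of all four fractions are
#' propagated (delta method) into a standard error of the normalized fold.
#'
#' @param assignments_chip,assignments_input [map_reads_to_clusters()]
#'   results for the ChIP and input (mock) sets.
#' @param n_chip_total,n_input_total Total reads in each set (assigned or
#'   not); fractions are computed over these.
#' @param negative_controls Cluster ids used to normalize enrichment.
#' @param clusters Optional character vector of cluster ids to report
#'   (default: all clusters seen in either assignment set).
#' @return A data.frame: `cluster_id`, `chip_fraction`, `input_fraction`,
#'   `fold` (`NA` when the input fraction is zero and the ChIP fraction is
#'   not), `normalized_fold`, `se_normalized_fold`.
#' @export
compute_enrichment <- function(assignments_chip, assignments_input,
                               n_chip_total, n_input_total,
                               negative_controls, clusters = NULL) {
  stopifnot(nrow(assignments_chip) > 0L, nrow(assignments_input) > 0L,
            n_chip_total > 0L, n_input_total > 0L,
            length(negative_controls) >= 1L)
  if (is.null(clusters)) {
    clusters <- sort(unique(c(assignments_chip$cluster_id,
                              assignments_input$cluster_id,
                              negative_controls)))
  }
  cc <- table(factor(assignments_chip$cluster_id, levels = clusters))
  ic <- table(factor(assignments_input$cluster_id, levels = clusters))
  if (all(ic[negative_controls] == 0L)) {
    stop("all negative-control clusters have zero input reads")
  }
  pc <- as.numeric(cc) / n_chip_total
  pi_ <- as.numeric(ic) / n_input_total
  fold <- ifelse(pi_ > 0, pc / pi_, ifelse(pc == 0, 0, NA_real_))
  names(fold) <- clusters
  ctrl_chip <- sum(cc[negative_controls])
  ctrl_input <- sum(ic[negative_controls])
  if (ctrl_chip == 0L || ctrl_input == 0L) {
    stop("no usable negative-control read counts")
  }
  ctrl_fold <- (ctrl_chip / n_chip_total) / (ctrl_input / n_input_total)
  norm <- fold / ctrl_fold
  relvar <- ifelse(pc > 0, (1 - pc) / (pc * n_chip_total), 0) +
    ifelse(pi_ > 0, (1 - pi_) / (pi_ * n_input_total), 0) +
    1 / ctrl_chip + 1 / ctrl_input
  se <- ifelse(is.na(norm), NA_real_, norm * sqrt(relvar))
  data.frame(cluster_id = clusters,
             chip_fraction = pc, input_fraction = pi_,
             fold = unname(fold), normalized_fold = unname(norm),
             se_normalized_fold = unname(se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Satellite variant share in ChIP versus genomic reads
#'
#' For each detected monomer variant of a satellite family, the percentage of
#' the family's ChIP reads that support the variant's deletion junction, with
#' the genome-wide analogue computed from the family's genomic reads.
#'
#' @param profile The family's `satellite_profile`.
#' @param variants Variant table from [detect_monomer_variants()] (at least
#'   one row).
#' @param chip_family_reads ChIP reads assigned to the satellite cluster;
#'   must be nonempty.
#' @param genomic_family_reads Optional genomic reads of the cluster.
#' @param flank,kmer_length,min_run_kmers Junction-detection parameters as in
#'   [detect_monomer_variants()].
#' @return A data.frame: `variant_length`, `chip_n_support`, `chip_percent`,
#'   `genomic_n_support`, `genomic_percent` (`NA` without genomic reads).
#' @export
chip_satellite_variant_share <- function(profile, variants, chip_family_reads,
                                         genomic_family_reads = NULL,
                                         flank = 20L, kmer_length = 12L,
                                         min_run_kmers = 3L) {
  stopifnot(inherits(profile, "satellite_profile"))
  if (is.null(variants) || nrow(variants) == 0L) {
    stop("family has no detected variants")
  }
  if (length(chip_family_reads) == 0L) {
    stop("no ChIP reads assigned to the family")
  }
  chip <- as_read_chr(chip_family_reads)
  jr_chip <- variant_junction_reads(chip, profile, flank, kmer_length,
                                    min_run_kmers)
  jr_gen <- NULL
  if (!is.null(genomic_family_reads)) {
    gen <- as_read_chr(genomic_family_reads)
    if (length(gen)) {
      jr_gen <- variant_junction_reads(gen, profile, flank, kmer_length,
                                       min_run_kmers)
    }
  }
  P <- profile$period
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    dv <- P - variants$variant_length[i]
    sc <- if (nrow(jr_chip)) sum(jr_chip$d == dv) else 0L
    out <- data.frame(variant_length = variants$variant_length[i],
                      chip_n_support = sc,
                      chip_percent = 100 * sc / length(chip),
                      genomic_n_support = NA_integer_,
                      genomic_percent = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(jr_gen)) {
      sg <- if (nrow(jr_gen)) sum(jr_gen$d == dv) else 0L
      out$genomic_n_support <- sg
      out$genomic_percent <- 100 * sg / length(as_read_chr(genomic_family_reads))
    }
    out
  })
  do.call(rbind, rows)
}
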