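#' Comparative clustering of a combined multi-species dataset
#'
#' Runs the similarity-graph clustering on pooled, sample-coded reads (ids of
#' the form `CODE|read_id`, as produced by [subsample_combined()]) and
#' computes, for every detailed cluster, the per-species genome proportion:
#' 100 times the cluster's reads of that species over all analyzed reads of
#' that species. A species is called present in a cluster when it contributes
#' at least `max(presence_min_reads, presence_min_frac * species reads)`
#' reads; the presence pattern is the sorted `+`-joined set of present
#' species.
#'
#' @param combined_reads Named character vector or `DNAStringSet` with
#'   `CODE|` read-id prefixes; at least two species, none empty.
#' @param config A [clustering_config()].
#' @param presence_min_reads Absolute presence floor in reads (default 5).
#' @param presence_min_frac Relative presence floor as a fraction of the
#'   species' reads (default 5e-6, i.e. 0.0005%).
#' @return A list of class `comparative_table`: `table` (data.frame:
#'   `cluster_id`, `n_reads`, per-species `gp_<code>` percent columns,
#'   `pattern`), `clustering` (the underlying [partition_graph()] result),
#'   and `species_totals`.
#' @export
comparative_cluster_analysis <- function(combined_reads,
                                         config = clustering_config(),
                                         presence_min_reads = 5L,
                                         presence_min_frac = 5e-6) {
  seqs <- as_read_chr(combined_reads)
  codes <- species_codes_of(names(seqs))
  tot <- table(codes)
  if (length(tot) < 2L) stop("need reads from at least two species")
  if (any(tot == 0L)) stop("a species has zero reads")
  edges <- build_similarity_graph(seqs, config)
  clustering <- partition_graph(edges, seqs, config)
  det <- clustering$clusters[clustering$clusters$detailed, , drop = FALSE]
  sp_names <- names(tot)
  rows <- lapply(det$cluster_id, function(cl) {
    mem <- cluster_members(clustering, cl)
    cnt <- table(factor(species_codes_of(mem), levels = sp_names))
    floor_n <- pmax(presence_min_reads, presence_min_frac * as.numeric(tot))
    present <- as.numeric(cnt) >= floor_n
    row <- data.frame(cluster_id = cl, n_reads = length(mem),
                      stringsAsFactors = FALSE)
    for (sc in sp_names) {
      row[[paste0("gp_", sc)]] <- 100 * as.numeric(cnt[sc]) / as.numeric(tot[sc])
    }
    row$pattern <- paste(sp_names[present], collapse = "+")
    row
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    out <- data.frame(cluster_id = character(), n_reads = integer(),
                      stringsAsFactors = FALSE)
    for (sc in sp_names) out[[paste0("gp_", sc)]] <- numeric()
    out$pattern <- character()
    out
  }
  structure(list(table = tab, clustering = clustering,
                 species_totals = tot),
            class = "comparative_table")
}

#' Summarize shared/specific cluster patterns
#'
#' @param table A [comparative_cluster_analysis()] result or its `table`
#'   data.frame.
#' @return A data.frame keyed by presence `pattern` with the number of
#'   clusters and, per species, the summed genome proportion of clusters in
#'   that pattern.
#' @export
pattern_summary <- function(table) {
  tab <- if (inherits(table, "comparative_table")) table$table else table
  stopifnot(nrow(tab) >= 1L)
  gp_cols <- grep("^gp_", names(tab), value = TRUE)
  agg <- aggregate(tab[gp_cols], by = list(pattern = tab$pattern), sum)
  cnt <- aggregate(list(n_clusters = tab$cluster_id),
                   by = list(pattern = tab$pattern), length)
  out <- merge(cnt, agg, by = "pattern")
  out[order(-out$n_clusters, out$pattern), , drop = FALSE]
}

#' Estimate genome size from flow cytometry
#'
#' 1C genome size of the object sample as the ratio of mean G1 nuclei
#' fluorescence intensities times the reference standard's genome size.
#'
#' @param mean_g1_object Mean G1 fluorescence of the object sample (a.u.).
#' @param mean_g1_standard Mean G1 fluorescence of the reference standard.
#' @param standard_size_mb Genome size of the standard in Mb.
#' @return Estimated genome size in Mb.
#' @export
estimate_genome_size <- function(mean_g1_object, mean_g1_standard,
                                 standard_size_mb) {
  if (any(c(mean_g1_object, mean_g1_standard, standard_size_mb) <= 0)) {
    stop("flow-cytometry inputs must be positive")
  }
  (mean_g1_object / mean_g1_standard) * standard_size_mb
}

#' Fold ratio of two genome sizes
#'
#' @param size_a,size_b Genome sizes (same units).
#' @return `size_a / size_b`, rounded half-up to one decimal.
#' @export
genome_size_ratio <- function(size_a, size_b) {
  stopifnot(size_a > 0, size_b > 0)
  round_half_up(size_a / size_b, 1)
}
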