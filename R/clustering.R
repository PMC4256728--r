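#' Clustering configuration
#'
#' Thresholds for the read-similarity graph and its partition. An edge
#' requires at least `min_identity` percent identity over at least
#' `min_overlap_fraction` of the shorter read; candidate pairs are found via
#' shared `kmer_length`-mers on either strand. Clusters holding at least
#' `detail_threshold` of all analyzed reads (and at least two reads) enter the
#' detailed report; everything else is retained as non-repetitive singletons
#' or minor clusters in the totals.
#'
#' @param min_identity Minimum percent identity (default 90).
#' @param min_overlap_fraction Minimum fraction of the shorter read covered by
#'   the alignment (default 0.55).
#' @param kmer_length Seed k-mer length (default 17).
#' @param detail_threshold Minimum cluster share of analyzed reads for the
#'   detailed report (default 0.00005, i.e. 0.005%).
#' @param partition_method `"connected_components"` (default) or `"louvain"`.
#' @param max_candidates_per_read Sparsification cap: per read, only the
#'   candidates with the most shared k-mers are alignment-verified.
#' @param max_offsets_per_pair Number of top seed offsets tried per candidate
#'   pair during ungapped verification.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(min_identity = 90, min_overlap_fraction = 0.55,
                              kmer_length = 17L, detail_threshold = 5e-5,
                              partition_method = c("connected_components",
                                                   "louvain"),
                              max_candidates_per_read = 30L,
                              max_offsets_per_pair = 3L) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            kmer_length >= 4, detail_threshold >= 0, detail_threshold < 1)
  structure(list(min_identity = min_identity,
                 min_overlap_fraction = min_overlap_fraction,
                 kmer_length = as.integer(kmer_length),
                 detail_threshold = detail_threshold,
                 partition_method = match.arg(partition_method),
                 max_candidates_per_read = as.integer(max_candidates_per_read),
                 max_offsets_per_pair = as.integer(max_offsets_per_pair)),
            class = "clustering_config")
}

# Candidate pairs from shared canonical k-mers, with per-pair seed offsets.
# Returns data.table: read_a, read_b (a < b), orient ("same"/"diff"),
# offset, support (k-mers agreeing on this offset).
candidate_pairs <- function(seqs, config) {
  k <- config$kmer_length
  kt <- kmer_table(seqs, k)
  if (nrow(kt) == 0L) {
    return(data.table(read_a = character(), read_b = character(),
                      orient = character(), offset = integer(),
                      support = integer()))
  }
  lens <- setNames(nchar(seqs), names(seqs))
  setkey(kt, canon)
  j <- kt[kt, on = "canon", allow.cartesian = TRUE]
  # columns: id, pos, cstrand (x side) and i.id, i.pos, i.cstrand (i side)
  j <- j[id < i.id]
  if (nrow(j) == 0L) {
    return(data.table(read_a = character(), read_b = character(),
                      orient = character(), offset = integer(),
                      support = integer()))
  }
  la <- lens[j$id]
  lb <- lens[j$i.id]
  same <- j$cstrand == j$i.cstrand
  # position of the k-mer within the oriented (possibly revcomp'd) b read
  pos_b <- ifelse(same, j$i.pos, lb - j$i.pos - k + 2L)
  off <- j$pos - pos_b
  pairs <- data.table(read_a = j$id, read_b = j$i.id,
                      orient = ifelse(same, "same", "diff"),
                      offset = as.integer(off))
  pairs[, .(support = .N), by = .(read_a, read_b, orient, offset)]
}

# Sparsify candidates: keep pairs ranked within the top `max_cand` partners
# (by total seed support) of either endpoint.
sparsify_pairs <- function(pair_scores, max_cand) {
  both <- rbindlist(list(
    pair_scores[, .(r = read_a, read_a, read_b, score)],
    pair_scores[, .(r = read_b, read_a, read_b, score)]))
  setorder(both, r, -score)
  both[, rank := seq_len(.N), by = r]
  keep <- unique(both[rank <= max_cand, .(read_a, read_b)])
  pair_scores[keep, on = c("read_a", "read_b")]
}

#' Build a read-similarity graph
#'
#' Candidate read pairs share at least one `kmer_length`-mer on either strand;
#' each candidate is verified by ungapped alignment at its best seed offsets
#' (planted copies and sequencing errors are substitution-only, so the seed
#' offset fixes the alignment frame). An edge is emitted when percent identity
#' and overlap fraction pass the configured thresholds.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param config A [clustering_config()].
#' @return A data.frame of edges: `read_a`, `read_b`, `identity` (percent),
#'   `overlap_fraction`, `orient` (`same`/`diff` strand), `offset`.
#' @export
build_similarity_graph <- function(reads, config = clustering_config()) {
  seqs <- as_read_chr(reads)
  stopifnot(length(seqs) >= 1L)
  empty <- data.frame(read_a = character(), read_b = character(),
                      identity = numeric(), overlap_fraction = numeric(),
                      orient = character(), offset = integer(),
                      stringsAsFactors = FALSE)
  if (length(seqs) < 2L) return(empty)
  cand <- candidate_pairs(seqs, config)
  if (nrow(cand) == 0L) return(empty)
  scores <- cand[, .(score = sum(support)), by = .(read_a, read_b)]
  kept <- sparsify_pairs(scores, config$max_candidates_per_read)
  cand <- cand[kept[, .(read_a, read_b)], on = c("read_a", "read_b")]
  setorder(cand, read_a, read_b, orient, -support)
  cand[, orank := seq_len(.N), by = .(read_a, read_b)]
  cand <- cand[orank <= config$max_offsets_per_pair]
  raw_f <- raw_list(seqs)
  rc_cache <- new.env(parent = emptyenv())
  raw_rc <- function(id) {
    if (is.null(rc_cache[[id]])) rc_cache[[id]] <- charToRaw(revcomp_chr(seqs[[id]]))
    rc_cache[[id]]
  }
  lens <- nchar(seqs)
  names(lens) <- names(seqs)
  n <- nrow(cand)
  ident <- numeric(n); ovf <- numeric(n)
  a_col <- cand$read_a; b_col <- cand$read_b
  or_col <- cand$orient; off_col <- cand$offset
  for (i in seq_len(n)) {
    ra <- raw_f[[a_col[i]]]
    rb <- if (or_col[i] == "same") raw_f[[b_col[i]]] else raw_rc(b_col[i])
    mo <- ungapped_compare(ra, rb, off_col[i])
    if (mo[2L] > 0L) {
      ident[i] <- 100 * mo[1L] / mo[2L]
      ovf[i] <- mo[2L] / min(lens[[a_col[i]]], lens[[b_col[i]]])
    }
  }
  cand[, `:=`(identity = ident, overlap_fraction = ovf)]
  # best offset per pair, then threshold
  setorder(cand, read_a, read_b, -identity, -overlap_fraction)
  best <- cand[, .SD[1L], by = .(read_a, read_b)]
  edges <- best[identity >= config$min_identity &
                overlap_fraction >= config$min_overlap_fraction]
  as.data.frame(edges[, .(read_a, read_b, identity, overlap_fraction,
                          orient, offset)])
}

#' Partition the similarity graph into repeat clusters
#'
#' Every read lands in exactly one cluster (singletons allowed; they stand for
#' non-repetitive sequence). Clusters are ranked by read count, ties broken by
#' the lexicographically smallest member read id, and labeled `CL1`, `CL2`,
#' ... in rank order. A cluster is `detailed` when it holds at least two reads
#' and at least `detail_threshold` of all analyzed reads.
#'
#' @param edges Edge data.frame from [build_similarity_graph()].
#' @param reads The full read set the graph was built from (named character or
#'   `DNAStringSet`); reads without edges become singleton clusters.
#' @param config A [clustering_config()]; `partition_method` selects connected
#'   components (default) or Louvain community detection.
#' @return An object of class `repeat_clustering`: list with `clusters` (one
#'   row per cluster: `cluster_id`, `n_reads`, `genome_proportion` in percent,
#'   `detailed`), `membership` (named read -> cluster_id vector), and
#'   `total_reads`.
#' @export
partition_graph <- function(edges, reads, config = clustering_config()) {
  seqs <- as_read_chr(reads)
  ids <- names(seqs)
  total <- length(ids)
  g <- igraph::graph_from_data_frame(
    edges[, c("read_a", "read_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- if (config$partition_method == "louvain" && nrow(edges) > 0) {
    igraph::membership(igraph::cluster_louvain(
      g, weights = edges$identity * edges$overlap_fraction))
  } else {
    igraph::components(g)$membership
  }
  comp <- comp[ids]
  sp <- split(ids, comp)
  sizes <- lengths(sp)
  firsts <- vapply(sp, function(x) min(x), character(1))
  ord <- order(-sizes, firsts)
  sp <- sp[ord]; sizes <- sizes[ord]
  cl_ids <- paste0("CL", seq_along(sp))
  membership <- setNames(rep(cl_ids, sizes), unlist(sp, use.names = FALSE))
  membership <- membership[ids]
  clusters <- data.frame(
    cluster_id = cl_ids,
    n_reads = as.integer(sizes),
    genome_proportion = 100 * as.integer(sizes) / total,
    stringsAsFactors = FALSE)
  clusters$detailed <- clusters$n_reads >= 2L &
    clusters$n_reads / total >= config$detail_threshold
  structure(list(clusters = clusters, membership = membership,
                 total_reads = total),
            class = "repeat_clustering")
}

#' Read ids belonging to a cluster
#'
#' @param clustering A [partition_graph()] result.
#' @param cluster_id Cluster label (e.g. `"CL1"`).
#' @return Character vector of read ids.
#' @export
cluster_members <- function(clustering, cluster_id) {
  stopifnot(inherits(clustering, "repeat_clustering"))
  names(clustering$membership)[clustering$membership == cluster_id]
}

#' Assemble consensus contigs for a cluster
#'
#' Greedy overlap layout: the highest-degree read seeds the layout at position
#' zero; neighbors are placed by their verified seed offsets (breadth-first,
#' first placement wins), and a majority-vote consensus is called per column.
#' Reads that cannot be placed consistently are dropped from the layout;
#' uncovered gaps split the consensus into multiple contigs.
#'
#' @param read_ids Reads of one cluster.
#' @param reads Full read set (named character or `DNAStringSet`).
#' @param config A [clustering_config()].
#' @return List with `contigs` (named character, `ctg1`, `ctg2`, ... longest
#'   first) and `layout` (data.frame: `read_id`, `contig`, `pos`, `strand`).
#' @export
assemble_cluster_contigs <- function(read_ids, reads,
                                     config = clustering_config()) {
  seqs <- as_read_chr(reads)[read_ids]
  stopifnot(length(seqs) >= 1L)
  if (length(seqs) == 1L) {
    return(list(contigs = c(ctg1 = unname(seqs)),
                layout = data.frame(read_id = names(seqs), contig = "ctg1",
                                    pos = 0L, strand = "+",
                                    stringsAsFactors = FALSE)))
  }
  # Layout accepts shorter overlaps than cluster membership did: the reads
  # are already known to belong together, and chaining only needs a solid
  # anchor (>= 30% of the shorter read).
  layout_cfg <- config
  layout_cfg$min_overlap_fraction <- min(config$min_overlap_fraction, 0.3)
  edges <- build_similarity_graph(seqs, layout_cfg)
  lens <- setNames(nchar(seqs), names(seqs))
  adj <- new.env(parent = emptyenv())
  for (id in names(seqs)) adj[[id]] <- list()
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges$read_a[i]; b <- edges$read_b[i]
      adj[[a]] <- c(adj[[a]], list(list(to = b, orient = edges$orient[i],
                                        offset = edges$offset[i], rev = FALSE)))
      adj[[b]] <- c(adj[[b]], list(list(to = a, orient = edges$orient[i],
                                        offset = edges$offset[i], rev = TRUE)))
    }
  }
  deg <- vapply(names(seqs), function(id) length(adj[[id]]), integer(1))
  placed_pos <- integer(0); placed_strand <- character(0)
  remaining <- names(seqs)
  comp_id <- character(0)
  comp_counter <- 0L
  while (length(remaining)) {
    comp_counter <- comp_counter + 1L
    seed <- remaining[which.max(deg[remaining])]
    queue <- seed
    placed_pos[seed] <- 0L; placed_strand[seed] <- "+"
    comp_id[seed] <- comp_counter
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[cur]]) {
        nb <- e$to
        if (!is.na(placed_pos[nb])) next
        # Edge stored as (a, b, orient, offset): the oriented b read (forward
        # when orient == "same", revcomp'd otherwise) starts at a-forward
        # position offset (0-based). Strand relation: the placed strands of a
        # and b agree iff orient == "same".
        flip <- function(s) if (s == "+") "-" else "+"
        if (!e$rev) {          # cur is a, place b
          sa <- placed_strand[[cur]]
          sb <- if (e$orient == "same") sa else flip(sa)
          pb <- if (sa == "+") placed_pos[[cur]] + e$offset
                else placed_pos[[cur]] + lens[[cur]] - e$offset - lens[[nb]]
          placed_pos[nb] <- pb; placed_strand[nb] <- sb
        } else {               # cur is b, place a by inverting the formulas
          sb <- placed_strand[[cur]]
          sa <- if (e$orient == "same") sb else flip(sb)
          pa <- if (sa == "+") placed_pos[[cur]] - e$offset
                else placed_pos[[cur]] - lens[[nb]] + e$offset + lens[[cur]]
          placed_pos[nb] <- pa; placed_strand[nb] <- sa
        }
        comp_id[nb] <- comp_counter
        queue <- c(queue, nb)
      }
    }
    remaining <- setdiff(remaining, names(placed_pos))
  }
  ids <- names(placed_pos)
  layout <- data.frame(read_id = ids, comp = comp_id[ids],
                       pos = placed_pos[ids], strand = placed_strand[ids],
                       stringsAsFactors = FALSE)
  contigs <- character(0)
  layout$contig <- NA_character_
  ctg_n <- 0L
  out_rows <- list()
  for (cp in unique(layout$comp)) {
    sub <- layout[layout$comp == cp, , drop = FALSE]
    sub$pos <- sub$pos - min(sub$pos)
    span <- max(sub$pos + lens[sub$read_id])
    tab <- matrix(0L, nrow = 4L, ncol = span)
    rownames(tab) <- DNA_BASES
    for (i in seq_len(nrow(sub))) {
      s <- seqs[[sub$read_id[i]]]
      if (sub$strand[i] == "-") s <- revcomp_chr(s)
      b <- strsplit(s, "", fixed = TRUE)[[1]]
      idx <- sub$pos[i] + seq_along(b)
      ok <- b %in% DNA_BASES
      tab[cbind(match(b[ok], DNA_BASES), idx[ok])] <-
        tab[cbind(match(b[ok], DNA_BASES), idx[ok])] + 1L
    }
    cov <- colSums(tab) > 0L
    cons <- rep("N", span)
    cons[cov] <- DNA_BASES[apply(tab[, cov, drop = FALSE], 2L, which.max)]
    runs <- rle(cov)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (ri in which(runs$values)) {
      ctg_n <- ctg_n + 1L
      contigs[paste0("ctg", ctg_n)] <-
        paste(cons[starts[ri]:ends[ri]], collapse = "")
      inside <- sub$pos >= starts[ri] - 1L & sub$pos + lens[sub$read_id] <= ends[ri]
      if (any(inside)) {
        rows <- sub[inside, c("read_id", "pos", "strand")]
        rows$contig <- paste0("ctg", ctg_n)
        rows$pos <- rows$pos - (starts[ri] - 1L)
        out_rows[[length(out_rows) + 1L]] <- rows
      }
    }
  }
  ord <- order(-nchar(contigs))
  contigs <- contigs[ord]
  relabel <- setNames(paste0("ctg", seq_along(contigs)), names(contigs))
  names(contigs) <- relabel[names(contigs)]
  layout_out <- if (length(out_rows)) {
    lo <- do.call(rbind, out_rows)
    lo$contig <- relabel[lo$contig]
    lo[, c("read_id", "contig", "pos", "strand")]
  } else {
    data.frame(read_id = character(), contig = character(), pos = integer(),
               strand = character(), stringsAsFactors = FALSE)
  }
  rownames(layout_out) <- NULL
  list(contigs = contigs, layout = layout_out)
}

#' Total repetitive fraction of the genome
#'
#' Sum of genome proportions over detailed clusters (at least `min_reads`
#' reads and the configured detail threshold), computed after any organelle
#' cluster elimination.
#'
#' @param clusters A [partition_graph()] result or its `clusters` data.frame.
#' @param min_reads Minimum cluster size counted as repetitive (default 2).
#' @return Percentage of analyzed reads in repeat clusters.
#' @export
total_repeat_fraction <- function(clusters, min_reads = 2L) {
  df <- if (inherits(clusters, "repeat_clustering")) clusters$clusters else clusters
  if (nrow(df) == 0L) return(0)
  sum(df$genome_proportion[df$detailed & df$n_reads >= min_reads])
}
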