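SUPERFAMILIES <- c("Ty1/Copia", "Ty3/Gypsy", "Unclassified LTR", "LINE/SINE",
                   "hAT", "Mutator", "RC/Helitron", "En-Spm", "PIF-Harbinger",
                   "Tc1-Mariner", "Other", "rDNA", "Satellite", "Organelle",
                   "Unclassified")
RETRO_ROWS <- c("Ty1/Copia", "Ty3/Gypsy", "Unclassified LTR", "LINE/SINE")
TRANSPOSON_ROWS <- c("hAT", "Mutator", "RC/Helitron", "En-Spm",
                     "PIF-Harbinger", "Tc1-Mariner", "Other")

#' Annotation configuration
#'
#' Screening thresholds for similarity hits against a reference repeat
#' library: a hit is retained only when identity is strictly above
#' `min_identity` percent and query coverage strictly above `min_coverage`
#' percent of the query (contig or read) length.
#'
#' @param min_identity Identity threshold in percent (default 70).
#' @param min_coverage Query-coverage threshold in percent (default 50).
#' @return A list of class `annotation_config`.
#' @export
annotation_config <- function(min_identity = 70, min_coverage = 50) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage),
            class = "annotation_config")
}

# Superfamily labels from library sequence names ("id#Superfamily", the
# RepeatMasker library convention). Unlabeled entries fall back to
# "Unclassified".
library_superfamily <- function(lib_names) {
  sf <- ifelse(grepl("#", lib_names, fixed = TRUE),
               sub("^[^#]*#", "", lib_names), "Unclassified")
  unname(sf)
}

library_family_id <- function(lib_names) {
  unname(sub("#.*$", "", lib_names))
}

dna_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
    }
    m
  }
})

# Best gapped local alignment of one query against every library sequence,
# both strands. Returns a data.frame of all hits (one row per library entry).
contig_library_hits <- function(query, library) {
  libseq <- as_read_chr(library)
  q <- Biostrings::DNAString(query)
  qr <- Biostrings::reverseComplement(q)
  hits <- lapply(seq_along(libseq), function(i) {
    s <- Biostrings::DNAString(libseq[[i]])
    best <- NULL
    for (pat in list(q, qr)) {
      aln <- Biostrings::pairwiseAlignment(pat, s, type = "local",
                                           substitutionMatrix = dna_submat(),
                                           gapOpening = 5, gapExtension = 2)
      alen <- nchar(gsub("-", "", as.character(Biostrings::pattern(aln)),
                         fixed = TRUE))
      cand <- data.frame(library_id = library_family_id(names(libseq)[i]),
                         superfamily = library_superfamily(names(libseq)[i]),
                         identity = Biostrings::pid(aln),
                         query_coverage = 100 * alen / nchar(query),
                         score = Biostrings::score(aln),
                         stringsAsFactors = FALSE)
      if (is.null(best) || cand$score > best$score) best <- cand
    }
    best
  })
  do.call(rbind, hits)
}

#' Annotate a cluster's contigs against a repeat library
#'
#' Each contig takes the superfamily of its best library hit that passes the
#' identity/coverage screen (best by identity, then coverage). The cluster's
#' superfamily is the plurality vote over contig-assigned reads; ties are
#' conservatively `Unclassified`. A cluster with no passing hit but with
#' detectable tandem structure in a contig is called `Satellite`.
#'
#' @param contigs Named character vector of cluster contigs (or an
#'   [assemble_cluster_contigs()] result).
#' @param library Reference repeat library: named `DNAStringSet` or character;
#'   names follow the `id#Superfamily` convention.
#' @param config An [annotation_config()].
#' @param reads_per_contig Optional named integer (reads laid out per contig)
#'   used to weight the plurality vote; defaults to equal weights.
#' @return List with `superfamily` (character scalar) and `contig_hits`
#'   (data.frame of per-contig best hits with a `passing` flag).
#' @export
annotate_cluster <- function(contigs, library, config = annotation_config(),
                             reads_per_contig = NULL) {
  if (is.list(contigs) && !is.null(contigs$contigs)) {
    if (is.null(reads_per_contig) && nrow(contigs$layout)) {
      reads_per_contig <- table(contigs$layout$contig)
    }
    contigs <- contigs$contigs
  }
  stopifnot(length(contigs) >= 1L)
  contigs <- as_read_chr(contigs)
  if (is.null(reads_per_contig)) {
    reads_per_contig <- setNames(rep(1L, length(contigs)), names(contigs))
  }
  libseq <- tryCatch(as_read_chr(library), error = function(e) character())
  assigned <- character(0)
  rows <- list()
  for (cn in names(contigs)) {
    sf <- NA_character_
    if (length(libseq)) {
      h <- contig_library_hits(contigs[[cn]], libseq)
      h <- h[order(-h$identity, -h$query_coverage), , drop = FALSE]
      h$passing <- h$identity > config$min_identity &
        h$query_coverage > config$min_coverage
      top <- h[h$passing, , drop = FALSE]
      if (nrow(top)) sf <- top$superfamily[1L]
      best <- h[1L, , drop = FALSE]
      best$query_id <- cn
      rows[[cn]] <- best
    }
    if (is.na(sf)) {
      sat <- find_satellite_monomer(contigs[[cn]])
      sf <- if (!is.null(sat)) "Satellite" else "Unclassified"
    }
    assigned[cn] <- sf
  }
  if (length(libseq) == 0L) {
    warning("empty reference library: cluster left Unclassified")
  }
  w <- as.numeric(reads_per_contig[names(assigned)])
  w[is.na(w)] <- 1
  votes <- tapply(w, assigned, sum)
  informative <- votes[names(votes) != "Unclassified"]
  winner <- if (length(informative) == 0L) "Unclassified" else {
    top <- informative[informative == max(informative)]
    if (length(top) > 1L) "Unclassified" else names(top)
  }
  hits_df <- if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("query_id", "library_id", "superfamily", "identity",
            "query_coverage", "passing")]
  } else {
    data.frame(query_id = character(), library_id = character(),
               superfamily = character(), identity = numeric(),
               query_coverage = numeric(), passing = logical(),
               stringsAsFactors = FALSE)
  }
  list(superfamily = winner, contig_hits = hits_df)
}

#' Eliminate organelle-derived clusters
#'
#' A cluster whose contigs hit the organelle (mitochondrial/plastid) reference
#' at strictly more than the screening thresholds is removed before any
#' genome-proportion total is computed. Surviving clusters are untouched.
#'
#' @param clusters Clusters data.frame (from [partition_graph()]'s `clusters`
#'   element, or any data.frame with a `cluster_id` column).
#' @param contigs_by_cluster Named list: cluster_id -> named character vector
#'   of contigs.
#' @param organelle_library Organelle reference sequences (named character or
#'   `DNAStringSet`); must be nonempty.
#' @param config An [annotation_config()].
#' @return List with `clusters` (filtered data.frame) and `removed`
#'   (data.frame: `cluster_id`, `library_id`, `identity`, `query_coverage`).
#' @export
eliminate_organelle_clusters <- function(clusters, contigs_by_cluster,
                                         organelle_library,
                                         config = annotation_config()) {
  if (inherits(clusters, "repeat_clustering")) clusters <- clusters$clusters
  libseq <- as_read_chr(organelle_library)
  stopifnot(length(libseq) >= 1L)
  removed <- list()
  for (cl in intersect(clusters$cluster_id, names(contigs_by_cluster))) {
    ctgs <- as_read_chr(contigs_by_cluster[[cl]])
    for (cn in names(ctgs)) {
      h <- contig_library_hits(ctgs[[cn]], libseq)
      h <- h[h$identity > config$min_identity &
             h$query_coverage > config$min_coverage, , drop = FALSE]
      if (nrow(h)) {
        h <- h[order(-h$identity), , drop = FALSE]
        removed[[cl]] <- data.frame(cluster_id = cl,
                                    library_id = h$library_id[1L],
                                    identity = h$identity[1L],
                                    query_coverage = h$query_coverage[1L],
                                    stringsAsFactors = FALSE)
        break
      }
    }
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(cluster_id = character(), library_id = character(),
               identity = numeric(), query_coverage = numeric(),
               stringsAsFactors = FALSE)
  rownames(removed_df) <- NULL
  list(clusters = clusters[!clusters$cluster_id %in% removed_df$cluster_id, ,
                           drop = FALSE],
       removed = removed_df)
}

#' Superfamily summary table
#'
#' Aggregates genome proportions by superfamily and derives the standard
#' summary rows: a retroelement subtotal (Ty1/Copia + Ty3/Gypsy + Unclassified
#' LTR + LINE/SINE), a DNA-transposon subtotal (hAT, Mutator, RC/Helitron,
#' En-Spm, PIF-Harbinger, Tc1-Mariner, Other), rDNA, Satellite, Unclassified,
#' and a grand total. All values are percentages of analyzed reads, rounded
#' half-up to two decimals in the output.
#'
#' @param x A data.frame with a `superfamily` (or `repeat_family`) column and
#'   one or more numeric genome-proportion columns (one per species).
#' @return A data.frame with a `repeat_family` column and the same numeric
#'   columns, containing member rows, `Retrotransposon` / `Transposon`
#'   subtotal rows, and a `Total` row.
#' @export
summarize_superfamilies <- function(x) {
  key <- if ("superfamily" %in% names(x)) "superfamily" else "repeat_family"
  stopifnot(key %in% names(x))
  num_cols <- names(x)[vapply(x, is.numeric, logical(1))]
  stopifnot(length(num_cols) >= 1L)
  if (nrow(x)) {
    agg <- aggregate(x[num_cols], by = list(repeat_family = x[[key]]), sum)
  } else {
    agg <- data.frame(repeat_family = character())
    for (nc in num_cols) agg[[nc]] <- numeric()
  }
  gp <- function(fam) {
    vapply(num_cols, function(nc) {
      v <- agg[[nc]][agg$repeat_family == fam]
      if (length(v)) sum(v) else 0
    }, numeric(1))
  }
  row_order <- c(RETRO_ROWS, TRANSPOSON_ROWS, "rDNA", "Satellite",
                 "Unclassified")
  vals <- vapply(row_order, gp, numeric(length(num_cols)))
  if (length(num_cols) == 1L) {
    vals <- matrix(vals, nrow = 1L, dimnames = list(num_cols, row_order))
  } else {
    rownames(vals) <- num_cols
  }
  retro <- rowSums(vals[, RETRO_ROWS, drop = FALSE])
  trans <- rowSums(vals[, TRANSPOSON_ROWS, drop = FALSE])
  total <- retro + trans + vals[, "rDNA"] + vals[, "Satellite"] +
    vals[, "Unclassified"]
  out_rows <- c("Retrotransposon", RETRO_ROWS, "Transposon", TRANSPOSON_ROWS,
                "rDNA", "Satellite", "Unclassified", "Total")
  out <- data.frame(repeat_family = out_rows, stringsAsFactors = FALSE)
  for (nc in num_cols) {
    v <- c(retro[nc], vals[nc, RETRO_ROWS], trans[nc],
           vals[nc, TRANSPOSON_ROWS], vals[nc, "rDNA"], vals[nc, "Satellite"],
           vals[nc, "Unclassified"], total[nc])
    out[[nc]] <- round_half_up(v, 2)
  }
  out
}

#' Annotate reads directly against a reference library
#'
#' Masking-style per-read annotation: each read is assigned to the library
#' family of its best seeded ungapped hit passing the identity (> threshold)
#' and read-coverage (> threshold) screen, or to no family. Counts are
#' order-invariant.
#'
#' @param reads Named character vector or `DNAStringSet`.
#' @param library Reference library (named; `id#Superfamily` names supported).
#' @param config An [annotation_config()].
#' @param kmer_length Seed length for candidate detection (default 13; shorter
#'   than the similarity-graph seed because annotation tolerates 30% sequence
#'   divergence).
#' @return List with `assignments` (data.frame: `read_id`, `family`,
#'   `superfamily`, `identity`, `coverage`) and `counts` (data.frame:
#'   `family`, `n_reads`, `percent_reads` of all input reads).
#' @export
annotate_reads_by_reference <- function(reads, library,
                                        config = annotation_config(),
                                        kmer_length = 13L) {
  seqs <- as_read_chr(reads)
  libseq <- as_read_chr(library)
  stopifnot(length(libseq) >= 1L)
  fam_of <- setNames(library_family_id(names(libseq)), names(libseq))
  sf_of <- setNames(library_superfamily(names(libseq)), names(libseq))
  empty_assign <- data.frame(read_id = character(), family = character(),
                             superfamily = character(), identity = numeric(),
                             coverage = numeric(), stringsAsFactors = FALSE)
  if (length(seqs) == 0L) {
    return(list(assignments = empty_assign,
                counts = data.frame(family = character(), n_reads = integer(),
                                    percent_reads = numeric())))
  }
  cand <- seeded_candidates(seqs, libseq, kmer_length)
  best <- NULL
  if (nrow(cand)) {
    setorder(cand, query, subject, orient, -support)
    cand[, orank := seq_len(.N), by = .(query, subject)]
    cand <- cand[orank <= 3L]
    lib_raw <- raw_list(libseq)
    read_raw <- raw_list(seqs)
    rc_cache <- new.env(parent = emptyenv())
    rc_raw <- function(id) {
      if (is.null(rc_cache[[id]])) rc_cache[[id]] <- charToRaw(revcomp_chr(seqs[[id]]))
      rc_cache[[id]]
    }
    n <- nrow(cand)
    ident <- numeric(n); cov <- numeric(n)
    for (i in seq_len(n)) {
      rq <- if (cand$orient[i] == "same") read_raw[[cand$query[i]]] else
        rc_raw(cand$query[i])
      mo <- ungapped_compare(lib_raw[[cand$subject[i]]], rq, cand$offset[i])
      if (mo[2L] > 0L) {
        ident[i] <- 100 * mo[1L] / mo[2L]
        cov[i] <- 100 * mo[2L] / length(rq)
      }
    }
    cand[, `:=`(identity = ident, coverage = cov)]
    cand <- cand[identity > config$min_identity &
                 coverage > config$min_coverage]
    if (nrow(cand)) {
      setorder(cand, query, -identity, -coverage, subject)
      best <- cand[, .SD[1L], by = query]
    }
  }
  assignments <- if (!is.null(best) && nrow(best)) {
    data.frame(read_id = best$query,
               family = unname(fam_of[best$subject]),
               superfamily = unname(sf_of[best$subject]),
               identity = best$identity, coverage = best$coverage,
               stringsAsFactors = FALSE)
  } else empty_assign
  counts <- if (nrow(assignments)) {
    tab <- table(assignments$family)
    data.frame(family = names(tab), n_reads = as.integer(tab),
               percent_reads = 100 * as.integer(tab) / length(seqs),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(), n_reads = integer(),
               percent_reads = numeric(), stringsAsFactors = FALSE)
  }
  list(assignments = assignments, counts = counts)
}
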