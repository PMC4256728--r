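blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

six_frame_peptides <- function(dna) {
  s <- Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(s)
  peps <- character(6L)
  for (f in 0:2) {
    for (strand in 1:2) {
      x <- if (strand == 1L) s else rc
      n <- length(x) - f
      n <- n - n %% 3L
      peps[f * 2L + strand] <- if (n >= 3L) {
        as.character(Biostrings::translate(
          Biostrings::subseq(x, start = f + 1L, width = n),
          if.fuzzy.codon = "X"))
      } else ""
    }
  }
  peps
}

#' Select one RT-domain representative contig per family
#'
#' Each contig is translated in all six frames and locally aligned (BLOSUM62)
#' against a set of reference reverse-transcriptase peptides; the family's
#' top-scoring contig becomes its representative and the aligned peptide
#' segment is extracted as the family's RT peptide. Families whose best score
#' stays below `min_score` carry no RT signal (e.g. satellites) and are
#' dropped from the phylogeny.
#'
#' @param contigs_by_family Named list: family id -> named character vector of
#'   contigs.
#' @param rt_reference_peptides Named character vector or `AAStringSet` of
#'   reference RT peptides; must be nonempty.
#' @param min_score Minimum local alignment score (BLOSUM62, gap open 10,
#'   extend 4) to accept an RT hit (default 50).
#' @return List with `representatives` (data.frame: `family_id`, `contig_id`,
#'   `score`, `reference`), `peptides` (named character of extracted RT
#'   peptides), and `dropped` (family ids without RT signal).
#' @export
select_rt_representative <- function(contigs_by_family, rt_reference_peptides,
                                     min_score = 50) {
  refs <- rt_reference_peptides
  if (!is.character(refs)) refs <- as.character(refs)
  stopifnot(length(refs) >= 1L, !is.null(names(refs)))
  reps <- list(); peptides <- character(); dropped <- character()
  for (fam in names(contigs_by_family)) {
    ctgs <- as_read_chr(contigs_by_family[[fam]])
    best <- list(score = -Inf)
    for (cn in names(ctgs)) {
      for (pep in six_frame_peptides(ctgs[[cn]])) {
        if (nchar(pep) < 10L) next
        for (rn in names(refs)) {
          aln <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(pep), Biostrings::AAString(refs[[rn]]),
            type = "local", substitutionMatrix = blosum62,
            gapOpening = 10, gapExtension = 4)
          sc <- Biostrings::score(aln)
          if (sc > best$score) {
            best <- list(score = sc, contig = cn, reference = rn,
                         peptide = gsub("-", "",
                                        as.character(Biostrings::pattern(aln)),
                                        fixed = TRUE))
          }
        }
      }
    }
    if (is.finite(best$score) && best$score >= min_score) {
      reps[[fam]] <- data.frame(family_id = fam, contig_id = best$contig,
                                score = best$score, reference = best$reference,
                                stringsAsFactors = FALSE)
      peptides[fam] <- best$peptide
    } else {
      dropped <- c(dropped, fam)
    }
  }
  list(representatives = if (length(reps)) do.call(rbind, c(reps, list(make.row.names = FALSE)))
       else data.frame(family_id = character(), contig_id = character(),
                       score = numeric(), reference = character(),
                       stringsAsFactors = FALSE),
       peptides = peptides, dropped = dropped)
}

#' Multiple alignment of RT peptides (center-star)
#'
#' Deterministic progressive alignment: the sequence with the highest total
#' pairwise similarity to all others is the center; every other sequence is
#' globally aligned to it and the pairwise gap patterns are merged into one
#' multiple alignment.
#'
#' @param peptides Named character vector (>= 2 sequences).
#' @return Named character vector of equal-length aligned sequences (`-` for
#'   gaps).
#' @export
align_rt_peptides <- function(peptides) {
  peps <- peptides
  stopifnot(length(peps) >= 2L, !is.null(names(peps)))
  n <- length(peps)
  scores <- matrix(0, n, n)
  pair_aln <- function(i, j) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(peps[[i]]), Biostrings::AAString(peps[[j]]),
      type = "global", substitutionMatrix = blosum62,
      gapOpening = 10, gapExtension = 1)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- pair_aln(i, j)
    scores[i, j] <- scores[j, i] <- Biostrings::score(a)
  }
  center <- which.max(rowSums(scores))
  others <- setdiff(seq_len(n), center)
  c_chars <- strsplit(peps[[center]], "", fixed = TRUE)[[1]]
  nc <- length(c_chars)
  # per-alignment inserted blocks before each center residue (index 1..nc+1)
  ins <- matrix(0L, nrow = length(others), ncol = nc + 1L)
  aligned_pairs <- vector("list", length(others))
  for (k in seq_along(others)) {
    a <- pair_aln(center, others[k])
    ca <- strsplit(as.character(Biostrings::alignedPattern(a)), "",
                   fixed = TRUE)[[1]]
    oa <- strsplit(as.character(Biostrings::alignedSubject(a)), "",
                   fixed = TRUE)[[1]]
    pos <- 1L; run <- 0L
    blocks <- vector("list", nc + 1L)
    chars_at <- vector("list", nc + 1L)
    buf <- character(0)
    for (t in seq_along(ca)) {
      if (ca[t] == "-") {
        buf <- c(buf, oa[t])
      } else {
        chars_at[[pos]] <- buf
        buf <- character(0)
        blocks[[pos]] <- oa[t]
        pos <- pos + 1L
      }
    }
    chars_at[[nc + 1L]] <- buf
    ins[k, ] <- vapply(chars_at, length, integer(1))
    aligned_pairs[[k]] <- list(ins_chars = chars_at, match_chars = blocks)
  }
  master_ins <- if (length(others)) apply(ins, 2L, max) else rep(0L, nc + 1L)
  build_row <- function(ins_chars, match_chars) {
    out <- character(0)
    for (p in seq_len(nc + 1L)) {
      blk <- ins_chars[[p]]
      out <- c(out, blk, rep("-", master_ins[p] - length(blk)))
      if (p <= nc) out <- c(out, match_chars[[p]])
    }
    paste(out, collapse = "")
  }
  res <- character(n)
  names(res) <- names(peps)
  # center row: no insertions of its own
  center_ins <- rep(list(character(0)), nc + 1L)
  res[center] <- build_row(center_ins, as.list(c_chars))
  for (k in seq_along(others)) {
    res[others[k]] <- build_row(aligned_pairs[[k]]$ins_chars,
                                aligned_pairs[[k]]$match_chars)
  }
  res
}

#' Pairwise p-distances on a multiple alignment
#'
#' For each pair, the proportion of alignment columns where both sequences
#' carry a residue and the residues differ; columns with a gap in either
#' member of the pair are excluded pairwise.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a character matrix (rows = taxa).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distances <- function(alignment) {
  m <- if (is.matrix(alignment)) alignment else {
    stopifnot(length(unique(nchar(alignment))) == 1L)
    do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  }
  if (!is.matrix(alignment)) rownames(m) <- names(alignment)
  n <- nrow(m)
  stopifnot(n >= 3L)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) {
      stop(sprintf("no comparable columns between %s and %s",
                   rownames(m)[i], rownames(m)[j]))
    }
    d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
  }
  d
}

#' Neighbor-joining tree
#'
#' Classical neighbor joining (Saitou-Nei Q criterion with the standard
#' branch-length formulas), deterministic: ties on the Q criterion are broken
#' by the lexicographically smallest pair of subtree labels (each subtree
#' labeled by its smallest leaf). Negative branch lengths are clamped to
#' zero. On an additive distance matrix the generating topology and exact
#' branch lengths are recovered.
#'
#' @param dm Symmetric numeric matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `phylo` object (ape).
#' @export
build_nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 3L,
            !is.null(rownames(dm)), identical(rownames(dm), colnames(dm)))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  labs <- rownames(dm)        # tie-break label = smallest leaf in subtree
  frag <- labs                # newick fragment per active node
  D <- dm
  clamp <- function(x) pmax(x, 0)
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(labs[ij[1]], labs[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newlab <- min(labs[i], labs[j])
    dk <- clamp((D[i, ] + D[j, ] - D[i, j]) / 2)
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labs <- c(labs[keep], newlab)
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- labs
    D <- D2
  }
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  ape::read.tree(text = nwk)
}

#' Bootstrap support for the NJ tree
#'
#' Resamples alignment columns with replacement `n_replicates` times, builds
#' an NJ tree per replicate, and labels each internal edge of the
#' point-estimate tree with the percentage of replicates containing its
#' bipartition.
#'
#' @param alignment Named character vector of aligned sequences (or character
#'   matrix); at least 10 columns.
#' @param n_replicates Bootstrap replicates (default 100); 0 returns the
#'   point tree without supports.
#' @param seed Integer seed for column resampling.
#' @return A `phylo` object; `node.label` holds supports in percent on
#'   internal nodes (`NA` on the root).
#' @export
bootstrap_support <- function(alignment, n_replicates = 100L, seed = 1L) {
  m <- if (is.matrix(alignment)) alignment else {
    stopifnot(length(unique(nchar(alignment))) == 1L)
    do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  }
  if (!is.matrix(alignment)) rownames(m) <- names(alignment)
  stopifnot(ncol(m) >= 10L)
  point <- build_nj_tree(pairwise_distances(m))
  if (n_replicates == 0L) return(point)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      build_nj_tree(pairwise_distances(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- n_replicates
  point$node.label <- round(100 * counts / n_replicates)
  point
}

#' Assign families to clades by nearest reference leaf
#'
#' @param tree A `phylo` containing both family and reference leaves.
#' @param reference_clades Named character vector: reference leaf -> clade.
#' @return Named character vector: family leaf -> clade of its nearest
#'   reference leaf (patristic distance).
#' @export
assign_clades <- function(tree, reference_clades) {
  stopifnot(inherits(tree, "phylo"), length(reference_clades) >= 1L)
  refs <- intersect(names(reference_clades), tree$tip.label)
  stopifnot(length(refs) >= 1L)
  fams <- setdiff(tree$tip.label, refs)
  cd <- ape::cophenetic.phylo(tree)
  vapply(fams, function(f) {
    reference_clades[[refs[which.min(cd[f, refs])]]]
  }, character(1))
}
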