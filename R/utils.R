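#' @import methods
#' @importFrom stats rbinom rnorm runif setNames aggregate
#' @importFrom utils adist head tail write.table
#' @importFrom data.table data.table setkey setkeyv as.data.table := .N .SD rbindlist setorder
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero (printed tables use commercial rounding, not
# banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna_chr <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases; used for synthetic repeat templates, satellite
#' monomers, and single-copy background.
#'
#' @param n Sequence length in bp.
#' @return A character scalar over `A`,`C`,`G`,`T`.
#' @export
random_dna <- function(n) {
  stopifnot(n >= 0)
  if (n == 0) return("")
  random_dna_chr(n)
}

# Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at per-base probability `p`, always to a different base.
mutate_seq_chr <- function(x, p) {
  if (p <= 0) return(x)
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < p)
  if (length(hit)) {
    b[hit] <- vapply(b[hit], function(cur) sample(setdiff(DNA_BASES, cur), 1L),
                     character(1))
  }
  paste(b, collapse = "")
}

#' Build a tandem array from a monomer
#'
#' Concatenates `n_copies` head-to-tail copies of `monomer`, each copy mutated
#' independently by substitutions at per-base probability `divergence`.
#'
#' @param monomer Character scalar, the repeating unit.
#' @param n_copies Number of head-to-tail copies (>= 1).
#' @param divergence Per-base substitution probability per copy.
#' @return A character scalar of length `n_copies * nchar(monomer)`.
#' @export
tandem_array <- function(monomer, n_copies, divergence = 0) {
  stopifnot(nchar(monomer) >= 1, n_copies >= 1)
  paste(vapply(seq_len(n_copies), function(i) mutate_seq_chr(monomer, divergence),
               character(1)), collapse = "")
}

# Normalize reads input (DNAStringSet / QualityScaledDNAStringSet / character)
# to a named character vector of sequences.
as_read_chr <- function(reads) {
  if (is.character(reads)) {
    x <- reads
  } else {
    x <- as.character(reads)
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("reads must be named with unique read ids")
  }
  if (anyDuplicated(names(x))) stop("duplicate read ids in input")
  x
}

# All k-mers of each sequence as a data.table:
#   id, pos (1-based start), kmer, canon (canonical k-mer), cstrand
# cstrand == "+" when the forward k-mer is the canonical one.
kmer_table <- function(seqs, k) {
  ids <- names(seqs)
  lens <- nchar(seqs)
  keep <- lens >= k
  if (!any(keep)) {
    return(data.table(id = character(), pos = integer(),
                      kmer = character(), canon = character(),
                      cstrand = character()))
  }
  seqs <- seqs[keep]; ids <- ids[keep]; lens <- lens[keep]
  nk <- lens - k + 1L
  id_col <- rep(ids, nk)
  pos_col <- unlist(lapply(nk, seq_len), use.names = FALSE)
  starts <- pos_col
  kmers <- substring(rep(seqs, nk), starts, starts + k - 1L)
  rc <- revcomp_chr(unique(kmers))
  names(rc) <- unique(kmers)
  rck <- rc[kmers]
  canon <- ifelse(kmers <= rck, kmers, rck)
  cstrand <- ifelse(kmers <= rck, "+", "-")
  dt <- data.table(id = id_col, pos = pos_col, kmer = kmers,
                   canon = canon, cstrand = cstrand)
  dt[!grepl("N", kmer, fixed = TRUE)]
}

# Raw-byte views of sequences for fast ungapped comparison.
raw_list <- function(seqs) lapply(seqs, charToRaw)

# Ungapped identity of b against a when b (possibly reverse-complemented)
# is shifted so that b position 1 sits at a position (offset + 1).
# Returns c(matches, overlap).
ungapped_compare <- function(ra, rb, offset) {
  la <- length(ra); lb <- length(rb)
  a_start <- max(1L, offset + 1L)
  a_end <- min(la, offset + lb)
  if (a_end < a_start) return(c(0L, 0L))
  b_start <- a_start - offset
  b_end <- a_end - offset
  seg_a <- ra[a_start:a_end]
  seg_b <- rb[b_start:b_end]
  c(sum(seg_a == seg_b), a_end - a_start + 1L)
}

# Seeded candidate hits of query sequences against subject sequences.
# Returns data.table(query, subject, orient, offset, support): the oriented
# query (forward when orient == "same", revcomp'd otherwise) starts at
# subject-forward position offset + 1; support = seed k-mers agreeing on that
# offset.
seeded_candidates <- function(qseqs, sseqs, k) {
  qt <- kmer_table(qseqs, k)
  st <- kmer_table(sseqs, k)
  empty <- data.table(query = character(), subject = character(),
                      orient = character(), offset = integer(),
                      support = integer())
  if (nrow(qt) == 0L || nrow(st) == 0L) return(empty)
  setkey(st, canon)
  j <- st[qt, on = "canon", allow.cartesian = TRUE, nomatch = NULL]
  # x side (id, pos, cstrand) = subject; i side = query
  if (nrow(j) == 0L) return(empty)
  qlen <- setNames(nchar(qseqs), names(qseqs))
  same <- j$cstrand == j$i.cstrand
  pos_q <- ifelse(same, j$i.pos, qlen[j$i.id] - j$i.pos - k + 2L)
  dt <- data.table(query = j$i.id, subject = j$id,
                   orient = ifelse(same, "same", "diff"),
                   offset = as.integer(j$pos - pos_q))
  dt[, .(support = .N), by = .(query, subject, orient, offset)]
}

# Write a data.frame as a TSV whose header line starts with '#'.
write_tsv_hash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
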