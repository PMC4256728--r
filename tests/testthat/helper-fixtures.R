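# Shared fixture builders; everything is generated in code at test time.

qreads <- function(x, qual_char = "I") {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(x),
    Biostrings::PhredQuality(strrep(qual_char, nchar(x))))
}

revcomp1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Union-find over an edge list: independent oracle for graph partitioning.
uf_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$read_a[i]); rb <- find(edges$read_b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  vapply(ids, find, character(1))
}

# Tiling reads of a template: start positions every `step` bp.
tiling_reads <- function(template, read_len = 100L, step = 50L,
                         prefix = "t") {
  L <- nchar(template)
  starts <- seq(1L, L - read_len + 1L, by = step)
  if (starts[length(starts)] != L - read_len + 1L) {
    starts <- c(starts, L - read_len + 1L)
  }
  setNames(substring(template, starts, starts + read_len - 1L),
           sprintf("%s%03d", prefix, seq_along(starts)))
}

# Reads sampled uniformly from a sequence with substitutions, both strands.
sample_reads <- function(seqs, n, read_len = 100L, divergence = 0,
                         prefix = "r", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  template <- if (length(seqs) == 1L) rep(seqs, n) else
    sample(seqs, n, replace = TRUE)
  out <- vapply(template, function(s) {
    st <- sample.int(nchar(s) - read_len + 1L, 1L)
    r <- substr(s, st, st + read_len - 1L)
    if (divergence > 0) {
      b <- strsplit(r, "")[[1]]
      hit <- which(runif(read_len) < divergence)
      if (length(hit)) {
        b[hit] <- vapply(b[hit], function(cur)
          sample(setdiff(c("A", "C", "G", "T"), cur), 1L), character(1))
      }
      r <- paste(b, collapse = "")
    }
    if (runif(1) < 0.5) r <- revcomp1(r)
    r
  }, character(1), USE.NAMES = FALSE)
  setNames(out, sprintf("%s%04d", prefix, seq_len(n)))
}

# Split simulated mates into a single named read vector with /1 /2 suffixes.
pool_mates <- function(sim) {
  r1 <- as.character(sim$r1); r2 <- as.character(sim$r2)
  names(r1) <- paste0(names(r1), "/1")
  names(r2) <- paste0(names(r2), "/2")
  c(r1, r2)
}

# Truth family label per pooled read id.
pooled_truth_labels <- function(sim) {
  setNames(sim$truth$family, paste0(sim$truth$read_id, "/", sim$truth$mate))
}

# A genomic window covering a run of consecutive full-length (non-variant)
# monomer copies of a satellite family, for profiling the canonical monomer.
clean_satellite_window <- function(g, family_id, n_units = 25) {
  tr <- g$truth[g$truth$family_id == family_id, ]
  tr <- tr[order(tr$start), ]
  r <- rle(tr$is_variant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(!r$values & r$lengths >= n_units)
  stopifnot(length(ok) >= 1)
  i <- ok[which.max(r$lengths[ok])]
  first <- starts[i]; last <- min(ends[i], starts[i] + n_units - 1)
  substr(g$sequence, tr$start[first] + 1, tr$end[last])
}

# Majority truth label of a cluster.
cluster_truth_label <- function(clustering, cluster_id, labels) {
  mem <- cluster_members(clustering, cluster_id)
  names(sort(table(labels[mem]), decreasing = TRUE))[1]
}
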