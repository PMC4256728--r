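min_rotation <- function(s) {
  p <- nchar(s)
  rots <- substring(strrep(s, 2L), seq_len(p), seq_len(p) + p - 1L)
  min(rots)
}

# Canonical monomer: lexicographically minimal rotation of the
# lexicographically smaller strand. Rotation- and strand-invariant.
canonical_monomer <- function(s) {
  min(min_rotation(s), min_rotation(revcomp_chr(s)))
}

# Evaluate one candidate period: chop the contig into consecutive windows of
# length p, call a majority consensus, and measure how much of the contig the
# consensus explains at >= min_identity per window. A partial final window
# (>= 20 bp) counts toward coverage, so arrays of at least 1.5 units are
# detectable — assembled satellite contigs are often only slightly longer
# than one monomer.
evaluate_period <- function(chars, p, min_identity) {
  L <- length(chars)
  nwin <- L %/% p
  if (nwin < 1L || L < 1.5 * p) return(NULL)
  m <- matrix(chars[seq_len(nwin * p)], nrow = p)
  cons <- apply(m, 1L, function(r) {
    tb <- tabulate(match(r, DNA_BASES), 4L)
    DNA_BASES[which.max(tb)]
  })
  win_ident <- colMeans(m == cons)
  covered <- p * sum(win_ident >= min_identity)
  rem <- L - nwin * p
  if (rem >= 20L) {
    part <- chars[(nwin * p + 1L):L]
    if (mean(part == cons[seq_len(rem)]) >= min_identity) {
      covered <- covered + rem
    }
  }
  list(period = p, consensus = paste(cons, collapse = ""),
       covered = covered, mean_identity = mean(win_ident),
       n_units = nwin + rem / p)
}

#' Detect the tandem monomer of a contig
#'
#' Candidate periods come from the recurrence-distance histogram of repeated
#' 12-mers (distances between successive occurrences of the same k-mer),
#' supplemented by a direct scan of small periods below 24 bp. Candidates are
#' tested in ascending order; the smallest period whose majority-vote
#' consensus explains at least `min_coverage` of the contig at window identity
#' `min_identity` or better is reported, which makes the result minimal (never
#' a multiple of the true unit). The consensus is returned in canonical form:
#' the lexicographically minimal rotation of the lexicographically smaller
#' strand.
#'
#' @param contig Character scalar (or `DNAString`).
#' @param kmer_length Recurrence seed length (default 12).
#' @param min_identity Minimum per-window identity to the consensus (default
#'   0.8).
#' @param min_coverage Minimum fraction of contig bases explained (default
#'   0.8).
#' @return `NULL` when no period qualifies; otherwise a list of class
#'   `satellite_profile`: `period`, `consensus_monomer` (canonical),
#'   `array_span` (bases explained), `n_units`, `mean_identity`.
#' @export
find_satellite_monomer <- function(contig, kmer_length = 12L,
                                   min_identity = 0.8, min_coverage = 0.8) {
  contig <- as.character(contig)[[1L]]
  L <- nchar(contig)
  if (L < 4L) return(NULL)
  chars <- strsplit(contig, "", fixed = TRUE)[[1]]
  half <- L %/% 2L
  small <- seq.int(2L, min(23L, half))
  rec <- integer(0)
  if (L >= kmer_length + 2L) {
    starts <- seq_len(L - kmer_length + 1L)
    kmers <- substring(contig, starts, starts + kmer_length - 1L)
    sp <- split(starts, kmers)
    d <- unlist(lapply(sp[lengths(sp) > 1L], function(x) diff(sort(x))),
                use.names = FALSE)
    d <- d[d >= 2L & d <= floor(L / 1.5)]
    if (length(d)) {
      tab <- sort(table(d), decreasing = TRUE)
      keep <- tab[tab >= max(3L, 0.2 * tab[1L])]
      rec <- as.integer(names(keep))
      if (length(rec) > 10L) rec <- rec[seq_len(10L)]
    }
  }
  cands <- sort(unique(c(small, rec)))
  for (p in cands) {
    ev <- evaluate_period(chars, p, min_identity)
    if (is.null(ev)) next
    if (ev$covered >= min_coverage * L) {
      return(structure(list(period = ev$period,
                            consensus_monomer = canonical_monomer(ev$consensus),
                            array_span = ev$covered, n_units = ev$n_units,
                            mean_identity = ev$mean_identity),
                       class = "satellite_profile"))
    }
  }
  NULL
}

# Map read k-mers onto the (circular) consensus and summarize, per read and
# orientation, the support for each offset class (cpos - pos) mod period.
read_offset_runs <- function(reads, consensus, kmer_length) {
  P <- nchar(consensus)
  cons2 <- paste0(consensus, consensus)
  cstarts <- seq_len(P)
  ckmers <- substring(cons2, cstarts, cstarts + kmer_length - 1L)
  cmap <- data.table(kmer = ckmers, cpos = cstarts)
  fwd <- reads
  rev <- revcomp_chr(reads)
  names(rev) <- names(reads)
  mk <- function(seqs, orient) {
    lens <- nchar(seqs)
    nk <- pmax(lens - kmer_length + 1L, 0L)
    ids <- rep(names(seqs), nk)
    pos <- unlist(lapply(nk, seq_len), use.names = FALSE)
    data.table(id = ids, pos = pos, orient = orient,
               kmer = substring(rep(seqs, nk), pos, pos + kmer_length - 1L))
  }
  dt <- rbindlist(list(mk(fwd, "+"), mk(rev, "-")))
  dt <- cmap[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(dt) == 0L) return(dt)
  dt[, offset := (cpos - pos) %% P]
  # keep the better-matching orientation per read
  osc <- dt[, .N, by = .(id, orient)]
  setorder(osc, id, -N)
  pick <- osc[, .SD[1L], by = id][, .(id, orient)]
  dt[pick, on = c("id", "orient")]
}

# Reads whose k-mer anchors split into two cleanly separated offset runs on
# the circular consensus: the signature of a read spanning an internal
# deletion junction. Returns data.table(id, off1, off2, d, junction) where d
# is the deleted length and junction the read position of the last base
# before the jump, filtered to junctions at least `flank` from both ends.
variant_junction_reads <- function(reads, profile, flank = 20L,
                                   kmer_length = 12L, min_run_kmers = 3L) {
  P <- profile$period
  empty <- data.table(id = character(), off1 = integer(), off2 = integer(),
                      d = integer(), junction = integer())
  dt <- read_offset_runs(reads, profile$consensus_monomer, kmer_length)
  if (nrow(dt) == 0L) return(empty)
  runs <- dt[, .(n = .N, minp = min(pos), maxp = max(pos)),
             by = .(id, offset)]
  runs <- runs[n >= min_run_kmers]
  L <- as.integer(names(sort(table(nchar(reads)), decreasing = TRUE))[1L])
  env_P <- P
  two <- runs[, if (.N >= 2L) {
    o <- order(-n)[1:2]
    s <- .SD[o][order(minp)]
    # runs must not interleave along the read (boundary ambiguity can let the
    # right-hand run start up to a few bases before the left run's last
    # anchor ends, so compare k-mer start positions)
    if (s$maxp[1L] < s$minp[2L]) {
      jun <- s$minp[2L] - 1L            # last base before the right run
      list(off1 = s$offset[1L], off2 = s$offset[2L],
           d = (s$offset[2L] - s$offset[1L]) %% env_P, junction = jun)
    }
  }, by = id]
  if (nrow(two) == 0L) return(empty)
  two[d > 0L & d < env_P & junction >= flank & junction <= L - flank]
}

#' Detect internally deleted monomer variants
#'
#' Reads assigned to a satellite family are mapped onto the consensus monomer
#' by exact k-mer anchors on the circular consensus. A read from a full-length
#' array shows one consistent offset; a read spanning a variant junction (a
#' monomer with a contiguous internal deletion) splits into two offset runs
#' whose circular difference equals the deleted length. A variant is reported
#' when the same deletion length is supported by at least `min_support` reads
#' whose junction lies at least `flank` bases from both read ends.
#'
#' The family fraction converts the junction-read rate into a copy fraction:
#' `family_fraction = 100 * (S / R) * period / (L - 2*flank + 1)`, where `S`
#' is the number of variant-supporting reads among `R` family reads of length
#' `L` (each variant copy exposes `L - 2*flank + 1` read start positions,
#' while a full monomer attracts reads in proportion to `period`). The raw
#' supporting-read percentage is also reported as `read_share`.
#'
#' @param profile A `satellite_profile` from [find_satellite_monomer()].
#' @param family_reads Reads assigned to the family (named character or
#'   `DNAStringSet`); must be nonempty.
#' @param min_support Minimum supporting reads per variant (default 5).
#' @param flank Minimum distance of the junction from either read end
#'   (default 20 bp).
#' @param kmer_length Anchor k-mer length (default 12).
#' @param min_run_kmers Minimum anchor k-mers per offset run (default 3).
#' @return A data.frame, one row per variant: `variant_length`, `n_support`,
#'   `family_fraction` (percent of monomer copies), `read_share` (percent of
#'   family reads), `del_start` (1-based position in the canonical consensus),
#'   `deleted_segment`. Zero rows when all reads match the full consensus.
#' @export
detect_monomer_variants <- function(profile, family_reads, min_support = 5L,
                                    flank = 20L, kmer_length = 12L,
                                    min_run_kmers = 3L) {
  stopifnot(inherits(profile, "satellite_profile"))
  if (length(family_reads) == 0L) stop("family_reads is empty")
  reads <- as_read_chr(family_reads)
  P <- profile$period
  cons <- profile$consensus_monomer
  empty <- data.frame(variant_length = integer(), n_support = integer(),
                      family_fraction = numeric(), read_share = numeric(),
                      del_start = integer(), deleted_segment = character(),
                      stringsAsFactors = FALSE)
  two <- variant_junction_reads(reads, profile, flank, kmer_length,
                                min_run_kmers)
  if (nrow(two) == 0L) return(empty)
  L <- as.integer(names(sort(table(nchar(reads)), decreasing = TRUE))[1L])
  env_P <- P
  out <- two[, .(n_support = .N,
                 del_start = {
                   ds <- ((off1 + junction) %% env_P) + 1L
                   as.integer(names(sort(table(ds), decreasing = TRUE))[1L])
                 }),
             by = d]
  out <- out[n_support >= min_support]
  if (nrow(out) == 0L) return(empty)
  R <- length(reads)
  cons2 <- paste0(cons, cons)
  res <- data.frame(
    variant_length = P - out$d,
    n_support = out$n_support,
    family_fraction = 100 * (out$n_support / R) * P / (L - 2L * flank + 1L),
    read_share = 100 * out$n_support / R,
    del_start = out$del_start,
    deleted_segment = substring(cons2, out$del_start,
                                out$del_start + out$d - 1L),
    stringsAsFactors = FALSE)
  res[order(-res$n_support), , drop = FALSE]
}

#' Ranked satellite table
#'
#' Ranks satellite families by genome proportion per species and reports each
#' family's monomer length, mirroring the layout of published satellite
#' summaries. Species lacking a family show an em dash.
#'
#' @param profiles Data.frame with `cluster_id` and `period` (one row per
#'   satellite family), optionally a `location` column.
#' @param gp_table Data.frame with `cluster_id`, `species_code`, and
#'   `genome_proportion` (percent).
#' @return A data.frame with one row per satellite: `cluster_id`,
#'   `length_bp`, and per species `rank_<code>` and `gp_<code>` columns
#'   (character; `"—"` when absent).
#' @export
satellite_table <- function(profiles, gp_table) {
  stopifnot(all(c("cluster_id", "period") %in% names(profiles)),
            all(c("cluster_id", "species_code", "genome_proportion") %in%
                  names(gp_table)))
  gp_table <- gp_table[gp_table$cluster_id %in% profiles$cluster_id, ,
                       drop = FALSE]
  out <- data.frame(cluster_id = profiles$cluster_id,
                    length_bp = profiles$period,
                    stringsAsFactors = FALSE)
  if ("location" %in% names(profiles)) out$location <- profiles$location
  dash <- "—"
  for (sc in sort(unique(gp_table$species_code))) {
    sub <- gp_table[gp_table$species_code == sc &
                    gp_table$genome_proportion > 0, , drop = FALSE]
    sub <- sub[order(-sub$genome_proportion), , drop = FALSE]
    rk <- setNames(seq_len(nrow(sub)), sub$cluster_id)
    gp <- setNames(sub$genome_proportion, sub$cluster_id)
    out[[paste0("rank_", sc)]] <-
      ifelse(out$cluster_id %in% names(rk),
             as.character(rk[out$cluster_id]), dash)
    out[[paste0("gp_", sc)]] <-
      ifelse(out$cluster_id %in% names(gp),
             sprintf("%.2f", gp[out$cluster_id]), dash)
  }
  ord <- order(out$length_bp * 0 - vapply(out$cluster_id, function(cl) {
    max(c(0, gp_table$genome_proportion[gp_table$cluster_id == cl]))
  }, numeric(1)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
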