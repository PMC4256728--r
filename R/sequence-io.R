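#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip-transparent).
#' @return A [Biostrings::QualityScaledDNAStringSet-class].
#' @export
read_fastq <- function(path) {
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns.*dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Write reads to FASTQ
#'
#' Sanger Phred+33 encoding; byte-identical output for identical input.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet-class] (or
#'   `DNAStringSet`, written with constant quality `I`).
#' @param path Output file; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    reads <- Biostrings::QualityScaledDNAStringSet(
      reads, Biostrings::PhredQuality(strrep("I", Biostrings::width(reads))))
  }
  Biostrings::writeQualityScaledXStringSet(reads, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

mean_phred <- function(reads) {
  if (length(reads) == 0L) return(numeric())
  q <- methods::as(Biostrings::quality(reads), "IntegerList")
  vapply(q, mean, numeric(1))
}

n_fraction <- function(reads) {
  if (length(reads) == 0L) return(numeric())
  as.numeric(Biostrings::letterFrequency(
    methods::as(reads, "DNAStringSet"), "N")) / Biostrings::width(reads)
}

#' Quality-filter paired reads
#'
#' A read fails when its mean Phred quality is below `min_mean_quality` or
#' more than `max_n_fraction` of its bases are `N`. When either mate of a pair
#' fails, both mates are discarded, so the output contains no orphans.
#'
#' @param r1,r2 Synchronized mate sets
#'   ([Biostrings::QualityScaledDNAStringSet-class]) with identical names in
#'   identical order.
#' @param min_mean_quality Mean-Phred cutoff (default 20).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases (default 0.1).
#' @return A list with filtered `r1`, `r2`, `n_discarded_pairs`, and
#'   `discarded_ids`.
#' @export
preprocess_reads <- function(r1, r2, min_mean_quality = 20,
                             max_n_fraction = 0.1) {
  if (length(r1) != length(r2)) {
    stop("mate files are desynchronized: unequal read counts")
  }
  if (length(r1) && any(names(r1) != names(r2))) {
    bad <- which(names(r1) != names(r2))[1L]
    stop(sprintf("mate files are desynchronized at read '%s' (mate 2: '%s')",
                 names(r1)[bad], names(r2)[bad]))
  }
  fail <- function(x) mean_phred(x) < min_mean_quality |
    n_fraction(x) > max_n_fraction
  drop <- if (length(r1)) fail(r1) | fail(r2) else logical()
  list(r1 = r1[!drop], r2 = r2[!drop],
       n_discarded_pairs = sum(drop),
       discarded_ids = names(r1)[drop])
}

#' Build a combined multi-species read dataset
#'
#' Subsamples each species' reads without replacement to fixed per-species
#' quotas (equal split of `n_total` by default) and labels every record with
#' its species code as a `CODE|` read-id prefix, mirroring sample-coded
#' combined datasets used for cross-species clustering.
#'
#' @param datasets Named list (names = species codes) of `DNAStringSet` /
#'   `QualityScaledDNAStringSet` / named character vectors.
#' @param n_total Total reads in the combined output.
#' @param seed Integer seed; output is deterministic.
#' @param quotas Optional named integer vector of per-species read counts
#'   (must sum to `n_total`).
#' @return A named character vector of sequences; names are `CODE|read_id`.
#' @export
subsample_combined <- function(datasets, n_total, seed = 1L, quotas = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)), all(names(datasets) != ""))
  codes <- names(datasets)
  sets <- lapply(datasets, as_read_chr)
  avail <- vapply(sets, length, integer(1))
  if (is.null(quotas)) {
    base <- n_total %/% length(codes)
    quotas <- setNames(rep(base, length(codes)), codes)
    extra <- n_total - sum(quotas)
    if (extra > 0L) quotas[seq_len(extra)] <- quotas[seq_len(extra)] + 1L
  } else {
    stopifnot(setequal(names(quotas), codes), sum(quotas) == n_total)
    quotas <- quotas[codes]
  }
  short <- quotas > avail
  if (any(short)) {
    stop(sprintf("requested %d reads for species %s but only %d available",
                 quotas[short][1L], codes[short][1L], avail[short][1L]))
  }
  with_seed(seed, {
    out <- lapply(codes, function(sc) {
      x <- sets[[sc]]
      take <- if (quotas[sc] == length(x)) seq_along(x)
              else sort(sample.int(length(x), quotas[sc]))
      sel <- x[take]
      names(sel) <- paste0(sc, "|", names(sel))
      sel
    })
    unlist(out)
  })
}

# Split "CODE|id" names back into species codes.
species_codes_of <- function(read_ids) {
  sub("\\|.*$", "", read_ids)
}

#' Sequencing and coverage statistics
#'
#' Total read length in Mb is `n_reads * read_length / 1e6`; genome coverage
#' is total read length over twice the genome size (the convention under which
#' printed read counts, genome sizes, and coverages of low-coverage plant
#' surveys are mutually consistent). Displayed values are rounded half-up to
#' two decimals.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in bp.
#' @param genome_size_mb Genome size in Mb.
#' @return A one-row data.frame: `n_reads`, `read_length`,
#'   `total_read_length_mb`, `genome_size_mb`, `coverage`.
#' @export
compute_sequencing_stats <- function(n_reads, read_length, genome_size_mb) {
  stopifnot(n_reads > 0, read_length > 0, genome_size_mb > 0)
  total_mb <- n_reads * read_length / 1e6
  coverage <- total_mb / (2 * genome_size_mb)
  data.frame(n_reads = n_reads, read_length = read_length,
             total_read_length_mb = round_half_up(total_mb, 2),
             genome_size_mb = genome_size_mb,
             coverage = round_half_up(coverage, 2))
}
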