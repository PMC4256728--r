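#' Specify a synthetic repeat family
#'
#' Describes one repeat family to be planted in a simulated genome: a dispersed
#' element (LTR-like, DNA transposon, rDNA) amplified as mutated copies of a
#' random template, or a satellite laid down as a head-to-tail tandem array of
#' a monomer, optionally carrying an internally deleted monomer length variant
#' at a controlled fraction of copies.
#'
#' @param family_id Unique family label.
#' @param kind One of `"LTR_copia"`, `"LTR_gypsy"`, `"DNA_transposon"`,
#'   `"satellite"`, `"rDNA"`.
#' @param target_gp Target genome proportion in `[0, 1)` (fraction of genome
#'   occupied by the family).
#' @param template_length Template length in bp (dispersed families).
#' @param monomer_length Monomer length in bp (satellites only).
#' @param variant_monomer_length Length of an internally deleted monomer
#'   variant, or `NULL` for none. Must be shorter than `monomer_length`.
#' @param variant_fraction Fraction of monomer copies carrying the variant
#'   (deterministic bookkeeping, rounded to a whole number of copies).
#' @param divergence Per-base substitution probability applied independently to
#'   each copy (no indels; copies stay length-true to the template).
#' @param template Optional fixed template (dispersed families) or monomer
#'   (satellites) sequence; random when `NULL`. Fixing it lets the same family
#'   be planted in several genomes (shared families).
#' @return An object of class `repeat_family_spec`.
#' @export
repeat_family_spec <- function(family_id, kind, target_gp,
                               template_length = 1000L,
                               monomer_length = NULL,
                               variant_monomer_length = NULL,
                               variant_fraction = 0,
                               divergence = 0.02,
                               template = NULL) {
  kinds <- c("LTR_copia", "LTR_gypsy", "DNA_transposon", "satellite", "rDNA")
  stopifnot(is.character(family_id), length(family_id) == 1L)
  kind <- match.arg(kind, kinds)
  stopifnot(target_gp >= 0, target_gp < 1, divergence >= 0, divergence < 1)
  if (kind == "satellite") {
    stopifnot(!is.null(monomer_length), monomer_length >= 2)
    if (!is.null(variant_monomer_length)) {
      stopifnot(variant_monomer_length >= 1,
                variant_monomer_length < monomer_length,
                variant_fraction > 0, variant_fraction < 1)
    } else if (variant_fraction != 0) {
      stop("variant_fraction must be 0 when no variant monomer is specified")
    }
  } else {
    stopifnot(template_length >= 1)
    if (!is.null(variant_monomer_length) || variant_fraction != 0) {
      stop("monomer variants only apply to satellite families")
    }
  }
  if (!is.null(template)) {
    template <- toupper(as.character(template)[[1L]])
    if (kind == "satellite") monomer_length <- nchar(template)
    else template_length <- nchar(template)
  }
  structure(list(family_id = family_id, kind = kind, target_gp = target_gp,
                 template = template,
                 template_length = as.integer(template_length),
                 monomer_length = if (is.null(monomer_length)) NULL else as.integer(monomer_length),
                 variant_monomer_length = if (is.null(variant_monomer_length)) NULL else as.integer(variant_monomer_length),
                 variant_fraction = variant_fraction,
                 divergence = divergence),
            class = "repeat_family_spec")
}

#' Specify a synthetic genome
#'
#' @param species_code Short species label (carried into combined datasets).
#' @param genome_size Genome length in bp.
#' @param families List of [repeat_family_spec()] objects. Their `target_gp`
#'   must sum to less than 1.
#' @param seed Integer seed; the genome is fully deterministic given the spec.
#' @param min_spacer Minimum background gap in bp between planted blocks
#'   (default 200). Dispersed element copies are flanked by unique sequence;
#'   without a spacer, reads spanning the junction of two abutting copies
#'   from different families would chain their clusters together. Reduced
#'   automatically when the background is too small.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(species_code, genome_size, families = list(), seed = 1L,
                        min_spacer = 200L) {
  stopifnot(is.character(species_code), length(species_code) == 1L,
            genome_size >= 1)
  if (length(families)) {
    stopifnot(all(vapply(families, inherits, logical(1), "repeat_family_spec")))
    ids <- vapply(families, `[[`, character(1), "family_id")
    if (anyDuplicated(ids)) stop("duplicate family_id in genome spec")
    if (sum(vapply(families, `[[`, numeric(1), "target_gp")) >= 1) {
      stop("target_gp over families must sum to < 1")
    }
  }
  structure(list(species_code = species_code,
                 genome_size = as.integer(genome_size),
                 families = families, seed = as.integer(seed),
                 min_spacer = as.integer(min_spacer)),
            class = "genome_spec")
}

#' Specify a read simulation
#'
#' Defaults emulate 100 bp paired-end short-read sequencing with a narrow
#' insert-size distribution and a small per-base substitution error rate.
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Insert (fragment) size distribution in bp.
#' @param error_rate Per-base substitution error probability.
#' @param chip_target_family Family id enriched in ChIP simulations, or `NULL`.
#' @param chip_enrichment_fold Sampling density over the target family relative
#'   to background (>= 1).
#' @param seed Integer seed.
#' @return An object of class `read_sim_spec`.
#' @export
read_sim_spec <- function(n_pairs, read_length = 100L, insert_mean = 300,
                          insert_sd = 30, error_rate = 0.001,
                          chip_target_family = NULL,
                          chip_enrichment_fold = 1, seed = 1L) {
  stopifnot(n_pairs >= 0, read_length >= 1, read_length <= insert_mean,
            error_rate >= 0, error_rate < 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate,
                 chip_target_family = chip_target_family,
                 chip_enrichment_fold = chip_enrichment_fold,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

empty_truth <- function() {
  data.frame(family_id = character(), kind = character(), start = integer(),
             end = integer(), copy_index = integer(), is_variant = logical(),
             stringsAsFactors = FALSE)
}

#' Simulate a genome with planted repeat families
#'
#' Dispersed families are planted as independently mutated copies of a random
#' template; satellites as one contiguous head-to-tail tandem array with
#' variant monomers (a fixed contiguous deletion of the full monomer)
#' interspersed at the requested fraction of copies. Copy counts are exact
#' bookkeeping (`round(target_gp * genome_size / unit_length)`), so the
#' realized genome proportion of every family is within rounding of its
#' target. The remaining sequence is i.i.d. uniform background.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `sim_genome`: a list with `sequence` (character
#'   scalar), `truth` (data.frame with 0-based half-open `start`/`end` per
#'   planted copy, plus `family_id`, `kind`, `copy_index`, `is_variant`),
#'   `realized_gp` (named fractions), `templates` (named character; satellite
#'   entries hold the monomer), `variant_info`, `species_code`, `genome_size`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  G <- spec$genome_size
  with_seed(spec$seed, {
    blocks <- list()     # each: list(seq, rows = truth rows)
    templates <- character()
    variant_info <- list()
    for (fam in spec$families) {
      if (fam$kind == "satellite") {
        P <- fam$monomer_length
        monomer <- if (is.null(fam$template)) random_dna_chr(P) else fam$template
        templates[fam$family_id] <- monomer
        n_cop <- max(2L, as.integer(round(fam$target_gp * G / P)))
        n_var <- 0L
        var_monomer <- NULL
        if (!is.null(fam$variant_monomer_length)) {
          del_len <- P - fam$variant_monomer_length
          del_start <- sample.int(P - del_len + 1L, 1L)  # 1-based in monomer
          var_monomer <- paste0(substr(monomer, 1L, del_start - 1L),
                                substr(monomer, del_start + del_len, P))
          n_var <- as.integer(round(fam$variant_fraction * n_cop))
          variant_info[[fam$family_id]] <- list(
            del_start = del_start, del_len = del_len,
            deleted_segment = substr(monomer, del_start, del_start + del_len - 1L),
            variant_monomer = var_monomer, n_variant = n_var, n_copies = n_cop)
        }
        is_var <- rep(FALSE, n_cop)
        if (n_var > 0L) is_var[sample.int(n_cop, n_var)] <- TRUE
        units <- vapply(seq_len(n_cop), function(i) {
          mutate_seq_chr(if (is_var[i]) var_monomer else monomer, fam$divergence)
        }, character(1))
        lens <- nchar(units)
        offs <- cumsum(c(0L, lens[-n_cop]))
        rows <- data.frame(family_id = fam$family_id, kind = fam$kind,
                           start = offs, end = offs + lens,
                           copy_index = seq_len(n_cop), is_variant = is_var,
                           stringsAsFactors = FALSE)
        blocks[[length(blocks) + 1L]] <-
          list(seq = paste(units, collapse = ""), rows = rows)
      } else {
        Tl <- fam$template_length
        template <- if (is.null(fam$template)) random_dna_chr(Tl) else fam$template
        templates[fam$family_id] <- template
        n_cop <- max(1L, as.integer(round(fam$target_gp * G / Tl)))
        for (i in seq_len(n_cop)) {
          blocks[[length(blocks) + 1L]] <- list(
            seq = mutate_seq_chr(template, fam$divergence),
            rows = data.frame(family_id = fam$family_id, kind = fam$kind,
                              start = 0L, end = Tl, copy_index = i,
                              is_variant = FALSE, stringsAsFactors = FALSE))
        }
      }
    }
    total_block <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
    if (total_block > G) {
      stop(sprintf("infeasible packing: families need %d bp but genome_size is %d",
                   total_block, G))
    }
    B <- G - total_block
    nb <- length(blocks)
    if (nb > 0L) blocks <- blocks[sample.int(nb)]
    background <- if (B > 0) random_dna_chr(B) else ""
    if (nb == 0L) {
      return(structure(list(sequence = background, truth = empty_truth(),
                            realized_gp = numeric(), templates = templates,
                            variant_info = variant_info,
                            species_code = spec$species_code, genome_size = G,
                            spec = spec),
                       class = "sim_genome"))
    }
    spacer <- min(spec$min_spacer %||% 200L, B %/% (nb + 1L))
    Bfree <- B - spacer * (nb + 1L)
    cuts <- sort(sample.int(Bfree + 1L, nb, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, Bfree)) + spacer   # nb + 1 gaps summing to B
    pieces <- character(2L * nb + 1L)
    truth_rows <- vector("list", nb)
    cursor <- 0L
    gpos <- cumsum(c(0L, gaps[-(nb + 1L)]))  # offsets into background
    for (i in seq_len(nb)) {
      pieces[2L * i - 1L] <- substr(background, gpos[i] + 1L, gpos[i] + gaps[i])
      cursor <- cursor + gaps[i]
      blk <- blocks[[i]]
      rows <- blk$rows
      rows$start <- rows$start + cursor
      rows$end <- rows$end + cursor
      truth_rows[[i]] <- rows
      pieces[2L * i] <- blk$seq
      cursor <- cursor + nchar(blk$seq)
    }
    pieces[2L * nb + 1L] <- substr(background, gpos[nb] + gaps[nb] + 1L, B)
    truth <- do.call(rbind, truth_rows)
    truth <- truth[order(truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    realized <- tapply(truth$end - truth$start, truth$family_id, sum) / G
    structure(list(sequence = paste(pieces, collapse = ""), truth = truth,
                   realized_gp = realized[unique(truth$family_id)],
                   templates = templates, variant_info = variant_info,
                   species_code = spec$species_code, genome_size = G,
                   spec = spec),
              class = "sim_genome")
  })
}

# Reduced IRanges per family (1-based closed, from 0-based half-open truth).
family_ranges <- function(truth) {
  if (nrow(truth) == 0L) return(list())
  sp <- split(truth, truth$family_id)
  lapply(sp, function(d) {
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
  })
}

# Majority-rule family label for read intervals (1-based closed IRanges).
label_reads <- function(read_ranges, fam_ranges, min_frac = 0.5) {
  n <- length(read_ranges)
  lab <- rep("background", n)
  if (length(fam_ranges) == 0L || n == 0L) return(lab)
  best <- rep(0L, n)
  L <- IRanges::width(read_ranges)
  for (fam in names(fam_ranges)) {
    ov <- IRanges::findOverlaps(read_ranges, fam_ranges[[fam]])
    if (!length(ov)) next
    qi <- S4Vectors::queryHits(ov)
    w <- IRanges::width(IRanges::pintersect(read_ranges[qi],
                                            fam_ranges[[fam]][S4Vectors::subjectHits(ov)]))
    tot <- tapply(w, qi, sum)
    idx <- as.integer(names(tot))
    better <- tot > best[idx]
    idx <- idx[better]; tot <- tot[better]
    take <- tot >= min_frac * L[idx]
    lab[idx[take]] <- fam
    best[idx] <- tot
  }
  lab
}

apply_substitution_errors <- function(reads, p) {
  if (p <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  tot <- sum(L)
  nhit <- rbinom(1L, tot, p)
  if (nhit == 0L) return(reads)
  hit <- sample.int(tot, nhit)
  cl <- cumsum(L)
  ridx <- findInterval(hit - 1L, cl) + 1L
  pos <- hit - c(0L, cl)[ridx]
  for (j in seq_along(hit)) {
    i <- ridx[j]
    cur <- substr(reads[i], pos[j], pos[j])
    substr(reads[i], pos[j], pos[j]) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  reads
}

make_pairs <- function(genome_seq, truth, spec, starts0, inserts, minus,
                       id_prefix = "read") {
  L <- spec$read_length
  n <- length(starts0)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  frag <- substring(genome_seq, starts0 + 1L, starts0 + inserts)
  frag[minus] <- revcomp_chr(frag[minus])
  r1 <- substr(frag, 1L, L)
  r2 <- revcomp_chr(substring(frag, inserts - L + 1L, inserts))
  r1 <- apply_substitution_errors(r1, spec$error_rate)
  r2 <- apply_substitution_errors(r2, spec$error_rate)
  # genomic intervals of each mate (0-based half-open)
  s1 <- ifelse(minus, starts0 + inserts - L, starts0)
  s2 <- ifelse(minus, starts0, starts0 + inserts - L)
  fr <- family_ranges(truth)
  lab1 <- label_reads(IRanges::IRanges(start = s1 + 1L, width = L), fr)
  lab2 <- label_reads(IRanges::IRanges(start = s2 + 1L, width = L), fr)
  qual <- strrep("I", L)
  mk <- function(x) {
    Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(x, ids)),
      Biostrings::PhredQuality(rep(qual, n)))
  }
  truth_df <- data.frame(
    read_id = rep(ids, 2L), mate = rep(1:2, each = n),
    start = c(s1, s2), end = c(s1, s2) + L,
    strand = rep(ifelse(minus, "-", "+"), 2L),
    family = c(lab1, lab2), stringsAsFactors = FALSE)
  list(r1 = mk(r1), r2 = mk(r2), truth = truth_df)
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are drawn uniformly over the genome on both strands; each mate is
#' labeled with the planted family covering at least half of its bases
#' (otherwise `"background"`). Deterministic given `spec$seed`.
#'
#' @param genome A [simulate_genome()] result or a character scalar sequence.
#' @param spec A [read_sim_spec()].
#' @param id_prefix Prefix for generated read ids.
#' @return A list with `r1`, `r2`
#'   ([Biostrings::QualityScaledDNAStringSet-class] of forward/reverse mates)
#'   and `truth` (one row per mate: `read_id`, `mate`, 0-based half-open
#'   `start`/`end`, `strand`, `family`).
#' @export
simulate_reads <- function(genome, spec, id_prefix = "read") {
  stopifnot(inherits(spec, "read_sim_spec"))
  gseq <- if (inherits(genome, "sim_genome")) genome$sequence else genome
  truth <- if (inherits(genome, "sim_genome")) genome$truth else empty_truth()
  glen <- nchar(gseq)
  stopifnot(glen >= 1)
  if (spec$read_length > glen) stop("read_length exceeds genome length")
  with_seed(spec$seed, {
    n <- spec$n_pairs
    if (n == 0L) {
      e <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character()))
      return(list(r1 = e, r2 = e,
                  truth = data.frame(read_id = character(), mate = integer(),
                                     start = integer(), end = integer(),
                                     strand = character(), family = character(),
                                     stringsAsFactors = FALSE)))
    }
    inserts <- pmin(pmax(as.integer(round(rnorm(n, spec$insert_mean, spec$insert_sd))),
                         spec$read_length), glen)
    starts0 <- floor(runif(n) * (glen - inserts + 1))
    minus <- runif(n) < 0.5
    make_pairs(gseq, truth, spec, starts0, inserts, minus, id_prefix)
  })
}

#' Simulate ChIP and input read sets
#'
#' In the ChIP set, fragment start density over the target family's planted
#' copies is `chip_enrichment_fold` times the background density; the matched
#' input (mock) set is sampled uniformly. Both sets are deterministic given
#' `spec$seed`.
#'
#' @param genome A [simulate_genome()] result.
#' @param spec A [read_sim_spec()] with `chip_target_family` set and
#'   `chip_enrichment_fold >= 1`.
#' @return A list with elements `chip` and `input`, each as in
#'   [simulate_reads()].
#' @export
simulate_chip_reads <- function(genome, spec) {
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "read_sim_spec"))
  if (is.null(spec$chip_target_family))
    stop("chip_target_family must be set")
  if (spec$chip_enrichment_fold < 1)
    stop("chip_enrichment_fold must be >= 1")
  if (!spec$chip_target_family %in% genome$truth$family_id)
    stop("chip_target_family not present in genome truth")
  gseq <- genome$sequence
  glen <- nchar(gseq)
  tr <- genome$truth[genome$truth$family_id == spec$chip_target_family, ]
  tgt <- IRanges::reduce(IRanges::IRanges(start = tr$start + 1L, end = tr$end))
  fold <- spec$chip_enrichment_fold
  chip <- with_seed(spec$seed, {
    n <- spec$n_pairs
    inserts <- pmin(pmax(as.integer(round(rnorm(n, spec$insert_mean, spec$insert_sd))),
                         spec$read_length), glen)
    t_bases <- sum(IRanges::width(tgt))
    p_target <- fold * t_bases / (fold * t_bases + (glen - t_bases))
    in_target <- runif(n) < p_target
    starts0 <- integer(n)
    # uniform start within the target array(s)
    nt <- sum(in_target)
    if (nt > 0L) {
      w <- IRanges::width(tgt)
      iv <- sample.int(length(tgt), nt, replace = TRUE, prob = w)
      offs <- floor(runif(nt) * w[iv])
      starts0[in_target] <- IRanges::start(tgt)[iv] - 1L + offs
    }
    # uniform start outside the target (rejection sampling)
    nb <- sum(!in_target)
    if (nb > 0L) {
      bs <- integer(0)
      while (length(bs) < nb) {
        cand <- floor(runif(2L * (nb - length(bs))) * (glen - spec$insert_mean))
        hit <- IRanges::overlapsAny(IRanges::IRanges(start = cand + 1L, width = 1L), tgt)
        bs <- c(bs, cand[!hit])
      }
      starts0[!in_target] <- bs[seq_len(nb)]
    }
    starts0 <- pmin(starts0, glen - inserts)
    minus <- runif(n) < 0.5
    make_pairs(gseq, genome$truth, spec, starts0, inserts, minus, "chip")
  })
  input_spec <- spec
  input_spec$seed <- spec$seed + 500003L
  input <- simulate_reads(genome, input_spec, id_prefix = "input")
  list(chip = chip, input = input)
}
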