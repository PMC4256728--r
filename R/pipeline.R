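KIND_SUPERFAMILY <- c(LTR_copia = "Ty1/Copia", LTR_gypsy = "Ty3/Gypsy",
                      DNA_transposon = "En-Spm", satellite = "Satellite",
                      rDNA = "rDNA")

pipeline_stages <- c("simulate", "preprocess", "cluster", "annotate",
                     "satellite", "compare", "chip", "phylo", "report")

#' Validate a pipeline configuration
#'
#' Checks stage names and that every referenced input path exists, naming the
#' offending field on failure.
#'
#' @param config A configuration list or path to a YAML file.
#' @return The normalized configuration list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages)) config$stages <- pipeline_stages
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad)) stop(sprintf("unknown stage '%s'", bad[1L]))
  path_fields <- list(
    c("annotate", "library"), c("annotate", "organelle_library"),
    c("phylo", "rt_reference_peptides"))
  for (pf in path_fields) {
    v <- config[[pf[1]]][[pf[2]]]
    if (!is.null(v) && is.character(v) && length(v) == 1L && !file.exists(v)) {
      stop(sprintf("config field %s.%s: path '%s' does not exist",
                   pf[1], pf[2], v))
    }
  }
  for (sp in config$fastq) {
    for (f in c("r1", "r2")) {
      if (!is.null(sp[[f]]) && !file.exists(sp[[f]])) {
        stop(sprintf("config field fastq.%s.%s: path '%s' does not exist",
                     sp$species_code, f, sp[[f]]))
      }
    }
  }
  config
}

build_family_specs <- function(fam_cfgs, templates) {
  lapply(fam_cfgs, function(fc) {
    repeat_family_spec(
      family_id = fc$family_id, kind = fc$kind, target_gp = fc$target_gp,
      template_length = fc$template_length %||% 1000L,
      monomer_length = fc$monomer_length,
      variant_monomer_length = fc$variant_monomer_length,
      variant_fraction = fc$variant_fraction %||% 0,
      divergence = fc$divergence %||% 0.02,
      template = templates[[fc$family_id]])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full repeat-landscape pipeline
#'
#' Orchestrates the stages (simulate, preprocess, cluster, annotate,
#' satellite, compare, chip, phylo) from a single configuration and writes
#' report tables, FASTA/Newick outputs, a log, and a manifest into
#' `out_dir`. Reruns with the same configuration and seed are bit-identical
#' for the deterministic stages.
#'
#' @param config Configuration list or YAML path; see the package vignette
#'   for the schema.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- sprintf(...)
    writeLines(line, log_con)
    message(line)
  }
  stage_active <- function(s) s %in% config$stages
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- list()
  seed <- as.integer(config$seed)
  cl_cfg <- do.call(clustering_config,
                    config$cluster %||% list())
  an_cfg <- do.call(annotation_config,
                    config$annotate[intersect(names(config$annotate),
                                              c("min_identity", "min_coverage"))] %||% list())

  # ---- simulate ------------------------------------------------------------
  species_reads <- list()   # species_code -> list(r1, r2, truth)
  genomes <- list()
  if (stage_active("simulate") && !is.null(config$simulate)) {
    run_stage("simulate", {
      sim <- config$simulate
      fam_ids <- unique(unlist(lapply(sim$species, function(sp)
        vapply(sp$families, `[[`, character(1), "family_id"))))
      fam_first <- list()
      for (sp in sim$species) for (fc in sp$families) {
        if (is.null(fam_first[[fc$family_id]])) fam_first[[fc$family_id]] <- fc
      }
      templates <- with_seed(seed, {
        out <- list()
        for (fid in fam_ids) {
          fc <- fam_first[[fid]]
          out[[fid]] <- if (identical(fc$kind, "satellite")) {
            random_dna_chr(fc$monomer_length)
          } else {
            random_dna_chr(fc$template_length %||% 1000L)
          }
        }
        out
      })
      for (i in seq_along(sim$species)) {
        sp <- sim$species[[i]]
        gs <- genome_spec(sp$species_code, sp$genome_size,
                          build_family_specs(sp$families, templates),
                          seed = seed + i)
        genomes[[sp$species_code]] <- simulate_genome(gs)
        rs <- read_sim_spec(
          n_pairs = sim$reads$n_pairs, read_length = sim$reads$read_length %||% 100L,
          insert_mean = sim$reads$insert_mean %||% 300,
          insert_sd = sim$reads$insert_sd %||% 30,
          error_rate = sim$reads$error_rate %||% 0.001,
          seed = seed + 100L + i)
        species_reads[[sp$species_code]] <-
          simulate_reads(genomes[[sp$species_code]], rs,
                         id_prefix = paste0(sp$species_code, "_"))
        logmsg("simulate: %s genome %d bp, %d read pairs",
               sp$species_code, sp$genome_size, sim$reads$n_pairs)
      }
      res$templates <- templates
    })
  } else if (!is.null(config$fastq)) {
    run_stage("simulate", {
      for (sp in config$fastq) {
        species_reads[[sp$species_code]] <- list(
          r1 = read_fastq(sp$r1), r2 = read_fastq(sp$r2), truth = NULL)
        logmsg("input: %s from %s", sp$species_code, sp$r1)
      }
    })
  }
  if (!length(species_reads)) stop("no input reads: provide simulate or fastq")

  # ---- preprocess ----------------------------------------------------------
  if (stage_active("preprocess")) {
    run_stage("preprocess", {
      for (sc in names(species_reads)) {
        pp <- preprocess_reads(species_reads[[sc]]$r1, species_reads[[sc]]$r2,
                               min_mean_quality = config$preprocess$min_mean_quality %||% 20)
        species_reads[[sc]]$r1 <- pp$r1
        species_reads[[sc]]$r2 <- pp$r2
        logmsg("preprocess: %s kept %d pairs, discarded %d",
               sc, length(pp$r1), pp$n_discarded_pairs)
      }
    })
  }

  # reads used for clustering: both mates, ids suffixed /1 /2
  pooled <- list()
  for (sc in names(species_reads)) {
    r1 <- as_read_chr(species_reads[[sc]]$r1)
    r2 <- as_read_chr(species_reads[[sc]]$r2)
    names(r1) <- paste0(names(r1), "/1")
    names(r2) <- paste0(names(r2), "/2")
    pooled[[sc]] <- c(r1, r2)
  }
  multi <- length(pooled) > 1L

  # ---- cluster / compare ---------------------------------------------------
  clustering <- NULL; reads_used <- NULL; comparative <- NULL
  if (stage_active("cluster")) {
    run_stage("cluster", {
      if (multi) {
        n_total <- config$compare$n_total %||% sum(lengths(pooled))
        reads_used <- subsample_combined(pooled, n_total, seed = seed)
        comparative <- comparative_cluster_analysis(reads_used, cl_cfg)
        clustering <- comparative$clustering
      } else {
        reads_used <- pooled[[1L]]
        edges <- build_similarity_graph(reads_used, cl_cfg)
        clustering <- partition_graph(edges, reads_used, cl_cfg)
      }
      logmsg("cluster: %d reads, %d clusters (%d detailed)",
             clustering$total_reads, nrow(clustering$clusters),
             sum(clustering$clusters$detailed))
    })
  }
  if (is.null(clustering)) stop("clustering stage is required downstream")

  detailed <- clustering$clusters[clustering$clusters$detailed, , drop = FALSE]
  contigs_by_cluster <- list()
  assemblies <- list()
  run_stage("cluster", {
    for (cl in detailed$cluster_id) {
      asm <- assemble_cluster_contigs(cluster_members(clustering, cl),
                                      reads_used, cl_cfg)
      assemblies[[cl]] <- asm
      contigs_by_cluster[[cl]] <- asm$contigs
    }
  })

  # ---- annotate ------------------------------------------------------------
  annotations <- NULL
  clusters_df <- detailed
  if (stage_active("annotate")) {
    run_stage("annotate", {
      lib <- NULL
      if (!is.null(config$annotate$library)) {
        lib <- as_read_chr(Biostrings::readDNAStringSet(config$annotate$library))
      } else if (!is.null(res$templates)) {
        kinds <- vapply(config$simulate$species[[1L]]$families, `[[`,
                        character(1), "kind")
        fam_ids <- vapply(config$simulate$species[[1L]]$families, `[[`,
                          character(1), "family_id")
        all_kinds <- setNames(character(0), character(0))
        for (sp in config$simulate$species) for (fc in sp$families) {
          all_kinds[fc$family_id] <- fc$kind
        }
        lib <- unlist(res$templates)
        names(lib) <- paste0(names(res$templates), "#",
                             KIND_SUPERFAMILY[all_kinds[names(res$templates)]])
      }
      if (!is.null(lib)) {
        sf <- vapply(detailed$cluster_id, function(cl) {
          annotate_cluster(assemblies[[cl]], lib, an_cfg)$superfamily
        }, character(1))
        clusters_df$superfamily <- unname(sf)
        if (!is.null(config$annotate$organelle_library)) {
          org <- as_read_chr(Biostrings::readDNAStringSet(
            config$annotate$organelle_library))
          el <- eliminate_organelle_clusters(clusters_df, contigs_by_cluster,
                                             org, an_cfg)
          clusters_df <- el$clusters
          logmsg("annotate: removed %d organelle clusters", nrow(el$removed))
        }
        annotations <- clusters_df
        logmsg("annotate: %d clusters annotated", nrow(clusters_df))
      } else {
        logmsg("annotate: no library available, skipped")
      }
    })
  }

  # ---- satellite -----------------------------------------------------------
  profiles <- list(); variant_tables <- list()
  if (stage_active("satellite")) {
    run_stage("satellite", {
      for (cl in clusters_df$cluster_id) {
        ctgs <- contigs_by_cluster[[cl]]
        if (is.null(ctgs) || !length(ctgs)) next
        prof <- find_satellite_monomer(ctgs[[1L]])
        if (!is.null(prof)) {
          profiles[[cl]] <- prof
          fam_reads <- reads_used[cluster_members(clustering, cl)]
          variant_tables[[cl]] <- detect_monomer_variants(prof, fam_reads)
        }
      }
      logmsg("satellite: %d tandem clusters", length(profiles))
    })
  }

  # ---- chip ----------------------------------------------------------------
  enrichment <- NULL
  if (stage_active("chip") && !is.null(config$simulate$chip) &&
      length(genomes)) {
    run_stage("chip", {
      ch <- config$simulate$chip
      sc <- ch$species_code %||% names(genomes)[1L]
      cs <- read_sim_spec(n_pairs = ch$n_pairs,
                          read_length = config$simulate$reads$read_length %||% 100L,
                          error_rate = config$simulate$reads$error_rate %||% 0.001,
                          chip_target_family = ch$target_family,
                          chip_enrichment_fold = ch$fold %||% 1,
                          seed = seed + 777L)
      sim <- simulate_chip_reads(genomes[[sc]], cs)
      chip_reads <- as_read_chr(sim$chip$r1)
      input_reads <- as_read_chr(sim$input$r1)
      cm_cfg <- chip_map_config()
      a_chip <- map_reads_to_clusters(chip_reads, clustering, reads_used, cm_cfg)
      a_input <- map_reads_to_clusters(input_reads, clustering, reads_used, cm_cfg)
      negs <- ch$negative_controls %||%
        setdiff(clusters_df$cluster_id,
                a_chip$cluster_id[which.max(table(a_chip$cluster_id))])
      enrichment <- compute_enrichment(a_chip, a_input,
                                        length(chip_reads), length(input_reads),
                                        intersect(negs, clusters_df$cluster_id))
      logmsg("chip: %d/%d ChIP reads assigned", nrow(a_chip), length(chip_reads))
    })
  }

  # ---- phylo ---------------------------------------------------------------
  tree <- NULL
  if (stage_active("phylo") && !is.null(config$phylo$rt_reference_peptides)) {
    run_stage("phylo", {
      refs <- Biostrings::readAAStringSet(config$phylo$rt_reference_peptides)
      fams <- contigs_by_cluster[clusters_df$cluster_id]
      sel <- select_rt_representative(fams, refs,
                                      min_score = config$phylo$min_score %||% 50)
      all_peps <- c(sel$peptides, setNames(as.character(refs), names(refs)))
      if (length(all_peps) >= 3L) {
        aln <- align_rt_peptides(all_peps)
        tree <- bootstrap_support(aln,
                                   n_replicates = config$phylo$n_replicates %||% 100L,
                                   seed = seed + 4242L)
        ape::write.tree(tree, file.path(out_dir, "rt_tree.nwk"))
        logmsg("phylo: %d RT representatives, %d dropped",
               length(sel$peptides), length(sel$dropped))
      } else {
        logmsg("phylo: fewer than 3 RT peptides, skipped")
      }
    })
  }

  # ---- report --------------------------------------------------------------
  run_stage("report", {
    write_tsv_hash(clusters_df, file.path(out_dir, "clusters.tsv"))
    if (!is.null(annotations) && "superfamily" %in% names(annotations)) {
      summary_df <- summarize_superfamilies(
        annotations[, c("superfamily", "genome_proportion")])
      write_tsv_hash(summary_df, file.path(out_dir, "superfamily_summary.tsv"))
    }
    if (length(contigs_by_cluster)) {
      all_ctgs <- unlist(lapply(names(contigs_by_cluster), function(cl) {
        x <- contigs_by_cluster[[cl]]
        setNames(unname(x), paste0(cl, "_", names(x)))
      }))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(all_ctgs),
                                  file.path(out_dir, "contigs.fasta"))
    }
    if (length(profiles)) {
      sat_df <- data.frame(
        cluster_id = names(profiles),
        period = vapply(profiles, `[[`, numeric(1), "period"),
        array_span = vapply(profiles, `[[`, numeric(1), "array_span"),
        consensus = vapply(profiles, `[[`, character(1), "consensus_monomer"),
        stringsAsFactors = FALSE)
      write_tsv_hash(sat_df, file.path(out_dir, "satellites.tsv"))
      vt <- rbindlist(lapply(names(variant_tables), function(cl) {
        v <- variant_tables[[cl]]
        if (nrow(v)) cbind(cluster_id = cl, v) else NULL
      }))
      if (!is.null(vt) && nrow(vt)) {
        write_tsv_hash(as.data.frame(vt), file.path(out_dir, "variants.tsv"))
      }
    }
    if (!is.null(comparative)) {
      write_tsv_hash(comparative$table, file.path(out_dir, "comparative.tsv"))
      write_tsv_hash(pattern_summary(comparative),
                     file.path(out_dir, "pattern_summary.tsv"))
    }
    if (!is.null(enrichment)) {
      write_tsv_hash(enrichment, file.path(out_dir, "enrichment.tsv"))
    }
    manifest <- list(
      package = "repeatscape",
      version = as.character(utils::packageVersion("repeatscape")),
      seed = seed,
      stages = config$stages,
      clustering = unclass(cl_cfg),
      annotation = unclass(an_cfg),
      n_reads_analyzed = clustering$total_reads,
      input_checksums = local({
        paths <- c(unlist(lapply(config$fastq, function(x) c(x$r1, x$r2))),
                   config$annotate$library, config$annotate$organelle_library,
                   config$phylo$rt_reference_peptides)
        paths <- paths[!vapply(paths, is.null, logical(1))]
        if (length(paths)) as.list(tools::md5sum(unlist(paths))) else list()
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logmsg("report: outputs in %s", out_dir)
  })

  invisible(list(clustering = clustering, clusters = clusters_df,
                 annotations = annotations, contigs = contigs_by_cluster,
                 profiles = profiles, variants = variant_tables,
                 comparative = comparative, enrichment = enrichment,
                 tree = tree, reads_used = reads_used))
}
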