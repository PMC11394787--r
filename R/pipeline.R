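#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter plus either the synthetic switch (with a
#' [synthetic_config()]) or the paths to real inputs. Validation is
#' fail-fast: missing files or out-of-range parameters abort before any
#' stage runs.
#'
#' @param outdir Output directory for stage artifacts and the manifest.
#' @param synthetic Use the synthetic generator (default) or file inputs.
#' @param synth A [synthetic_config()] (synthetic mode).
#' @param counts_file,labels_file,gtf_file,fasta_file,gmt_file,category_file
#'   Input paths (file mode).
#' @param seed Master seed; all stage randomness derives from it.
#' @param gamma Ordering window percentage, default 55.
#' @param grid A [grid_spec()] for the threshold search.
#' @param bins Number of pseudo-time bins, default 4.
#' @param fc_thresh,padj_thresh Group-level DET thresholds (1.3, 0.05).
#' @param inflation,mass MCL inflation and lncRNA mass retention.
#' @param alpha ssGSEA rank-weight exponent.
#' @param r2_threshold,var_threshold,window,energy_threshold,ridge
#'   Regulation and discerning parameters.
#' @return List of class `lnc_run_config`.
#' @export
run_config <- function(outdir, synthetic = TRUE, synth = synthetic_config(),
                       counts_file = NULL, labels_file = NULL,
                       gtf_file = NULL, fasta_file = NULL, gmt_file = NULL,
                       category_file = NULL, seed = 1L, gamma = 55,
                       grid = grid_spec(), bins = 4, fc_thresh = 1.3,
                       padj_thresh = 0.05, inflation = 2, mass = 0.95,
                       alpha = 0.25, r2_threshold = 0.5, var_threshold = 0.6,
                       window = 100000, energy_threshold = -10,
                       ridge = 1e-6) {
  cfg <- as.list(environment())
  if (!synthetic) {
    needed <- c("counts_file", "labels_file", "gtf_file", "gmt_file")
    for (f in needed) {
      if (is.null(cfg[[f]])) abort_arg(paste0("`", f, "` required when synthetic = FALSE"))
      if (!file.exists(cfg[[f]])) abort_arg(paste0(f, " does not exist: ", cfg[[f]]))
    }
  }
  if (gamma <= 0 || gamma > 100) abort_arg("`gamma` must lie in (0, 100]")
  if (inflation <= 1) abort_arg("`inflation` must exceed 1")
  if (mass <= 0 || mass > 1) abort_arg("`mass` must lie in (0, 1]")
  if (bins < 1) abort_arg("`bins` must be >= 1")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "lnc_run_config")
}

.write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_tsv(x, path)
  path
}

#' Run the full pipeline
#'
#' Stage order: data (synthetic or load) -> candidate screening and
#' classification -> normalization and group DE -> per-sample DE ->
#' gamma-constrained ordering and binning -> per-bin bi-color network,
#' MCL, cluster retention, enrichment and category counts -> per-bin
#' regulator assignment -> discerning scores and AUC over the stage
#' contrasts -> ssGSEA matrix. Every stage's outputs are written to
#' `outdir` before the next begins; the returned manifest records the
#' config, per-file md5 checksums and timestamps.
#'
#' @param cfg An [run_config()] object.
#' @return List of class `lnc_manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "lnc_run_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  t0 <- Sys.time()
  set.seed(derive_seed(cfg$seed, "pipeline"))

  # --- stage: data -----------------------------------------------------
  if (cfg$synthetic) {
    synth <- cfg$synth
    synth$seed <- cfg$seed
    world <- simulate_cohort(synth)
    counts <- world$counts; samples <- world$samples
    annotation <- world$annotation; sequences <- world$sequences
    catalog <- world$catalog
    coding <- generate_coding_calls(synth, annotation)
    files["truth"] <- file.path(cfg$outdir, "ground_truth.json")
    jsonlite::write_json(
      list(true_t = world$truth$true_t,
           progression_transcripts = world$truth$progression_transcripts,
           cis_pairs = world$truth$cis_pairs,
           trans_pairs = world$truth$trans_pairs[c("lncRNA", "mRNA")],
           module_membership = world$truth$module_membership),
      files["truth"], dataframe = "rows", auto_unbox = TRUE
    )
  } else {
    counts <- read_counts(cfg$counts_file)
    samples <- read_samples(cfg$labels_file)
    annotation <- read_gtf(cfg$gtf_file)
    sequences <- if (!is.null(cfg$fasta_file)) read_fasta(cfg$fasta_file) else NULL
    catalog <- read_gmt(cfg$gmt_file, cfg$category_file)
    coding <- NULL
  }
  files["samples"] <- .write_stage(samples, cfg$outdir, "samples.tsv")

  # --- stage: annotate -------------------------------------------------
  is_lnc_biotype <- annotation$biotype %in% c("lncRNA", "candidate")
  candidates <- filter_candidates(annotation[is_lnc_biotype, ])
  if (!is.null(coding)) {
    cons <- consensus_noncoding(semi_join(coding, candidates, by = "transcript_id"))
    candidates <- semi_join(candidates,
                            filter(cons, .data$noncoding), by = "transcript_id")
  }
  reference <- annotation[annotation$biotype == "mRNA", ]
  classification <- classify_vs_reference(candidates, reference)
  files["classification"] <- .write_stage(classification, cfg$outdir,
                                          "classification.tsv")
  lnc_ids <- candidates$transcript_id
  mrna_ids <- reference$transcript_id

  # --- stage: de -------------------------------------------------------
  norm <- normalize_counts(counts)
  normalized <- norm$normalized
  files["size_factors"] <- .write_stage(norm$size_factors, cfg$outdir,
                                        "size_factors.tsv")
  groups <- sample_groups(samples)
  controls <- names(groups)[groups == "control"]
  disease <- names(groups)[groups != "control"]
  de_group <- group_de(normalized, disease, controls)
  files["group_de"] <- .write_stage(de_group, cfg$outdir, "group_de.tsv")
  dets <- call_dets(de_group, cfg$fc_thresh, cfg$padj_thresh)
  files["dets"] <- .write_stage(as_tibble(dets), cfg$outdir, "dets.tsv")

  per_sample <- lapply(setNames(disease, disease), function(s) {
    sample_de(normalized, s, controls)
  })

  # --- stage: order ----------------------------------------------------
  labels <- filter(samples, .data$group != "control")
  solution <- optimize_ordering(per_sample, labels, cfg$grid, cfg$gamma)
  bins_tbl <- assign_bins(solution, cfg$bins)
  ordering_tbl <- left_join(tidy(solution), bins_tbl,
                            by = c("sample_id", "rank"))
  files["ordering"] <- .write_stage(ordering_tbl, cfg$outdir, "ordering.tsv")
  files["thresholds"] <- file.path(cfg$outdir, "thresholds.json")
  jsonlite::write_json(glance(solution), files["thresholds"],
                       dataframe = "rows", auto_unbox = TRUE)

  # --- stage: per-bin network / enrichment / regulation ---------------
  edge_rows <- list(); cluster_rows <- list(); enrich_rows <- list()
  regulator_rows <- list()
  for (b in sort(unique(bins_tbl$bin))) {
    bin_samples <- bins_tbl$sample_id[bins_tbl$bin == b]
    if (length(bin_samples) < 5) next
    net <- spearman_edges(normalized, lnc_ids, mrna_ids, bin_samples,
                          cfg$padj_thresh)
    edge_rows[[b]] <- mutate(net$edges, bin = b)
    if (nrow(net$edges) == 0) next
    cl <- mcl_cluster(net, inflation = cfg$inflation)
    kept <- filter_clusters_by_lncrna_mass(cl, cfg$mass)
    cluster_rows[[b]] <- mutate(kept$membership, bin = b)

    de_bin <- group_de(normalized, bin_samples, controls)
    fc_map <- setNames(de_bin$log2fc, de_bin$transcript_id)
    universe <- filter(net$nodes, .data$color == "mRNA")$id
    for (cid in unique(kept$membership$cluster_id)) {
      cluster_genes <- kept$membership$id[kept$membership$cluster_id == cid &
                                            kept$membership$color == "mRNA"]
      if (length(cluster_genes) == 0) next
      enr <- hypergeom_enrich(cluster_genes, universe, catalog)
      enr$direction <- vapply(enr$pathway, function(pw) {
        ov <- intersect(catalog$sets[[pw]], cluster_genes)
        if (length(ov) == 0) return(NA_character_)
        if (mean(fc_map[ov]) >= 0) "up" else "down"
      }, character(1))
      enrich_rows[[length(enrich_rows) + 1]] <-
        mutate(enr, bin = b, cluster_id = cid)
    }

    reg <- assign_regulators(normalized, bin_samples, net, annotation,
                             sequences, catalog,
                             r2_threshold = cfg$r2_threshold,
                             padj_thresh = cfg$padj_thresh,
                             var_threshold = cfg$var_threshold,
                             window = cfg$window,
                             energy_threshold = cfg$energy_threshold)
    regulator_rows[[b]] <- mutate(reg, bin = b)
  }
  edges_all <- bind_rows(edge_rows)
  if (nrow(edges_all) == 0) {
    edges_all <- tibble(lncRNA = character(0), mRNA = character(0),
                        scc = numeric(0), p = numeric(0), padj = numeric(0),
                        bin = integer(0))
  }
  files["edges"] <- .write_stage(edges_all, cfg$outdir, "network_edges.tsv")
  clusters_all <- bind_rows(cluster_rows)
  if (nrow(clusters_all) == 0) {
    clusters_all <- tibble(cluster_id = integer(0), id = character(0),
                           color = character(0), bin = integer(0))
  }
  files["clusters"] <- .write_stage(clusters_all, cfg$outdir, "clusters.tsv")
  enrich_all <- bind_rows(enrich_rows)
  if (nrow(enrich_all) == 0) {
    enrich_all <- tibble(pathway = character(0), overlap = integer(0),
                         cluster_size = integer(0), set_size = integer(0),
                         universe_size = integer(0), p = numeric(0),
                         padj = numeric(0), direction = character(0),
                         bin = integer(0), cluster_id = integer(0))
  }
  files["enrichment"] <- .write_stage(enrich_all, cfg$outdir, "enrichment.tsv")
  cat_counts <- categorize_counts(enrich_all, catalog, cfg$padj_thresh)
  files["categories"] <- .write_stage(cat_counts, cfg$outdir,
                                      "category_counts.tsv")
  regulators_all <- bind_rows(regulator_rows)
  if (nrow(regulators_all) == 0) {
    regulators_all <- tibble(lncRNA = character(0), pathway = character(0),
                             mode = character(0), evidence = numeric(0),
                             scc = numeric(0), scc_padj = numeric(0),
                             r2 = numeric(0), intercept = numeric(0),
                             direction = character(0), bin = integer(0))
  }
  files["regulators"] <- .write_stage(regulators_all, cfg$outdir,
                                      "regulators.tsv")

  # --- stage: discerning ----------------------------------------------
  bin1 <- bins_tbl$sample_id[bins_tbl$bin == 1]
  late <- bins_tbl$sample_id[bins_tbl$bin > 1]
  contrasts <- list(
    Normal_vs_allAD = list(d1 = controls, d2 = disease),
    Normal_vs_eAD = list(d1 = controls, d2 = bin1),
    Normal_vs_aAD = list(d1 = controls, d2 = late),
    eAD_vs_aAD = list(d1 = bin1, d2 = late)
  )
  ds_rows <- purrr::imap_dfr(contrasts, function(ct, name) {
    if (length(ct$d1) < 2 || length(ct$d2) < 2) return(NULL)
    purrr::imap_dfr(catalog$sets, function(genes, pw) {
      res <- tryCatch(
        discern(normalized, ct$d1, ct$d2, genes, ridge = cfg$ridge),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      proj <- res$projections
      roc <- roc_auc(proj$projection, proj$set == "D2")
      tibble(gene_set = pw, contrast = name, f = res$f, ds = res$ds,
             auc = roc$auc, auc_direction = roc$direction,
             ridge = res$ridge_used,
             n1 = length(ct$d1), n2 = length(ct$d2))
    })
  })
  files["discern"] <- .write_stage(ds_rows, cfg$outdir, "discerning.tsv")

  # --- stage: ssgsea ---------------------------------------------------
  ss <- ssgsea_matrix(normalized, catalog, cfg$alpha)
  files["ssgsea"] <- .write_stage(ss, cfg$outdir, "ssgsea.tsv")

  manifest <- structure(list(
    config = cfg,
    outdir = cfg$outdir,
    files = files,
    checksums = tools::md5sum(unname(files)),
    version = as.character(utils::packageVersion("lncprog")),
    started = format(t0), finished = format(Sys.time())
  ), class = "lnc_manifest")
  jsonlite::write_json(
    list(files = as.list(files),
         checksums = as.list(manifest$checksums),
         version = manifest$version,
         seed = cfg$seed, started = manifest$started,
         finished = manifest$finished),
    file.path(cfg$outdir, "manifest.json"), auto_unbox = TRUE
  )
  manifest
}

#' Summarize a completed run
#'
#' Re-reads the stage TSVs named by the manifest and assembles the
#' reporting tables: per-bin pathway-category counts, per-bin regulator
#' counts by direction, and the DS/AUC contrast grid. Missing stage files
#' yield a partial report with the gap named in `missing`.
#'
#' @param manifest An `lnc_manifest` from [run_pipeline()].
#' @return List of class `lnc_report`: `category_counts`,
#'   `regulator_counts`, `ds_auc`, `missing`.
#' @export
summarize_run <- function(manifest) {
  read_or_null <- function(key) {
    path <- manifest$files[key]
    if (is.na(path) || !file.exists(path)) return(NULL)
    readr::read_tsv(path, show_col_types = FALSE)
  }
  missing <- character(0)
  cats <- read_or_null("categories")
  if (is.null(cats)) missing <- c(missing, "category_counts")
  regs <- read_or_null("regulators")
  reg_counts <- if (is.null(regs)) {
    missing <- c(missing, "regulator_counts")
    NULL
  } else if (nrow(regs) == 0) {
    tibble(bin = integer(0), direction = character(0), n_lncrna = integer(0))
  } else {
    regs %>%
      distinct(.data$bin, .data$direction, .data$lncRNA) %>%
      count(.data$bin, .data$direction, name = "n_lncrna")
  }
  ds <- read_or_null("discern")
  ds_auc <- if (is.null(ds)) {
    missing <- c(missing, "ds_auc")
    NULL
  } else if (nrow(ds) == 0) {
    ds
  } else {
    tidyr::pivot_wider(select(ds, "gene_set", "contrast", "auc"),
                       names_from = "contrast", values_from = "auc")
  }
  structure(list(category_counts = cats, regulator_counts = reg_counts,
                 ds_auc = ds_auc, missing = missing),
            class = "lnc_report")
}

#' @export
print.lnc_manifest <- function(x, ...) {
  cat("lncprog run manifest (seed", x$config$seed, ")\n")
  cat("  outdir:", x$outdir, "\n")
  cat("  files:", length(x$files), "stage artifacts\n")
  invisible(x)
}
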