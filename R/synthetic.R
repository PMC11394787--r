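#' Configuration for the synthetic AD-progression cohort generator
#'
#' Builds the parameter set for [generate_annotation()], [generate_counts()]
#' and [generate_pathways()]. Defaults describe the cohort used throughout
#' the package's tests: 30 controls plus 90 disease samples (45 MCI, 45 AD)
#' over 2,000 transcripts, with a quarter of transcripts drifting
#' monotonically along a latent disease progression, six pathway modules
#' driven by shared latent factors, and planted cis neighbours and trans
#' sequence-complementarity partners for a subset of lncRNAs.
#'
#' @param n_control,n_mci,n_ad Sample counts per diagnostic group.
#' @param n_mrna,n_lncrna Transcript counts per biotype.
#' @param n_pathways Number of pathway modules with shared latent factors.
#' @param genes_per_pathway mRNA members per pathway module.
#' @param frac_progression_transcripts Fraction of transcripts whose log2
#'   mean shifts with the latent progression value, in (0, 1].
#' @param progression_effect Maximum absolute log2 shift at progression 1.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi * mu^2), shared across transcripts.
#' @param baseline_log_mean_range Interval (log2 scale) for per-transcript
#'   baseline mean counts.
#' @param module_loading log2-scale loading of module members on their
#'   pathway's latent factor.
#' @param n_cis_pairs Planted lncRNA-gene pairs within the 100 kb window
#'   (an equal number of decoys is placed beyond it).
#' @param n_trans_pairs Planted lncRNA-mRNA pairs sharing an exact
#'   reverse-complement segment.
#' @param complement_len Length (nt) of the planted complement segment.
#' @param seed Integer master seed; every generator operation derives its
#'   own stream from it.
#' @return A list of class `lnc_synth_config`.
#' @export
synthetic_config <- function(n_control = 30, n_mci = 45, n_ad = 45,
                             n_mrna = 1700, n_lncrna = 300,
                             n_pathways = 6, genes_per_pathway = 30,
                             frac_progression_transcripts = 0.25,
                             progression_effect = 2,
                             nb_dispersion = 0.1,
                             baseline_log_mean_range = c(3, 9),
                             module_loading = 1,
                             n_cis_pairs = 10, n_trans_pairs = 10,
                             complement_len = 30, seed = 1L) {
  cfg <- list(
    n_control = n_control, n_mci = n_mci, n_ad = n_ad,
    n_mrna = n_mrna, n_lncrna = n_lncrna,
    n_pathways = n_pathways, genes_per_pathway = genes_per_pathway,
    frac_progression_transcripts = frac_progression_transcripts,
    progression_effect = progression_effect,
    nb_dispersion = nb_dispersion,
    baseline_log_mean_range = baseline_log_mean_range,
    module_loading = module_loading,
    n_cis_pairs = n_cis_pairs, n_trans_pairs = n_trans_pairs,
    complement_len = complement_len, seed = as.integer(seed)
  )
  counts <- c("n_control", "n_mrna", "n_lncrna", "n_pathways",
              "genes_per_pathway", "complement_len")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      abort_arg(paste0("`", f, "` must be a count >= 1"))
    }
  }
  if (cfg$n_mci < 2 || cfg$n_ad < 2) abort_arg("`n_mci` and `n_ad` must be >= 2")
  if (cfg$n_cis_pairs < 0 || cfg$n_trans_pairs < 0) {
    abort_arg("planted pair counts must be >= 0")
  }
  if (cfg$frac_progression_transcripts <= 0 || cfg$frac_progression_transcripts > 1) {
    abort_arg("`frac_progression_transcripts` must lie in (0, 1]")
  }
  if (cfg$nb_dispersion <= 0) abort_arg("`nb_dispersion` must be positive")
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) <= 0) {
    abort_arg("`baseline_log_mean_range` must be an increasing interval")
  }
  if (cfg$n_lncrna < 2 * cfg$n_cis_pairs + cfg$n_trans_pairs) {
    abort_sizing("`n_lncrna` too small for the requested cis/trans plantings")
  }
  if (cfg$n_mrna < cfg$n_cis_pairs + cfg$n_trans_pairs) {
    abort_sizing("`n_mrna` too small for the requested cis/trans plantings")
  }
  structure(cfg, class = "lnc_synth_config")
}

# Toy genome geometry: two chromosomes, fixed length, transcripts laid out
# in jittered slots so incidental 100 kb neighbours stay rare.
.chrom_names <- c("chrS1", "chrS2")
.chrom_len <- 2e8
.slot_width <- 150000

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw an exon chain starting at `start`; returns tibble(start, end),
# 1-based inclusive, non-overlapping, sorted.
.draw_exons <- function(start, n_exons, exon_range, intron_range) {
  lens <- sample(seq(exon_range[1], exon_range[2]), n_exons, replace = TRUE)
  introns <- if (n_exons > 1) {
    sample(seq(intron_range[1], intron_range[2]), n_exons - 1, replace = TRUE)
  } else integer(0)
  starts <- start + cumsum(c(0, head(lens, -1) + introns))
  tibble(start = starts, end = starts + lens - 1)
}

#' Generate a toy annotation with planted cis/trans structure
#'
#' Lays out `n_mrna + n_lncrna` transcripts over two toy chromosomes.
#' lncRNAs get fewer exons and shorter spliced lengths than mRNAs. For each
#' of the `n_cis_pairs` pairs one lncRNA is placed within 100 kb of a
#' partner gene and one decoy lncRNA beyond 100 kb of its own partner;
#' `n_trans_pairs` lncRNAs (on the other chromosome than their partner)
#' carry an exact reverse complement of a `complement_len`-nt segment of
#' their partner mRNA's sequence.
#'
#' @param config A [synthetic_config()].
#' @return A list with `annotation` (tibble, one row per transcript with an
#'   `exons` list-column), `sequences` (named character vector of spliced
#'   sequences), and the planting tables `cis_pairs`, `cis_decoys`,
#'   `trans_pairs`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "lnc_synth_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  n_total <- config$n_mrna + config$n_lncrna
  slots_per_chrom <- floor(.chrom_len / .slot_width)
  if (n_total > 2 * slots_per_chrom) {
    abort_sizing(paste0("chromosome capacity exceeded: n_mrna + n_lncrna = ",
                        n_total, " > ", 2 * slots_per_chrom, " slots"))
  }

  mrna_ids <- sprintf("mRNA_%04d", seq_len(config$n_mrna))
  lnc_ids <- sprintf("lnc_%04d", seq_len(config$n_lncrna))

  # slot assignment: chromosome then slot index, sampled without replacement
  all_slots <- tibble(
    chrom = rep(.chrom_names, each = slots_per_chrom),
    slot = rep(seq_len(slots_per_chrom), 2)
  )
  picked <- all_slots[sample.int(nrow(all_slots), n_total), ]

  # planted lncRNAs: first 2*n_cis are cis/decoy, next n_trans are trans
  n_cis <- config$n_cis_pairs
  n_trans <- config$n_trans_pairs
  cis_lnc <- lnc_ids[seq_len(n_cis)]
  decoy_lnc <- lnc_ids[n_cis + seq_len(n_cis)]
  trans_lnc <- lnc_ids[2 * n_cis + seq_len(n_trans)]
  partner_pool <- sample(mrna_ids, n_cis * 2 + n_trans)
  cis_partner <- partner_pool[seq_len(n_cis)]
  decoy_partner <- partner_pool[n_cis + seq_len(n_cis)]
  trans_partner <- partner_pool[2 * n_cis + seq_len(n_trans)]

  build <- function(ids, biotype, slot_rows) {
    purrr::map2_dfr(ids, seq_along(ids), function(id, i) {
      ne <- if (biotype == "mRNA") sample(4:12, 1) else sample(2:4, 1)
      er <- if (biotype == "mRNA") c(100, 300) else c(150, 400)
      slot_start <- (slot_rows$slot[i] - 1) * .slot_width + 1
      start <- slot_start + sample.int(.slot_width / 3, 1)
      ex <- .draw_exons(start, ne, er, c(200, 2000))
      tibble(
        transcript_id = id,
        gene_id = paste0("g_", id),
        chrom = slot_rows$chrom[i],
        start = min(ex$start), end = max(ex$end),
        strand = sample(c("+", "-"), 1),
        n_exons = ne,
        spliced_length = sum(ex$end - ex$start + 1),
        biotype = biotype,
        exons = list(ex)
      )
    })
  }

  mrna_rows <- picked[seq_len(config$n_mrna), ]
  lnc_rows <- picked[config$n_mrna + seq_len(config$n_lncrna), ]
  ann_m <- build(mrna_ids, "mRNA", mrna_rows)
  ann_l <- build(lnc_ids, "lncRNA", lnc_rows)

  # re-place cis lncRNAs next to their partners, decoys far from theirs
  place_near <- function(ann_l, lnc, partner, dist_range) {
    for (k in seq_along(lnc)) {
      p <- ann_m[ann_m$transcript_id == partner[k], ]
      i <- which(ann_l$transcript_id == lnc[k])
      d <- sample(seq(dist_range[1], dist_range[2]), 1)
      span <- ann_l$end[i] - ann_l$start[i]
      downstream <- p$end + d + span < .chrom_len
      new_start <- if (downstream) p$end + d else max(1, p$start - d - span)
      shift <- new_start - ann_l$start[i]
      ex <- ann_l$exons[[i]]
      ex$start <- ex$start + shift
      ex$end <- ex$end + shift
      ann_l$exons[[i]] <- ex
      ann_l$start[i] <- ann_l$start[i] + shift
      ann_l$end[i] <- ann_l$end[i] + shift
      ann_l$chrom[i] <- p$chrom
    }
    ann_l
  }
  if (n_cis > 0) {
    ann_l <- place_near(ann_l, cis_lnc, cis_partner, c(1000, 80000))
    ann_l <- place_near(ann_l, decoy_lnc, decoy_partner, c(150000, 300000))
  }
  # trans lncRNAs must not be incidental cis partners: move to other chrom
  if (n_trans > 0) {
    for (k in seq_along(trans_lnc)) {
      p_chrom <- ann_m$chrom[ann_m$transcript_id == trans_partner[k]]
      i <- which(ann_l$transcript_id == trans_lnc[k])
      ann_l$chrom[i] <- setdiff(.chrom_names, p_chrom)[1]
    }
  }

  ann <- bind_rows(ann_m, ann_l)

  seqs <- setNames(
    vapply(ann$spliced_length, rand_seq, character(1)),
    ann$transcript_id
  )
  # plant reverse complements
  trans_tbl <- tibble(lncRNA = character(0), mRNA = character(0),
                      lnc_offset = integer(0), mrna_offset = integer(0))
  if (n_trans > 0) {
    L <- config$complement_len
    for (k in seq_len(n_trans)) {
      ms <- seqs[[trans_partner[k]]]
      ls <- seqs[[trans_lnc[k]]]
      if (nchar(ms) < L || nchar(ls) < L) {
        abort_sizing("`complement_len` exceeds a transcript's spliced length")
      }
      mo <- sample.int(nchar(ms) - L + 1, 1)
      lo <- sample.int(nchar(ls) - L + 1, 1)
      seg <- revcomp(substr(ms, mo, mo + L - 1))
      substr(ls, lo, lo + L - 1) <- seg
      seqs[[trans_lnc[k]]] <- ls
      trans_tbl <- bind_rows(trans_tbl, tibble(
        lncRNA = trans_lnc[k], mRNA = trans_partner[k],
        lnc_offset = lo, mrna_offset = mo
      ))
    }
  }

  span_dist <- function(a, b) {
    ifelse(a$chrom != b$chrom, Inf,
           pmax(0, pmax(a$start, b$start) - pmin(a$end, b$end)))
  }
  pair_tbl <- function(lnc, partner) {
    purrr::map2_dfr(lnc, partner, function(l, m) {
      la <- ann[ann$transcript_id == l, ]
      ma <- ann[ann$transcript_id == m, ]
      tibble(lncRNA = l, mRNA = m, gene_id = ma$gene_id,
             distance = span_dist(la, ma))
    })
  }
  cis_tbl <- if (n_cis > 0) pair_tbl(cis_lnc, cis_partner) else
    tibble(lncRNA = character(0), mRNA = character(0),
           gene_id = character(0), distance = numeric(0))
  decoy_tbl <- if (n_cis > 0) pair_tbl(decoy_lnc, decoy_partner) else cis_tbl[0, ]

  list(annotation = ann, sequences = seqs,
       cis_pairs = cis_tbl, cis_decoys = decoy_tbl, trans_pairs = trans_tbl)
}

#' Generate negative-binomial counts with a latent disease progression
#'
#' Each sample carries a latent progression value `true_t` (controls 0, MCI
#' uniform on \[0.05, 0.45\], AD uniform on \[0.35, 1.0\]). A configured
#' fraction of transcripts shifts its log2 mean by `effect * true_t`;
#' pathway module members add a shared per-sample latent factor; planted
#' regulator lncRNAs (the cis and trans lncRNAs from the annotation) track
#' their partner gene's module factor. Counts are NB(mu, phi) with variance
#' `mu + phi mu^2`.
#'
#' @param config A [synthetic_config()].
#' @param ann Result of [generate_annotation()] for the same config.
#' @return List with `counts` (tibble, transcripts x samples), `samples`
#'   (tibble `sample_id`, `group`), and `truth` (ground-truth list).
#' @export
generate_counts <- function(config, ann) {
  stopifnot(inherits(config, "lnc_synth_config"))
  if (!is.list(ann) || is.null(ann$annotation) ||
      nrow(ann$annotation) != config$n_mrna + config$n_lncrna) {
    abort_arg("`ann` does not match `config` (transcript count mismatch)")
  }
  set.seed(derive_seed(config$seed, "counts"))
  a <- ann$annotation
  ids <- a$transcript_id
  n_total <- length(ids)

  samples <- tibble(
    sample_id = c(sprintf("C%03d", seq_len(config$n_control)),
                  sprintf("M%03d", seq_len(config$n_mci)),
                  sprintf("A%03d", seq_len(config$n_ad))),
    group = c(rep("control", config$n_control),
              rep("MCI", config$n_mci),
              rep("AD", config$n_ad))
  )
  # latent progression; redraw (bounded) until every MCI value sits strictly
  # below the AD median, the generator's stated stage-ordering invariant
  for (attempt in seq_len(100)) {
    t_mci <- runif(config$n_mci, 0.05, 0.45)
    t_ad <- runif(config$n_ad, 0.35, 1.0)
    if (max(t_mci) < median(t_ad)) break
  }
  true_t <- c(rep(0, config$n_control), t_mci, t_ad)

  # module membership: planted partners are forced into modules so their
  # regulator lncRNAs have a co-expressed pathway to be assigned to
  if (config$n_pathways * config$genes_per_pathway > config$n_mrna) {
    abort_sizing("`genes_per_pathway` * `n_pathways` exceeds `n_mrna`")
  }
  pathways <- sprintf("pathway_%02d", seq_len(config$n_pathways))
  forced <- unique(c(ann$cis_pairs$mRNA, ann$trans_pairs$mRNA))
  mrna_ids <- a$transcript_id[a$biotype == "mRNA"]
  pool <- sample(setdiff(mrna_ids, forced))
  membership <- tibble(
    transcript_id = forced,
    pathway = pathways[(seq_along(forced) - 1) %% config$n_pathways + 1]
  )
  need <- config$n_pathways * config$genes_per_pathway - nrow(membership)
  fill <- tibble(transcript_id = pool[seq_len(need)])
  open_slots <- unlist(lapply(pathways, function(p) {
    rep(p, config$genes_per_pathway - sum(membership$pathway == p))
  }))
  fill$pathway <- open_slots
  membership <- bind_rows(membership, fill) %>% arrange(pathway, transcript_id)

  # regulator lncRNAs track the module of their partner gene
  reg <- bind_rows(
    mutate(ann$cis_pairs[c("lncRNA", "mRNA")], mode = "cis"),
    mutate(ann$trans_pairs[c("lncRNA", "mRNA")], mode = "trans")
  )
  reg <- left_join(reg, membership, by = c(mRNA = "transcript_id")) %>%
    rename(target_gene = "mRNA")

  # per-transcript baselines and progression effects
  blr <- config$baseline_log_mean_range
  baseline <- runif(n_total, blr[1], blr[2])
  # regulator and decoy lncRNAs are excluded from the progression pool:
  # their expression is defined by their module factor (or pure noise for
  # decoys); a direct progression effect would confound the planted
  # cis/trans structure
  planted_lnc <- unique(c(ann$cis_pairs$lncRNA, ann$cis_decoys$lncRNA,
                          ann$trans_pairs$lncRNA))
  n_prog <- ceiling(config$frac_progression_transcripts * n_total)
  prog_ids <- sample(setdiff(ids, planted_lnc), n_prog)
  effect <- setNames(rep(0, n_total), ids)
  effect[prog_ids] <- sample(c(-1, 1), n_prog, replace = TRUE) *
    config$progression_effect * runif(n_prog, 0.5, 1)

  # pathway latent factors, N(0,1) per sample
  factors <- matrix(rnorm(nrow(samples) * config$n_pathways),
                    nrow = nrow(samples),
                    dimnames = list(samples$sample_id, pathways))

  loading <- matrix(0, nrow = n_total, ncol = config$n_pathways,
                    dimnames = list(ids, pathways))
  loading[cbind(membership$transcript_id, membership$pathway)] <- config$module_loading
  if (nrow(reg)) {
    loading[cbind(reg$lncRNA, reg$pathway)] <- config$module_loading
  }

  log2mu <- matrix(baseline, n_total, nrow(samples),
                   dimnames = list(ids, samples$sample_id)) +
    outer(effect[ids], true_t) + loading %*% t(factors)
  mu <- 2^log2mu
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                nrow = n_total, dimnames = dimnames(mu))

  truth <- list(
    true_t = mutate(samples, true_t = true_t),
    progression_transcripts = tibble(transcript_id = prog_ids,
                                     effect = unname(effect[prog_ids])),
    pathway_factors = factors,
    module_membership = membership,
    cis_pairs = ann$cis_pairs, cis_decoys = ann$cis_decoys,
    trans_pairs = ann$trans_pairs,
    regulators = reg
  )
  out <- list(counts = counts_tibble(cnt), samples = samples, truth = truth)
  audit_ground_truth(config, ann, out)
  out
}

#' Audit planted ground truth after generation
#'
#' Re-checks every structural promise of the generator: MCI progression
#' values below the AD median, cis pairs within / decoys beyond the 100 kb
#' window, planted reverse-complement segments present, module membership
#' sized as configured.
#'
#' @param config,ann,sim The generator's config, annotation and counts output.
#' @return `TRUE` invisibly; aborts on any violated promise.
#' @export
audit_ground_truth <- function(config, ann, sim) {
  tr <- sim$truth
  tt <- tr$true_t
  if (!all(tt$true_t[tt$group == "control"] == 0)) {
    abort("audit: control true_t not all zero")
  }
  if (max(tt$true_t[tt$group == "MCI"]) >= median(tt$true_t[tt$group == "AD"])) {
    abort("audit: an MCI true_t is not below the AD median")
  }
  if (nrow(tr$cis_pairs) && any(tr$cis_pairs$distance > 100000)) {
    abort("audit: a planted cis pair exceeds the 100 kb window")
  }
  if (nrow(tr$cis_decoys) && any(tr$cis_decoys$distance <= 100000)) {
    abort("audit: a cis decoy lies inside the 100 kb window")
  }
  if (nrow(tr$trans_pairs)) {
    for (k in seq_len(nrow(tr$trans_pairs))) {
      l <- ann$sequences[[tr$trans_pairs$lncRNA[k]]]
      m <- ann$sequences[[tr$trans_pairs$mRNA[k]]]
      mo <- tr$trans_pairs$mrna_offset[k]
      seg <- revcomp(substr(m, mo, mo + config$complement_len - 1))
      if (!grepl(seg, l, fixed = TRUE)) {
        abort("audit: planted reverse-complement segment missing")
      }
    }
  }
  tab <- table(tr$module_membership$pathway)
  if (length(tab) != config$n_pathways ||
      any(tab != config$genes_per_pathway)) {
    abort("audit: module membership sizes disagree with config")
  }
  invisible(TRUE)
}

#' Build the pathway catalog (true modules plus decoy sets)
#'
#' Emits one gene set per planted module (its mRNA members) and an equal
#' number of decoy sets of random mRNAs, each labelled with one of the six
#' functional categories used by the per-bin summaries.
#'
#' @param config A [synthetic_config()].
#' @param sim Result of [generate_counts()].
#' @return List of class `lnc_catalog` with `sets` (named list of character
#'   vectors) and `categories` (named character vector).
#' @export
generate_pathways <- function(config, sim) {
  set.seed(derive_seed(config$seed, "pathways"))
  mem <- sim$truth$module_membership
  sets <- split(mem$transcript_id, mem$pathway)
  mrna_pool <- setdiff(
    grep("^mRNA_", sim$counts$transcript_id, value = TRUE),
    mem$transcript_id
  )
  for (k in seq_len(config$n_pathways)) {
    sets[[sprintf("decoy_%02d", k)]] <- sample(mrna_pool, config$genes_per_pathway)
  }
  cats <- setNames(
    pathway_categories()[(seq_along(sets) - 1) %% 6 + 1],
    names(sets)
  )
  structure(list(sets = sets, categories = cats), class = "lnc_catalog")
}

#' The six functional categories used to summarise enriched pathways
#' @return Character vector of the six category names.
#' @export
pathway_categories <- function() {
  c("immune activities", "metabolism", "stress response",
    "development-related", "cell polarity", "neural functions")
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_annotation()],
#' [generate_counts()] and [generate_pathways()].
#'
#' @param config A [synthetic_config()].
#' @return List with `annotation`, `sequences`, `counts`, `samples`,
#'   `truth`, `catalog` and the `config` used.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  ann <- generate_annotation(config)
  sim <- generate_counts(config, ann)
  catalog <- generate_pathways(config, sim)
  list(annotation = ann$annotation, sequences = ann$sequences,
       counts = sim$counts, samples = sim$samples, truth = sim$truth,
       catalog = catalog, config = config)
}

#' Fabricate coding-potential verdicts for a synthetic annotation
#'
#' Stands in for running CPC/CNCI/CPAT/PLEK/CPPred: true lncRNAs receive
#' five noncoding verdicts; mRNAs receive coding verdicts, except a small
#' fraction given four noncoding calls and one coding call to exercise the
#' unanimity rule downstream.
#'
#' @param config A [synthetic_config()].
#' @param annotation Annotation tibble from [generate_annotation()].
#' @param near_miss_frac Fraction of mRNAs with a 4/5 noncoding near-miss.
#' @return Tibble `transcript_id` plus columns `cpc`, `cnci`, `cpat`,
#'   `plek`, `cppred` with values `"coding"`/`"noncoding"`.
#' @export
generate_coding_calls <- function(config, annotation, near_miss_frac = 0.05) {
  set.seed(derive_seed(config$seed, "coding_calls"))
  tools <- c("cpc", "cnci", "cpat", "plek", "cppred")
  out <- tibble(transcript_id = annotation$transcript_id)
  is_lnc <- annotation$biotype == "lncRNA"
  verdicts <- matrix("coding", nrow(annotation), 5,
                     dimnames = list(NULL, tools))
  verdicts[is_lnc, ] <- "noncoding"
  near <- which(!is_lnc & runif(nrow(annotation)) < near_miss_frac)
  for (i in near) {
    keep <- sample(5, 1)
    verdicts[i, -keep] <- "noncoding"
  }
  bind_cols(out, as_tibble(verdicts))
}
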