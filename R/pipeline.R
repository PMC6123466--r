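#' Run the full analysis pipeline
#'
#' End-to-end orchestration: (optionally) generate a synthetic cohort with
#' reference panels and a knowledge base, apply sample coverage QC and the
#' somatic filtering cascade, compute per-gene recurrence and hotspot
#' enrichment, subtype association and co-occurrence tests, the VAF
#' germline-suspicion report, gated univariate and multivariate survival
#' screens with min-p permutation adjustment, and the two-gene analysis.
#' Every stage writes its table under `out_dir` and a run manifest records
#' input checksums, seeds and telescoping per-stage counts.  Given the
#' same config and seed the output tree is byte-identical across runs.
#'
#' @param config a `run_config` from [load_config()], or `NULL` for
#'   defaults.
#' @param out_dir output directory.
#' @param seed root seed (overrides the generator config seed).
#' @param synthetic generate inputs with the synthetic module (`TRUE`) or
#'   read them from `input_dir`.
#' @param input_dir directory holding `variants.maf`, `clinical.tsv`,
#'   `survival.tsv`, `coverage.tsv`, `targets.bed` and `panels/` when
#'   `synthetic = FALSE`.
#' @return the run manifest, invisibly.
#' @export
run_all <- function(config = NULL, out_dir, seed = NULL, synthetic = TRUE,
                    input_dir = NULL) {
  if (is.null(config)) config <- load_config(NULL)
  if (!inherits(config, "run_config")) stop("config must come from load_config()")
  if (!is.null(seed)) config$generator$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  counts <- list()
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- inputs --------------------------------------------------------------
  if (synthetic) {
    note("generating synthetic cohort (n = ", config$generator$n_samples,
         ", seed = ", config$generator$seed, ")")
    gcfg <- do.call(generator_config, as.list(config$generator))
    cohort <- generate_cohort(gcfg)
    panels <- generate_reference_panels(cohort)
    kbgen <- generate_knowledge_base(cohort)
    multistudy <- generate_multistudy_maf(gcfg)
    variants <- cohort$variants
    clinical <- cohort$clinical
    surv <- cohort$survival
    coverage <- cohort$coverage
    regions <- cohort$regions
    kb <- kbgen$kb; kb_rc <- kbgen$readcounts
    write_cohort(cohort, file.path(out_dir, "inputs"), panels = panels)
    if (!is.null(kb) && nrow(kb)) {
      write_tsv(kb, file.path(out_dir, "inputs", "knowledge_base.tsv"))
      write_tsv(kb_rc, file.path(out_dir, "inputs", "kb_readcounts.tsv"))
    }
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("input directory not found: ", input_dir %||% "<NULL>")
    }
    pdir <- file.path(input_dir, "panels")
    if (!dir.exists(pdir)) stop("missing panels directory: ", pdir)
    variants <- read_maf(file.path(input_dir, "variants.maf"))
    clinical <- read_clinical(file.path(input_dir, "clinical.tsv"))
    surv <- read_survival(file.path(input_dir, "survival.tsv"))
    coverage <- read.delim(file.path(input_dir, "coverage.tsv"), sep = "\t")
    regions <- read_bed(file.path(input_dir, "targets.bed"))
    panels <- read_panels(pdir)
    kbf <- file.path(input_dir, "knowledge_base.tsv")
    kb <- if (file.exists(kbf)) read_knowledge_base(kbf) else NULL
    kcf <- file.path(input_dir, "kb_readcounts.tsv")
    kb_rc <- if (file.exists(kcf)) {
      read.delim(kcf, sep = "\t", stringsAsFactors = FALSE,
                 colClasses = c(chrom = "character", ref = "character",
                                alt = "character"))
    } else NULL
    multistudy <- NULL
    cohort <- NULL
  }
  counts$variants_in <- nrow(variants)

  # --- QC + filtering ------------------------------------------------------
  qc <- sample_coverage_qc(coverage, config$thresholds)
  pass_ids <- qc$sample_id[qc$pass]
  note(sum(!qc$pass), " sample(s) failed coverage QC; ", length(pass_ids),
       " analyzable")
  variants <- variants[variants$sample_id %in% pass_ids, , drop = FALSE]
  counts$variants_post_qc <- nrow(variants)

  fres <- run_filter_cascade(variants, panels, regions = regions, kb = kb,
                             kb_readcounts = kb_rc,
                             thresholds = config$thresholds)
  fres$variants <- fres$variants[fres$variants$sample_id %in% pass_ids, ,
                                 drop = FALSE]
  counts$variants_retained <- nrow(fres$variants)
  note("filter cascade: ", counts$variants_post_qc, " -> ",
       counts$variants_retained, " retained")
  write_maf(fres$variants, file.path(out_dir, "filtered.maf"))
  write_tsv(fres$trace, file.path(out_dir, "filter_trace.tsv"))
  write_tsv(fres$summary, file.path(out_dir, "filter_summary.tsv"))

  retained <- fres$variants
  n_samples <- length(pass_ids)

  # --- recurrence + hotspots ----------------------------------------------
  recur <- gene_recurrence_table(retained, "non_silent", n_samples)
  write_tsv(recur, file.path(out_dir, "gene_recurrence.tsv"))
  counts$genes_with_carriers <- nrow(recur)

  mrate <- tapply(rep(1, nrow(assign_class_sets(retained, "non_silent"))),
                  assign_class_sets(retained, "non_silent")$sample_id, sum)
  m <- integer(n_samples); names(m) <- pass_ids
  m[names(mrate)] <- as.integer(mrate)
  mpmb <- mutations_per_mb(as.vector(m),
                           correction = if (!is.null(cohort))
                             cohort$truth$mpmb_correction else 1)
  mpmb$sample_id <- pass_ids
  write_tsv(mpmb[, c("sample_id", "m", "rate_per_mb", "excluded")],
            file.path(out_dir, "mutations_per_mb.tsv"))

  if (!is.null(multistudy)) {
    hs <- find_hotspots(assign_class_sets(retained, "non_silent"),
                        multistudy, n_study = n_samples,
                        q_level = config$analysis$hotspot_q_level)
    write_tsv(as.data.frame(hs), file.path(out_dir, "hotspots.tsv"))
    counts$hotspot_positions_tested <- nrow(hs)
  }

  # --- association ---------------------------------------------------------
  cl <- clinical[match(pass_ids, clinical$sample_id), , drop = FALSE]
  assoc_rows <- list()
  for (pol in config$analysis$policies) {
    mm <- build_mutation_matrix(retained, pass_ids, pol)
    for (g in colnames(mm)) {
      known <- cl$subtype != "unknown"
      if (sum(mm[known, g]) >= 3 && length(unique(cl$subtype[known])) >= 2) {
        r <- tryCatch(
          test_categorical_association(mm[known, g], cl$subtype[known],
                                       gene = g, covariate = "subtype"),
          error = function(e) NULL)
        if (!is.null(r)) { r$policy <- pol; assoc_rows[[length(assoc_rows) + 1]] <- r }
      }
    }
  }
  if (length(assoc_rows)) {
    assoc <- do.call(rbind, assoc_rows)
    # one BH family per (policy x covariate)
    assoc$q <- NA_real_
    for (pol in unique(assoc$policy)) {
      i <- assoc$policy == pol
      assoc$q[i] <- bh_adjust(assoc$p[i])
    }
    write_tsv(assoc, file.path(out_dir, "subtype_associations.tsv"))
    counts$subtype_tests <- nrow(assoc)
  }

  mm_ns <- build_mutation_matrix(retained, pass_ids, "non_silent")
  if (ncol(mm_ns) >= 2) {
    co <- pairwise_cooccurrence(mm_ns, config$analysis$cooccurrence_top_k)
    write_tsv(co, file.path(out_dir, "cooccurrence.tsv"))
    counts$cooccurrence_pairs <- nrow(co)
  }

  vs <- vaf_germline_suspicion(retained)
  write_tsv(vs$per_gene, file.path(out_dir, "vaf_suspicion_per_gene.tsv"))
  write_tsv(vs$overall, file.path(out_dir, "vaf_suspicion_overall.tsv"))

  # --- survival screens ----------------------------------------------------
  screens <- list()
  for (pol in c("non_silent", "fs_ns")) {
    mm <- build_mutation_matrix(retained, pass_ids, pol)
    for (ep in intersect(config$analysis$endpoints, unique(surv$endpoint))) {
      uni <- univariate_screen(mm, surv, endpoint = ep, policy = pol,
                               ties = config$analysis$ties)
      multi <- multivariate_screen(mm, surv, cl, endpoint = ep, policy = pol,
                                   split_at = config$analysis$split_at,
                                   ties = config$analysis$ties)
      gated <- multi$gene[multi$gate == "tested"]
      if (length(gated) >= 1 && config$analysis$permutations >= 1) {
        padj <- permutation_adjust(
          mm[, gated, drop = FALSE], surv, clinical = cl, endpoint = ep,
          B = config$analysis$permutations,
          seed = child_seed(config$generator$seed, paste0("perm_", pol, "_", ep)),
          split_at = config$analysis$split_at, ties = config$analysis$ties)
        multi$p_adjusted <- padj$p_adjusted[match(multi$gene, padj$gene)]
      } else {
        multi$p_adjusted <- NA_real_
      }
      tag <- paste0(pol, "_", ep)
      write_tsv(as.data.frame(uni), file.path(out_dir,
                                              paste0("screen_uni_", tag, ".tsv")))
      write_tsv(as.data.frame(multi), file.path(out_dir,
                                                paste0("screen_multi_", tag, ".tsv")))
      screens[[tag]] <- list(uni = uni, multi = multi)
    }
  }
  counts$screens <- length(screens)

  if (all(c("MAP3K1", "PIK3CA") %in% colnames(mm_ns)) &&
      any(mm_ns[, "MAP3K1"]) && any(mm_ns[, "PIK3CA"])) {
    tg <- two_gene_analysis(mm_ns, surv, endpoint = "BCSS")
    write_tsv(tg$table, file.path(out_dir, "two_gene_groups.tsv"))
    write_tsv(data.frame(statistic = tg$logrank$statistic,
                         df = tg$logrank$df, p = tg$logrank$p),
              file.path(out_dir, "two_gene_logrank.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  cfg_file <- file.path(out_dir, "resolved_config.yaml")
  yaml::write_yaml(cfg_to_plain(config), cfg_file)
  input_files <- list.files(file.path(out_dir, "inputs"), recursive = TRUE,
                            full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tumoronly")),
    seed = config$generator$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    input_md5 = as.list(setNames(unname(tools::md5sum(input_files)),
                                 basename(input_files))),
    counts = counts,
    filter_summary = as.list(setNames(fres$summary$n, fres$summary$stage)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  )
  jsonlite::write_json(manifest[setdiff(names(manifest), "elapsed_s")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}

#' Build bundled test cohorts
#'
#' `tiny` is a 12-sample / 3-gene cohort small enough to check the filter
#' cascade by hand; `small` is a 400-sample / 20-gene cohort sized for
#' statistical tests.  Regeneration with the pinned seed is byte-identical.
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir optional output directory to write the cohort to.
#' @return list with `cohort`, `panels`, `config` (and files under `dir`
#'   when given).
#' @export
make_fixtures <- function(size = c("tiny", "small"), dir = NULL) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    g <- default_gene_panel()[c(1, 2, 4), ]  # PIK3CA, TP53, MAP3K1
    g$p_mut <- c(0.5, 0.3, 0.25)
    generator_config(n_samples = 12, genes = g, germline_rate = 1,
                     artifact_rate = 2, seed = 424243L)
  } else {
    g <- default_gene_panel()
    g2 <- g
    g2$gene <- paste0(g$gene, "B")
    g2$hotspot_pos <- NA
    g2$hotspot_share <- 0
    g <- rbind(g, g2[seq_len(8), ])
    generator_config(n_samples = 400, genes = g, seed = 424244L)
  }
  cohort <- generate_cohort(cfg)
  panels <- generate_reference_panels(cohort)
  if (!is.null(dir)) write_cohort(cohort, dir, panels = panels)
  list(cohort = cohort, panels = panels, config = cfg)
}
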