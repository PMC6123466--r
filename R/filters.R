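#' Restrict variants to target regions
#'
#' Keeps a variant iff its position falls within any target region
#' (1-based inclusive on both ends).  Overlapping regions are merged per
#' chromosome before testing.
#'
#' @param variants a variant table.
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return the subset of `variants` inside the targets.
#' @export
restrict_to_targets <- function(variants, regions) {
  if (is.null(regions) || nrow(regions) == 0) stop("empty target region set")
  keep <- logical(nrow(variants))
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    # merge overlapping/adjacent intervals
    merged_start <- r$start[1]; merged_end <- r$end[1]
    ms <- integer(0); me <- integer(0)
    if (nrow(r) > 1) {
      for (i in 2:nrow(r)) {
        if (r$start[i] <= merged_end + 1L) {
          merged_end <- max(merged_end, r$end[i])
        } else {
          ms <- c(ms, merged_start); me <- c(me, merged_end)
          merged_start <- r$start[i]; merged_end <- r$end[i]
        }
      }
    }
    ms <- c(ms, merged_start); me <- c(me, merged_end)
    vi <- which(variants$chrom == ch)
    if (!length(vi)) next
    j <- findInterval(variants$pos[vi], ms)
    keep[vi] <- j >= 1 & variants$pos[vi] <= me[pmax(j, 1)]
  }
  variants[keep, , drop = FALSE]
}

# panel lookup helpers ------------------------------------------------------

panel_maf_max <- function(variants, panels) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  pm <- panels$population_maf
  if (!nrow(pm)) return(rep(0, nrow(variants)))
  pkey <- variant_key(pm$chrom, pm$pos, pm$ref, pm$alt)
  m <- match(key, pkey)
  maf <- pmax(pm$maf_1kg[m], pm$maf_nhlbi[m], pm$maf_exac[m])
  maf[is.na(maf)] <- 0  # absence from the resources means MAF 0
  maf
}

normal_call_count <- function(variants, panels) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  nc <- panels$normal_calls
  if (!nrow(nc)) return(rep(0L, nrow(variants)))
  m <- match(key, variant_key(nc$chrom, nc$pos, nc$ref, nc$alt))
  cnt <- nc$n_called[m]
  cnt[is.na(cnt)] <- 0L
  cnt
}

# number of panel samples with qualifying evidence per cascade site
panel_evidence_count <- function(variants, panel, thresholds) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (!nrow(panel)) return(rep(0L, nrow(variants)))
  ev <- panel$var_reads >= thresholds$panel_min_var_reads &
    panel$depth >= thresholds$panel_min_depth &
    panel$var_reads / pmax(panel$depth, 1L) >= thresholds$panel_min_vaf
  pk <- variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  tab <- tapply(ev, pk, sum)
  cnt <- as.integer(tab[key])
  cnt[is.na(cnt)] <- 0L
  cnt
}

#' Filter on population minor allele frequency
#'
#' Removes a variant iff its minor allele frequency exceeds
#' `pop_maf_max` (default 0.1%, strictly greater) in any of the three
#' population resources.  Absence from the table is informative: it means
#' MAF 0 and the variant is retained.
#'
#' @param variants a variant table.
#' @param panels a `reference_panels` list.
#' @param thresholds a [default_thresholds()] list.
#' @return list with `variants` (retained rows) and `trace` (per-variant
#'   stage record).
#' @export
filter_population_frequency <- function(variants, panels,
                                        thresholds = default_thresholds()) {
  maf <- panel_maf_max(variants, panels)
  pass <- !(maf > thresholds$pop_maf_max)
  stage_result(variants, pass, "population_maf", maf)
}

#' Filter on unmatched-normal call counts
#'
#' Removes a variant iff it was called in `normal_call_min` (default 10)
#' or more of the unmatched normal samples.
#'
#' @inheritParams filter_population_frequency
#' @return list with `variants` and `trace`.
#' @export
filter_unmatched_normal_calls <- function(variants, panels,
                                          thresholds = default_thresholds()) {
  cnt <- normal_call_count(variants, panels)
  pass <- cnt < thresholds$normal_call_min
  stage_result(variants, pass, "normal_calls", cnt)
}

#' Filter on read-count panels of normals
#'
#' A panel sample "has evidence" of a variant iff it shows at least 3
#' supporting reads, at least 1% VAF and at least 20x coverage.  In
#' `exome` mode a variant is removed iff the fraction of panel samples with
#' evidence is at least `exome_panel_frac` (default 1%) of the panel size;
#' in `genome` mode iff the evidence count is at least
#' `genome_panel_count` (default 2).
#'
#' @inheritParams filter_population_frequency
#' @param mode `"exome"` or `"genome"`.
#' @return list with `variants` and `trace`.
#' @export
filter_readcount_panel <- function(variants, panels, mode,
                                   thresholds = default_thresholds()) {
  if (!mode %in% c("exome", "genome")) stop("unknown panel mode: ", mode)
  if (mode == "exome") {
    cnt <- panel_evidence_count(variants, panels$exome_panel, thresholds)
    frac <- cnt / panels$n2
    pass <- frac < thresholds$exome_panel_frac
    stage_result(variants, pass, "exome_panel", frac)
  } else {
    cnt <- panel_evidence_count(variants, panels$genome_panel, thresholds)
    pass <- cnt < thresholds$genome_panel_count
    stage_result(variants, pass, "genome_panel", cnt)
  }
}

#' Binomial log-likelihood-ratio somatic classifier
#'
#' Scores the supporting-read evidence of each variant against a
#' sequencing-error null: `llr = ln Binom(x; n, x/n) - ln Binom(x; n,
#' p_err)`, which simplifies to `n * KL(x/n || p_err)` in natural-log
#' units.  A variant is kept iff its LLR is at least `llr_snv` (default
#' 10) for SNV/DNP or at least `llr_indel` (default 6) for indels; smaller
#' values mean the read support is consistent with sequencing error and
#' the variant is not predicted to be somatic.
#'
#' @param variants a variant table (needs `var_reads`, `depth`,
#'   `variant_type`).
#' @param thresholds a [default_thresholds()] list (`p_err` default 0.005).
#' @return list with `variants`, `trace`, and numeric vector `llr`.
#' @export
classify_somatic_llr <- function(variants, thresholds = default_thresholds()) {
  if (any(variants$depth <= 0)) stop("depth must be positive for the LLR classifier")
  llr <- binom_llr(variants$var_reads, variants$depth, thresholds$p_err)
  thr <- ifelse(variants$variant_type %in% c("INS", "DEL"),
                thresholds$llr_indel, thresholds$llr_snv)
  pass <- llr >= thr  # "less than threshold" is eliminated; equality kept
  out <- stage_result(variants, pass, "llr_classifier", llr)
  out$llr <- llr
  out
}

# n * KL(phat || p_err) with the 0 log 0 = 0 convention; vectorized
binom_llr <- function(x, n, p_err) {
  phat <- x / n
  t1 <- ifelse(x == 0, 0, x * log(phat / p_err))
  t2 <- ifelse(x == n, 0, (n - x) * log((1 - phat) / (1 - p_err)))
  t1 + t2
}

stage_result <- function(variants, pass, stage, metric) {
  trace <- data.frame(
    key = sample_variant_key(variants$sample_id, variants$chrom,
                             variants$pos, variants$ref, variants$alt),
    stage = stage,
    pass = pass,
    metric = as.numeric(metric),
    stringsAsFactors = FALSE
  )
  list(variants = variants[pass, , drop = FALSE], trace = trace)
}

#' Rescue known actionable variants from read-count evidence
#'
#' Scans per-sample read counts at knowledge-base sites and emits a call
#' wherever at least 5 reads support the variant with at least 1% VAF and
#' at least 20x total coverage.  Rescued calls are exempt from the LLR
#' classifier.  Sites with no read-count data are skipped with a warning.
#'
#' @param kb_readcounts data.frame of per-sample read counts at
#'   knowledge-base sites (`sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `protein_change`, `var_reads`, `depth`).
#' @param kb the knowledge-base site table ([read_knowledge_base()]).
#' @param thresholds a [default_thresholds()] list.
#' @return a variant table of rescued calls (possibly 0 rows), with
#'   `consequence_class` `"missense"` unless provided.
#' @export
rescue_known_hotspots <- function(kb_readcounts, kb,
                                  thresholds = default_thresholds()) {
  empty <- data.frame(sample_id = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      variant_type = character(),
                      consequence_class = character(),
                      protein_change = character(), var_reads = integer(),
                      depth = integer(), vaf = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(kb) || nrow(kb) == 0) return(empty)
  if (is.null(kb_readcounts) || nrow(kb_readcounts) == 0) {
    warning("no read-count data at any knowledge-base site; nothing rescued")
    return(empty)
  }
  kb_key <- variant_key(kb$chrom, kb$pos, kb$ref, kb$alt)
  rc_key <- variant_key(kb_readcounts$chrom, kb_readcounts$pos,
                        kb_readcounts$ref, kb_readcounts$alt)
  missing_sites <- setdiff(kb_key, rc_key)
  if (length(missing_sites)) {
    warning(length(missing_sites),
            " knowledge-base site(s) lack read-count data; skipped")
  }
  rc <- kb_readcounts[rc_key %in% kb_key, , drop = FALSE]
  vaf <- rc$var_reads / pmax(rc$depth, 1L)
  called <- rc$var_reads >= thresholds$rescue_min_var_reads &
    vaf >= thresholds$rescue_min_vaf &
    rc$depth >= thresholds$rescue_min_depth
  rc <- rc[called, , drop = FALSE]
  if (!nrow(rc)) return(empty)
  data.frame(sample_id = rc$sample_id, gene = rc$gene, chrom = rc$chrom,
             pos = rc$pos, ref = rc$ref, alt = rc$alt,
             variant_type = ifelse(nchar(rc$ref) == nchar(rc$alt), "SNV",
                                   ifelse(nchar(rc$ref) < nchar(rc$alt),
                                          "INS", "DEL")),
             consequence_class = "missense",
             protein_change = rc$protein_change,
             var_reads = rc$var_reads, depth = rc$depth,
             vaf = rc$var_reads / rc$depth,
             stringsAsFactors = FALSE)
}

#' Variant-class policies
#'
#' Returns the consequence-class sets behind the four carrier policies:
#' `non_silent` (missense, nonsense, frameshift, in-frame indel, proximal
#' splice site, plus RNA-gene variants for whitelisted genes — by default
#' MALAT1), `missense`, `fs_ns` (frameshift or nonsense, the truncating
#' set) and `fs_ns_splice` (truncating plus splice site).  Splice-region,
#' UTR, intronic, silent and non-whitelisted RNA variants are never
#' included.
#'
#' @param name policy name.
#' @param rna_whitelist genes whose RNA variants count as non-silent.
#' @return list with `name`, `classes`, `rna_whitelist`.
#' @export
class_policy <- function(name = c("non_silent", "missense", "fs_ns",
                                  "fs_ns_splice"),
                         rna_whitelist = "MALAT1") {
  name <- match.arg(name)
  classes <- switch(name,
    non_silent   = c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice_site"),
    missense     = "missense",
    fs_ns        = c("frameshift", "nonsense"),
    fs_ns_splice = c("frameshift", "nonsense", "splice_site")
  )
  list(name = name, classes = classes,
       rna_whitelist = if (name == "non_silent") rna_whitelist else character(0))
}

#' Subset variants to a class policy
#'
#' @param variants a variant table.
#' @param policy a [class_policy()] or policy name.
#' @return the qualifying subset of `variants`.
#' @export
assign_class_sets <- function(variants, policy = "non_silent") {
  if (is.character(policy)) policy <- class_policy(policy)
  keep <- variants$consequence_class %in% policy$classes |
    (variants$consequence_class == "rna" &
       variants$gene %in% policy$rna_whitelist)
  variants[keep, , drop = FALSE]
}

#' Run the tumor-only somatic filtering cascade
#'
#' Applies the fixed-order cascade: target restriction, population MAF,
#' unmatched-normal call counts, exome read-count panel, genome read-count
#' panel, and the binomial LLR classifier; knowledge-base rescue is applied
#' last and merged in.  For auditability every stage is evaluated for every
#' variant that passed target restriction (no short-circuiting); a
#' variant's final status cites the first failing stage.  Rescued calls
#' carry status `"rescued"` and are exempt from the LLR stage.
#'
#' @param variants a variant table.
#' @param panels a `reference_panels` list.
#' @param regions target regions (1-based inclusive), or `NULL` to skip
#'   target restriction.
#' @param kb,kb_readcounts knowledge base and per-sample read counts at its
#'   sites, or `NULL` to skip rescue.
#' @param thresholds a [default_thresholds()] list.
#' @return list of class `filter_result` with `variants` (retained +
#'   rescued), `trace` (long per-variant stage table), `status`
#'   (per-variant final status) and `summary` (per-stage counts).
#' @export
run_filter_cascade <- function(variants, panels, regions = NULL,
                               kb = NULL, kb_readcounts = NULL,
                               thresholds = default_thresholds()) {
  validate_variants(variants)
  n_input <- nrow(variants)
  if (!is.null(regions)) {
    on_target <- restrict_to_targets(variants, regions)
  } else {
    on_target <- variants
  }
  key_all <- sample_variant_key(variants$sample_id, variants$chrom,
                                variants$pos, variants$ref, variants$alt)
  key_on <- sample_variant_key(on_target$sample_id, on_target$chrom,
                               on_target$pos, on_target$ref, on_target$alt)
  target_trace <- data.frame(key = key_all, stage = "target_restriction",
                             pass = key_all %in% key_on, metric = NA_real_,
                             stringsAsFactors = FALSE)

  stages <- list(
    function(v) filter_population_frequency(v, panels, thresholds),
    function(v) filter_unmatched_normal_calls(v, panels, thresholds),
    function(v) filter_readcount_panel(v, panels, "exome", thresholds),
    function(v) filter_readcount_panel(v, panels, "genome", thresholds),
    function(v) classify_somatic_llr(v, thresholds)
  )
  # every stage is evaluated on everything that reached the cascade
  traces <- list(target_trace)
  pass_mat <- matrix(TRUE, nrow(on_target), length(stages))
  colnames(pass_mat) <- c("population_maf", "normal_calls", "exome_panel",
                          "genome_panel", "llr_classifier")
  for (s in seq_along(stages)) {
    res <- stages[[s]](on_target)
    traces[[length(traces) + 1L]] <- res$trace
    pass_mat[, s] <- res$trace$pass
  }
  retained <- on_target[rowSums(!pass_mat) == 0, , drop = FALSE]

  # final status: first failing stage
  first_fail <- apply(pass_mat, 1, function(p) {
    f <- which(!p)
    if (length(f)) colnames(pass_mat)[f[1]] else NA_character_
  })
  status <- data.frame(
    key = key_on,
    status = ifelse(is.na(first_fail), "retained",
                    paste0("removed:", first_fail)),
    stringsAsFactors = FALSE
  )
  off <- setdiff(key_all, key_on)
  if (length(off)) {
    status <- rbind(status,
                    data.frame(key = off, status = "removed:target_restriction",
                               stringsAsFactors = FALSE))
  }

  rescued <- rescue_known_hotspots(kb_readcounts, kb, thresholds)
  if (nrow(rescued)) {
    rkey <- sample_variant_key(rescued$sample_id, rescued$chrom, rescued$pos,
                               rescued$ref, rescued$alt)
    new <- !rkey %in% sample_variant_key(retained$sample_id, retained$chrom,
                                         retained$pos, retained$ref,
                                         retained$alt)
    add <- rescued[new, , drop = FALSE]
    retained <- rbind(retained[, names(add)], add)
    status$status[status$key %in% rkey[new]] <- "rescued"
    extra <- setdiff(rkey[new], status$key)
    if (length(extra)) {
      status <- rbind(status, data.frame(key = extra, status = "rescued",
                                         stringsAsFactors = FALSE))
    }
  }

  trace <- do.call(rbind, traces)
  summary <- data.frame(
    stage = c("input", "target_restriction", colnames(pass_mat), "rescued",
              "retained"),
    n = c(n_input, nrow(on_target),
          vapply(seq_len(ncol(pass_mat)), function(s) {
            sum(rowSums(!pass_mat[, seq_len(s), drop = FALSE]) == 0)
          }, integer(1)),
          sum(status$status == "rescued"),
          nrow(retained)),
    stringsAsFactors = FALSE
  )
  structure(list(variants = retained, trace = trace, status = status,
                 summary = summary, thresholds = thresholds),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Tumor-only somatic filter cascade\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-20s %d\n", x$summary$stage[i], x$summary$n[i]))
  }
  invisible(x)
}

#' Per-sample sequencing coverage QC
#'
#' A sample passes iff the fraction of targeted bases covered above the QC
#' depth is at least `qc_min_frac` (default 0.80 at > 20x).  Failing
#' samples must be excluded from all downstream analyses.
#'
#' @param coverage data.frame with `sample_id` and `frac_bases_gt20` in
#'   \[0,1\].
#' @param thresholds a [default_thresholds()] list.
#' @return data.frame with `sample_id`, `frac_bases_gt20`, `pass`.
#' @export
sample_coverage_qc <- function(coverage, thresholds = default_thresholds()) {
  if (is.null(coverage) || nrow(coverage) == 0) {
    stop("missing per-sample coverage summary")
  }
  if (any(coverage$frac_bases_gt20 < 0 | coverage$frac_bases_gt20 > 1)) {
    stop("coverage fractions must be in [0,1]")
  }
  pass <- coverage$frac_bases_gt20 >= thresholds$qc_min_frac
  if (!any(pass)) stop("no analyzable samples: all failed coverage QC")
  data.frame(sample_id = coverage$sample_id,
             frac_bases_gt20 = coverage$frac_bases_gt20,
             pass = pass, stringsAsFactors = FALSE)
}

#' Mutations per megabase
#'
#' `rate = correction * m / (L / 1e6)` where `m` is the sample's mutation
#' count, `L` the tiled target length in bp, and `correction >= 1`
#' accounts for genes not assayed.  Samples with zero mutations get rate 0
#' and are flagged for exclusion from cohort range summaries.
#'
#' @param m integer vector of per-sample mutation counts.
#' @param L tiled target length in bp (default 362572, the unique tiled
#'   space of the 83-gene capture design).
#' @param correction correction factor (>= 1).
#' @return data.frame with `m`, `rate_per_mb`, `excluded`.
#' @export
#' @examples
#' mutations_per_mb(1, L = 362572)  # 2.758 per MB
mutations_per_mb <- function(m, L = 362572, correction = 1) {
  if (L <= 0) stop("tiled length L must be positive")
  if (correction < 1) stop("correction factor must be >= 1")
  if (any(m < 0)) stop("mutation counts must be non-negative")
  data.frame(m = m,
             rate_per_mb = correction * m / (L / 1e6),
             excluded = m == 0)
}
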