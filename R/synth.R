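#' Default synthetic gene panel
#'
#' A small panel whose somatic mutation probabilities echo the recurrence
#' ranking reported for ER+ breast cancer (PIK3CA highest, then TP53,
#' MAP3K1, CDH1, MALAT1 as the RNA-gene case, GATA3, ...), with
#' gene-specific consequence-class mixes (MAP3K1 and GATA3
#' truncation-heavy, PIK3CA hotspot-missense-heavy), per-endpoint
#' log-hazard ratios (TP53/DDR1 adverse, MAP3K1/PIK3CA favorable), subtype
#' enrichment weights, and reference-catalog recurrence frequencies used by
#' the multi-study generator.
#'
#' @return data.frame, one row per gene.
#' @export
default_gene_panel <- function() {
  g <- data.frame(
    gene  = c("PIK3CA", "TP53", "MLL3", "MAP3K1", "CDH1", "MALAT1",
              "GATA3", "ARID1A", "BRCA2", "ATM", "NF1", "DDR1"),
    p_mut = c(0.41, 0.155, 0.134, 0.12, 0.105, 0.10,
              0.091, 0.072, 0.066, 0.05, 0.03, 0.02),
    stringsAsFactors = FALSE
  )
  # consequence-class mix (rows sum to 1)
  mix <- rbind(
    PIK3CA = c(0.90, 0.02, 0.02, 0.02, 0.01, 0.01, 0.01, 0.00, 0.005, 0.005),
    TP53   = c(0.55, 0.15, 0.15, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    MLL3   = c(0.50, 0.15, 0.20, 0.03, 0.05, 0.03, 0.02, 0.00, 0.01, 0.01),
    MAP3K1 = c(0.20, 0.20, 0.45, 0.05, 0.04, 0.02, 0.02, 0.00, 0.01, 0.01),
    CDH1   = c(0.30, 0.20, 0.35, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    MALAT1 = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 1.00, 0.00, 0.00),
    GATA3  = c(0.15, 0.15, 0.45, 0.05, 0.14, 0.02, 0.02, 0.00, 0.01, 0.01),
    ARID1A = c(0.30, 0.25, 0.30, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    BRCA2  = c(0.45, 0.20, 0.20, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    ATM    = c(0.50, 0.18, 0.17, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    NF1    = c(0.35, 0.25, 0.25, 0.03, 0.06, 0.02, 0.02, 0.00, 0.01, 0.01),
    DDR1   = c(0.70, 0.10, 0.08, 0.03, 0.03, 0.02, 0.02, 0.00, 0.01, 0.01)
  )
  colnames(mix) <- paste0("mix_", CONSEQUENCE_CLASSES)
  g <- cbind(g, as.data.frame(mix, row.names = NULL))
  g$loghr_bcss <- c(-0.30, 0.50, 0, -0.40, 0, 0, 0, 0, 0, 0, 0.40, 0.70)
  g$loghr_rfs  <- c(-0.25, 0.45, 0, -0.35, 0, 0, 0, 0, 0, 0, 0.40, 0.60)
  g$loghr_os   <- c(-0.20, 0.40, 0, -0.30, 0, 0, 0, 0, 0, 0, 0.35, 0.50)
  # multiplicative subtype enrichment weights (1 = no enrichment)
  g$w_LumA  <- c(1.3, 0.5, 1, 1.5, 1.2, 1, 0.8, 1, 1, 1, 0.8, 1)
  g$w_LumB  <- c(1.0, 1.2, 1, 0.8, 0.9, 1, 1.6, 1, 1, 1.5, 0.9, 1)
  g$w_HER2E <- c(0.5, 2.0, 1, 0.5, 0.6, 1, 0.8, 1, 1, 1, 3.0, 1)
  g$w_Basal <- c(0.3, 3.0, 1, 0.3, 0.5, 1, 0.5, 1, 1, 1, 1.2, 1)
  g$w_Normal <- 1
  # reference-catalog recurrence and the share of reference mutations
  # concentrated at the gene's canonical hotspot residue
  g$ref_freq <- c(0.30, 0.20, 0.08, 0.06, 0.10, 0.01,
                  0.09, 0.05, 0.03, 0.02, 0.02, 0.005)
  g$hotspot_share <- c(0.60, 0.15, 0, 0, 0, 0, 0.10, 0, 0, 0, 0, 0)
  g$prot_len <- c(1068, 393, 4911, 1512, 882, 500,
                  444, 2285, 3418, 3056, 2818, 913)
  g$hotspot_pos <- c(1047, 175, NA, NA, NA, NA, 308, NA, NA, NA, NA, NA)
  g
}

#' Synthetic-cohort generator configuration
#'
#' All defaults are fixed study conditions chosen to emulate a
#' targeted-capture tumor-only FFPE cohort: 625 samples, mean on-target
#' coverage 135.8x (negative-binomial dispersion 8), tumor purity centred
#' at 0.60 (sd 0.12), per-read miscall rate 1e-3, on average two residual
#' germline contaminants per sample with population minor-allele
#' frequencies log-uniform on \[1e-5, 0.2\], five recurrent low-VAF
#' artifact sites per cohort visible in 5% of panel-of-normals samples,
#' panel sizes 151 / 912 / 87, exponential baseline hazard 0.024 per year
#' with administrative censoring at 25 years plus random censoring at rate
#' 0.02, and intrinsic-subtype proportions (0.50, 0.42, 0.04, 0.02, 0.02)
#' for LumA/LumB/HER2E/Basal/Normal.
#'
#' @param ... named overrides of any configuration field.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_samples      = 625,
    genes          = default_gene_panel(),
    purity_mean    = 0.60,
    purity_sd      = 0.12,
    depth_mean     = 135.8,
    depth_dispersion = 8,
    error_rate     = 0.001,
    germline_rate  = 2,
    germline_pool_size = 200,
    germline_maf_log10_range = c(-5, log10(0.2)),
    germline_beta_conc = 30,
    artifact_rate  = 5,
    artifact_panel_prevalence = 0.05,
    artifact_tumor_prevalence = 0.10,
    artifact_vaf_range = c(0.01, 0.10),
    n1 = 151, n2 = 912, n3 = 87,
    baseline_dist  = "exponential",
    baseline_hazard = 0.024,
    weibull_shape  = 1,
    admin_censor_time = 25,
    censor_rate    = 0.02,
    subtype_props  = c(LumA = 0.50, LumB = 0.42, HER2E = 0.04,
                       Basal = 0.02, Normal = 0.02),
    per_study_n    = c(study1 = 507, study2 = 441, study3 = 237,
                       study4 = 103, study5 = 100, study6 = 65),
    mpmb_correction = 1.6,
    qc_fail_rate   = 0.02,
    seed           = 1L
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown generator config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_samples) || cfg$n_samples < 1) {
    stop("n_samples must be a positive count")
  }
  g <- cfg$genes
  if (!is.data.frame(g)) g <- as.data.frame(g, stringsAsFactors = FALSE)
  cfg$genes <- g
  if (!nrow(g)) stop("gene list must be non-empty")
  if (any(g$p_mut < 0 | g$p_mut > 1)) stop("gene mutation probabilities must be in [0,1]")
  if (any(g$ref_freq < 0 | g$ref_freq > 1)) stop("reference frequencies must be in [0,1]")
  if (cfg$error_rate < 0 || cfg$error_rate > 1) stop("error_rate must be in [0,1]")
  if (any(cfg$subtype_props < 0) || abs(sum(cfg$subtype_props) - 1) > 1e-8) {
    stop("subtype_props must be non-negative and sum to 1")
  }
  if (cfg$purity_mean <= 0 || cfg$purity_mean > 1) stop("purity mean must be in (0,1]")
  if (cfg$depth_mean < 0) stop("depth mean must be non-negative")
  if (any(c(cfg$n1, cfg$n2, cfg$n3) <= 0)) stop("panel sizes must be positive")
  if (cfg$baseline_hazard <= 0) stop("baseline hazard must be positive")
  structure(cfg, class = c("generator_config", "list"))
}

# one root seed; submodules derive child seeds from fixed labels so adding
# a generator stage never perturbs the others
child_seed <- function(seed, label) {
  s <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(label)) {
    s <- (s * 31 + code) %% 2147483647
  }
  as.integer(max(1, s))
}

with_child_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, label), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Simulate sequencing read counts at a site
#'
#' Total depth is negative-binomial; variant-supporting reads are binomial
#' with success probability `true_vaf * (1 - error_rate) +
#' (1 - true_vaf) * error_rate / 3` (a miscall lands on the variant base a
#' third of the time).
#'
#' @param true_vaf true variant allele fraction(s) in \[0,1\] (recycled).
#' @param depth_mean,depth_dispersion negative-binomial mean and size.
#' @param error_rate per-read miscall probability.
#' @param n number of draws (default `length(true_vaf)`).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return data.frame with integer columns `var_reads`, `depth`.
#' @export
#' @examples
#' simulate_readcounts(0.3, 200, 8, 0.001, n = 5, seed = 1)
simulate_readcounts <- function(true_vaf, depth_mean, depth_dispersion,
                                error_rate = 0.001, n = length(true_vaf),
                                seed = NULL) {
  if (any(true_vaf < 0 | true_vaf > 1)) stop("true_vaf must be in [0,1]")
  if (depth_mean < 0) stop("depth mean must be non-negative")
  draw <- function() {
    depth <- rnbinom(n, size = depth_dispersion, mu = depth_mean)
    p <- true_vaf * (1 - error_rate) + (1 - true_vaf) * error_rate / 3
    var_reads <- rbinom(n, size = depth, prob = rep_len(p, n))
    data.frame(var_reads = var_reads, depth = depth)
  }
  if (is.null(seed)) draw() else with_child_seed(seed, "readcounts", draw())
}

#' Generate a fully labeled synthetic tumor-only cohort
#'
#' Produces a variant table (somatic, germline-contaminant and
#' recurrent-artifact variants with binomially sampled read counts at
#' purity-scaled VAFs), clinical covariates with PAM50-like subtype labels,
#' per-endpoint survival times under a proportional-hazards model with
#' gene-specific log-hazard ratios, a per-sample coverage QC summary, and a
#' truth object labelling every variant.
#'
#' Somatic variants are clonal heterozygous: expected VAF = purity / 2.
#' Germline heterozygous contaminants have expected VAF 0.5 (Beta-jittered).
#' Artifacts have VAF uniform on the configured low range.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_cohort` with components `variants`,
#'   `clinical`, `survival`, `coverage`, `regions`, `truth`, `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  genes <- config$genes
  n <- as.integer(config$n_samples)
  sample_ids <- sprintf("S%04d", seq_len(n))
  regions <- gene_regions(genes)

  # --- samples: purity, subtype, clinical covariates -----------------------
  samples <- with_child_seed(config$seed, "samples", {
    m <- config$purity_mean; s <- config$purity_sd
    v <- s^2
    a <- m * (m * (1 - m) / v - 1); b <- (1 - m) * (m * (1 - m) / v - 1)
    purity <- pmin(1, pmax(0.05, rbeta(n, a, b)))
    subtype <- names(config$subtype_props)[
      apply(rmultinom(n, 1, config$subtype_props), 2, which.max)]
    data.frame(
      sample_id = sample_ids,
      purity = purity,
      subtype = subtype,
      age = pmin(95, pmax(28, round(rnorm(n, 67, 10)))),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.5, 0.3)),
      nodes_positive = rpois(n, 1.2),
      tumor_size_category = sample(1:4, n, replace = TRUE,
                                   prob = c(0.3, 0.4, 0.2, 0.1)),
      her2_amplified = runif(n) < ifelse(subtype == "HER2E", 0.5, 0.05),
      stringsAsFactors = FALSE
    )
  })

  # --- somatic variants ----------------------------------------------------
  somatic <- with_child_seed(config$seed, "somatic", {
    rows <- vector("list", nrow(genes))
    w <- as.matrix(genes[, paste0("w_", names(config$subtype_props))])
    for (gi in seq_len(nrow(genes))) {
      p <- pmin(1, genes$p_mut[gi] *
                  w[gi, match(samples$subtype, names(config$subtype_props))])
      hit <- runif(n) < p
      if (!any(hit)) next
      idx <- which(hit)
      rows[[gi]] <- make_variants(genes[gi, ], regions[gi, ], samples[idx, ],
                                  true_vaf = samples$purity[idx] / 2,
                                  config = config)
    }
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })

  # --- germline contaminants ----------------------------------------------
  germ <- with_child_seed(config$seed, "germline", {
    pool_n <- config$germline_pool_size
    rng <- config$germline_maf_log10_range
    pool_maf <- 10^runif(pool_n, rng[1], rng[2])
    pool_gene <- sample(seq_len(nrow(genes)), pool_n, replace = TRUE)
    pool_pos <- regions$start[pool_gene] +
      floor(runif(pool_n) * (regions$end[pool_gene] - regions$start[pool_gene] + 1))
    bases <- c("A", "C", "G", "T")
    pool_ref <- sample(bases, pool_n, replace = TRUE)
    pool_alt <- vapply(pool_ref, function(r) sample(setdiff(bases, r), 1), "")
    k <- rpois(n, config$germline_rate)
    out <- vector("list", n)
    conc <- config$germline_beta_conc
    for (i in which(k > 0)) {
      site <- sample(pool_n, min(k[i], pool_n), prob = pool_maf)
      vaf <- rbeta(length(site), conc, conc)
      rc <- simulate_readcounts(vaf, config$depth_mean,
                                config$depth_dispersion, config$error_rate)
      gi <- pool_gene[site]
      pos <- pool_pos[site]
      out[[i]] <- data.frame(
        sample_id = samples$sample_id[i],
        gene = genes$gene[gi],
        chrom = regions$chrom[gi],
        pos = pos,
        ref = pool_ref[site], alt = pool_alt[site],
        variant_type = "SNV",
        consequence_class = draw_classes_multi(genes, gi),
        protein_change = protein_change_at(pos, regions$start[gi]),
        var_reads = rc$var_reads, depth = rc$depth,
        true_vaf = vaf, label = "germline", pop_maf = pool_maf[site],
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })

  # --- recurrent artifacts -------------------------------------------------
  # NB: no early return() inside with_child_seed() blocks — the expression
  # is a promise evaluated in this frame, so return() would exit generate_cohort
  art <- with_child_seed(config$seed, "artifacts", {
    n_art <- rpois(1, config$artifact_rate)
    gi <- if (n_art > 0) sample(seq_len(nrow(genes)), n_art, replace = TRUE)
          else integer(0)
    pos <- regions$start[gi] +
      floor(runif(n_art) * (regions$end[gi] - regions$start[gi] + 1))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_art, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    out <- vector("list", length(gi))
    for (a in seq_along(gi)) {
      hit <- which(runif(n) < config$artifact_tumor_prevalence)
      if (!length(hit)) next
      vaf <- runif(length(hit), config$artifact_vaf_range[1],
                   config$artifact_vaf_range[2])
      rc <- simulate_readcounts(vaf, config$depth_mean,
                                config$depth_dispersion, config$error_rate)
      out[[a]] <- data.frame(
        sample_id = samples$sample_id[hit],
        gene = genes$gene[gi[a]],
        chrom = regions$chrom[gi[a]],
        pos = pos[a], ref = ref[a], alt = alt[a],
        variant_type = "SNV",
        consequence_class = "missense",
        protein_change = protein_change_at(pos[a], regions$start[gi[a]]),
        var_reads = rc$var_reads, depth = rc$depth,
        true_vaf = vaf, label = "artifact", pop_maf = NA_real_,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  })

  variants <- rbind(somatic, germ, art)
  if (is.null(variants)) {
    variants <- data.frame(sample_id = character(), gene = character(),
                           chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           variant_type = character(),
                           consequence_class = character(),
                           protein_change = character(),
                           var_reads = integer(), depth = integer(),
                           true_vaf = numeric(), label = character(),
                           pop_maf = numeric(), stringsAsFactors = FALSE)
  }
  variants <- variants[variants$depth > 0, , drop = FALSE]
  rownames(variants) <- NULL
  variants$vaf <- variants$var_reads / variants$depth

  # --- survival ------------------------------------------------------------
  carrier <- matrix(FALSE, n, nrow(genes),
                    dimnames = list(sample_ids, genes$gene))
  som <- variants[variants$label == "somatic", c("sample_id", "gene")]
  if (nrow(som)) {
    carrier[cbind(match(som$sample_id, sample_ids),
                  match(som$gene, genes$gene))] <- TRUE
  }
  surv <- with_child_seed(config$seed, "survival", {
    out <- vector("list", 3)
    eps <- c(BCSS = "loghr_bcss", RFS = "loghr_rfs", OS = "loghr_os")
    for (e in seq_along(eps)) {
      lp <- as.vector(carrier %*% genes[[eps[e]]])
      h <- config$baseline_hazard * exp(lp)
      t_event <- if (config$baseline_dist == "weibull") {
        # hazard multiplier enters as scale^-shape
        (rexp(n) / h)^(1 / config$weibull_shape)
      } else {
        rexp(n, rate = h)
      }
      t_cens <- pmin(config$admin_censor_time,
                     if (config$censor_rate > 0) rexp(n, config$censor_rate)
                     else Inf)
      time <- pmax(1e-4, pmin(t_event, t_cens))
      out[[e]] <- data.frame(sample_id = sample_ids,
                             endpoint = names(eps)[e],
                             time = time,
                             event = as.integer(t_event <= t_cens),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  # --- coverage QC summary -------------------------------------------------
  coverage <- with_child_seed(config$seed, "coverage", {
    frac <- rbeta(n, 40, 2.5)  # centred ~0.94
    fail <- runif(n) < config$qc_fail_rate
    frac[fail] <- runif(sum(fail), 0.40, 0.79)
    data.frame(sample_id = sample_ids, frac_bases_gt20 = round(frac, 4),
               stringsAsFactors = FALSE)
  })

  clinical <- data.frame(
    sample_id = samples$sample_id,
    age = samples$age,
    grade = samples$grade,
    nodes_positive = samples$nodes_positive,
    tumor_size_category = samples$tumor_size_category,
    er_status = "positive",
    pr_status = "unknown",
    her2_status = ifelse(samples$her2_amplified, "positive", "negative"),
    her2_amplified = samples$her2_amplified,
    subtype = samples$subtype,
    stringsAsFactors = FALSE
  )

  truth <- list(
    variant_labels = data.frame(
      key = sample_variant_key(variants$sample_id, variants$chrom,
                               variants$pos, variants$ref, variants$alt),
      label = variants$label,
      true_vaf = variants$true_vaf,
      pop_maf = variants$pop_maf,
      stringsAsFactors = FALSE
    ),
    gene_loghr = genes[, c("gene", "loghr_bcss", "loghr_rfs", "loghr_os")],
    purity = samples[, c("sample_id", "purity")],
    mpmb_correction = config$mpmb_correction
  )

  out_vars <- variants[, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                           "variant_type", "consequence_class",
                           "protein_change", "var_reads", "depth", "vaf")]
  validate_variants(out_vars)
  structure(list(variants = out_vars, clinical = clinical, survival = surv,
                 coverage = coverage, regions = regions, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

# synthetic gene loci: one region per gene, coding length 3 * protein length
gene_regions <- function(genes) {
  k <- nrow(genes)
  len <- 3L * as.integer(genes$prot_len)
  data.frame(chrom = as.character((seq_len(k) - 1L) %% 22L + 1L),
             start = 1000000L * seq_len(k),
             end = 1000000L * seq_len(k) + len - 1L,
             gene = genes$gene,
             stringsAsFactors = FALSE)
}

draw_classes <- function(gene_row, n) {
  mix <- as.numeric(gene_row[1, paste0("mix_", CONSEQUENCE_CLASSES)])
  sample(CONSEQUENCE_CLASSES, n, replace = TRUE, prob = mix)
}

# one class draw per element of the gene-index vector gi
draw_classes_multi <- function(genes, gi) {
  vapply(gi, function(g) draw_classes(genes[g, , drop = FALSE], 1L), "")
}

# protein position deterministically tied to the genomic offset (vectorized)
protein_change_at <- function(pos, region_start) {
  aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  prot_pos <- (pos - region_start) %/% 3L + 1L
  paste0(aa[(pos %% 19L) + 1L], prot_pos, aa[((pos %/% 7L) %% 19L) + 1L])
}

# one somatic variant per hit sample for one gene
make_variants <- function(gene_row, region_row, hit_samples, true_vaf, config) {
  m <- nrow(hit_samples)
  cls <- draw_classes(gene_row, m)
  use_hot <- !is.na(gene_row$hotspot_pos) &
    runif(m) < gene_row$hotspot_share & cls == "missense"
  pos <- region_row$start +
    floor(runif(m) * (region_row$end - region_row$start + 1))
  pos[use_hot] <- region_row$start + (gene_row$hotspot_pos - 1L) * 3L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  vt <- rep("SNV", m)
  indel <- cls %in% c("frameshift", "inframe_indel")
  ins <- indel & runif(m) < 0.5
  vt[indel & ins] <- "INS"; vt[indel & !ins] <- "DEL"
  ref[vt == "INS"] <- "A"; alt[vt == "INS"] <- "AT"
  ref[vt == "DEL"] <- "AT"; alt[vt == "DEL"] <- "A"
  rc <- simulate_readcounts(true_vaf, config$depth_mean,
                            config$depth_dispersion, config$error_rate)
  data.frame(
    sample_id = hit_samples$sample_id,
    gene = gene_row$gene,
    chrom = region_row$chrom,
    pos = pos, ref = ref, alt = alt,
    variant_type = vt,
    consequence_class = cls,
    protein_change = protein_change_at(pos, region_row$start),
    var_reads = rc$var_reads, depth = rc$depth,
    true_vaf = true_vaf, label = "somatic", pop_maf = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Generate reference panels consistent with a synthetic cohort
#'
#' Builds the population allele-frequency table, unmatched-normal call
#' counts, and exome/genome read-count panels such that every
#' truth-labelled germline variant carries its assigned population MAF (in
#' all three resources), every artifact site shows qualifying read
#' evidence in about `artifact_panel_prevalence` of panel samples, and
#' somatic truth variants are absent from the population table and below
#' evidence thresholds in all panels.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] (required:
#'   the panels must contain the cohort's germline and artifact sites).
#' @return a `reference_panels` list (see [read_panels()]).
#' @export
generate_reference_panels <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("generate the cohort first: generate_reference_panels() needs the ",
         "synthetic_cohort object from generate_cohort()")
  }
  config <- cohort$config
  v <- cohort$variants
  lab <- cohort$truth$variant_labels
  site_key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  sites <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                      key = site_key, label = lab$label,
                      pop_maf = lab$pop_maf, stringsAsFactors = FALSE)
  sites <- sites[!duplicated(sites$key), , drop = FALSE]

  with_child_seed(config$seed, "panels", {
    germ <- sites[sites$label == "germline", , drop = FALSE]
    art <- sites[sites$label == "artifact", , drop = FALSE]

    population_maf <- data.frame(
      chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
      maf_1kg = germ$pop_maf, maf_nhlbi = germ$pop_maf,
      maf_exac = germ$pop_maf, stringsAsFactors = FALSE
    )

    # call counts in the unmatched-normal panel: germline sites follow
    # carrier frequency; artifact sites are rarely *called* in normals
    carrier_p <- 1 - (1 - germ$pop_maf)^2
    normal_calls <- rbind(
      data.frame(chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
                 alt = germ$alt,
                 n_called = rbinom(nrow(germ), config$n1, carrier_p),
                 stringsAsFactors = FALSE),
      if (nrow(art)) data.frame(chrom = art$chrom, pos = art$pos,
                                ref = art$ref, alt = art$alt,
                                n_called = rbinom(nrow(art), config$n1, 0.01),
                                stringsAsFactors = FALSE)
    )

    make_readcount_panel <- function(panel_n) {
      rows <- list()
      if (nrow(art)) {
        for (i in seq_len(nrow(art))) {
          k <- rbinom(1, panel_n, config$artifact_panel_prevalence)
          if (k == 0) next
          depth <- pmax(20L, rnbinom(k, size = config$depth_dispersion,
                                     mu = config$depth_mean))
          vaf <- runif(k, 0.02, 0.08)
          var_reads <- pmax(3L, rbinom(k, depth, vaf))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = art$chrom[i], pos = art$pos[i], ref = art$ref[i],
            alt = art$alt[i], var_reads = var_reads, depth = depth,
            stringsAsFactors = FALSE)
        }
      }
      if (nrow(germ)) {
        for (i in seq_len(nrow(germ))) {
          k <- rbinom(1, panel_n, carrier_p[i])
          if (k == 0) next
          depth <- pmax(20L, rnbinom(k, size = config$depth_dispersion,
                                     mu = config$depth_mean))
          var_reads <- rbinom(k, depth, 0.5)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = germ$chrom[i], pos = germ$pos[i], ref = germ$ref[i],
            alt = germ$alt[i], var_reads = var_reads, depth = depth,
            stringsAsFactors = FALSE)
        }
      }
      if (!length(rows)) {
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          var_reads = integer(), depth = integer(),
                          stringsAsFactors = FALSE))
      }
      do.call(rbind, rows)
    }

    panels <- list(
      population_maf = population_maf,
      normal_calls = normal_calls %||% data.frame(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), n_called = integer()),
      exome_panel = make_readcount_panel(config$n2),
      genome_panel = make_readcount_panel(config$n3),
      n1 = config$n1, n2 = config$n2, n3 = config$n3
    )
    validate_panels(panels)
  })
}

#' Generate a multi-study reference mutation catalog
#'
#' Emits reference mutations per gene at the configured reference
#' recurrence frequencies across the configured studies, concentrating
#' `hotspot_share` of each gene's mutations at its canonical hotspot
#' residue.  `n_ref` equals the sum of the per-study sample counts.
#'
#' @param config a [generator_config()].
#' @return list of class `multistudy_maf` with `records`, `per_study_n`,
#'   `n_ref`.
#' @export
generate_multistudy_maf <- function(config = generator_config()) {
  config <- validate_generator_config(config)
  genes <- config$genes
  if (!nrow(genes)) stop("gene list must be non-empty")
  with_child_seed(config$seed, "multistudy", {
    recs <- list()
    for (s in seq_along(config$per_study_n)) {
      ns <- config$per_study_n[s]
      for (gi in seq_len(nrow(genes))) {
        carriers <- which(runif(ns) < genes$ref_freq[gi])
        if (!length(carriers)) next
        k <- length(carriers)
        hot <- !is.na(genes$hotspot_pos[gi]) &
          runif(k) < genes$hotspot_share[gi]
        prot_pos <- 1L + floor(runif(k) * genes$prot_len[gi])
        prot_pos[hot] <- genes$hotspot_pos[gi]
        cls <- draw_classes(genes[gi, , drop = FALSE], k)
        keep <- cls %in% c("missense", "nonsense", "frameshift",
                           "inframe_indel", "splice_site")
        if (!any(keep)) next
        aa <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K", "M",
                "F", "P", "S", "T", "W", "Y", "V")
        recs[[length(recs) + 1L]] <- data.frame(
          gene = genes$gene[gi],
          protein_change = paste0(aa[(prot_pos[keep] %% 19L) + 1L],
                                  prot_pos[keep],
                                  aa[((prot_pos[keep] %/% 3L) %% 19L) + 1L]),
          protein_pos = prot_pos[keep],
          consequence_class = cls[keep],
          sample_id = sprintf("%s_N%04d", names(config$per_study_n)[s],
                              carriers[keep]),
          study = names(config$per_study_n)[s],
          stringsAsFactors = FALSE
        )
      }
    }
    records <- if (length(recs)) do.call(rbind, recs) else
      data.frame(gene = character(), protein_change = character(),
                 protein_pos = integer(), consequence_class = character(),
                 sample_id = character(), study = character())
    structure(list(records = records,
                   per_study_n = config$per_study_n,
                   n_ref = sum(config$per_study_n)),
              class = "multistudy_maf")
  })
}

#' Generate a knowledge base of actionable sites with per-sample read counts
#'
#' The knowledge base lists the canonical hotspot residues of the cohort's
#' genes (e.g. the PIK3CA helical/kinase hotspots in the default panel).
#' Per-sample read counts at those sites are taken from the cohort's own
#' reads for carriers and drawn at the sequencing error rate for
#' non-carriers, so the rescue caller can be exercised end to end.
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `kb` (site table) and `readcounts` (sample x site read
#'   counts).
#' @export
generate_knowledge_base <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("generate the cohort first")
  }
  config <- cohort$config
  genes <- config$genes
  regions <- cohort$regions
  hot <- which(!is.na(genes$hotspot_pos))
  if (!length(hot)) {
    return(list(kb = data.frame(), readcounts = data.frame()))
  }
  kb <- data.frame(
    chrom = regions$chrom[hot],
    pos = regions$start[hot] + (genes$hotspot_pos[hot] - 1L) * 3L,
    ref = "C", alt = "T",
    gene = genes$gene[hot],
    protein_change = protein_change_at(regions$start[hot] +
                                         (genes$hotspot_pos[hot] - 1L) * 3L,
                                       regions$start[hot]),
    source = "curated",
    stringsAsFactors = FALSE
  )
  # per-sample lookup: carriers at the hotspot keep their cohort reads,
  # everyone else shows background error-level reads
  v <- cohort$variants
  with_child_seed(config$seed, "knowledge_base", {
    out <- list()
    for (i in seq_len(nrow(kb))) {
      at_site <- v[v$chrom == kb$chrom[i] & v$pos == kb$pos[i], , drop = FALSE]
      ids <- cohort$clinical$sample_id
      rc <- simulate_readcounts(rep(0, length(ids)), config$depth_mean,
                                config$depth_dispersion, config$error_rate)
      df <- data.frame(sample_id = ids, chrom = kb$chrom[i], pos = kb$pos[i],
                       ref = kb$ref[i], alt = kb$alt[i],
                       gene = kb$gene[i],
                       protein_change = kb$protein_change[i],
                       var_reads = rc$var_reads, depth = rc$depth,
                       stringsAsFactors = FALSE)
      m <- match(at_site$sample_id, df$sample_id)
      df$var_reads[m] <- at_site$var_reads
      df$depth[m] <- at_site$depth
      df$ref[m] <- at_site$ref
      df$alt[m] <- at_site$alt
      out[[i]] <- df
    }
    list(kb = kb, readcounts = do.call(rbind, out))
  })
}

#' Write a synthetic cohort and its panels to a directory
#'
#' Writes the variant table as a TCGA-dialect MAF, clinical/survival/
#' coverage TSVs, target regions as BED, reference panels as TSV, the truth
#' labels as JSON and the generator configuration as YAML.  Output is
#' deterministic (UTF-8, LF, fixed number formatting).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory.
#' @param panels optional `reference_panels`; generated if `NULL`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, panels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_maf(cohort$variants, file.path(dir, "variants.maf"))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  surv <- cohort$survival
  surv$time <- round(surv$time, 6)
  write_tsv(surv, file.path(dir, "survival.tsv"))
  write_tsv(cohort$coverage, file.path(dir, "coverage.tsv"))
  write_bed(cohort$regions, file.path(dir, "targets.bed"))
  if (is.null(panels)) panels <- generate_reference_panels(cohort)
  write_panels(panels, file.path(dir, "panels"))
  truth <- cohort$truth
  truth$variant_labels$true_vaf <- round(truth$variant_labels$true_vaf, 6)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  cfg <- unclass(cohort$config)
  cfg$genes <- NULL  # gene table is regenerable; keep YAML small
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
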