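empty_panels <- function(n1 = 151, n2 = 912, n3 = 87) {
  validate_panels(list(
    population_maf = data.frame(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                maf_1kg = numeric(), maf_nhlbi = numeric(),
                                maf_exac = numeric()),
    normal_calls = data.frame(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              n_called = integer()),
    exome_panel = data.frame(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             var_reads = integer(), depth = integer()),
    genome_panel = data.frame(chrom = character(), pos = integer(),
                              ref = character(), alt = character(),
                              var_reads = integer(), depth = integer()),
    n1 = n1, n2 = n2, n3 = n3))
}

one_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                        var_reads = 40L, depth = 100L, type = "SNV",
                        cc = "missense", gene = "G1", sample = "s1") {
  data.frame(sample_id = sample, gene = gene, chrom = chrom, pos = pos,
             ref = ref, alt = alt, variant_type = type,
             consequence_class = cc, protein_change = NA_character_,
             var_reads = var_reads, depth = depth, vaf = var_reads / depth,
             stringsAsFactors = FALSE)
}

test_that("target restriction is 1-based inclusive on both boundaries", {
  regions <- data.frame(chrom = "1", start = 100L, end = 200L, gene = "G1")
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 200L),
             one_variant(pos = 201L), one_variant(pos = 99L),
             one_variant(pos = 150L))
  kept <- restrict_to_targets(v, regions)
  expect_equal(sort(kept$pos), c(100L, 150L, 200L))
  expect_error(restrict_to_targets(v, regions[0, ]), "empty")
})

test_that("population MAF rule is strictly greater than 0.1% in any resource", {
  p <- empty_panels()
  p$population_maf <- data.frame(
    chrom = "1", pos = c(100L, 101L, 102L), ref = "A", alt = "G",
    maf_1kg = c(0.002, 0.001, 0), maf_nhlbi = c(0, 0.001, 0),
    maf_exac = c(0, 0.001, 0))
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 101L),
             one_variant(pos = 102L), one_variant(pos = 999L))
  res <- filter_population_frequency(v, p)
  # 0.2% removed; exactly 0.1% retained; absent retained
  expect_equal(sort(res$variants$pos), c(101L, 102L, 999L))
  expect_equal(res$trace$pass, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("unmatched-normal rule removes at 10 or more of 151 calls", {
  p <- empty_panels()
  p$normal_calls <- data.frame(chrom = "1", pos = c(100L, 101L, 102L),
                               ref = "A", alt = "G",
                               n_called = c(10L, 9L, 0L))
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 101L),
             one_variant(pos = 102L))
  res <- filter_unmatched_normal_calls(v, p)
  expect_equal(sort(res$variants$pos), c(101L, 102L))
})

panel_rows <- function(pos, k, var_reads = 5L, depth = 100L) {
  if (k == 0) return(NULL)
  data.frame(chrom = "1", pos = pos, ref = "A", alt = "G",
             var_reads = var_reads, depth = depth)
}

test_that("exome panel removes at >= 1% evidence fraction of 912", {
  p <- empty_panels()
  # 10/912 = 1.096% (removed), 9/912 = 0.987% (retained)
  p$exome_panel <- rbind(panel_rows(100L, 10)[rep(1, 10), ],
                         panel_rows(101L, 9)[rep(1, 9), ])
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 101L))
  res <- filter_readcount_panel(v, p, "exome")
  expect_equal(res$variants$pos, 101L)
  expect_error(filter_readcount_panel(v, p, "wes"), "unknown panel mode")
})

test_that("genome panel removes at >= 2 evidence samples of 87", {
  p <- empty_panels()
  p$genome_panel <- rbind(panel_rows(100L, 1)[rep(1, 2), ],
                          panel_rows(101L, 1)[rep(1, 1), ])
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 101L))
  res <- filter_readcount_panel(v, p, "genome")
  expect_equal(res$variants$pos, 101L)
})

test_that("panel evidence requires reads, VAF and depth jointly", {
  p <- empty_panels()
  # var_reads = 3 at depth 400 is 0.75% VAF: NOT evidence
  p$exome_panel <- data.frame(chrom = "1", pos = rep(100L, 20), ref = "A",
                              alt = "G", var_reads = 3L, depth = 400L)
  v <- one_variant(pos = 100L)
  res <- filter_readcount_panel(v, p, "exome")
  expect_equal(nrow(res$variants), 1)
  # depth 19 fails the coverage arm even at high VAF
  p$exome_panel$depth <- 19L
  p$exome_panel$var_reads <- 10L
  expect_equal(nrow(filter_readcount_panel(v, p, "exome")$variants), 1)
})

test_that("binomial LLR equals the direct log-pmf ratio (identity property)", {
  set.seed(11)
  n <- sample(1:10000, 400, replace = TRUE)
  x <- vapply(n, function(ni) sample(0:ni, 1), integer(1))
  for (p_err in c(0.005, 0.01)) {
    mine <- tumoronly:::binom_llr(x, n, p_err)
    direct <- dbinom(x, n, x / n, log = TRUE) - dbinom(x, n, p_err, log = TRUE)
    expect_lt(max(abs(mine - direct)), 1e-9)
  }
})

test_that("LLR is monotone nondecreasing in x above the error rate", {
  for (n in c(50, 100, 1000)) {
    x <- seq(ceiling(n * 0.005), n)
    llr <- tumoronly:::binom_llr(x, n, 0.005)
    expect_true(all(diff(llr) >= -1e-12))
  }
})

test_that("LLR classifier decisions match direct pmf evaluation at the boundary", {
  th <- default_thresholds(p_err = 0.01)
  v8 <- one_variant(var_reads = 8L, depth = 100L)
  v9 <- one_variant(var_reads = 9L, depth = 100L)
  # oracle: direct log-pmf difference
  llr8 <- dbinom(8, 100, 0.08, log = TRUE) - dbinom(8, 100, 0.01, log = TRUE)
  llr9 <- dbinom(9, 100, 0.09, log = TRUE) - dbinom(9, 100, 0.01, log = TRUE)
  expect_lt(llr8, 10); expect_gt(llr9, 10)
  expect_equal(nrow(classify_somatic_llr(v8, th)$variants), 0)
  expect_equal(nrow(classify_somatic_llr(v9, th)$variants), 1)
  # zero supporting reads is always removed
  expect_equal(nrow(classify_somatic_llr(one_variant(var_reads = 0L), th)$variants), 0)
  # "less than" is eliminated: equality is kept
  v <- one_variant(var_reads = 9L, depth = 100L)
  th_eq <- default_thresholds(p_err = 0.01, llr_snv = llr9)
  expect_equal(nrow(classify_somatic_llr(v, th_eq)$variants), 1)
  expect_error(classify_somatic_llr(one_variant(depth = 0L, var_reads = 0L)),
               "depth")
})

test_that("indels use the lower LLR threshold", {
  th <- default_thresholds(p_err = 0.01)
  v <- one_variant(var_reads = 7L, depth = 100L, type = "DEL")
  llr7 <- dbinom(7, 100, 0.07, log = TRUE) - dbinom(7, 100, 0.01, log = TRUE)
  expect_true(llr7 > 6 && llr7 < 10)
  expect_equal(nrow(classify_somatic_llr(v, th)$variants), 1)
  v$variant_type <- "SNV"
  expect_equal(nrow(classify_somatic_llr(v, th)$variants), 0)
})

test_that("knowledge-base rescue applies the 5-read / 1% / 20x rule", {
  kb <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G",
                   gene = "PIK3CA", protein_change = "H1047R",
                   source = "curated")
  rc <- data.frame(sample_id = "s1", chrom = "1",
                   pos = c(100L, 100L, 200L),
                   ref = "A", alt = "G", gene = "PIK3CA",
                   protein_change = "H1047R",
                   var_reads = c(5L, 4L, 50L), depth = c(500L, 20L, 100L))
  rc$sample_id <- c("s1", "s2", "s3")
  out <- rescue_known_hotspots(rc, kb)
  # 5/500 = exactly 1% VAF: called; 4/20 fails the read-count rule
  expect_equal(out$sample_id, c("s1", "s3"))
  # site absent from the knowledge base emits nothing
  rc2 <- rc; rc2$pos <- 999L
  expect_warning(out2 <- rescue_known_hotspots(rc2, kb), "lack read-count")
  expect_equal(nrow(out2), 0)
})

test_that("class policies encode the non-silent definition", {
  v <- rbind(one_variant(cc = "silent"), one_variant(cc = "splice_region"),
             one_variant(cc = "splice_site"), one_variant(cc = "utr"),
             one_variant(cc = "intron"), one_variant(cc = "missense"),
             one_variant(cc = "inframe_indel"),
             one_variant(cc = "rna", gene = "MALAT1"),
             one_variant(cc = "rna", gene = "LINC1"))
  ns <- assign_class_sets(v, "non_silent")
  expect_setequal(ns$consequence_class,
                  c("splice_site", "missense", "inframe_indel", "rna"))
  expect_true(all(ns$gene[ns$consequence_class == "rna"] == "MALAT1"))
  fs <- assign_class_sets(rbind(v, one_variant(cc = "nonsense"),
                                one_variant(cc = "frameshift", type = "DEL")),
                          "fs_ns")
  expect_setequal(fs$consequence_class, c("nonsense", "frameshift"))
  expect_error(class_policy("nonsilent"), "arg")
})

test_that("policy class sets are nested", {
  fs <- class_policy("fs_ns")$classes
  fss <- class_policy("fs_ns_splice")$classes
  ns <- class_policy("non_silent")$classes
  expect_true(all(fs %in% fss))
  expect_true(all(fss %in% ns))
})

test_that("cascade equals rule-by-rule oracle on randomized variants", {
  set.seed(21)
  n <- 300
  regions <- data.frame(chrom = "1", start = 1L, end = 10000L, gene = "G1")
  v <- do.call(rbind, lapply(seq_len(n), function(i) {
    depth <- sample(30:300, 1)
    one_variant(pos = sample(1:11000, 1),
                var_reads = sample(0:min(40, depth), 1), depth = depth,
                type = sample(c("SNV", "DEL"), 1, prob = c(0.8, 0.2)),
                sample = sprintf("s%03d", i))
  }))
  p <- empty_panels()
  sites <- sample(unique(v$pos), 150)
  p$population_maf <- data.frame(chrom = "1", pos = sites[1:50], ref = "A",
                                 alt = "G",
                                 maf_1kg = runif(50, 0, 0.004),
                                 maf_nhlbi = 0, maf_exac = 0)
  p$normal_calls <- data.frame(chrom = "1", pos = sites[51:100], ref = "A",
                               alt = "G", n_called = sample(0:20, 50, TRUE))
  p$exome_panel <- do.call(rbind, lapply(sites[101:125], function(s) {
    k <- sample(0:15, 1)
    if (k == 0) return(NULL)
    data.frame(chrom = "1", pos = s, ref = "A", alt = "G",
               var_reads = sample(0:10, k, TRUE),
               depth = sample(10:200, k, TRUE))
  }))
  p$genome_panel <- do.call(rbind, lapply(sites[126:150], function(s) {
    k <- sample(0:4, 1)
    if (k == 0) return(NULL)
    data.frame(chrom = "1", pos = s, ref = "A", alt = "G",
               var_reads = sample(0:10, k, TRUE),
               depth = sample(10:200, k, TRUE))
  }))
  v <- v[v$depth > 0, ]
  th <- default_thresholds()
  res <- run_filter_cascade(v, p, regions = regions, thresholds = th)
  expected <- oracle_cascade(v, p, regions, th)
  got <- paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt, sep = ":") %in%
    paste(res$variants$sample_id, res$variants$chrom, res$variants$pos,
          res$variants$ref, res$variants$alt, sep = ":")
  expect_identical(got, expected)
})

test_that("cascade trace cites the first failing stage and retains subsets", {
  p <- empty_panels()
  p$population_maf <- data.frame(chrom = "1", pos = 100L, ref = "A",
                                 alt = "G", maf_1kg = 0.05, maf_nhlbi = 0.05,
                                 maf_exac = 0.05)
  p$normal_calls <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                               n_called = 50L)
  v <- rbind(one_variant(pos = 100L), one_variant(pos = 101L))
  regions <- data.frame(chrom = "1", start = 1L, end = 1000L, gene = "G1")
  res <- run_filter_cascade(v, p, regions = regions)
  st <- res$status
  expect_equal(st$status[grepl(":100:", st$key)], "removed:population_maf")
  expect_equal(st$status[grepl(":101:", st$key)], "retained")
  # every evaluated stage appears once per variant in the trace
  expect_equal(sum(res$trace$key == st$key[1]), 6)
  expect_true(all(res$variants$pos %in% v$pos))
})

test_that("rescued variants that fail the LLR stage appear with status rescued", {
  p <- empty_panels()
  v <- one_variant(pos = 100L, var_reads = 6L, depth = 200L)  # llr < 10
  kb <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                   gene = "G1", protein_change = "X1Y", source = "curated")
  rc <- data.frame(sample_id = "s1", chrom = "1", pos = 100L, ref = "A",
                   alt = "G", gene = "G1", protein_change = "X1Y",
                   var_reads = 6L, depth = 200L)
  res <- run_filter_cascade(v, p, kb = kb, kb_readcounts = rc)
  expect_equal(nrow(res$variants), 1)
  expect_equal(res$status$status, "rescued")
})

test_that("coverage QC boundary is at least 80 percent", {
  cov <- data.frame(sample_id = c("a", "b", "c"),
                    frac_bases_gt20 = c(0.80, 0.799, 0.95))
  qc <- sample_coverage_qc(cov)
  expect_equal(qc$pass, c(TRUE, FALSE, TRUE))
  cov$frac_bases_gt20 <- c(0.1, 0.2, 0.3)
  expect_error(sample_coverage_qc(cov), "no analyzable samples")
  expect_error(sample_coverage_qc(cov[0, ]), "missing")
})

test_that("mutations per MB uses the tiled space and scales with correction", {
  r <- mutations_per_mb(1, L = 362572, correction = 1)
  expect_equal(r$rate_per_mb, 2.758, tolerance = 1e-3)
  r15 <- mutations_per_mb(1, L = 362572, correction = 1.5)
  expect_equal(r15$rate_per_mb, 1.5 * r$rate_per_mb)
  r0 <- mutations_per_mb(c(0, 2), L = 362572)
  expect_equal(r0$rate_per_mb[1], 0)
  expect_true(r0$excluded[1]); expect_false(r0$excluded[2])
  expect_error(mutations_per_mb(1, L = 0), "positive")
})
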