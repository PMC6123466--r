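#' Build a sample-by-gene mutation carrier matrix
#'
#' `TRUE` iff the sample has at least one retained variant of the policy's
#' class set in that gene.  Samples with zero variants appear as all-FALSE
#' rows.  Carrier sets shrink as the policy narrows: the `fs_ns` matrix is
#' elementwise `<=` the `non_silent` matrix.
#'
#' @param variants a filtered variant table.
#' @param samples character vector of analyzable sample ids (post-QC).
#' @param policy a [class_policy()] or name.
#' @param genes optional gene universe; defaults to genes seen in
#'   `variants`.
#' @return logical matrix (samples x genes) of class `mutation_matrix`
#'   with attribute `policy`.
#' @export
build_mutation_matrix <- function(variants, samples, policy = "non_silent",
                                  genes = NULL) {
  if (is.character(policy)) policy <- class_policy(policy)
  v <- assign_class_sets(variants, policy)
  unknown <- setdiff(unique(v$sample_id), samples)
  if (length(unknown)) {
    stop("variant(s) from sample(s) not in the sample list: ",
         paste(head(unknown, 3), collapse = ", "))
  }
  if (is.null(genes)) genes <- sort(unique(variants$gene))
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  v <- v[v$gene %in% genes, , drop = FALSE]
  if (nrow(v)) {
    m[cbind(match(v$sample_id, samples), match(v$gene, genes))] <- TRUE
  }
  structure(m, policy = policy$name, class = c("mutation_matrix", "matrix"))
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation matrix: %d samples x %d genes (policy: %s)\n",
              nrow(x), ncol(x), attr(x, "policy")))
  cat("carriers per gene:\n")
  print(sort(colSums(x), decreasing = TRUE))
  invisible(x)
}

#' Categorical association test with automatic test selection
#'
#' Cross-tabulates carrier status (or any factor) against category labels
#' and applies Fisher's exact test when the table is 2x2 or any expected
#' cell count is below 5, and the chi-squared test otherwise — the
#' codified version of "Fisher's exact and chi-squared tests as
#' appropriate".  Two-sided throughout; the odds ratio is reported for
#' 2x2 tables.
#'
#' @param carrier logical (or factor) vector.
#' @param labels category labels, same length.
#' @param gene,covariate optional names recorded in the result.
#' @return one-row data.frame: `gene`, `covariate`, `test`, `statistic`,
#'   `p`, `odds_ratio`, `direction`.
#' @export
#' @examples
#' # HER2E non-amplified enrichment: 8/51 carriers vs 12/582
#' x <- c(rep(TRUE, 8), rep(FALSE, 43), rep(TRUE, 12), rep(FALSE, 570))
#' g <- rep(c("HER2E_nonamp", "other"), c(51, 582))
#' test_categorical_association(x, g)$p  # < 1e-4
test_categorical_association <- function(carrier, labels, gene = NA_character_,
                                         covariate = NA_character_) {
  keep <- !is.na(carrier) & !is.na(labels)
  carrier <- carrier[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop("degenerate input: fewer than 2 category levels")
  }
  if (length(unique(carrier)) < 2) {
    stop("degenerate input: carrier status is constant")
  }
  tab <- table(carrier, labels)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- all(dim(tab) == c(2, 2)) || any(expected < 5)
  if (use_fisher) {
    ft <- fisher.test(tab)
    or <- if (all(dim(tab) == c(2, 2))) unname(ft$estimate) else NA_real_
    res <- data.frame(gene = gene, covariate = covariate, test = "fisher",
                      statistic = NA_real_, p = ft$p.value, odds_ratio = or,
                      stringsAsFactors = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- data.frame(gene = gene, covariate = covariate, test = "chi2",
                      statistic = unname(ct$statistic), p = ct$p.value,
                      odds_ratio = NA_real_, stringsAsFactors = FALSE)
  }
  res$direction <- if (!is.na(res$odds_ratio)) {
    if (res$odds_ratio > 1) "enriched" else if (res$odds_ratio < 1)
      "depleted" else "none"
  } else NA_character_
  res
}

#' Pairwise co-occurrence / mutual exclusivity among top genes
#'
#' Tests all unordered pairs among the `top_k` most-mutated genes
#' (Fisher's exact on the 2x2 carrier table), labels each pair
#' co-occurring (odds ratio > 1) or exclusive (< 1), and applies
#' Benjamini-Hochberg across the pairs.
#'
#' @param mat a `mutation_matrix`.
#' @param top_k number of top genes (default 7, giving 21 pairs).
#' @return data.frame with one row per pair: `gene_a`, `gene_b`,
#'   `both`, `a_only`, `b_only`, `neither`, `odds_ratio`, `p`, `q`,
#'   `direction`.
#' @export
pairwise_cooccurrence <- function(mat, top_k = 7) {
  if (ncol(mat) < 2) stop("need at least 2 genes")
  counts <- colSums(mat)
  top <- names(sort(counts, decreasing = TRUE))[seq_len(min(top_k, ncol(mat)))]
  pairs <- utils::combn(top, 2)
  out <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- mat[, pairs[1, i]]; b <- mat[, pairs[2, i]]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2, 2)
    ft <- fisher.test(tab)
    # sample odds ratio decides direction; conditional MLE can be 0/Inf
    or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    out[[i]] <- data.frame(
      gene_a = pairs[1, i], gene_b = pairs[2, i],
      both = tab[1, 1], a_only = tab[1, 2], b_only = tab[2, 1],
      neither = tab[2, 2],
      odds_ratio = unname(ft$estimate), p = ft$p.value,
      direction = if (is.nan(or_sample) || or_sample == 1) "none"
                  else if (or_sample > 1) "co-occurring" else "exclusive",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$q <- bh_adjust(res$p)
  res[order(res$p), , drop = FALSE]
}

#' Continuous association test with normality-based test selection
#'
#' Tests each group for consistency with a normal distribution
#' (Kolmogorov-Smirnov against a normal with the group's moments); if both
#' groups are consistent (p >= `ks_alpha`) a two-sample Welch t-test is
#' used, otherwise the Mann-Whitney U test.  Group medians are always
#' reported.
#'
#' @param values numeric vector.
#' @param groups two-level grouping vector.
#' @param ks_alpha normality screening level (default 0.05).
#' @param gene,covariate names recorded in the result.
#' @return one-row data.frame: `test`, `statistic`, `p`, `median_a`,
#'   `median_b`, `direction`.
#' @export
test_continuous_association <- function(values, groups, ks_alpha = 0.05,
                                        gene = NA_character_,
                                        covariate = NA_character_) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  lv <- unique(groups)
  if (length(lv) != 2) stop("need exactly 2 groups")
  a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
  if (length(a) < 2 || length(b) < 2) {
    stop("degenerate input: each group needs at least 2 observations")
  }
  normal_ok <- function(x) {
    if (sd(x) == 0) return(FALSE)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value) >= ks_alpha
  }
  if (normal_ok(a) && normal_ok(b)) {
    tt <- t.test(a, b)
    test <- "ttest"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    test <- "mannwhitney"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  data.frame(gene = gene, covariate = covariate, test = test,
             statistic = stat, p = p,
             median_a = median(a), median_b = median(b),
             group_a = lv[1], group_b = lv[2],
             direction = if (median(a) > median(b)) "higher" else
               if (median(a) < median(b)) "lower" else "equal",
             stringsAsFactors = FALSE)
}

#' VAF-based germline suspicion report
#'
#' For genes where de novo germline variants are hard to distinguish from
#' somatic ones (by default BRCA1, BRCA2 and ATM), counts variants
#' observed at VAF strictly greater than 40% and 60% — VAFs that high are
#' unlikely to be somatic given impure tumors and heterozygous mutations —
#' and compares mean VAF in flagged vs other genes with the
#' normality-gated continuous test.
#'
#' @param variants a filtered variant table with `vaf`.
#' @param flagged_genes genes under germline suspicion.
#' @return list with `per_gene` (counts per flagged gene), `overall`
#'   (pooled counts and mean VAFs) and `comparison` (the test result, or
#'   `NULL` if either side is too small).
#' @export
vaf_germline_suspicion <- function(variants,
                                   flagged_genes = c("BRCA1", "BRCA2", "ATM")) {
  fl <- variants$gene %in% flagged_genes
  per_gene <- do.call(rbind, lapply(flagged_genes, function(g) {
    v <- variants$vaf[variants$gene == g]
    data.frame(gene = g, n = length(v),
               n_vaf_gt40 = sum(v > 0.40), n_vaf_gt60 = sum(v > 0.60),
               mean_vaf = if (length(v)) mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  overall <- data.frame(
    n_flagged = sum(fl),
    n_vaf_gt40 = sum(variants$vaf[fl] > 0.40),
    n_vaf_gt60 = sum(variants$vaf[fl] > 0.60),
    mean_vaf_flagged = if (any(fl)) mean(variants$vaf[fl]) else NA_real_,
    mean_vaf_other = if (any(!fl)) mean(variants$vaf[!fl]) else NA_real_
  )
  comparison <- NULL
  if (sum(fl) >= 2 && sum(!fl) >= 2) {
    comparison <- test_continuous_association(
      variants$vaf, ifelse(fl, "flagged", "other"),
      covariate = "vaf_flagged_vs_other")
  }
  list(per_gene = per_gene, overall = overall, comparison = comparison)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min over ranks j >= rank(i) of
#' p_(j) * m / j`, capped at 1.  Delegates to [stats::p.adjust()] after
#' validating the inputs.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return q-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  # fisher.test can return 1 + 2e-16; clamp rounding excursions but
  # reject genuinely invalid input
  if (any(is.na(p)) || any(p < -1e-9 | p > 1 + 1e-9)) {
    stop("p-values must be in [0,1] with no NA")
  }
  p.adjust(pmin(pmax(p, 0), 1), method = "BH")
}
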