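#' Select panel genes from a multi-study reference
#'
#' A gene is selected iff it is recurrently mutated in at least 2% of
#' reference cases, or in at least 1% of cases and druggable — membership
#' in more than two druggable gene categories or more than two
#' interactions with known anti-cancer drugs (both strictly greater than
#' two).  The returned `reason` records which clause fired.
#'
#' @param multistudy a `multistudy_maf` (see [generate_multistudy_maf()]).
#' @param drugs data.frame with `gene`, `categories`, `interactions`.
#' @return data.frame with `gene`, `recurrence`, `selected`, `reason`.
#' @export
select_panel_genes <- function(multistudy, drugs = NULL) {
  if (multistudy$n_ref <= 0) stop("reference sample count must be positive")
  rec <- multistudy$records
  carriers <- tapply(rec$sample_id, rec$gene,
                     function(s) length(unique(s)))
  genes <- names(carriers)
  recurrence <- as.numeric(carriers) / multistudy$n_ref
  cat_n <- int_n <- rep(0, length(genes))
  if (!is.null(drugs) && nrow(drugs)) {
    orphan <- setdiff(drugs$gene, genes)
    if (length(orphan)) {
      warning("druggability entries for gene(s) absent from the reference ",
              "catalog ignored: ", paste(orphan, collapse = ", "))
    }
    m <- match(genes, drugs$gene)
    cat_n <- ifelse(is.na(m), 0, drugs$categories[m])
    int_n <- ifelse(is.na(m), 0, drugs$interactions[m])
  }
  clause1 <- recurrence >= 0.02
  druggable <- cat_n > 2 | int_n > 2
  clause2 <- recurrence >= 0.01 & druggable
  reason <- ifelse(clause1, "recurrence>=2%",
                   ifelse(clause2, "recurrence>=1%+druggable", ""))
  data.frame(gene = genes, recurrence = recurrence,
             categories = cat_n, interactions = int_n,
             selected = clause1 | clause2, reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Parse a protein position from a protein-change string
#'
#' Takes the first integer in the string (`H1047R` -> 1047, `E545K` ->
#' 545).  Splice-junction forms such as `e2-1` or `e2+1` map to a
#' synthetic per-exon key so splice-site events at the same junction
#' aggregate as one hotspot.
#'
#' @param protein_change character vector.
#' @param splice logical vector: treat as splice-junction event.
#' @return character vector of position keys (`NA` when unparseable).
#' @export
parse_protein_position <- function(protein_change,
                                   splice = rep(FALSE, length(protein_change))) {
  out <- rep(NA_character_, length(protein_change))
  m <- regmatches(protein_change, regexpr("[0-9]+", protein_change))
  has <- regexpr("[0-9]+", protein_change) > 0
  out[has] <- m
  exon <- grepl("^e[0-9]+", protein_change)
  out[splice | exon] <- ifelse(
    exon[splice | exon],
    paste0("splice_", sub("^e([0-9]+).*", "e\\1", protein_change[splice | exon])),
    paste0("splice_", out[splice | exon]))
  out
}

#' Find mutation hotspots against a multi-study reference
#'
#' Aggregates study and reference mutations by (gene, amino-acid position)
#' — splice-site events by (gene, splice-junction) — and, for every
#' position with at least three mutations in either cohort, runs a
#' two-sided Fisher's exact test on the 2x2 table
#' `[[k_study, N_study - k_study], [k_ref, N_ref - k_ref]]`.
#' Benjamini-Hochberg q-values are computed across the tested positions; a
#' position is flagged `novel` iff its q-value is below `q_level` and the
#' study proportion exceeds the reference proportion.
#'
#' @param variants the study's retained variant table (needs
#'   `protein_change`, `consequence_class`).
#' @param multistudy a `multistudy_maf` reference catalog.
#' @param n_study number of analyzable study samples (samples passing QC,
#'   not samples with a variant).
#' @param q_level novelty significance level (default 0.05).
#' @param min_count minimum mutations in either cohort (default 3).
#' @return data.frame of class `hotspot_result`, one row per tested
#'   position.
#' @export
find_hotspots <- function(variants, multistudy, n_study,
                          q_level = 0.05, min_count = 3) {
  if (n_study <= 0) stop("n_study must be positive")
  n_ref <- multistudy$n_ref

  study_key <- position_keys(variants$gene, variants$protein_change,
                             variants$consequence_class == "splice_site")
  skip <- is.na(study_key$key)
  if (any(skip)) {
    message(sum(skip), " study variant(s) with unparseable protein change skipped")
  }
  k_study <- table(study_key$key[!skip])

  rec <- multistudy$records
  ref_key <- position_keys(rec$gene, rec$protein_change,
                           rec$consequence_class == "splice_site")
  k_ref <- table(ref_key$key[!is.na(ref_key$key)])

  all_keys <- union(names(k_study), names(k_ref))
  ks <- as.integer(k_study[all_keys]); ks[is.na(ks)] <- 0L
  kr <- as.integer(k_ref[all_keys]); kr[is.na(kr)] <- 0L
  test <- ks >= min_count | kr >= min_count
  keys <- all_keys[test]; ks <- ks[test]; kr <- kr[test]
  if (!length(keys)) {
    return(structure(data.frame(gene = character(), position = character(),
                                k_study = integer(), n_study = integer(),
                                k_ref = integer(), n_ref = integer(),
                                odds_ratio = numeric(), p = numeric(),
                                q = numeric(), novel = logical()),
                     class = c("hotspot_result", "data.frame")))
  }
  p <- or <- numeric(length(keys))
  for (i in seq_along(keys)) {
    tab <- matrix(c(ks[i], n_study - ks[i], kr[i], n_ref - kr[i]), 2, 2)
    ft <- fisher.test(tab)
    p[i] <- ft$p.value
    or[i] <- unname(ft$estimate)
  }
  q <- p.adjust(p, method = "BH")
  parts <- strsplit(keys, "\r")
  out <- data.frame(
    gene = vapply(parts, `[`, "", 1),
    position = vapply(parts, `[`, "", 2),
    k_study = ks, n_study = n_study, k_ref = kr, n_ref = n_ref,
    odds_ratio = or, p = p, q = q,
    novel = q < q_level & ks / n_study > kr / n_ref,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, -out$k_study), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "test") <- "fisher.two.sided.minlik"
  structure(out, class = c("hotspot_result", "data.frame"))
}

position_keys <- function(gene, protein_change, splice) {
  pos <- parse_protein_position(protein_change, splice)
  list(key = ifelse(is.na(pos), NA_character_, paste(gene, pos, sep = "\r")),
       pos = pos)
}

#' Per-gene carrier recurrence table
#'
#' A carrier is a sample with at least one qualifying variant in the gene
#' (multiple variants count once).  Percentages use the full analyzable
#' sample count, not the number of samples with a variant.
#'
#' @param variants a variant table (already filtered).
#' @param policy a [class_policy()] or name; `NULL` for no class
#'   restriction.
#' @param n_samples number of analyzable samples.
#' @return data.frame with `gene`, `carriers`, `percent`, sorted
#'   descending.
#' @export
#' @examples
#' v <- data.frame(sample_id = c("a", "a", "b"), gene = "PIK3CA",
#'                 consequence_class = "missense")
#' gene_recurrence_table(v, policy = NULL, n_samples = 10)
gene_recurrence_table <- function(variants, policy = "non_silent", n_samples) {
  if (n_samples == 0) stop("n_samples must be positive")
  v <- if (is.null(policy)) variants else assign_class_sets(variants, policy)
  if (!nrow(v)) {
    return(data.frame(gene = character(), carriers = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  carriers <- tapply(v$sample_id, v$gene, function(s) length(unique(s)))
  out <- data.frame(gene = names(carriers),
                    carriers = as.integer(carriers),
                    percent = 100 * as.integer(carriers) / n_samples,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$carriers, out$gene), , drop = FALSE]
}
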