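#' @name consequence_classes
#' @title Consequence vocabulary
#' @description Internal consequence classes and the mapping from the
#'   TCGA-style `Variant_Classification` vocabulary used in MAF files.
#'   The mapping is user-extensible through the `extra_map` argument of
#'   [read_maf()].
#' @keywords internal
NULL

CONSEQUENCE_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                         "splice_site", "splice_region", "silent", "rna",
                         "utr", "intron")

VARIANT_TYPES <- c("SNV", "INS", "DEL", "DNP")

# Variant_Classification -> internal consequence class
MAF_CLASS_MAP <- c(
  "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "nonsense",
  "Nonstop_Mutation"  = "nonsense",
  "Frame_Shift_Del"   = "frameshift",
  "Frame_Shift_Ins"   = "frameshift",
  "In_Frame_Del"      = "inframe_indel",
  "In_Frame_Ins"      = "inframe_indel",
  "Splice_Site"       = "splice_site",
  "Splice_Region"     = "splice_region",
  "Silent"            = "silent",
  "RNA"               = "rna",
  "3'UTR"             = "utr",
  "5'UTR"             = "utr",
  "3'Flank"           = "utr",
  "5'Flank"           = "utr",
  "Intron"            = "intron"
)

# internal class (+ variant type for indels) -> Variant_Classification
maf_classification <- function(consequence_class, variant_type) {
  out <- character(length(consequence_class))
  for (i in seq_along(consequence_class)) {
    cc <- consequence_class[i]
    out[i] <- switch(cc,
      missense      = "Missense_Mutation",
      nonsense      = "Nonsense_Mutation",
      frameshift    = if (variant_type[i] == "INS") "Frame_Shift_Ins" else "Frame_Shift_Del",
      inframe_indel = if (variant_type[i] == "INS") "In_Frame_Ins" else "In_Frame_Del",
      splice_site   = "Splice_Site",
      splice_region = "Splice_Region",
      silent        = "Silent",
      rna           = "RNA",
      utr           = "3'UTR",
      intron        = "Intron",
      stop("unknown consequence class: ", cc)
    )
  }
  out
}

MAF_REQUIRED_COLS <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                       "Reference_Allele", "Tumor_Seq_Allele2",
                       "Variant_Classification", "Variant_Type",
                       "Tumor_Sample_Barcode", "t_ref_count", "t_alt_count")

# MAF Variant_Type dialect -> internal
MAF_TYPE_MAP <- c(SNP = "SNV", SNV = "SNV", DNP = "DNP", TNP = "DNP",
                  INS = "INS", DEL = "DEL")

#' Validate a variant table
#'
#' Checks the in-memory variant table invariants: read counts are
#' non-negative integers with `var_reads <= depth`, VAF in \[0,1\],
#' positions >= 1, and consequence classes drawn from the internal
#' vocabulary.
#'
#' @param variants a variant data.frame (see [read_maf()]).
#' @return the validated data.frame, invisibly.
#' @export
validate_variants <- function(variants) {
  req <- c("sample_id", "gene", "chrom", "pos", "ref", "alt", "variant_type",
           "consequence_class", "var_reads", "depth", "vaf")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(variants) == 0) return(invisible(variants))
  bad <- which(variants$var_reads < 0 | variants$depth < 0 |
               variants$var_reads > variants$depth)
  if (length(bad)) stop("row ", bad[1],
                        ": var_reads must satisfy 0 <= var_reads <= depth")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  unknown <- setdiff(unique(variants$consequence_class), CONSEQUENCE_CLASSES)
  if (length(unknown)) stop("unknown consequence class(es): ",
                            paste(unknown, collapse = ", "))
  unknown_t <- setdiff(unique(variants$variant_type), VARIANT_TYPES)
  if (length(unknown_t)) stop("unknown variant type(s): ",
                              paste(unknown_t, collapse = ", "))
  invisible(variants)
}

#' Read a MAF-dialect variant table
#'
#' Parses a tab-separated mutation annotation format (MAF) file in the TCGA
#' column dialect into the package's variant table.  VAF is always computed
#' from the read counts, never trusted from the file.  Unknown
#' `Variant_Classification` values are a row-level error unless mapped via
#' `extra_map`.
#'
#' @param path path to a tab-separated MAF file.
#' @param extra_map optional named character vector extending the built-in
#'   `Variant_Classification` mapping (names = file vocabulary, values =
#'   internal classes).
#' @return A data.frame with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_type`, `consequence_class`, `protein_change`,
#'   `var_reads`, `depth`, `vaf`.
#' @export
read_maf <- function(path, extra_map = NULL) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "#")
  miss <- setdiff(MAF_REQUIRED_COLS, names(raw))
  if (length(miss)) stop("MAF missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  cmap <- c(MAF_CLASS_MAP, extra_map)
  alt_count <- suppressWarnings(as.integer(raw$t_alt_count))
  ref_count <- suppressWarnings(as.integer(raw$t_ref_count))
  bad <- which(is.na(alt_count) | is.na(ref_count))
  if (length(bad)) stop("MAF row ", bad[1], ": non-integer read counts")
  cc <- unname(cmap[raw$Variant_Classification])
  bad <- which(is.na(cc))
  if (length(bad)) stop("MAF row ", bad[1], ": unknown Variant_Classification '",
                        raw$Variant_Classification[bad[1]], "'")
  vt <- unname(MAF_TYPE_MAP[raw$Variant_Type])
  bad <- which(is.na(vt))
  if (length(bad)) stop("MAF row ", bad[1], ": unknown Variant_Type '",
                        raw$Variant_Type[bad[1]], "'")
  depth <- ref_count + alt_count
  out <- data.frame(
    sample_id = raw$Tumor_Sample_Barcode,
    gene      = raw$Hugo_Symbol,
    chrom     = raw$Chromosome,
    pos       = as.integer(raw$Start_Position),
    ref       = raw$Reference_Allele,
    alt       = raw$Tumor_Seq_Allele2,
    variant_type = vt,
    consequence_class = cc,
    protein_change = if ("Protein_Change" %in% names(raw)) raw$Protein_Change else NA_character_,
    var_reads = alt_count,
    depth     = depth,
    vaf       = ifelse(depth > 0, alt_count / depth, 0),
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  out
}

#' Write a variant table as a TCGA-dialect MAF
#'
#' @param variants a validated variant table.
#' @param path output path; written UTF-8, tab-separated, LF line endings.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  validate_variants(variants)
  out <- data.frame(
    Hugo_Symbol = variants$gene,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Classification = maf_classification(variants$consequence_class,
                                                variants$variant_type),
    Variant_Type = ifelse(variants$variant_type == "SNV", "SNP",
                          variants$variant_type),
    Tumor_Sample_Barcode = variants$sample_id,
    t_ref_count = variants$depth - variants$var_reads,
    t_alt_count = variants$var_reads,
    Protein_Change = ifelse(is.na(variants$protein_change), "",
                            variants$protein_change),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(path)
}

# deterministic TSV writer: UTF-8, LF, tab-separated, no quoting
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  txt <- capture_tsv(df)
  writeLines(txt, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

capture_tsv <- function(df) {
  cols <- lapply(df, function(x) {
    if (is.double(x)) {
      format(x, trim = TRUE, digits = 15, scientific = FALSE)
    } else as.character(x)
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  c(paste(names(df), collapse = "\t"), body)
}

#' Read clinical covariates
#'
#' Reads the tab-separated clinical table and validates every enum field.
#' Unknown intrinsic subtype is allowed (value `"unknown"`) and counted in
#' the returned attribute `n_unknown_subtype`.
#'
#' @param path tab-separated file with header columns `sample_id`, `age`,
#'   `grade`, `nodes_positive`, `tumor_size_category`, `er_status`,
#'   `pr_status`, `her2_status`, `her2_amplified`, `subtype`, plus optional
#'   `cnv_` boolean columns.
#' @return a validated data.frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "age", "grade", "nodes_positive",
           "tumor_size_category", "subtype")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(!is.finite(d$age) | d$age <= 0)) stop("age must be positive")
  if (any(!d$grade %in% 1:3)) stop("grade must be 1, 2 or 3")
  if (any(d$nodes_positive < 0)) stop("nodes_positive must be >= 0")
  if (any(!d$tumor_size_category %in% 1:4)) stop("tumor_size_category must be 1-4")
  subtypes <- c("LumA", "LumB", "HER2E", "Basal", "Normal", "unknown")
  if (any(!d$subtype %in% subtypes)) {
    stop("invalid subtype value(s): ",
         paste(setdiff(unique(d$subtype), subtypes), collapse = ", "))
  }
  attr(d, "n_unknown_subtype") <- sum(d$subtype == "unknown")
  d
}

#' Read survival outcomes
#'
#' @param path tab-separated file with columns `sample_id`, `endpoint`
#'   (BCSS, RFS or OS), `time` (years, > 0) and `event` (0/1).
#' @return a validated data.frame.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "endpoint", "time", "event")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("survival table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!d$endpoint %in% c("BCSS", "RFS", "OS"))) {
    stop("endpoint must be one of BCSS, RFS, OS")
  }
  if (any(!is.finite(d$time) | d$time <= 0)) {
    stop("survival time must be finite and positive")
  }
  if (any(!d$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (anyDuplicated(d[, c("sample_id", "endpoint")])) {
    stop("duplicate (sample_id, endpoint) in survival table")
  }
  d
}

#' Read a BED file of target regions
#'
#' BED is 0-based half-open on disk; coordinates are converted to 1-based
#' inclusive in memory, the convention used everywhere in this package.
#'
#' @param path BED file (chrom, start, end, optional name).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene`
#'   (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  d <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(d[[1]]),
                    start = as.integer(d[[2]]) + 1L,
                    end   = as.integer(d[[3]]),
                    gene  = if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("BED interval with start > end")
  out
}

#' Write target regions as BED (0-based half-open)
#' @param regions data.frame with 1-based inclusive `chrom`, `start`, `end`,
#'   `gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end, gene = regions$gene)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(do.call(paste, c(out, sep = "\t")), con, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' Read reference panels from a directory
#'
#' Expects `population_maf.tsv` (chrom, pos, ref, alt, maf_1kg, maf_nhlbi,
#' maf_exac), `normal_calls.tsv` (chrom, pos, ref, alt, n_called), and
#' long-format read-count panels `exome_panel.tsv` / `genome_panel.tsv`
#' (chrom, pos, ref, alt, var_reads, depth; one row per panel sample with
#' variant-supporting reads — panel samples without alt reads are implicit).
#' Panel sizes are read from `panel_sizes.tsv` (n1, n2, n3).
#'
#' @param dir directory containing the panel files.
#' @return a list of class `reference_panels`.
#' @export
read_panels <- function(dir) {
  if (!dir.exists(dir)) stop("panels directory not found: ", dir)
  pth <- function(f) file.path(dir, f)
  for (f in c("population_maf.tsv", "normal_calls.tsv", "exome_panel.tsv",
              "genome_panel.tsv", "panel_sizes.tsv")) {
    if (!file.exists(pth(f))) stop("missing panel file: ", pth(f))
  }
  sizes <- read.delim(pth("panel_sizes.tsv"), sep = "\t")
  # ref/alt must never be type-guessed: a column of "T" parses as logical
  cc <- c(chrom = "character", ref = "character", alt = "character")
  rd <- function(f) read.delim(pth(f), sep = "\t", stringsAsFactors = FALSE,
                               colClasses = cc)
  panels <- list(
    population_maf = rd("population_maf.tsv"),
    normal_calls   = rd("normal_calls.tsv"),
    exome_panel    = rd("exome_panel.tsv"),
    genome_panel   = rd("genome_panel.tsv"),
    n1 = sizes$n1[1], n2 = sizes$n2[1], n3 = sizes$n3[1]
  )
  validate_panels(panels)
}

validate_panels <- function(panels) {
  stopifnot(is.list(panels))
  for (nm in c("population_maf", "normal_calls", "exome_panel", "genome_panel")) {
    if (is.null(panels[[nm]])) stop("panels missing component: ", nm)
  }
  if (any(panels$normal_calls$n_called > panels$n1)) {
    stop("normal call count exceeds panel size n1")
  }
  mafcols <- c("maf_1kg", "maf_nhlbi", "maf_exac")
  pm <- panels$population_maf
  if (nrow(pm) && any(unlist(pm[mafcols]) < 0 | unlist(pm[mafcols]) > 1)) {
    stop("population MAFs must be in [0,1]")
  }
  structure(panels, class = "reference_panels")
}

#' Write reference panels to a directory
#' @param panels a `reference_panels` list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panels <- function(panels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(panels$population_maf, file.path(dir, "population_maf.tsv"))
  write_tsv(panels$normal_calls, file.path(dir, "normal_calls.tsv"))
  write_tsv(panels$exome_panel, file.path(dir, "exome_panel.tsv"))
  write_tsv(panels$genome_panel, file.path(dir, "genome_panel.tsv"))
  write_tsv(data.frame(n1 = panels$n1, n2 = panels$n2, n3 = panels$n3),
            file.path(dir, "panel_sizes.tsv"))
  invisible(dir)
}

#' Read a knowledge base of actionable sites
#' @param path TSV with columns chrom, pos, ref, alt, gene, protein_change,
#'   source.
#' @return a data.frame.
#' @export
read_knowledge_base <- function(path) {
  if (!file.exists(path)) stop("knowledge base not found: ", path)
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character"))
  req <- c("chrom", "pos", "ref", "alt", "gene", "protein_change")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("knowledge base missing column(s): ",
                         paste(miss, collapse = ", "))
  d
}
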