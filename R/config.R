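#' Default thresholds for the tumor-only filtering cascade
#'
#' Returns the filter thresholds used throughout the cascade.  Defaults are
#' the values used for the archival ER+ breast cancer cohorts this pipeline
#' was designed around: population minor allele frequency strictly greater
#' than 0.1% removes a variant; presence in 10 or more of the 151 unmatched
#' normals removes it; a panel-of-normals sample counts as having evidence of
#' a variant when it shows at least 3 supporting reads, at least 1% VAF and
#' at least 20x coverage; evidence in >= 1% of the exome panel (912 samples)
#' or >= 2 of the genome panel (87 samples) removes it; a binomial
#' log-likelihood ratio below 10 (SNV/DNP) or below 6 (indel) against a
#' sequencing-error null of 0.005 removes it; knowledge-base rescue requires
#' 5 reads, 1% VAF and 20x; sample QC requires at least 80% of targeted
#' bases covered above 20x.
#'
#' @param ... named overrides of individual thresholds.
#' @return A named list of class `filter_thresholds`.
#' @export
#' @examples
#' th <- default_thresholds()
#' th$pop_maf_max
#' default_thresholds(llr_snv = 12)$llr_snv
default_thresholds <- function(...) {
  th <- list(
    pop_maf_max       = 0.001,
    normal_call_min   = 10,
    panel_min_var_reads = 3,
    panel_min_vaf     = 0.01,
    panel_min_depth   = 20,
    exome_panel_frac  = 0.01,
    genome_panel_count = 2,
    llr_snv           = 10,
    llr_indel         = 6,
    p_err             = 0.005,
    rescue_min_var_reads = 5,
    rescue_min_vaf    = 0.01,
    rescue_min_depth  = 20,
    qc_min_frac       = 0.80,
    qc_depth          = 20
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) {
    stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
  }
  th[names(ov)] <- ov
  validate_thresholds(th)
  structure(th, class = "filter_thresholds")
}

validate_thresholds <- function(th) {
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all thresholds must be single finite numbers")
  if (th$pop_maf_max < 0 || th$pop_maf_max > 1) stop("pop_maf_max must be in [0,1]")
  if (th$p_err <= 0 || th$p_err >= 1) stop("p_err must be in (0,1)")
  if (th$qc_min_frac < 0 || th$qc_min_frac > 1) stop("qc_min_frac must be in [0,1]")
  invisible(th)
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file, merges it over the package defaults, and
#' errors on any unknown key (misspellings are never silently ignored).
#' An empty or absent file yields the full default configuration; in
#' particular the default population-MAF removal threshold is 0.001.
#'
#' @param path path to a YAML or JSON configuration file, or `NULL` for
#'   defaults.
#' @param echo_to optional path; when given, the fully resolved configuration
#'   is written there as YAML for provenance.
#' @return A named list of class `run_config` with components `thresholds`
#'   (a [default_thresholds()] list), `generator` (a [generator_config()]
#'   list) and `analysis` (policy names, top-k for co-occurrence tests,
#'   permutation count, significance labels).
#' @export
load_config <- function(path = NULL, echo_to = NULL) {
  defaults <- list(
    thresholds = unclass(default_thresholds()),
    generator  = unclass(generator_config()),
    analysis   = list(
      policies        = c("non_silent", "missense", "fs_ns", "fs_ns_splice"),
      cooccurrence_top_k = 7,
      permutations    = 1000,
      hotspot_q_level = 0.05,
      reportable_q    = 0.2,
      ks_alpha        = 0.05,
      split_at        = 5,
      ties            = "efron",
      endpoints       = c("BCSS", "RFS", "OS")
    )
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(defaults, user, path = "")
  validate_thresholds(cfg$thresholds)
  class(cfg$thresholds) <- "filter_thresholds"
  cfg$generator <- validate_generator_config(cfg$generator)
  if (!is.null(echo_to)) yaml::write_yaml(cfg_to_plain(cfg), echo_to)
  structure(cfg, class = "run_config")
}

# recursive merge that rejects unknown keys
merge_config <- function(defaults, user, path = "") {
  if (!length(user)) return(defaults)
  if (is.null(names(user)) || any(!nzchar(names(user)))) {
    stop("configuration entries must be named (at '", path, "')")
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    stop("unknown configuration key(s): ",
         paste0(sub("^/", "", paste0(path, "/", bad)), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.data.frame(defaults[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, "/", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

cfg_to_plain <- function(x) {
  rapply(unclass(x), f = function(v) v, how = "replace")
}
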