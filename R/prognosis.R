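#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the product-limit
#' estimator with the standard convention that subjects censored at an
#' event time are censored after the events.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @return list of class `km_estimate` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (any(!is.finite(times) | times <= 0)) stop("times must be positive")
  fit <- survfit(Surv(times, events) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, n = length(times)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n",
              x$n, sum(x$n_event)))
  ev <- x$n_event > 0
  print(data.frame(time = x$time[ev], n_risk = x$n_risk[ev],
                   n_event = x$n_event[ev], surv = round(x$surv[ev], 4)))
  invisible(x)
}

#' k-group log-rank (Mantel-Cox) test
#'
#' @param times positive times.
#' @param events 0/1 event indicators.
#' @param groups grouping vector with >= 2 non-empty levels.
#' @return list of class `logrank_test` with `statistic` (chi-squared),
#'   `df` (k - 1) and `p`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  sd_ <- survdiff(Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  structure(list(statistic = sd_$chisq, df = df,
                 p = pchisq(sd_$chisq, df, lower.tail = FALSE),
                 n = as.vector(table(groups)),
                 obs = sd_$obs, exp = sd_$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

# expand subjects into counting-process episodes at the split time.
# conserves total follow-up and event counts.
split_episodes <- function(time, event, split_at) {
  late <- time > split_at
  early <- data.frame(id = seq_along(time), tstart = 0,
                      tstop = pmin(time, split_at),
                      event = ifelse(late, 0L, as.integer(event)),
                      period = "early", stringsAsFactors = FALSE)
  if (any(late)) {
    late_df <- data.frame(id = which(late), tstart = split_at,
                          tstop = time[late],
                          event = as.integer(event[late]),
                          period = "late", stringsAsFactors = FALSE)
    rbind(early, late_df)
  } else early
}

#' Cox proportional-hazards fit with optional year-5 episode splitting
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default)
#' via [survival::coxph()].  With `split_at` set, each subject is expanded
#' into counting-process episodes `[0, min(T, s))` and, when `T > s`,
#' `[s, T)`, and every covariate gets period-specific copies
#' (`<name>_early`, `<name>_late`), yielding separate early/late
#' coefficient estimates — the standard device for
#' non-proportional-hazard effects that differ before and after year 5.
#'
#' @param X data.frame or matrix of covariates (no intercept).
#' @param times,events survival outcome.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param split_at optional split time in years (e.g. 5).
#' @return data.frame of class `cox_result`: `term`, `beta`, `hr`, `se`,
#'   `z`, `p`, `ci_lo`, `ci_hi`, with attributes `ties`, `split_at`,
#'   `loglik`, `n`, `n_event`.
#' @export
cox_fit <- function(X, times, events, ties = c("efron", "breslow"),
                    split_at = NULL) {
  ties <- match.arg(ties)
  X <- as.data.frame(X)
  if (sum(events) < 1) stop("need at least one event")
  const <- vapply(X, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    stop("degenerate input: constant covariate(s): ",
         paste(names(X)[const], collapse = ", "))
  }
  if (is.null(split_at)) {
    d <- cbind(data.frame(.time = times, .event = events), X)
    f <- stats::as.formula(paste("Surv(.time, .event) ~",
                                 paste(names(X), collapse = " + ")))
  } else {
    ep <- split_episodes(times, events, split_at)
    Xe <- X[ep$id, , drop = FALSE]
    d <- data.frame(.tstart = ep$tstart, .tstop = ep$tstop,
                    .event = ep$event)
    terms <- character(0)
    for (nm in names(X)) {
      for (per in c("early", "late")) {
        col <- paste0(nm, "_", per)
        v <- Xe[[nm]] * (ep$period == per)
        if (length(unique(v)) > 1) {  # a period with no episodes is dropped
          d[[col]] <- v
          terms <- c(terms, col)
        }
      }
    }
    if (!length(terms)) stop("no estimable period-specific covariates")
    f <- stats::as.formula(paste("Surv(.tstart, .tstop, .event) ~",
                                 paste(terms, collapse = " + ")))
  }
  fit <- coxph(f, data = d, ties = ties)
  if (any(is.na(coef(fit)))) {
    stop("Cox fit failed to estimate all coefficients (singular design)")
  }
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    beta = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    z = s$coefficients[, "z"],
    p = s$coefficients[, "Pr(>|z|)"],
    ci_lo = s$conf.int[, "lower .95"],
    ci_hi = s$conf.int[, "upper .95"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "ties") <- ties
  attr(out, "split_at") <- split_at
  attr(out, "loglik") <- fit$loglik[length(fit$loglik)]
  attr(out, "n") <- fit$n
  attr(out, "n_event") <- fit$nevent
  class(out) <- c("cox_result", "data.frame")
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (ties: %s%s)\n",
              attr(x, "ties"),
              if (!is.null(attr(x, "split_at")))
                paste0(", split at ", attr(x, "split_at")) else ""))
  df <- as.data.frame(x)
  df$hr <- round(df$hr, 3); df$beta <- round(df$beta, 4)
  df$p <- signif(df$p, 3)
  print(df[, c("term", "beta", "hr", "ci_lo", "ci_hi", "p")], row.names = FALSE)
  invisible(x)
}

# fast vectorized univariate Cox (Breslow ties): one binary/numeric
# covariate per column of X, all fitted simultaneously by Newton steps on
# the partial likelihood. Used by the permutation engine where tens of
# thousands of single-covariate refits are needed.
fast_cox_univariate <- function(X, time, event, max_iter = 30, tol = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); G <- ncol(X)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; Xs <- X[ord, , drop = FALSE]
  first_idx <- match(t_s, t_s)        # first index of each tie group
  ev <- which(e_s == 1)
  risk_row <- first_idx[ev]           # risk-set start per event
  beta <- rep(0, G)
  estimable <- apply(Xs, 2, function(v) length(unique(v)) > 1)
  revcs <- function(M) {
    M[n:1, , drop = FALSE] |> apply(2, cumsum) |> (\(z) z[n:1, , drop = FALSE])()
  }
  for (it in seq_len(max_iter)) {
    eb <- exp(sweep(Xs, 2, beta, `*`))          # n x G
    s0 <- revcs(eb)[risk_row, , drop = FALSE]   # events x G
    s1 <- revcs(Xs * eb)[risk_row, , drop = FALSE]
    s2 <- revcs(Xs * Xs * eb)[risk_row, , drop = FALSE]
    mu <- s1 / s0
    U <- colSums(Xs[ev, , drop = FALSE] - mu)
    I <- colSums(s2 / s0 - mu^2)
    step <- ifelse(estimable & I > 1e-12, U / pmax(I, 1e-12), 0)
    step <- pmax(pmin(step, 2), -2)
    beta <- pmax(pmin(beta + step, 25), -25)
    if (max(abs(U[estimable & I > 1e-12])) < tol) break
  }
  eb <- exp(sweep(Xs, 2, beta, `*`))
  s0 <- revcs(eb)[risk_row, , drop = FALSE]
  s1 <- revcs(Xs * eb)[risk_row, , drop = FALSE]
  s2 <- revcs(Xs * Xs * eb)[risk_row, , drop = FALSE]
  I <- colSums(s2 / s0 - (s1 / s0)^2)
  se <- ifelse(estimable & I > 1e-12, 1 / sqrt(I), NA_real_)
  beta[!estimable] <- NA_real_
  p <- 2 * pnorm(-abs(beta / se))
  p[is.na(p)] <- 1   # inestimable genes contribute p = 1
  list(beta = beta, se = se, p = p)
}

# clinical covariate design: node dummies (1-3, 4+ vs 0), grade binary
# (3 vs 1/2), tumor size dummies (2, 3, 4 vs 1), optional extra booleans
clinical_design <- function(clinical, extra = NULL) {
  X <- data.frame(
    nodes_1_3 = as.integer(clinical$nodes_positive >= 1 &
                             clinical$nodes_positive <= 3),
    nodes_4p = as.integer(clinical$nodes_positive >= 4),
    grade_3 = as.integer(clinical$grade == 3),
    size_2 = as.integer(clinical$tumor_size_category == 2),
    size_3 = as.integer(clinical$tumor_size_category == 3),
    size_4 = as.integer(clinical$tumor_size_category == 4)
  )
  if (!is.null(extra)) {
    for (nm in extra) X[[nm]] <- as.integer(clinical[[nm]])
  }
  rownames(X) <- clinical$sample_id
  X
}

# carrier gate: 15 for non-silent / missense carriers, 8 for truncating
gate_min_carriers <- function(policy) {
  if (policy %in% c("fs_ns", "fs_ns_splice")) 8L else 15L
}

#' Gated univariate survival screen
#'
#' For every gene whose carrier count passes the policy-specific gate (at
#' least 15 carriers for non-silent/missense policies, at least 8 for
#' truncating policies) the screen runs a carrier-vs-non-carrier log-rank
#' test and a univariate Cox fit, with Benjamini-Hochberg q-values across
#' the tested genes.  Gated-out genes are reported with `gate =
#' "skipped"` and no statistics.
#'
#' @param mat a `mutation_matrix` (rows = samples).
#' @param surv survival data.frame (`sample_id`, `endpoint`, `time`,
#'   `event`).
#' @param endpoint endpoint to screen (BCSS, RFS or OS).
#' @param policy carrier policy name; defaults to the matrix's policy.
#' @param ties passed to [cox_fit()].
#' @return data.frame of class `screen_result`.
#' @export
univariate_screen <- function(mat, surv, endpoint = "BCSS",
                              policy = attr(mat, "policy"),
                              ties = "efron") {
  s <- align_survival(mat, surv, endpoint)
  gmin <- gate_min_carriers(policy)
  carriers <- colSums(mat)
  rows <- vector("list", ncol(mat))
  for (g in seq_len(ncol(mat))) {
    gene <- colnames(mat)[g]
    base <- data.frame(gene = gene, policy = policy, endpoint = endpoint,
                       n_carriers = carriers[g], gate = "tested",
                       logrank_p = NA_real_, beta = NA_real_, hr = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
    if (carriers[g] < gmin) {
      base$gate <- "skipped"
      rows[[g]] <- base
      next
    }
    x <- as.integer(mat[, g])
    lr <- logrank_test(s$time, s$event, x)
    cx <- cox_fit(data.frame(mutation = x), s$time, s$event, ties = ties)
    base$logrank_p <- lr$p
    base$beta <- cx$beta[1]; base$hr <- cx$hr[1]
    base$ci_lo <- cx$ci_lo[1]; base$ci_hi <- cx$ci_hi[1]
    base$p <- cx$p[1]
    rows[[g]] <- base
  }
  out <- do.call(rbind, rows)
  tested <- out$gate == "tested"
  out$q <- NA_real_
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

align_survival <- function(mat, surv, endpoint) {
  s <- surv[surv$endpoint == endpoint, , drop = FALSE]
  if (!nrow(s)) stop("no survival records for endpoint ", endpoint)
  m <- match(rownames(mat), s$sample_id)
  if (any(is.na(m))) stop("survival records missing for ",
                          sum(is.na(m)), " sample(s)")
  list(time = s$time[m], event = s$event[m])
}

#' Gated multivariate survival screen with year-5 splitting
#'
#' Per gated gene, fits a Cox model on mutation status plus the clinical
#' covariates — node status (1-3 and 4+ vs 0), grade (3 vs 1/2) and tumor
#' size category (2/3/4 vs 1), plus any extra boolean covariates — with
#' episode splitting at `split_at` years, yielding early/late hazard
#' ratios for every covariate.  The gene-level p-value is the smaller of
#' the early and late mutation Wald p-values.  Samples missing clinical
#' data are dropped (counted in the `n_dropped` attribute).
#'
#' @param mat a `mutation_matrix`.
#' @param surv survival table (`sample_id`, `endpoint`, `time`, `event`).
#' @param clinical clinical table ([read_clinical()]).
#' @param endpoint endpoint name.
#' @param policy carrier policy; defaults to the matrix's.
#' @param split_at split time in years (default 5); `NULL` disables
#'   splitting.
#' @param extra_covariates optional names of boolean clinical columns
#'   (e.g. CNV flags) added to the design.
#' @param ties tie handling.
#' @return data.frame of class `screen_result` with early/late columns.
#' @export
multivariate_screen <- function(mat, surv, clinical, endpoint = "BCSS",
                                policy = attr(mat, "policy"), split_at = 5,
                                extra_covariates = NULL, ties = "efron") {
  keep_cl <- clinical[complete.cases(clinical[, c("nodes_positive", "grade",
                                                  "tumor_size_category")]), ]
  m <- match(rownames(mat), keep_cl$sample_id)
  dropped <- sum(is.na(m))
  if (dropped > 0) {
    message(dropped, " sample(s) dropped for missing clinical covariates")
    if (dropped > 0.1 * nrow(mat)) {
      warning("clinical covariates missing for more than 10% of samples")
    }
  }
  keep <- !is.na(m)
  mat_k <- mat[keep, , drop = FALSE]
  cl <- keep_cl[m[keep], , drop = FALSE]
  s <- align_survival(mat_k, surv, endpoint)
  clinX <- clinical_design(cl, extra_covariates)
  # a clinical dummy with no variation (e.g. no 4+-node patients) is
  # inestimable and is dropped rather than failing every gene's fit
  const <- vapply(clinX, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    message("dropping constant clinical covariate(s): ",
            paste(names(clinX)[const], collapse = ", "))
    clinX <- clinX[, !const, drop = FALSE]
  }
  gmin <- gate_min_carriers(policy)
  carriers <- colSums(mat_k)
  rows <- vector("list", ncol(mat_k))
  for (g in seq_len(ncol(mat_k))) {
    gene <- colnames(mat_k)[g]
    base <- data.frame(gene = gene, policy = policy, endpoint = endpoint,
                       n_carriers = carriers[g], gate = "tested",
                       beta_early = NA_real_, hr_early = NA_real_,
                       p_early = NA_real_, beta_late = NA_real_,
                       hr_late = NA_real_, p_late = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
    if (carriers[g] < gmin) {
      base$gate <- "skipped"
      rows[[g]] <- base
      next
    }
    X <- cbind(data.frame(mutation = as.integer(mat_k[, g])), clinX)
    cx <- tryCatch(cox_fit(X, s$time, s$event, ties = ties,
                           split_at = split_at),
                   error = function(e) NULL)
    if (is.null(cx)) {
      base$gate <- "failed"
      rows[[g]] <- base
      next
    }
    if (is.null(split_at)) {
      i <- match("mutation", cx$term)
      base$beta_early <- cx$beta[i]; base$hr_early <- cx$hr[i]
      base$p_early <- cx$p[i]; base$p <- cx$p[i]
    } else {
      ie <- match("mutation_early", cx$term)
      il <- match("mutation_late", cx$term)
      if (!is.na(ie)) {
        base$beta_early <- cx$beta[ie]; base$hr_early <- cx$hr[ie]
        base$p_early <- cx$p[ie]
      }
      if (!is.na(il)) {
        base$beta_late <- cx$beta[il]; base$hr_late <- cx$hr[il]
        base$p_late <- cx$p[il]
      }
      base$p <- min(base$p_early, base$p_late, na.rm = TRUE)
    }
    rows[[g]] <- base
  }
  out <- do.call(rbind, rows)
  tested <- out$gate == "tested"
  out$q <- NA_real_
  if (any(tested)) out$q[tested] <- bh_adjust(out$p[tested])
  attr(out, "n_dropped") <- dropped
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("survival screen: %s, policy %s, %d gene(s), %d tested\n",
              x$endpoint[1], x$policy[1], nrow(x), sum(x$gate == "tested")))
  df <- as.data.frame(x)[x$gate == "tested", , drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 3)
  print(head(df[order(df$p), ], 15), row.names = FALSE)
  invisible(x)
}

#' Min-p permutation family-wise adjustment
#'
#' At each permutation the survival outcome and clinical covariates are
#' permuted jointly while the mutation matrix is untouched; the same Cox
#' model as the observed fits is refitted for every gene and the smallest
#' p-value across genes recorded.  A gene's adjusted p-value is the
#' proportion of permutations in which that minimum is less than or equal
#' to the gene's observed p-value (ties count against the gene).  Genes
#' whose refit fails in a permutation contribute p = 1 for that
#' permutation.
#'
#' @param mat a `mutation_matrix` restricted to the gated genes.
#' @param surv survival table, or a list with `time` and `event` aligned
#'   to `mat` rows.
#' @param clinical optional clinical table for multivariate refits
#'   (`NULL` = univariate).
#' @param endpoint endpoint name (used when `surv` is a table).
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutation stream.
#' @param split_at optional year-5 split for the multivariate model.
#' @param ties tie handling for the multivariate path; the univariate
#'   fast path uses Breslow weights (ties have probability zero for
#'   continuous times).
#' @return data.frame with `gene`, `p_obs`, `p_adjusted` and attribute
#'   `B`.  `p_adjusted >= p_obs` for every gene whenever the permutation
#'   distribution is calibrated (min-p can only inflate a raw p-value).
#' @export
permutation_adjust <- function(mat, surv, clinical = NULL,
                               endpoint = "BCSS", B = 1000, seed = 1,
                               split_at = NULL, ties = "efron") {
  if (B < 1) stop("B must be >= 1")
  if (is.list(surv) && !is.data.frame(surv)) {
    time <- surv$time; event <- surv$event
  } else {
    s <- align_survival(mat, surv, endpoint)
    time <- s$time; event <- s$event
  }
  n <- nrow(mat)
  univariate <- is.null(clinical) && is.null(split_at)
  clinX <- NULL
  if (!is.null(clinical)) {
    m <- match(rownames(mat), clinical$sample_id)
    if (any(is.na(m))) stop("clinical records missing for some samples")
    clinX <- clinical_design(clinical[m, , drop = FALSE])
  }

  fit_all <- function(tt, ee, cX) {
    if (univariate) {
      fast_cox_univariate(mat, tt, ee)$p
    } else {
      vapply(seq_len(ncol(mat)), function(g) {
        X <- data.frame(mutation = as.integer(mat[, g]))
        if (!is.null(cX)) X <- cbind(X, cX)
        cx <- tryCatch(cox_fit(X, tt, ee, ties = ties, split_at = split_at),
                       error = function(e) NULL)
        if (is.null(cx)) return(1)
        idx <- grep("^mutation", cx$term)
        if (!length(idx)) return(1)
        min(cx$p[idx])
      }, numeric(1))
    }
  }

  p_obs <- fit_all(time, event, clinX)
  min_p <- numeric(B)
  with_child_seed(seed, "permutation", {
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      cXp <- if (!is.null(clinX)) clinX[perm, , drop = FALSE] else NULL
      pb <- fit_all(time[perm], event[perm], cXp)
      min_p[b] <- min(pb)
    }
  })
  adj <- vapply(p_obs, function(pg) mean(min_p <= pg), numeric(1))
  out <- data.frame(gene = colnames(mat), p_obs = p_obs, p_adjusted = adj,
                    stringsAsFactors = FALSE)
  attr(out, "B") <- B
  out
}

#' Four-group survival analysis for a gene pair
#'
#' Partitions samples into both-mutated, A-only, B-only and
#' neither-mutated (exhaustive and disjoint), estimates a Kaplan-Meier
#' curve per group and runs a k-group log-rank test.  Empty groups are
#' dropped with a warning and the degrees of freedom reduced.
#'
#' @param mat a `mutation_matrix` containing both genes.
#' @param surv survival table.
#' @param gene_a,gene_b gene names (defaults MAP3K1 and PIK3CA, whose
#'   joint mutation marks a favorable course).
#' @param endpoint endpoint name.
#' @return list of class `two_gene_result` with `groups` (per-sample
#'   labels), `table` (group sizes and events), `km` (per-group
#'   [km_estimate()]), `logrank`.
#' @export
two_gene_analysis <- function(mat, surv, gene_a = "MAP3K1",
                              gene_b = "PIK3CA", endpoint = "BCSS") {
  for (g in c(gene_a, gene_b)) {
    if (!g %in% colnames(mat)) stop("gene not in matrix: ", g)
  }
  a <- mat[, gene_a]; b <- mat[, gene_b]
  if (!any(a) && !any(b)) stop("no carriers of either gene")
  grp <- ifelse(a & b, "both", ifelse(a, "a_only", ifelse(b, "b_only",
                                                          "neither")))
  s <- align_survival(mat, surv, endpoint)
  present <- names(which(table(grp) > 0))
  if (length(present) < 4) {
    warning("empty group(s) dropped: ",
            paste(setdiff(c("both", "a_only", "b_only", "neither"), present),
                  collapse = ", "))
  }
  km <- lapply(setNames(present, present), function(gname) {
    sel <- grp == gname
    km_estimate(s$time[sel], s$event[sel])
  })
  lr <- logrank_test(s$time, s$event, grp)
  tab <- data.frame(group = present,
                    n = as.vector(table(grp)[present]),
                    events = vapply(present, function(gname)
                      sum(s$event[grp == gname]), numeric(1)),
                    stringsAsFactors = FALSE)
  structure(list(gene_a = gene_a, gene_b = gene_b, groups = grp,
                 table = tab, km = km, logrank = lr),
            class = "two_gene_result")
}

#' @export
print.two_gene_result <- function(x, ...) {
  cat(sprintf("two-gene survival analysis: %s x %s\n", x$gene_a, x$gene_b))
  print(x$table, row.names = FALSE)
  print(x$logrank)
  invisible(x)
}
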