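# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# direct probability evaluations.

# Kaplan-Meier by explicit risk-set enumeration (censored after events at
# equal times)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# k-group log-rank statistic by direct O-E / covariance enumeration
oracle_logrank <- function(time, event, group) {
  group <- as.factor(as.character(group))
  k <- nlevels(group)
  ut <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    nj <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dj <- vapply(levels(group), function(g)
      sum(time == t & event == 1 & group == g), numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (a in 1:k) for (b in 1:k) {
        V[a, b] <- V[a, b] + d * (n - d) / (n - 1) *
          (nj[a] / n) * ((a == b) - nj[b] / n)
      }
    }
  }
  v <- V[-1, -1, drop = FALSE]
  x <- (O - E)[-1]
  stat <- as.numeric(t(x) %*% solve(v) %*% x)
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, k - 1, lower.tail = FALSE))
}

# Efron-ties Cox partial log-likelihood for a single covariate, evaluated
# directly; maximized by a 1-D scan + optimize
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  ut <- sort(unique(time[event == 1]))
  for (t in ut) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    s0R <- sum(exp(beta * x[R]))
    s0D <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d)) {
      ll <- ll - log(s0R - (l - 1) / d * s0D)
    }
  }
  ll
}

oracle_cox_beta <- function(x, time, event, lower = -5, upper = 5) {
  optimize(function(b) oracle_cox_loglik(b, x, time, event),
           c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
# (minimum-likelihood rule), for a 2x2 table given as (a, b, c, d)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# closed-form BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# rule-by-rule filter-cascade oracle: applies the six removal rules to
# each variant independently, per the printed thresholds
oracle_cascade <- function(variants, panels, regions, th) {
  n1 <- panels$n1; n2 <- panels$n2; n3 <- panels$n3
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    # rule 1: inside a target region
    r <- regions[regions$chrom == v$chrom, , drop = FALSE]
    if (!any(v$pos >= r$start & v$pos <= r$end)) next
    # rule 2: population MAF strictly greater than the cap in any resource
    pm <- panels$population_maf
    j <- which(pm$chrom == v$chrom & pm$pos == v$pos & pm$ref == v$ref &
                 pm$alt == v$alt)
    if (length(j) &&
        max(pm$maf_1kg[j], pm$maf_nhlbi[j], pm$maf_exac[j]) > th$pop_maf_max) next
    # rule 3: called in >= 10 unmatched normals
    nc <- panels$normal_calls
    j <- which(nc$chrom == v$chrom & nc$pos == v$pos & nc$ref == v$ref &
                 nc$alt == v$alt)
    if (length(j) && nc$n_called[j[1]] >= th$normal_call_min) next
    # rules 4-5: read-count panel evidence
    ev_count <- function(panel) {
      j <- which(panel$chrom == v$chrom & panel$pos == v$pos &
                   panel$ref == v$ref & panel$alt == v$alt)
      if (!length(j)) return(0)
      sum(panel$var_reads[j] >= th$panel_min_var_reads &
            panel$depth[j] >= th$panel_min_depth &
            panel$var_reads[j] / panel$depth[j] >= th$panel_min_vaf)
    }
    if (ev_count(panels$exome_panel) / n2 >= th$exome_panel_frac) next
    if (ev_count(panels$genome_panel) >= th$genome_panel_count) next
    # rule 6: binomial LLR against the error null
    llr <- dbinom(v$var_reads, v$depth, v$var_reads / v$depth, log = TRUE) -
      dbinom(v$var_reads, v$depth, th$p_err, log = TRUE)
    thr <- if (v$variant_type %in% c("INS", "DEL")) th$llr_indel else th$llr_snv
    if (llr < thr) next
    keep[i] <- TRUE
  }
  keep
}

# small aligned survival table builder for screen tests
make_surv_df <- function(ids, time, event, endpoint = "BCSS") {
  data.frame(sample_id = ids, endpoint = endpoint, time = time,
             event = event, stringsAsFactors = FALSE)
}

mutmat <- function(m, policy = "non_silent") {
  structure(m, policy = policy, class = c("mutation_matrix", "matrix"))
}
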