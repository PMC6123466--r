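test_that("product-limit estimate matches hand computation", {
  # 4 subjects, events at distinct times, no censoring
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  # mixed toy set of 6 against explicit risk-set enumeration
  t6 <- c(1, 2, 2, 3, 5, 6); e6 <- c(1, 0, 1, 1, 0, 1)
  km6 <- km_estimate(t6, e6)
  orc <- oracle_km(t6, e6)
  ev <- km6$n_event > 0
  expect_equal(km6$surv[ev], orc$surv, tolerance = 1e-12)
})

test_that("KM and log-rank match risk-set enumeration on random toy sets", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    tm <- sample(1:12, n, replace = TRUE) + 0  # heavy ties on purpose
    ev <- rbinom(n, 1, 0.7)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    if (sum(ev) == 0 || length(unique(grp)) < 2) next
    km <- km_estimate(tm, ev)
    orc <- oracle_km(tm, ev)
    expect_equal(km$surv[km$n_event > 0], orc$surv, tolerance = 1e-10)
    if (all(table(grp) > 0) && sum(ev) > 1) {
      lr <- logrank_test(tm, ev, grp)
      lro <- oracle_logrank(tm, ev, grp)
      expect_equal(lr$statistic, lro$statistic, tolerance = 1e-8)
      expect_equal(lr$p, lro$p, tolerance = 1e-8)
    }
  }
})

test_that("log-rank degenerate and directional cases", {
  # two identical groups: statistic 0, p 1
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4); ev <- rep(1, 8)
  grp <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(tm, ev, grp)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # 4 identical groups: df = 3, p = 1
  lr4 <- logrank_test(rep(c(1, 2, 3, 4), 4), rep(1, 16),
                      rep(c("a", "b", "c", "d"), each = 4))
  expect_equal(lr4$df, 3)
  expect_equal(lr4$p, 1, tolerance = 1e-12)
  # group A events strictly earlier: A observed > expected
  tmd <- c(1, 2, 3, 4); evd <- rep(1, 4); grpd <- c("A", "A", "B", "B")
  lrd <- logrank_test(tmd, evd, grpd)
  lro <- oracle_logrank(tmd, evd, grpd)
  expect_equal(lrd$statistic, lro$statistic, tolerance = 1e-8)
  expect_gt(lrd$obs[1], lrd$exp[1])  # A fares worse
  expect_error(logrank_test(tmd, evd, rep("A", 4)), "2 groups")
})

test_that("single-covariate Cox matches 1-D partial-likelihood maximization", {
  set.seed(71)
  for (i in 1:5) {
    n <- 20
    x <- rbinom(n, 1, 0.4)
    tm <- round(rexp(n, 0.1 * exp(0.6 * x)), 1) + 0.1  # induces some ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 3 || length(unique(x)) < 2) next
    fit <- cox_fit(data.frame(x = x), tm, ev)
    beta_orc <- oracle_cox_beta(x, tm, ev)
    expect_lt(abs(fit$beta - beta_orc), 1e-4)
  }
})

test_that("Cox sign follows the hazard direction", {
  set.seed(73)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.1 * exp(-0.8 * x))  # carriers live longer
  ev <- rep(1, n)
  fit <- cox_fit(data.frame(x = x), tm, ev)
  expect_lt(fit$beta, 0)
  expect_lt(fit$hr, 1)
  expect_true(fit$ci_lo <= fit$hr && fit$hr <= fit$ci_hi)
  expect_error(cox_fit(data.frame(x = rep(1, n)), tm, ev), "constant")
  expect_error(cox_fit(data.frame(x = x), tm, rep(0, n)), "event")
})

test_that("episode splitting conserves follow-up time and events", {
  set.seed(79)
  tm <- c(7, 3, 5, 12, 4.5); ev <- c(1, 0, 1, 1, 0)
  ep <- tumoronly:::split_episodes(tm, ev, 5)
  expect_equal(sum(ep$tstop - ep$tstart), sum(tm))
  expect_equal(sum(ep$event), sum(ev))
  # subject with T = 7, event: censored early episode (0,5], event in (5,7]
  e1 <- ep[ep$id == 1, ]
  expect_equal(e1$tstart, c(0, 5))
  expect_equal(e1$tstop, c(5, 7))
  expect_equal(e1$event, c(0L, 1L))
  # T = 3 event-free: single early episode
  e2 <- ep[ep$id == 2, ]
  expect_equal(nrow(e2), 1)
  expect_equal(e2$event, 0L)
})

test_that("split fit yields early/late coefficient pairs", {
  set.seed(83)
  n <- 400
  x <- rbinom(n, 1, 0.3)
  # adverse only within the first 5 years
  tm <- ifelse(x == 1, rexp(n, 0.25), rexp(n, 0.08))
  ev <- as.integer(tm < 15); tm <- pmin(tm, 15)
  fit <- cox_fit(data.frame(mutation = x), tm, ev, split_at = 5)
  expect_setequal(fit$term, c("mutation_early", "mutation_late"))
  expect_gt(fit$beta[fit$term == "mutation_early"], 0)
})

test_that("clinical covariate coding follows the node/grade/size scheme", {
  cl <- data.frame(sample_id = c("a", "b", "c", "d"),
                   nodes_positive = c(0, 2, 6, 1),
                   grade = c(1, 2, 3, 3),
                   tumor_size_category = c(1, 2, 3, 4))
  X <- tumoronly:::clinical_design(cl)
  expect_equal(X$nodes_1_3, c(0, 1, 0, 1))
  expect_equal(X$nodes_4p, c(0, 0, 1, 0))
  expect_equal(X$grade_3, c(0, 0, 1, 1))
  expect_equal(unname(as.matrix(X[, c("size_2", "size_3", "size_4")])),
               matrix(c(0, 1, 0, 0,  0, 0, 1, 0,  0, 0, 0, 1), 4, 3),
               ignore_attr = TRUE)
})

sim_screen_cohort <- function(n, p_carrier, loghr, seed, n_genes = 1) {
  set.seed(seed)
  ids <- sprintf("s%04d", seq_len(n))
  m <- matrix(rbinom(n * n_genes, 1, p_carrier) == 1, n, n_genes,
              dimnames = list(ids, paste0("G", seq_len(n_genes))))
  lp <- m[, 1] * loghr
  tm <- rexp(n, 0.05 * exp(lp))
  cens <- pmin(25, rexp(n, 0.02))
  list(mat = mutmat(m),
       surv = make_surv_df(ids, pmax(pmin(tm, cens), 1e-5),
                           as.integer(tm <= cens)))
}

test_that("screen gating: 14 non-silent or 7 truncating carriers are skipped", {
  d <- sim_screen_cohort(200, 0.5, 0, seed = 5, n_genes = 3)
  m <- d$mat
  m[, 2] <- c(rep(TRUE, 14), rep(FALSE, 186))
  m[, 3] <- c(rep(TRUE, 15), rep(FALSE, 185))
  res <- univariate_screen(m, d$surv, policy = "non_silent")
  expect_equal(res$gate[res$gene == "G2"], "skipped")
  expect_true(is.na(res$p[res$gene == "G2"]))
  expect_equal(res$gate[res$gene == "G3"], "tested")
  expect_false(is.na(res$p[res$gene == "G3"]))
  # truncating gate at 8
  m[, 2] <- c(rep(TRUE, 7), rep(FALSE, 193))
  m[, 3] <- c(rep(TRUE, 8), rep(FALSE, 192))
  attr(m, "policy") <- "fs_ns"
  res2 <- univariate_screen(m, d$surv, policy = "fs_ns")
  expect_equal(res2$gate[res2$gene == "G2"], "skipped")
  expect_equal(res2$gate[res2$gene == "G3"], "tested")
})

test_that("univariate screen recovers a known hazard ratio", {
  d <- sim_screen_cohort(2000, 0.15, log(2), seed = 11)
  res <- univariate_screen(d$mat, d$surv)
  fit <- cox_fit(data.frame(mutation = as.integer(d$mat[, 1])),
                 d$surv$time, d$surv$event)
  expect_equal(res$beta[1], fit$beta[1])
  expect_lt(abs(res$beta[1] - log(2)), 3 * fit$se[1])
})

test_that("multivariate screen leaves a null confounded gene's CI covering 1", {
  # mutation correlated with grade; grade carries the real hazard
  cover <- logical(100)
  for (r in seq_len(100)) {
    set.seed(100 + r)
    n <- 250
    grade3 <- rbinom(n, 1, 0.4)
    mut <- rbinom(n, 1, ifelse(grade3 == 1, 0.35, 0.10)) == 1
    tm <- rexp(n, 0.05 * exp(0.8 * grade3))
    cens <- pmin(25, rexp(n, 0.02))
    ids <- sprintf("s%03d", seq_len(n))
    m <- mutmat(matrix(mut, n, 1, dimnames = list(ids, "G1")))
    cl <- data.frame(sample_id = ids, age = 60, grade = 2 + grade3,
                     nodes_positive = rpois(n, 1),
                     tumor_size_category = sample(1:4, n, TRUE),
                     subtype = "LumA")
    sv <- make_surv_df(ids, pmax(pmin(tm, cens), 1e-5),
                       as.integer(tm <= cens))
    res <- multivariate_screen(m, sv, cl, split_at = NULL)
    cover[r] <- res$p_early[1] > 0.05  # Wald 95% CI covers HR = 1 iff p > 0.05
  }
  expect_gte(mean(cover), 0.90)
})

test_that("min-p adjustment follows its proportion definition", {
  set.seed(19)
  n <- 60
  ids <- sprintf("s%02d", seq_len(n))
  m <- mutmat(matrix(rbinom(n * 3, 1, 0.4) == 1, n, 3,
                     dimnames = list(ids, c("A", "B", "C"))))
  tm <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.8)
  sv <- list(time = tm, event = ev)
  B <- 25
  res <- permutation_adjust(m, sv, B = B, seed = 99)
  # independent oracle: same child-seeded permutation stream, coxph refits
  p_obs <- sapply(1:3, function(g)
    summary(survival::coxph(survival::Surv(tm, ev) ~ m[, g],
                            ties = "breslow"))$coefficients[, "Pr(>|z|)"])
  min_p <- numeric(B)
  tumoronly:::with_child_seed(99, "permutation", {
    for (b in seq_len(B)) {
      prm <- sample.int(n)
      pb <- sapply(1:3, function(g)
        summary(survival::coxph(survival::Surv(tm[prm], ev[prm]) ~ m[, g],
                                ties = "breslow"))$coefficients[, "Pr(>|z|)"])
      min_p[b] <- min(pb)
    }
  })
  expect_equal(res$p_obs, p_obs, tolerance = 1e-6)
  adj_oracle <- sapply(p_obs, function(pg) mean(min_p <= pg))
  expect_equal(res$p_adjusted, adj_oracle, tolerance = 1e-6)
  # observed p = 1 is always adjusted to 1
  expect_true(all(res$p_adjusted[res$p_obs >= max(min_p)] == 1 |
                    res$p_obs < max(min_p)))
  expect_error(permutation_adjust(m, sv, B = 0), "B must be")
})

test_that("adjusted p never undercuts the raw p under the null", {
  # with no true effect every raw p is well above the 1/B granularity and
  # the min across genes can only inflate it
  d <- sim_screen_cohort(300, 0.2, 0, seed = 33, n_genes = 8)
  res <- permutation_adjust(d$mat,
                            list(time = d$surv$time, event = d$surv$event),
                            B = 100, seed = 3)
  expect_true(all(res$p_adjusted >= res$p_obs - 1e-12))
})

test_that("two-gene partition is exhaustive, disjoint, and df-reducing", {
  set.seed(37)
  n <- 120
  ids <- sprintf("s%03d", seq_len(n))
  a <- rbinom(n, 1, 0.3) == 1
  b <- rbinom(n, 1, 0.4) == 1
  m <- mutmat(cbind(MAP3K1 = a, PIK3CA = b))
  rownames(m) <- ids
  sv <- make_surv_df(ids, rexp(n, 0.1), rbinom(n, 1, 0.7))
  tg <- two_gene_analysis(m, sv)
  expect_equal(sum(tg$table$n), n)
  expect_equal(sort(unique(tg$groups)),
               sort(c("both", "a_only", "b_only", "neither")))
  # empty both-group: 3-group test with a warning
  a2 <- c(rep(TRUE, 30), rep(FALSE, 90))
  b2 <- c(rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 60))
  m2 <- mutmat(cbind(MAP3K1 = a2, PIK3CA = b2)); rownames(m2) <- ids
  expect_warning(tg2 <- two_gene_analysis(m2, sv), "dropped")
  expect_equal(tg2$logrank$df, 2)
  expect_error(two_gene_analysis(m, sv, gene_a = "NOPE"), "not in matrix")
})

test_that("additive protective effects put the double-mutant curve on top", {
  set.seed(43)
  n <- 2000
  ids <- sprintf("s%04d", seq_len(n))
  a <- rbinom(n, 1, 0.3); b <- rbinom(n, 1, 0.4)
  tm <- rexp(n, 0.08 * exp(-0.6 * a - 0.6 * b))
  ev <- as.integer(tm < 20); tm <- pmin(tm, 20)
  m <- mutmat(cbind(MAP3K1 = a == 1, PIK3CA = b == 1)); rownames(m) <- ids
  sv <- make_surv_df(ids, tm, ev)
  tg <- two_gene_analysis(m, sv)
  s10 <- vapply(tg$km, function(k) {
    i <- which(k$time <= 10); if (!length(i)) 1 else k$surv[max(i)]
  }, numeric(1))
  expect_true(s10["both"] == max(s10))
  expect_lt(tg$logrank$p, 1e-6)
})
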