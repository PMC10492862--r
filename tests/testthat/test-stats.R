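# ANOVA, Fisher combination, KS, BH and the site-level testing machinery.

test_that("one-way ANOVA matches hand and brute-force computations", {
  r <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$F, 3.0, tolerance = 1e-12)
  expect_equal(r$p, stats::pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  same <- anova_oneway(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # two groups: F equals the squared equal-variance t statistic
  x <- c(1.2, 3.1, 2.2, 4.0); y <- c(2.5, 5.1, 3.3)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(anova_oneway(list(x, y))$F, unname(tt$statistic)^2, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:20) {
    gr <- lapply(seq_len(sample(2:4, 1)), function(j) stats::rnorm(sample(3:8, 1)))
    expect_equal(anova_oneway(gr)$F, anova_F_oracle(gr), tolerance = 1e-10)
  }

  expect_error(anova_oneway(list(1:3)), "2 groups")
  expect_error(anova_oneway(list(1:3, 2)), ">= 2 values")
})

test_that("Fisher's method combines p-values via the chi-square upper tail", {
  expect_equal(fisher_combine(0.2), 0.2, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1)), 1.0)
  # independent numerical check of the chi-square survival integral
  X <- -2 * sum(log(c(0.05, 0.05)))
  surv <- stats::integrate(function(x) stats::dchisq(x, df = 4), X, Inf,
                           rel.tol = 1e-12)$value
  expect_equal(fisher_combine(c(0.05, 0.05)), surv, tolerance = 1e-9)
  expect_lt(abs(fisher_combine(c(0.05, 0.05)) - 0.0175), 1e-3)

  expect_error(fisher_combine(numeric(0)), "no p-values")
  expect_error(fisher_combine(c(0.5, 1.2)), "in \\(0, 1\\]")
  expect_warning(p0 <- fisher_combine(c(0, 0.5)), "floored")
  expect_true(p0 > 0)

  # a diluted pair is never more significant than a concordant pair
  for (p in c(0.001, 0.01, 0.2, 0.6)) {
    expect_gte(fisher_combine(c(p, 1)), fisher_combine(c(p, p)))
  }
})

test_that("two-sample KS statistic matches hand-computed ECDF gaps", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))$D, 0.25)
  d <- ks_two_sample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(d$D, 1)
  expect_lt(d$p, 0.2)   # exact small-sample p for complete separation
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment reproduces the step-up values and dominates raw p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(8)
  p <- stats::runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in the sorted order
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("BH thresholding controls the simulated false discovery rate", {
  set.seed(97)
  fdps <- replicate(200, {
    true_alt <- c(rep(TRUE, 20), rep(FALSE, 80))
    p <- ifelse(true_alt, stats::rbeta(100, 0.1, 1), stats::runif(100))
    sel <- bh_fdr(p) < 0.1
    if (!any(sel)) 0 else mean(!true_alt[sel])
  })
  expect_lte(mean(fdps), 0.1 + 0.02)
})

# small deterministic peptidoform table for test_sites
make_pf_table <- function(shift = 0, n_rep = 4, groups = c("WT", "M")) {
  grid <- expand.grid(pf = c("P1:1-10", "P1:8-20"), group = groups,
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  set.seed(5)
  s <- 0.4 + ifelse(grid$group == "M", shift, 0) + stats::rnorm(nrow(grid), 0, 0.01)
  data.frame(protein_id = "P1", site_position = 5L, peptidoform_id = grid$pf,
             group = grid$group, replicate_id = paste0(grid$group, "_r", grid$rep),
             s = pmin(pmax(s, 0), 1))
}

test_that("test_sites combines per-peptidoform ANOVA p-values across peptidoforms", {
  pf <- make_pf_table(shift = 0.2)
  res <- test_sites(pf, groups = c("WT", "M"), ref = "WT")
  expect_equal(nrow(res), 1)
  expect_equal(res$n_peptidoforms, 2L)
  expect_true(res$significant)
  expect_equal(res$delta, 0.2, tolerance = 0.05)
  # p_site is the Fisher combination of the per-peptidoform ANOVA p-values
  pp <- vapply(split(pf, pf$peptidoform_id), function(d) {
    anova_oneway(split(d$s, d$group))$p
  }, numeric(1))
  expect_equal(res$p_site, fisher_combine(pp), tolerance = 1e-12)
  expect_equal(res$p_anova, min(pp), tolerance = 1e-12)
})

test_that("sites without full replication in every group are excluded, not tested", {
  pf <- make_pf_table(shift = 0.2)
  pf_missing <- pf[!(pf$group == "M"), ]   # site absent in the model group
  res <- test_sites(pf_missing, groups = c("WT", "M"), ref = "WT")
  expect_equal(nrow(res), 0)
  exc <- attr(res, "excluded")
  expect_equal(nrow(exc), 1)
  expect_equal(exc$groups_present, "WT")

  # under-replication is also excluded
  pf_low <- pf[!(pf$group == "M" & pf$replicate_id %in% c("M_r1", "M_r2")), ]
  res2 <- test_sites(pf_low, groups = c("WT", "M"), ref = "WT", min_replicates = 3)
  expect_equal(nrow(res2), 0)
})

test_that("model overlap counts shared and unique significant sites", {
  mk <- function(sites, sig, ref = "WT") {
    res <- data.frame(protein_id = sub(":.*", "", sites),
                      site_position = as.integer(sub(".*:", "", sites)),
                      site_key = sites, delta = 0.1,
                      p_site = ifelse(sites %in% sig, 0.001, 0.9))
    res$q_bh <- bh_fdr(res$p_site); res$significant <- res$p_site < 0.05
    attr(res, "ref_group") <- ref; attr(res, "alpha") <- 0.05
    class(res) <- c("group_comparison", class(res))
    res
  }
  all_sites <- paste0("P", 1:6, ":", 10)
  a <- mk(all_sites, all_sites[1:3])
  b <- mk(all_sites, all_sites[2:4])
  ov <- compare_models(a, b)
  expect_equal(ov$sites$shared, 2)
  expect_equal(ov$sites$unique_A, 1)
  expect_equal(ov$sites$unique_B, 1)
  expect_equal(ov$sites$total_A, 3)

  # identical tables: nothing unique
  ov2 <- compare_models(a, a)
  expect_equal(ov2$sites$unique_A, 0)
  expect_equal(ov2$sites$unique_B, 0)
  expect_equal(ov2$shared_fraction, 1)

  # mismatched reference groups are rejected
  b2 <- mk(all_sites, all_sites[2:4], ref = "other")
  expect_error(compare_models(a, b2), "reference group")
})

test_that("detection rate increases with effect size at fixed noise", {
  # same latent design, three planted effect sizes
  rates <- vapply(c(0.05, 0.1, 0.2), function(d) {
    set.seed(202)
    hits <- replicate(60, {
      pf <- make_pf_table(shift = 0)
      pf$s[pf$group == "M"] <- pf$s[pf$group == "M"] + d +
        stats::rnorm(sum(pf$group == "M"), 0, 0.05)
      res <- test_sites(pf, groups = c("WT", "M"), ref = "WT")
      res$p_site < 0.05
    })
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})
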