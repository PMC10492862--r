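# Envelope correction, stoichiometry computation and site aggregation.

test_that("heavy-channel correction subtracts light leakage and clamps at zero", {
  expect_equal(as.numeric(correct_heavy(900, 120, 0.02)), 102)
  expect_equal(as.numeric(correct_heavy(500, 77, 0)), 77)
  clamped <- correct_heavy(100, 1, 0.05)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_false(attr(correct_heavy(900, 120, 0.02), "clamped"))
  expect_error(correct_heavy(-1, 5, 0.1), "non-negative")
  expect_error(correct_heavy(1, 5, -0.1), "non-negative")
})

test_that("fragment stoichiometry is light over total, NA when undefined", {
  expect_equal(fragment_stoichiometry(900, 102), 900 / 1002)
  expect_equal(fragment_stoichiometry(5, 0), 1)
  expect_equal(fragment_stoichiometry(0, 3), 0)
  expect_true(is.na(fragment_stoichiometry(0, 0)))
  expect_error(fragment_stoichiometry(-1, 1), "non-negative")
})

make_toy_quant <- function(s_values, min_k = 1L) {
  n <- length(s_values)
  data.frame(
    protein_id = "P1", site_position = 10L,
    peptidoform_id = "P1:5-15", charge = 1L,
    fragment_kind = "b", fragment_index = seq_len(n) + 5L,
    k_acetyl = min_k, group = "WT", replicate_id = "WT_r1",
    light_area = 1000 * s_values, heavy_area = 1000 * (1 - s_values)
  )
}

toy_pairs <- function(quant) {
  data.frame(quant[, c("peptidoform_id", "charge", "fragment_kind", "fragment_index")],
             correction_ratio = 0)
}

test_that("site aggregation is the median over fragments with a count threshold", {
  q <- make_toy_quant(c(0.2, 0.3, 0.4))
  sq <- quantify_sites(q, toy_pairs(q), min_fragments = 3)
  expect_equal(nrow(sq$sites), 1)
  expect_equal(sq$sites$s, 0.3)
  expect_equal(sq$sites$n_fragments_used, 3L)

  # below the threshold no row is emitted
  q2 <- make_toy_quant(c(0.2, 0.4))
  sq2 <- quantify_sites(q2, toy_pairs(q2), min_fragments = 3)
  expect_equal(nrow(sq2$sites), 0)

  # identical fragment values are idempotent under aggregation
  q3 <- make_toy_quant(rep(0.37, 10))
  sq3 <- quantify_sites(q3, toy_pairs(q3))
  expect_equal(sq3$sites$s, 0.37)

  # mean aggregation available via config
  q4 <- make_toy_quant(c(0.2, 0.3, 0.7))
  sq4 <- quantify_sites(q4, toy_pairs(q4), aggregate = "mean")
  expect_equal(sq4$sites$s, mean(c(0.2, 0.3, 0.7)))
})

test_that("fragments covering two or more lysines are discarded", {
  q <- rbind(make_toy_quant(c(0.2, 0.3, 0.4)), make_toy_quant(rep(0.9, 3), min_k = 2L))
  sq <- quantify_sites(q, toy_pairs(q))
  expect_equal(sq$sites$s, 0.3)
  expect_equal(sq$qc$n_multi_k_discarded, 3)
})

test_that("quant schema violations are rejected with informative errors", {
  q <- make_toy_quant(c(0.2, 0.3, 0.4))
  expect_error(quantify_sites(q[, -1], toy_pairs(q)), "protein_id")
  expect_error(quantify_sites(q[0, ], toy_pairs(q)), "empty")
  qneg <- q; qneg$light_area[1] <- -5
  expect_error(quantify_sites(qneg, toy_pairs(q)), "non-negative")
})

test_that("noise-free simulation is recovered exactly through the pipeline", {
  st <- noise_free_study(seed = 7)
  sq <- quantify_sites(st$quant, st$pairs)
  m <- merge(sq$sites, st$truth, by = c("protein_id", "site_position", "group"))
  expect_gt(nrow(m), 0)
  expect_lt(max(abs(m$s - m$s_true)), 1e-9)
  # every reported stoichiometry is a proportion
  expect_true(all(sq$sites$s >= 0 & sq$sites$s <= 1))
})

test_that("estimated stoichiometry is strictly increasing in true stoichiometry", {
  # fixed total abundance, no noise, leakage on: the estimator chain must be
  # strictly monotone in s
  r <- 0.02
  s_true <- seq(0.05, 0.95, by = 0.05)
  L <- 1000 * s_true
  H_obs <- 1000 * (1 - s_true) + L * r
  s_hat <- fragment_stoichiometry(L, as.numeric(correct_heavy(L, H_obs, r)))
  expect_true(all(diff(s_hat) > 0))
  expect_equal(s_hat, s_true, tolerance = 1e-12)
})

test_that("stoichiometries stay in [0, 1] under heavy noise", {
  st <- make_study(study_config(n_proteins = 25, n_sites = 30, cv = 0.5,
                                missing_rate = 0.2, seed = 13))
  sq <- quantify_sites(st$quant, st$pairs)
  expect_true(all(sq$sites$s >= 0 & sq$sites$s <= 1))
  expect_true(all(sq$fragments$s >= 0 & sq$fragments$s <= 1))
})

test_that("disabling envelope correction biases stoichiometry downward", {
  st <- make_study(study_config(n_proteins = 30, n_sites = 40, seed = 5))
  sq_on <- quantify_sites(st$quant, st$pairs, correction = TRUE)
  sq_off <- quantify_sites(st$quant, st$pairs, correction = FALSE)
  m <- merge(
    merge(sq_on$sites[, .(protein_id, site_position, group, replicate_id, s_on = s)],
          sq_off$sites[, .(protein_id, site_position, group, replicate_id, s_off = s)],
          by = c("protein_id", "site_position", "group", "replicate_id")),
    unique(st$truth[, c("protein_id", "site_position", "group", "s_true")]),
    by = c("protein_id", "site_position", "group"))
  # without correction the heavy channel keeps light leakage: bias negative
  bias_off <- mean(m$s_off - m$s_true)
  bias_on <- mean(m$s_on - m$s_true)
  expect_lt(bias_off, 0)
  expect_lt(abs(bias_on), abs(bias_off))
  err_on <- median(abs(m$s_on - m$s_true))
  err_off <- median(abs(m$s_off - m$s_true))
  expect_lt(err_on, err_off)
})

test_that("labeling QC reports the acetylated fraction and warns below 99%", {
  tb <- data.frame(k_state = c(rep("acetyl-light", 300), rep("acetyl-heavy", 696),
                               rep("unmodified", 4)))
  expect_silent(expect_equal(qc_labeling(tb), 0.996))
  expect_equal(qc_labeling(data.frame(k_state = rep("acetyl-heavy", 50))), 1.0)
  tb2 <- data.frame(k_state = c(rep("acetyl-light", 980), rep("unmodified", 20)))
  expect_warning(expect_equal(qc_labeling(tb2), 0.98), "labeling efficiency")
  expect_error(qc_labeling(data.frame(k_state = character())), "empty")
})
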