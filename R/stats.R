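# Per-site group comparison and distribution statistics.
#
# Testing scheme: a one-way ANOVA (stoichiometry ~ group, no covariates) is
# run per peptidoform at a site, and the per-peptidoform p-values are
# combined across peptidoforms by Fisher's method to give the site-level
# p-value. Fragments within a peptidoform are not independent (they sample
# the same precursor), so they are collapsed to one value per replicate
# before testing; distinct peptidoforms are treated as approximately
# independent observations of the site.

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test) on a list of numeric group samples.
#'
#' @param groups List of numeric vectors, one per group; at least 2 groups
#'   with at least 2 values each.
#' @return Named list with `F` and `p` (upper tail of the F distribution).
#'   Degenerate inputs: identical values everywhere give `F = 0, p = 1`;
#'   zero within-group variance with real between-group spread gives
#'   `F = Inf` and the smallest positive representable p.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) return(list(F = 0, p = 1))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) return(list(F = Inf, p = .Machine$double.xmin))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p_i))` is referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`. Zeros are floored
#'   at the smallest positive representable double (with a warning).
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # ~0.0175
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values to combine")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (any(pvalues == 0)) {
    warning("p-value of 0 floored at .Machine$double.xmin")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(pvalues))
  stats::pchisq(X, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the exact null distribution for small
#' samples (both n <= 10) and the asymptotic distribution otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return Named list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) <= 10L && length(y) <= 10L
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1).
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-site group comparison
#'
#' For each acetylation site, runs a one-way ANOVA (`stoichiometry ~ group`)
#' per peptidoform and combines the per-peptidoform p-values across
#' peptidoforms with Fisher's method. Sites not observed with at least
#' `min_replicates` replicates in every requested group (for at least one
#' peptidoform) are excluded from testing and reported separately.
#'
#' @param peptidoforms Peptidoform-level stoichiometry table (the
#'   `peptidoforms` element of [quantify_sites()]): columns `protein_id`,
#'   `site_position`, `peptidoform_id`, `group`, `replicate_id`, `s`.
#' @param groups Character vector of group labels to compare (2 for a
#'   model-vs-reference volcano, or all groups for a joint test).
#' @param ref Reference group label (must be in `groups`); effect sizes
#'   (`delta`) are computed against it.
#' @param alpha Significance threshold on the Fisher-combined p (default
#'   0.05, unadjusted, mirroring the display convention; BH-adjusted values
#'   are reported alongside).
#' @param min_replicates Minimum replicates per group per peptidoform
#'   (default 3).
#' @return Data frame of class `group_comparison` with one row per tested
#'   site: `protein_id`, `site_position`, `site_key`, per-group means
#'   (`mean_<group>`), `delta` (non-reference mean minus reference mean; NA
#'   when more than two groups are compared), `n_peptidoforms`, `p_anova`
#'   (minimum per-peptidoform ANOVA p), `p_site` (Fisher-combined), `q_bh`,
#'   `significant`. Attributes: `ref_group`, `groups`, `alpha`, and
#'   `excluded` (presence/absence table of untested sites).
#' @export
test_sites <- function(peptidoforms, groups, ref = groups[1], alpha = 0.05,
                       min_replicates = 3L) {
  pf <- data.table::as.data.table(peptidoforms)
  need <- c("protein_id", "site_position", "peptidoform_id", "group",
            "replicate_id", "s")
  miss <- setdiff(need, names(pf))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!ref %in% groups) stop("'ref' must be one of 'groups'")
  if (length(groups) < 2L) stop("need >= 2 groups")
  pf <- pf[group %in% groups]
  if (!nrow(pf)) stop("no measurements for the requested groups")

  # peptidoforms fully replicated in every requested group
  cnt <- pf[, .(n = .N), by = .(protein_id, site_position, peptidoform_id, group)]
  ok <- cnt[, .(valid = (.N == length(groups)) && all(n >= min_replicates)),
            by = .(protein_id, site_position, peptidoform_id)]
  pf <- merge(pf, ok, by = c("protein_id", "site_position", "peptidoform_id"),
              sort = FALSE)

  all_sites <- unique(pf[, .(protein_id, site_position)])
  tested <- unique(pf[valid == TRUE, .(protein_id, site_position)])
  excluded <- data.table::fsetdiff(all_sites, tested)
  excluded_tb <- merge(
    excluded,
    unique(pf[, .(protein_id, site_position, group)])[
      , .(groups_present = paste(sort(unique(group)), collapse = ",")),
      by = .(protein_id, site_position)],
    by = c("protein_id", "site_position"), all.x = TRUE, sort = FALSE)

  pv <- pf[valid == TRUE]
  if (!nrow(pv)) {
    res <- data.table::data.table(protein_id = character(),
                                  site_position = integer())
  } else {
    ppf <- pv[, .(p = anova_oneway(split(s, group))$p),
              by = .(protein_id, site_position, peptidoform_id)]
    res <- ppf[, .(n_peptidoforms = .N, p_anova = min(p),
                   p_site = fisher_combine(p)),
               by = .(protein_id, site_position)]
    gm <- pv[, .(m = mean(s)), by = .(protein_id, site_position, group)]
    gw <- data.table::dcast(gm, protein_id + site_position ~ group,
                            value.var = "m")
    data.table::setnames(gw, setdiff(names(gw), c("protein_id", "site_position")),
                         paste0("mean_", setdiff(names(gw), c("protein_id", "site_position"))))
    res <- merge(res, gw, by = c("protein_id", "site_position"), sort = FALSE)
    nonref <- setdiff(groups, ref)
    res[, delta := if (length(nonref) == 1L) {
      get(paste0("mean_", nonref)) - get(paste0("mean_", ref))
    } else NA_real_]
    res[, q_bh := bh_fdr(p_site)]
    res[, significant := p_site < alpha]
    res[, site_key := paste0(protein_id, ":", site_position)]
    data.table::setcolorder(res, c("protein_id", "site_position", "site_key"))
    data.table::setorder(res, protein_id, site_position)
  }
  res <- res[]
  data.table::setattr(res, "ref_group", ref)
  data.table::setattr(res, "groups", groups)
  data.table::setattr(res, "alpha", alpha)
  data.table::setattr(res, "excluded", excluded_tb[])
  data.table::setattr(res, "class", c("group_comparison", class(res)))
  res
}

#' Overlap of two model-vs-reference comparisons
#'
#' Summarizes shared and model-unique significant sites and proteins between
#' two [test_sites()] results computed against the same reference group, and
#' emits volcano-plot tables (effect size vs -log10 Fisher p) for each.
#'
#' @param resA,resB `group_comparison` results for model A and model B, both
#'   against the same reference group.
#' @param alpha Significance threshold; defaults to the alpha stored in
#'   `resA`.
#' @return List of class `model_overlap`: `sites` and `proteins` overlap
#'   counts (`unique_A`, `unique_B`, `shared`, `total_A`, `total_B`),
#'   `shared_fraction` (shared / mean per-model significant count), and
#'   `volcano_A` / `volcano_B` tables.
#' @export
compare_models <- function(resA, resB, alpha = NULL) {
  if (!inherits(resA, "group_comparison") || !inherits(resB, "group_comparison")) {
    stop("inputs must be test_sites() results")
  }
  if (!identical(attr(resA, "ref_group"), attr(resB, "ref_group"))) {
    stop("comparisons were not computed against the same reference group")
  }
  if (is.null(alpha)) alpha <- attr(resA, "alpha")
  sigA <- resA[resA$p_site < alpha, ]
  sigB <- resB[resB$p_site < alpha, ]
  ov <- function(a, b) {
    shared <- length(intersect(a, b))
    list(unique_A = length(setdiff(a, b)), unique_B = length(setdiff(b, a)),
         shared = shared, total_A = length(a), total_B = length(b))
  }
  sites <- ov(sigA$site_key, sigB$site_key)
  prots <- ov(unique(sigA$protein_id), unique(sigB$protein_id))
  volcano <- function(res) {
    data.frame(site_key = res$site_key, delta = res$delta,
               neg_log10_p = -log10(res$p_site),
               significant = res$p_site < alpha)
  }
  denom <- mean(c(sites$total_A, sites$total_B))
  structure(list(
    sites = sites, proteins = prots,
    shared_fraction = if (denom > 0) sites$shared / denom else NA_real_,
    alpha = alpha,
    volcano_A = volcano(resA), volcano_B = volcano(resB)
  ), class = "model_overlap")
}

#' @export
print.model_overlap <- function(x, ...) {
  cat(sprintf(paste0(
    "<model_overlap> alpha = %g\n",
    "  sites:    A-only %d | shared %d | B-only %d  (totals %d / %d)\n",
    "  proteins: A-only %d | shared %d | B-only %d  (totals %d / %d)\n",
    "  shared fraction of significant sites: %.3f\n"),
    x$alpha,
    x$sites$unique_A, x$sites$shared, x$sites$unique_B,
    x$sites$total_A, x$sites$total_B,
    x$proteins$unique_A, x$proteins$shared, x$proteins$unique_B,
    x$proteins$total_A, x$proteins$total_B,
    x$shared_fraction))
  invisible(x)
}
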