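# Envelope-corrected stoichiometry quantification.
#
# The stoichiometry of acetylation at a site is the fraction of its molecules
# carrying the endogenous (light) acetyl group: s = L / (L + H), where L and
# H are the light and (envelope-corrected) heavy fragment-ion peak areas.
# The heavy channel must first be corrected for the +3k natural isotopologue
# of the light species, which coincides with the heavy monoisotopic peak.

#' Envelope correction of the heavy peak area
#'
#' Removes the contribution of the light species' natural +3k isotopologue
#' from the observed heavy peak area: `H_corr = max(0, H_obs - L * r)`, where
#' `r = a_3k / a_0` of the light fragment's isotope envelope. Over-corrected
#' (negative) values are clamped to zero; use `attr(, "clamped")` to retrieve
#' the clamp flags for QC.
#'
#' @param L Light peak area(s), non-negative.
#' @param H_obs Observed heavy peak area(s), non-negative.
#' @param r Envelope-correction ratio(s), non-negative.
#' @return Corrected heavy area(s), with logical attribute `clamped`.
#' @examples
#' correct_heavy(900, 120, 0.02)   # 102
#' @export
correct_heavy <- function(L, H_obs, r) {
  if (any(L < 0, na.rm = TRUE) || any(H_obs < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative")
  }
  if (any(r < 0, na.rm = TRUE)) stop("correction ratio must be non-negative")
  raw <- H_obs - L * r
  out <- pmax(0, raw)
  attr(out, "clamped") <- raw < 0
  out
}

#' Fragment-level stoichiometry
#'
#' `s = L / (L + H_corr)`, the endogenous (light) fraction of the total
#' (endogenous + chemical) signal. Undefined when `L + H_corr == 0`; such
#' measurements yield `NA` and should be dropped.
#'
#' @param L Light peak area(s).
#' @param H_corr Corrected heavy peak area(s).
#' @return Stoichiometry values in `[0, 1]` (`NA` where undefined).
#' @examples
#' fragment_stoichiometry(900, 102)  # 0.8982...
#' @export
fragment_stoichiometry <- function(L, H_corr) {
  if (any(L < 0, na.rm = TRUE) || any(H_corr < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative")
  }
  tot <- L + H_corr
  ifelse(tot > 0, L / tot, NA_real_)
}

#' Site-level stoichiometry from a paired quantification table
#'
#' Full quantification step: joins observed light/heavy peak areas to the
#' in-silico pair table (for the envelope-correction ratio), corrects the
#' heavy channel, computes fragment stoichiometries, and aggregates to
#' peptidoform and site level. Only site-informative fragments — those
#' covering exactly one lysine — contribute; fragments spanning two or more
#' lysines cannot localize the signal and are discarded.
#'
#' @param quant Quantification table (data frame) with columns `protein_id`,
#'   `site_position`, `peptidoform_id`, `charge`, `fragment_kind`,
#'   `fragment_index`, `k_acetyl`, `group`, `replicate_id`, `light_area`,
#'   `heavy_area`.
#' @param pairs Pair table from [build_pair_table()] (supplies
#'   `correction_ratio` per fragment).
#' @param min_fragments Minimum number of fragment measurements required to
#'   report a site/replicate stoichiometry (default 3, so one interfered
#'   fragment cannot dominate).
#' @param correction Apply envelope correction (default `TRUE`; `FALSE` is
#'   provided for regression testing the necessity of the correction).
#' @param aggregate `"median"` (default, robust) or `"mean"`.
#' @return List of class `site_quant` with elements
#'   \describe{
#'     \item{fragments}{fragment-level table with `H_corr`, `s`, `clamped`}
#'     \item{peptidoforms}{per (site, peptidoform, group, replicate) medians}
#'     \item{sites}{per (site, group, replicate) stoichiometries with
#'       `n_fragments_used` and `clamped_flag`, thresholded at `min_fragments`}
#'     \item{qc}{list: clamp rate, dropped zero-total count, unmatched rows}
#'   }
#' @export
quantify_sites <- function(quant, pairs, min_fragments = 3L, correction = TRUE,
                           aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "median") stats::median else mean
  quant <- data.table::as.data.table(quant)
  .check_quant_schema(quant)
  pairs <- data.table::as.data.table(pairs)

  keyv <- c("peptidoform_id", "charge", "fragment_kind", "fragment_index")
  pr <- unique(pairs[, c(keyv, "correction_ratio"), with = FALSE])
  dt <- merge(quant, pr, by = keyv, all.x = TRUE, sort = FALSE)
  n_unmatched <- sum(is.na(dt$correction_ratio))
  if (n_unmatched > 0) {
    warning(n_unmatched, " quant rows have no matching in-silico fragment pair; dropped")
    dt <- dt[!is.na(dt$correction_ratio)]
  }

  r_eff <- if (correction) dt$correction_ratio else 0
  hc <- correct_heavy(dt$light_area, dt$heavy_area, r_eff)
  dt[, `:=`(H_corr = as.numeric(hc), clamped = attr(hc, "clamped"))]
  dt[, s := fragment_stoichiometry(light_area, H_corr)]
  n_zero_total <- sum(is.na(dt$s))
  dt <- dt[!is.na(s)]

  info <- dt[k_acetyl == 1L]
  pf <- info[, .(s = agg_fun(s), n_fragments = .N),
             by = .(protein_id, site_position, peptidoform_id, group, replicate_id)]
  sites <- info[, .(s = agg_fun(s), n_fragments_used = .N,
                    clamped_flag = any(clamped)),
                by = .(protein_id, site_position, group, replicate_id)]
  sites <- sites[n_fragments_used >= min_fragments]

  structure(list(
    fragments = dt[],
    peptidoforms = pf[],
    sites = sites[],
    qc = list(
      clamp_rate = if (nrow(dt)) mean(dt$clamped) else NA_real_,
      n_zero_total_dropped = n_zero_total,
      n_unmatched_dropped = n_unmatched,
      n_multi_k_discarded = nrow(dt) - nrow(info)
    )
  ), class = "site_quant")
}

#' @export
print.site_quant <- function(x, ...) {
  cat(sprintf(paste0(
    "<site_quant> %d fragment measurements, %d peptidoform rows, %d site rows\n",
    "  clamp rate %.4f; %d zero-total dropped; %d multi-K fragments discarded\n"),
    nrow(x$fragments), nrow(x$peptidoforms), nrow(x$sites),
    x$qc$clamp_rate, x$qc$n_zero_total_dropped, x$qc$n_multi_k_discarded))
  invisible(x)
}

#' Labeling-efficiency QC
#'
#' Fraction of lysine residues carrying either acetyl form (endogenous light
#' or chemical heavy). The chemistry aims for complete labeling (two rounds
#' of D6-acetic anhydride, >99%); a warning is emitted below the threshold
#' because unlabeled lysines bias stoichiometry upward.
#'
#' @param peptidoform_table Data frame with a `k_state` column, one row per
#'   observed lysine, values in `acetyl-light`, `acetyl-heavy`, `unmodified`.
#' @param threshold Warn when the labeled fraction falls below this
#'   (default 0.99).
#' @return Fraction labeled (numeric scalar).
#' @export
qc_labeling <- function(peptidoform_table, threshold = 0.99) {
  tb <- as.data.frame(peptidoform_table)
  if (!nrow(tb)) stop("empty peptidoform table")
  if (!"k_state" %in% names(tb)) stop("'peptidoform_table' must have a 'k_state' column")
  frac <- mean(tb$k_state %in% .ACETYL_MODS)
  if (frac < threshold) {
    warning(sprintf("labeling efficiency %.4f below %.2f threshold", frac, threshold))
  }
  frac
}

.QUANT_COLS <- c("protein_id", "site_position", "peptidoform_id", "charge",
                 "fragment_kind", "fragment_index", "k_acetyl", "group",
                 "replicate_id", "light_area", "heavy_area")

.check_quant_schema <- function(quant) {
  miss <- setdiff(.QUANT_COLS, names(quant))
  if (length(miss)) {
    stop("quant table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!nrow(quant)) stop("quant table is empty")
  if (any(quant$light_area < 0, na.rm = TRUE) ||
      any(quant$heavy_area < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative")
  }
  invisible(TRUE)
}
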