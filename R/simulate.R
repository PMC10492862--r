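# Ground-truthed synthetic data emulating the statistical structure of the
# stoichiometry experiment: three groups (wild type plus two transporter
# overexpression models) x n replicates, per-site true stoichiometries with a
# planted effect structure, near-complete chemical labeling, natural-isotope
# leakage of the light species into the heavy channel, multiplicative
# log-normal peak-area noise, and missingness.

#' Study configuration for the synthetic generator
#'
#' Bundles and validates all generator parameters. Defaults encode the study
#' design the pipeline targets: three groups (WT + two overexpression
#' models), 5 replicates per group, 200 quantifiable sites, labeling
#' efficiency 0.995 (the chemistry achieves >99% after two labeling rounds),
#' peak-area coefficient of variation 0.10, 5% missing fragment
#' measurements, 35% of sites affected per model with 30% of each model's
#' affected sites shared between models, and effect sizes drawn uniformly
#' from \[0.05, 0.30\] with random sign.
#'
#' @param n_proteins,length_range Simulated proteome size and protein length
#'   range.
#' @param n_sites Number of quantifiable lysine sites retained in the study.
#' @param groups Group labels; the first is the reference (wild type).
#' @param n_replicates Replicates per group.
#' @param affected_fraction Fraction of sites with a true effect in each
#'   model.
#' @param shared_fraction Fraction of each model's affected sites shared with
#'   the other model.
#' @param effect_range Range of |delta| (stoichiometry units).
#' @param baseline_range Range of wild-type stoichiometries.
#' @param cv Multiplicative log-normal noise CV per channel.
#' @param eta Chemical labeling efficiency in (0, 1].
#' @param missing_rate Fraction of fragment measurements missing at random.
#' @param t_mean,t_sdlog Log-normal latent total-abundance model per fragment.
#' @param charges,max_missed,length_bounds In-silico digestion / pair-table
#'   settings used for the simulated proteome.
#' @param n_categories,planted_category_size,planted_hit_fraction Annotation
#'   structure: number of random categories, size of the planted category and
#'   the fraction of its members drawn from proteins harboring shared-effect
#'   sites.
#' @param seed Integer seed; the whole bundle is deterministic given the
#'   config.
#' @return Validated list of class `study_config`.
#' @export
study_config <- function(n_proteins = 150L, length_range = c(60L, 120L),
                         n_sites = 200L,
                         groups = c("WT", "sTgA", "sTgB"),
                         n_replicates = 5L,
                         affected_fraction = 0.35,
                         shared_fraction = 0.30,
                         effect_range = c(0.05, 0.30),
                         baseline_range = c(0.05, 0.95),
                         cv = 0.10, eta = 0.995, missing_rate = 0.05,
                         t_mean = 1e5, t_sdlog = 0.5,
                         charges = c(1L, 2L), max_missed = 2L,
                         length_bounds = c(6L, 30L),
                         n_categories = 15L, planted_category_size = 20L,
                         planted_hit_fraction = 0.5,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), length_range = length_range,
              n_sites = as.integer(n_sites), groups = groups,
              n_replicates = as.integer(n_replicates),
              affected_fraction = affected_fraction,
              shared_fraction = shared_fraction,
              effect_range = effect_range, baseline_range = baseline_range,
              cv = cv, eta = eta, missing_rate = missing_rate,
              t_mean = t_mean, t_sdlog = t_sdlog,
              charges = as.integer(charges), max_missed = as.integer(max_missed),
              length_bounds = length_bounds,
              n_categories = as.integer(n_categories),
              planted_category_size = as.integer(planted_category_size),
              planted_hit_fraction = planted_hit_fraction,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1L) stop("n_proteins must be >= 1")
  if (length(cfg$groups) < 2L) stop("need at least a reference and one model group")
  if (cfg$eta <= 0 || cfg$eta > 1) stop("labeling efficiency eta must be in (0, 1]")
  if (cfg$cv < 0) stop("cv must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  if (cfg$affected_fraction < 0 || cfg$affected_fraction > 1) {
    stop("affected_fraction must be in [0, 1]")
  }
  if (cfg$affected_fraction * (2 - cfg$shared_fraction) > 1) {
    stop("affected fractions of the two models exceed the available sites")
  }
  if (cfg$planted_hit_fraction < 0 || cfg$planted_hit_fraction > 1) {
    stop("planted_hit_fraction must be in [0, 1]")
  }
  structure(cfg, class = "study_config")
}

# Default residue frequencies: K, R and E elevated so that Trypsin+GluC
# digestion yields plenty of short single-K (site-informative) peptides;
# P kept low to limit cleavage suppression.
.default_aa_freq <- function() {
  f <- c(K = 0.08, R = 0.08, E = 0.08, P = 0.02, C = 0.02, M = 0.02, W = 0.01)
  rest <- setdiff(rownames(.RESIDUE_COMP), names(f))
  c(f, stats::setNames(rep((1 - sum(f)) / length(rest), length(rest)), rest))
}

#' Simulate a random proteome
#'
#' Random amino-acid sequences with controlled residue frequencies (elevated
#' K/R/E) so that in-silico digestion yields site-informative peptides.
#' Deterministic given `seed`.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Protein length range, inclusive.
#' @param aa_freq Named residue-frequency vector over the 20 residues.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named character vector of sequences (`SYN0001`, ...).
#' @export
simulate_proteome <- function(n_proteins = 150L, length_range = c(60L, 120L),
                              aa_freq = .default_aa_freq(), seed = NULL) {
  if (n_proteins < 1L) stop("n_proteins must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  aa <- names(aa_freq)
  lens <- sample(length_range[1]:length_range[2], n_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = aa_freq), collapse = "")
  }, character(1))
  stats::setNames(seqs, sprintf("SYN%04d", seq_len(n_proteins)))
}

#' Simulate a fragment quantification table
#'
#' For each site-informative fragment pair, group and replicate, draws a
#' latent total abundance `T` (log-normal), sets the expected light signal to
#' `T * (s*eta + (1-eta))` (endogenous acetyl plus unlabeled lysines, which
#' are indistinguishable light signal), the expected heavy monoisotopic
#' signal to `T * (1-s) * eta`, adds natural-isotope leakage
#' `expected_light * r` to the heavy channel (with `r` the fragment's
#' envelope-correction ratio), multiplies both channels by independent
#' log-normal noise of the stated CV, and drops rows at the missing rate.
#'
#' @param truth Data frame with columns `protein_id`, `site_position`,
#'   `group`, `s_true` — the true stoichiometry per site and group.
#' @param pairs Pair table restricted to the simulated sites (only
#'   `k_acetyl == 1` rows are used).
#' @param groups,n_replicates Group labels and replicates per group.
#' @param cv,eta,missing_rate,t_mean,t_sdlog See [study_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Quantification `data.table` in the schema of
#'   [read_quant_table()].
#' @export
simulate_quant <- function(truth, pairs, groups, n_replicates = 5L,
                           cv = 0.10, eta = 0.995, missing_rate = 0.05,
                           t_mean = 1e5, t_sdlog = 0.5, seed = NULL) {
  if (eta <= 0 || eta > 1) stop("labeling efficiency eta must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pr <- data.table::as.data.table(pairs)[k_acetyl == 1L]
  tr <- data.table::as.data.table(truth)
  pr <- merge(pr, tr[, .(protein_id, site_position, group, s_true)],
              by = c("protein_id", "site_position"), allow.cartesian = TRUE)
  reps <- data.table::data.table(group = rep(groups, each = n_replicates),
                                 rep_i = rep(seq_len(n_replicates), length(groups)))
  reps[, replicate_id := paste0(group, "_r", rep_i)]
  dt <- merge(pr, reps, by = "group", allow.cartesian = TRUE)
  data.table::setorder(dt, protein_id, site_position, peptidoform_id, charge,
                       fragment_kind, fragment_index, group, rep_i)
  n <- nrow(dt)
  Tlat <- stats::rlnorm(n, meanlog = log(t_mean), sdlog = t_sdlog)
  light_e <- Tlat * (dt$s_true * eta + (1 - eta))
  heavy_e <- Tlat * (1 - dt$s_true) * eta
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    e1 <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    e2 <- stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  } else {
    e1 <- e2 <- rep(1, n)
  }
  dt[, light_area := light_e * e1]
  dt[, heavy_area := (heavy_e + light_e * correction_ratio) * e2]
  if (missing_rate > 0) dt <- dt[stats::runif(n) >= missing_rate]
  dt[, .QUANT_COLS, with = FALSE]
}

#' Generate a complete ground-truthed study bundle
#'
#' One call producing everything the pipeline consumes: a simulated proteome
#' (FASTA), its in-silico fragment pair table, a per-site/per-group truth
#' table with a planted effect structure (a fraction of sites affected in
#' each overexpression model, a fraction of those shared between models), a
#' noisy fragment quantification table, a category annotation table with one
#' planted category enriched among shared-effect proteins, and a
#' lysine-labeling-state table for QC.
#'
#' @param config A [study_config()].
#' @return List of class `acetyl_study`: `config`, `proteome`, `pairs`,
#'   `truth`, `quant`, `annotations`, `labeling`.
#' @export
make_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stop("'config' must be a study_config()")
  set.seed(config$seed)

  proteome <- simulate_proteome(config$n_proteins, config$length_range)
  pairs <- build_pair_table(proteome, charges = config$charges,
                            max_missed = config$max_missed,
                            length_bounds = config$length_bounds)
  sites <- unique(pairs[k_acetyl == 1L & !is.na(site_position),
                        .(protein_id, site_position)])
  # keep only sites with enough informative fragments to pass the default
  # min_fragments threshold even under missingness
  nfrag <- pairs[k_acetyl == 1L, .N, by = .(protein_id, site_position)]
  sites <- merge(sites, nfrag, by = c("protein_id", "site_position"))[N >= 6L]
  if (nrow(sites) < config$n_sites) {
    stop("only ", nrow(sites), " quantifiable sites available; asked for ",
         config$n_sites, " - increase n_proteins")
  }
  sites <- sites[sample(.N, config$n_sites)][, .(protein_id, site_position)]

  truth <- .plant_effects(sites, config)
  pairs_sel <- merge(pairs, sites, by = c("protein_id", "site_position"))
  quant <- simulate_quant(truth, pairs_sel, groups = config$groups,
                          n_replicates = config$n_replicates,
                          cv = config$cv, eta = config$eta,
                          missing_rate = config$missing_rate,
                          t_mean = config$t_mean, t_sdlog = config$t_sdlog)

  annotations <- .plant_annotations(truth, config)
  labeling <- .simulate_labeling(truth, config)

  structure(list(config = config, proteome = proteome, pairs = pairs_sel,
                 truth = truth, quant = quant, annotations = annotations,
                 labeling = labeling),
            class = "acetyl_study")
}

# Plant the effect structure: per model, affected_fraction of sites carry a
# true effect; shared_fraction of each model's affected sites are common to
# both models (with the same delta, a shared biological response). Effect
# sizes |delta| ~ U(effect_range) with random sign; stoichiometries truncated
# to [0.01, 0.99].
.plant_effects <- function(sites, config) {
  ns <- nrow(sites)
  models <- setdiff(config$groups, config$groups[1])
  n_aff <- round(config$affected_fraction * ns)
  n_shared <- if (length(models) >= 2L) round(config$shared_fraction * n_aff) else 0L
  n_only <- n_aff - n_shared

  idx <- sample(ns)
  take <- function(k) { out <- idx[seq_len(k)]; idx <<- idx[-seq_len(k)]; out }
  shared_idx <- if (n_shared > 0L) take(n_shared) else integer(0)
  only_idx <- lapply(seq_along(models), function(i) {
    if (length(models) >= 2L || i == 1L) take(n_only) else integer(0)
  })

  effect_class <- rep("null", ns)
  effect_class[shared_idx] <- "shared"
  for (i in seq_along(models)) {
    effect_class[only_idx[[i]]] <- paste0(models[i], "-only")
  }

  s_wt <- stats::runif(ns, config$baseline_range[1], config$baseline_range[2])
  draw_delta <- function(k) {
    stats::runif(k, config$effect_range[1], config$effect_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  shared_delta <- draw_delta(length(shared_idx))

  truth <- data.table::rbindlist(lapply(config$groups, function(g) {
    s <- s_wt
    if (g != config$groups[1]) {
      d <- numeric(ns)
      d[shared_idx] <- shared_delta
      i <- match(g, models)
      d[only_idx[[i]]] <- draw_delta(length(only_idx[[i]]))
      aff <- d != 0
      s[aff] <- pmin(pmax(s[aff] + d[aff], 0.01), 0.99)
    }
    data.table::data.table(protein_id = sites$protein_id,
                           site_position = sites$site_position,
                           group = g, s_true = s,
                           effect_class = effect_class)
  }))
  truth[]
}

# Annotation table: n_categories random categories plus one planted category
# ("CAT_PLANTED") drawing planted_hit_fraction of its members from proteins
# harboring shared-effect sites.
.plant_annotations <- function(truth, config) {
  universe <- unique(truth$protein_id)
  shared_prot <- unique(truth$protein_id[truth$effect_class == "shared"])
  rows <- list()
  for (i in seq_len(config$n_categories)) {
    m <- sample(5:25, 1)
    rows[[i]] <- data.frame(
      category_id = sprintf("CAT%02d", i),
      category_name = sprintf("random category %02d", i),
      protein_id = sample(universe, min(m, length(universe))))
  }
  m <- min(config$planted_category_size, length(universe))
  n_hit <- min(round(config$planted_hit_fraction * m), length(shared_prot))
  planted <- unique(c(sample(shared_prot, n_hit),
                      sample(setdiff(universe, shared_prot), m - n_hit)))
  rows[[length(rows) + 1L]] <- data.frame(
    category_id = "CAT_PLANTED", category_name = "planted enriched category",
    protein_id = planted)
  data.table::rbindlist(rows)[]
}

# Lysine labeling-state table: one observed K state per site, replicate and
# group. Endogenous light with probability s, chemical heavy with
# probability (1-s)*eta, unmodified (escaped chemistry) otherwise.
.simulate_labeling <- function(truth, config) {
  tr <- data.table::as.data.table(truth)
  n_rep <- config$n_replicates
  dt <- tr[rep(seq_len(.N), each = n_rep)]
  dt[, replicate_id := paste0(group, "_r", rep(seq_len(n_rep), times = nrow(tr)))]
  u <- stats::runif(nrow(dt))
  p_light <- dt$s_true
  p_heavy <- (1 - dt$s_true) * config$eta
  dt[, k_state := ifelse(u < p_light, "acetyl-light",
                         ifelse(u < p_light + p_heavy, "acetyl-heavy",
                                "unmodified"))]
  dt[, .(protein_id, site_position, group, replicate_id, k_state)]
}

#' @export
print.acetyl_study <- function(x, ...) {
  cat(sprintf(paste0(
    "<acetyl_study> seed %d: %d proteins, %d sites, groups %s x %d replicates\n",
    "  quant rows %d; cv %.2f, eta %.3f, missing %.2f\n"),
    x$config$seed, length(x$proteome),
    nrow(unique(x$truth[, c("protein_id", "site_position")])),
    paste(x$config$groups, collapse = "/"), x$config$n_replicates,
    nrow(x$quant), x$config$cv, x$config$eta, x$config$missing_rate))
  invisible(x)
}

#' Write / read a study bundle on disk
#'
#' Writes FASTA, pair table, quant table, truth table, annotation table,
#' labeling table and a JSON echo of the configuration into `dir`.
#'
#' @param study An [make_study()] bundle.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(fasta = file.path(dir, "proteome.fasta"),
         pairs = file.path(dir, "pair_table.tsv"),
         quant = file.path(dir, "quant_table.tsv"),
         truth = file.path(dir, "truth.tsv"),
         annotations = file.path(dir, "annotations.tsv"),
         labeling = file.path(dir, "labeling.tsv"),
         config = file.path(dir, "config.json"))
  write_fasta(study$proteome, p[["fasta"]])
  write_pair_table(study$pairs, p[["pairs"]])
  write_quant_table(study$quant, p[["quant"]])
  .write_tsv(study$truth, p[["truth"]], "truth")
  .write_tsv(study$annotations, p[["annotations"]], "annotations")
  .write_tsv(study$labeling, p[["labeling"]], "labeling")
  jsonlite::write_json(unclass(study$config), p[["config"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' @rdname write_study
#' @param path Path to a truth TSV written by [write_study()].
#' @export
read_truth <- function(path) {
  .read_tsv(path, required = c("protein_id", "site_position", "group",
                               "s_true", "effect_class"),
            schema = "truth")
}

#' Simulate an over-representation problem with one planted category
#'
#' Generates a protein universe, random annotation categories and one
#' planted category whose members enter the significant list with elevated
#' probability so that its expected fold enrichment equals `planted_fold`.
#' Used to benchmark [enrich()] against ground truth.
#'
#' @param n_universe Universe size.
#' @param n_categories Number of random (null) categories.
#' @param category_size Size of every category.
#' @param sig_size Expected significant-list size.
#' @param planted_fold Target fold enrichment of the planted category.
#' @param seed Integer seed, or `NULL`.
#' @return List: `universe`, `annotations`, `sig_proteins`,
#'   `planted_id` (`"CAT_PLANTED"`).
#' @export
simulate_enrichment <- function(n_universe = 1000L, n_categories = 20L,
                                category_size = 40L, sig_size = 100L,
                                planted_fold = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_hit <- planted_fold * sig_size / n_universe
  if (p_hit > 1) stop("planted_fold too large for this universe/list size")
  universe <- sprintf("U%04d", seq_len(n_universe))
  planted <- sample(universe, category_size)
  in_sig <- planted[stats::runif(category_size) < p_hit]
  p_rest <- (sig_size - planted_fold * sig_size * category_size / n_universe) /
    (n_universe - category_size)
  rest <- setdiff(universe, planted)
  in_sig <- c(in_sig, rest[stats::runif(length(rest)) < max(p_rest, 0)])
  rows <- lapply(seq_len(n_categories), function(i) {
    data.frame(category_id = sprintf("CAT%02d", i),
               category_name = sprintf("random category %02d", i),
               protein_id = sample(universe, category_size))
  })
  rows[[n_categories + 1L]] <- data.frame(
    category_id = "CAT_PLANTED", category_name = "planted enriched category",
    protein_id = planted)
  list(universe = universe,
       annotations = data.table::rbindlist(rows)[],
       sig_proteins = in_sig,
       planted_id = "CAT_PLANTED")
}
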