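# High-level pipeline steps, shared by interactive use and the command-line
# wrapper: quantify -> test -> enrich, each reading and writing the package's
# plain-text formats.

#' Quantify site stoichiometries from files
#'
#' Reads a protein FASTA and a fragment quantification TSV, rebuilds the
#' in-silico fragment pair table (for envelope-correction ratios), and writes
#' the site stoichiometry table plus a QC report.
#'
#' @param fasta,quant Input file paths.
#' @param outdir Output directory.
#' @param min_fragments,correction,aggregate See [quantify_sites()].
#' @param charges,max_missed,length_bounds,gluc_specificity See
#'   [build_pair_table()].
#' @return The [quantify_sites()] result, invisibly. Writes
#'   `site_table.tsv`, `peptidoform_table.tsv` and `quantify_qc.json` into
#'   `outdir`.
#' @export
run_quantify <- function(fasta, quant, outdir, min_fragments = 3L,
                         correction = TRUE, aggregate = "median",
                         charges = c(1L, 2L), max_missed = 5L,
                         length_bounds = c(6L, 30L), gluc_specificity = "E") {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  proteins <- read_fasta(fasta)
  qt <- read_quant_table(quant)
  pairs <- build_pair_table(proteins, charges = charges, max_missed = max_missed,
                            length_bounds = length_bounds,
                            gluc_specificity = gluc_specificity)
  sq <- quantify_sites(qt, pairs, min_fragments = min_fragments,
                       correction = correction, aggregate = aggregate)
  write_site_table(sq$sites, file.path(outdir, "site_table.tsv"))
  .write_tsv(sq$peptidoforms, file.path(outdir, "peptidoform_table.tsv"),
             "peptidoform_table")
  jsonlite::write_json(sq$qc, file.path(outdir, "quantify_qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sq)
}

#' Test sites and summarize model overlap from files
#'
#' Quantifies (via [run_quantify()] inputs already on disk) and runs the
#' per-site comparison of each non-reference group against the reference,
#' writing one comparison TSV per model and an overlap summary JSON when two
#' or more models are present.
#'
#' @param fasta,quant Input file paths.
#' @param outdir Output directory.
#' @param ref Reference group label (default `"WT"`).
#' @param alpha Significance threshold on the Fisher-combined p.
#' @param min_replicates,min_fragments See [test_sites()] /
#'   [quantify_sites()].
#' @param ... Passed to [run_quantify()].
#' @return List with `comparisons` (one [test_sites()] result per model) and
#'   `overlap` (a [compare_models()] result, or `NULL` for a single model),
#'   invisibly.
#' @export
run_test <- function(fasta, quant, outdir, ref = "WT", alpha = 0.05,
                     min_replicates = 3L, min_fragments = 3L, ...) {
  sq <- run_quantify(fasta, quant, outdir, min_fragments = min_fragments, ...)
  grps <- unique(sq$peptidoforms$group)
  if (!ref %in% grps) stop("reference group '", ref, "' not present in the data")
  models <- setdiff(grps, ref)
  if (!length(models)) stop("no non-reference group to test")
  comparisons <- lapply(models, function(m) {
    res <- test_sites(sq$peptidoforms, groups = c(ref, m), ref = ref,
                      alpha = alpha, min_replicates = min_replicates)
    write_comparison(res, file.path(outdir, paste0("comparison_", m, "_vs_",
                                                   ref, ".tsv")))
    res
  })
  names(comparisons) <- models
  overlap <- NULL
  if (length(models) >= 2L) {
    overlap <- compare_models(comparisons[[1]], comparisons[[2]], alpha = alpha)
    write_overlap_json(overlap, file.path(outdir, "overlap.json"))
  }
  invisible(list(comparisons = comparisons, overlap = overlap))
}

#' Over-representation analysis from files
#'
#' Reads one or more comparison TSVs and an annotation TSV, takes the
#' proteins harboring significant sites (in all comparisons jointly:
#' significant in each, i.e. the shared set, when `mode = "shared"`, or in
#' any, when `mode = "union"`), and tests category over-representation
#' against the universe of all tested proteins.
#'
#' @param comparison_files Paths to comparison TSVs written by [run_test()].
#' @param annotations Path to the annotation TSV.
#' @param outdir Output directory.
#' @param mode `"union"` (default) or `"shared"`.
#' @param alpha Site-significance threshold.
#' @param top_n,min_fold,fdr_cut See [enrich()].
#' @return The [enrich()] result, invisibly. Writes `enrichment.tsv`.
#' @export
run_enrich <- function(comparison_files, annotations, outdir,
                       mode = c("union", "shared"), alpha = 0.05,
                       top_n = 10L, min_fold = 5, fdr_cut = 0.05) {
  mode <- match.arg(mode)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tabs <- lapply(comparison_files, function(p) {
    .read_tsv(p, required = c("protein_id", "site_position", "p_site"),
              schema = "comparison")
  })
  sig_sets <- lapply(tabs, function(tb) unique(tb$protein_id[tb$p_site < alpha]))
  sig <- if (mode == "shared") Reduce(intersect, sig_sets) else Reduce(union, sig_sets)
  universe <- Reduce(union, lapply(tabs, function(tb) unique(tb$protein_id)))
  ann <- read_annotations(annotations)
  res <- enrich(sig, ann, universe, top_n = top_n, min_fold = min_fold,
                fdr_cut = fdr_cut)
  .write_tsv(res, file.path(outdir, "enrichment.tsv"), "enrichment")
  full <- attr(res, "all")
  .write_tsv(full, file.path(outdir, "enrichment_all.tsv"), "enrichment")
  invisible(res)
}
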