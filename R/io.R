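# Readers and writers for the plain-text formats used by the pipeline.
# Every TSV written by the package carries a one-line comment header naming
# the schema and its version; readers skip it transparently.

.SCHEMA_VERSION <- 1L

#' Read protein sequences from FASTA
#'
#' The accession is the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  nm <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  stats::setNames(as.character(aa), nm)
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

.write_tsv <- function(x, path, schema) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# acstoich schema=%s version=%d", schema, .SCHEMA_VERSION), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, required = NULL, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && startsWith(first, "#")) 1L else 0L
  if (skip == 1L && !is.null(schema) && !grepl(paste0("schema=", schema), first)) {
    warning("file ", path, " does not declare schema '", schema, "'")
  }
  dt <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE,
                          na.strings = "NA")
  if (!is.null(required)) {
    miss <- setdiff(required, names(dt))
    if (length(miss)) {
      stop("file ", path, ": missing required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  dt
}

#' Write / read the in-silico fragment pair table
#'
#' @param pairs Pair table from [build_pair_table()].
#' @param path File path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_pair_table <- function(pairs, path) .write_tsv(pairs, path, "pair_table")

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  .read_tsv(path, required = c("protein_id", "peptide_start", "peptide_end",
                               "peptidoform_id", "charge", "fragment_kind",
                               "fragment_index", "k_acetyl", "light_mz",
                               "heavy_mz", "correction_ratio"),
            schema = "pair_table")
}

#' Write / read the fragment quantification table
#'
#' Long-format table of observed light/heavy fragment peak areas per
#' fragment, peptidoform, charge, replicate and group.
#'
#' @param quant Quantification table.
#' @param path File path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_quant_table <- function(quant, path) .write_tsv(quant, path, "quant_table")

#' @rdname write_quant_table
#' @export
read_quant_table <- function(path) {
  .read_tsv(path, required = .QUANT_COLS, schema = "quant_table")
}

#' Write / read a site stoichiometry table
#'
#' @param sites Site table (the `sites` element of [quantify_sites()]).
#' @param path File path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_site_table <- function(sites, path) .write_tsv(sites, path, "site_table")

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  .read_tsv(path, required = c("protein_id", "site_position", "group",
                               "replicate_id", "s"),
            schema = "site_table")
}

#' Write a group-comparison result table
#'
#' @param res A [test_sites()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(res, path) .write_tsv(res, path, "comparison")

#' Read a category annotation table
#'
#' Long-format two-column TSV mapping `category_id` to `protein_id`, with an
#' optional `category_name` column.
#'
#' @param path File path.
#' @return `data.table` of annotations.
#' @export
read_annotations <- function(path) {
  .read_tsv(path, required = c("category_id", "protein_id"))
}

#' Write an overlap summary as JSON
#'
#' @param overlap A [compare_models()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_json <- function(overlap, path) {
  jsonlite::write_json(
    list(sites = overlap$sites, proteins = overlap$proteins,
         shared_fraction = overlap$shared_fraction, alpha = overlap$alpha),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
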