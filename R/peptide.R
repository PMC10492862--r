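# Residue chemistry, in-silico digestion, peptidoforms and fragment ions.
#
# Chemistry convention: after chemical acetylation with D6-acetic anhydride,
# every lysine carries exactly one acetyl group — endogenous ("acetyl-light",
# CH3CO, +C2H2O) or chemical ("acetyl-heavy", CD3CO, +C2H-1D3O). The heavy
# form replaces the three methyl protons by deuterium, adding
# 3 x (2H - 1H) = 3.018830 Da per site.

# Residue elemental compositions (C, H, N, O, S) of the 20 canonical amino
# acid residues (i.e. amino acids minus water).
.RESIDUE_COMP <- local({
  m <- rbind(
    G = c(2, 3, 1, 1, 0),
    A = c(3, 5, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0),
    V = c(5, 9, 1, 1, 0),
    T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1),
    L = c(6, 11, 1, 1, 0),
    I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0),
    E = c(5, 7, 1, 3, 0),
    M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(11, 10, 2, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m <- cbind(m, D = 0)
  m
})

.RESIDUE_MASS <- .RESIDUE_COMP %*% .MONO_MASS[colnames(.RESIDUE_COMP)]

# Modification composition deltas. The heavy acetyl has a transiently
# negative H count (three methyl H replaced by D); compositions are only
# validated after summation over a whole peptidoform or fragment.
.MOD_DELTA <- list(
  "acetyl-light"    = c(C = 2, H = 2, O = 1),
  "acetyl-heavy"    = c(C = 2, H = -1, D = 3, O = 1),
  "carbamidomethyl" = c(C = 2, H = 3, N = 1, O = 1),
  "oxidation"       = c(O = 1)
)

.MOD_MASS <- vapply(.MOD_DELTA, function(d) mass_of(.as_comp_vec(d)), numeric(1))

.ACETYL_MODS <- c("acetyl-light", "acetyl-heavy")

#' Peptidoform
#'
#' A peptide sequence located in a protein, with a specific set of
#' modifications and a charge state. Validation enforces the post-labeling
#' chemistry: every lysine carries exactly one of `acetyl-light` (endogenous)
#' or `acetyl-heavy` (chemical, D3).
#'
#' @param protein_id Protein accession.
#' @param start,end 1-based inclusive residue positions in the protein.
#' @param sequence Amino-acid string (20 canonical residues).
#' @param mods Data frame with columns `pos` (1-based position within the
#'   peptide) and `name` (one of `acetyl-light`, `acetyl-heavy`,
#'   `carbamidomethyl`, `oxidation`).
#' @param charge Positive integer charge state.
#' @return Object of class `peptidoform`.
#' @examples
#' peptidoform("P1", 1, 2, "AK",
#'             mods = data.frame(pos = 2, name = "acetyl-light"), charge = 1)
#' @export
peptidoform <- function(protein_id, start, end, sequence,
                        mods = data.frame(pos = integer(), name = character()),
                        charge = 2L) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% rownames(.RESIDUE_COMP))
  if (length(bad)) {
    stop("unknown residue symbol '", res[bad[1]], "' at position ", bad[1])
  }
  if (end - start + 1L != n) stop("end - start + 1 must equal peptide length")
  if (charge < 1 || charge != round(charge)) stop("'charge' must be a positive integer")
  mods <- as.data.frame(mods)
  if (nrow(mods)) {
    if (any(mods$pos < 1 | mods$pos > n)) stop("modification position outside [1, length]")
    badm <- setdiff(mods$name, names(.MOD_DELTA))
    if (length(badm)) stop("unknown modification(s): ", paste(badm, collapse = ", "))
  }
  k_pos <- which(res == "K")
  ac <- mods[mods$name %in% .ACETYL_MODS, , drop = FALSE]
  if (!setequal(ac$pos, k_pos) || anyDuplicated(ac$pos)) {
    stop("every K residue must carry exactly one of acetyl-light/acetyl-heavy")
  }
  if (any(!mods$pos[mods$name %in% .ACETYL_MODS] %in% k_pos)) {
    stop("acetyl modifications are only allowed on K")
  }
  structure(
    list(protein_id = protein_id, start = as.integer(start), end = as.integer(end),
         sequence = sequence, residues = res, mods = mods, charge = as.integer(charge)),
    class = "peptidoform"
  )
}

#' @export
print.peptidoform <- function(x, ...) {
  ms <- if (nrow(x$mods)) {
    paste(sprintf("%s@%d", x$mods$name, x$mods$pos), collapse = ",")
  } else "none"
  cat(sprintf("<peptidoform> %s %d-%d %s z=%d mods: %s\n",
              x$protein_id, x$start, x$end, x$sequence, x$charge, ms))
  invisible(x)
}

#' Elemental composition of a peptidoform
#'
#' Sums residue compositions, one water, and all modification deltas.
#'
#' @param p A [peptidoform()].
#' @return An [elemental_composition()].
#' @export
composition_of_peptidoform <- function(p) {
  stopifnot(inherits(p, "peptidoform"))
  v <- colSums(.RESIDUE_COMP[p$residues, , drop = FALSE]) + .WATER
  for (i in seq_len(nrow(p$mods))) {
    v <- v + .as_comp_vec(.MOD_DELTA[[p$mods$name[i]]])
  }
  elemental_composition(v)
}

# Per-position monoisotopic masses of a peptidoform (residue + its mods).
.position_masses <- function(p) {
  m <- .RESIDUE_MASS[p$residues, 1]
  for (i in seq_len(nrow(p$mods))) {
    j <- p$mods$pos[i]
    m[j] <- m[j] + .MOD_MASS[[p$mods$name[i]]]
  }
  m
}

#' Fragment ion m/z
#'
#' m/z of a b- or y-type fragment ion of a peptidoform at the peptidoform's
#' charge state. The b-ion neutral mass is the sum of the first `index`
#' residue-plus-modification masses; the y-ion neutral mass is the sum of the
#' last `index` positions plus one water. m/z = (neutral + z * 1.007276466)/z.
#'
#' @param p A [peptidoform()].
#' @param kind `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index <= length(peptide)` (backbone
#'   fragments have `index < length`; the full-length b/y species are also
#'   accepted).
#' @return m/z in Th.
#' @export
fragment_mz <- function(p, kind = c("b", "y"), index) {
  kind <- match.arg(kind)
  n <- length(p$residues)
  if (index < 1 || index > n) {
    stop("fragment index must lie in [1, ", n, "], got ", index)
  }
  pm <- .position_masses(p)
  neutral <- if (kind == "b") sum(pm[seq_len(index)])
             else sum(pm[(n - index + 1L):n]) + mass_of(.WATER)
  (neutral + p$charge * .PROTON_MASS) / p$charge
}

#' In-silico Trypsin + GluC digestion with acetyl-blocked lysines
#'
#' Cleaves C-terminal to R (trypsin; K is never cleaved because all lysines
#' are acetylated by the labeling chemistry) and C-terminal to E (GluC;
#' optionally also D), with cleavage suppressed before proline. Returns all
#' peptide spans with at most `max_missed` internal cleavage sites and length
#' within `length_bounds`.
#'
#' @param sequence Protein sequence (non-empty string).
#' @param max_missed Maximum number of missed cleavages (internal cleavage
#'   sites) per peptide. Default 5, the search setting used with this
#'   chemistry (acetyl-blocked K makes fully specific peptides long).
#' @param length_bounds Length-2 numeric `c(min, max)` peptide length bounds,
#'   or `NULL` for no bounds. Default `c(6, 30)`.
#' @param gluc_specificity `"E"` (default) or `"ED"`: whether GluC cleaves
#'   after E only or after E and D (buffer-dependent).
#' @return Data frame with columns `start`, `end` (1-based inclusive
#'   protein coordinates), `sequence`, `n_missed`.
#' @examples
#' digest("AKRDEKR", max_missed = 0, length_bounds = NULL)
#' @export
digest <- function(sequence, max_missed = 5L, length_bounds = c(6L, 30L),
                   gluc_specificity = c("E", "ED")) {
  gluc_specificity <- match.arg(gluc_specificity)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("'sequence' must be a non-empty string")
  }
  if (max_missed < 0) stop("'max_missed' must be >= 0")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cleave_aa <- c("R", "E", if (gluc_specificity == "ED") "D")
  cut_after <- which(ch %in% cleave_aa)
  cut_after <- cut_after[cut_after < n]
  cut_after <- cut_after[ch[cut_after + 1L] != "P"]   # no cleavage before proline
  seg_start <- c(1L, cut_after + 1L)
  seg_end <- c(cut_after, n)
  nseg <- length(seg_start)
  out <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    j <- i:min(i + max_missed, nseg)
    out[[i]] <- data.frame(start = seg_start[i], end = seg_end[j], n_missed = j - i)
  }
  spans <- do.call(rbind, out)
  len <- spans$end - spans$start + 1L
  if (!is.null(length_bounds)) {
    keep <- len >= length_bounds[1] & len <= length_bounds[2]
    spans <- spans[keep, , drop = FALSE]
  }
  spans$sequence <- substring(sequence, spans$start, spans$end)
  rownames(spans) <- NULL
  spans[, c("start", "end", "sequence", "n_missed")]
}

# Canonical peptidoform id: protein:start-end. Modifications are implied
# (all-K acetyl + fixed carbamidomethyl), so the id is reproducible from the
# FASTA alone; charge is carried as a separate column.
.peptidoform_id <- function(protein_id, start, end) {
  sprintf("%s:%d-%d", protein_id, start, end)
}

#' Generate light/heavy acetyl fragment-ion pairs in silico
#'
#' For every peptide from a Trypsin+GluC digest of each protein, enumerates
#' b/y fragment ions that cover at least one (acetylated) lysine and emits
#' the light (endogenous acetyl) and heavy (D3-acetyl) m/z pair together with
#' the envelope-correction ratio `r = a_3k / a_0` of the light fragment's
#' natural isotope envelope, where `k` is the number of acetyl-lysines the
#' fragment covers. The +3k natural isotopologue of the light fragment
#' coincides with the heavy fragment's monoisotopic peak; `r` quantifies that
#' leakage. Fragments covering no lysine form no pair and are excluded.
#'
#' Carbamidomethylation of cysteine is applied as a fixed modification;
#' variable oxidation is not enumerated here.
#'
#' @param proteins Named character vector of protein sequences (names are
#'   accessions), or an `AAStringSet`.
#' @param charges Integer vector of fragment charge states (default `c(1, 2)`).
#' @param max_missed,length_bounds,gluc_specificity Passed to [digest()].
#' @return A `data.table` with columns `protein_id`, `peptide_start`,
#'   `peptide_end`, `peptidoform_id`, `charge`, `fragment_kind`,
#'   `fragment_index`, `k_acetyl`, `site_position` (protein position of the
#'   covered K when `k_acetyl == 1`, `NA` otherwise), `light_mz`, `heavy_mz`,
#'   `correction_ratio`.
#' @export
build_pair_table <- function(proteins, charges = c(1L, 2L), max_missed = 5L,
                             length_bounds = c(6L, 30L),
                             gluc_specificity = c("E", "ED")) {
  gluc_specificity <- match.arg(gluc_specificity)
  if (inherits(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  if (is.null(names(proteins)) || any(!nzchar(names(proteins)))) {
    stop("'proteins' must be named by accession")
  }
  charges <- as.integer(charges)
  if (any(charges < 1)) stop("charges must be positive integers")
  cache <- new.env(parent = emptyenv())
  res <- vector("list", length(proteins))
  for (pi in seq_along(proteins)) {
    acc <- names(proteins)[pi]
    spans <- digest(proteins[[pi]], max_missed = max_missed,
                    length_bounds = length_bounds,
                    gluc_specificity = gluc_specificity)
    if (!nrow(spans)) next
    per_pep <- vector("list", nrow(spans))
    for (si in seq_len(nrow(spans))) {
      per_pep[[si]] <- .pair_rows_for_peptide(
        acc, spans$start[si], spans$end[si], spans$sequence[si],
        charges = charges, cache = cache)
    }
    res[[pi]] <- data.table::rbindlist(per_pep)
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out)) {
    out <- data.table::data.table(
      protein_id = character(), peptide_start = integer(), peptide_end = integer(),
      peptidoform_id = character(), charge = integer(), fragment_kind = character(),
      fragment_index = integer(), k_acetyl = integer(), site_position = integer(),
      light_mz = numeric(), heavy_mz = numeric(), correction_ratio = numeric())
  }
  out[]
}

# Fragment pair rows for one peptide (all-light vs all-heavy acetyl states).
.pair_rows_for_peptide <- function(acc, start, end, sequence, charges, cache) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(res)
  k_pos <- which(res == "K")
  if (length(k_pos) == 0L || n < 2L) return(NULL)

  # per-position masses: residue + fixed carbamidomethyl(C) + acetyl on K
  base <- .RESIDUE_MASS[res, 1]
  is_c <- res == "C"
  base[is_c] <- base[is_c] + .MOD_MASS[["carbamidomethyl"]]
  light <- base; light[k_pos] <- light[k_pos] + .MOD_MASS[["acetyl-light"]]
  heavy <- base; heavy[k_pos] <- heavy[k_pos] + .MOD_MASS[["acetyl-heavy"]]

  # per-position light-state compositions (cumulative, for envelopes)
  comp <- .RESIDUE_COMP[res, , drop = FALSE]
  if (any(is_c)) {
    comp[is_c, ] <- sweep(comp[is_c, , drop = FALSE], 2,
                          .as_comp_vec(.MOD_DELTA[["carbamidomethyl"]]), `+`)
  }
  comp[k_pos, ] <- sweep(comp[k_pos, , drop = FALSE], 2,
                         .as_comp_vec(.MOD_DELTA[["acetyl-light"]]), `+`)
  ccomp <- apply(comp, 2, cumsum)
  if (n == 1L) ccomp <- matrix(ccomp, nrow = 1, dimnames = list(NULL, colnames(comp)))
  tot_comp <- ccomp[n, ]

  cum_light <- cumsum(light); cum_heavy <- cumsum(heavy)
  cumK <- cumsum(res == "K")
  water <- mass_of(.WATER)

  idx <- seq_len(n - 1L)
  frag <- data.frame(
    fragment_kind = rep(c("b", "y"), each = n - 1L),
    fragment_index = c(idx, idx)
  )
  frag$k_acetyl <- c(cumK[idx], cumK[n] - cumK[n - idx])
  frag$neutral_light <- c(cum_light[idx], cum_light[n] - cum_light[n - idx] + water)
  frag$neutral_heavy <- c(cum_heavy[idx], cum_heavy[n] - cum_heavy[n - idx] + water)
  frag <- frag[frag$k_acetyl >= 1L, , drop = FALSE]
  if (!nrow(frag)) return(NULL)

  # localized site (protein coordinates) for single-K fragments
  frag$site_position <- NA_integer_
  one <- frag$k_acetyl == 1L
  if (any(one)) {
    site_b <- function(i) k_pos[k_pos <= i][1]
    site_y <- function(i) k_pos[k_pos > n - i][1]
    pos_in_pep <- ifelse(frag$fragment_kind[one] == "b",
                         vapply(frag$fragment_index[one], site_b, integer(1)),
                         vapply(frag$fragment_index[one], site_y, integer(1)))
    frag$site_position[one] <- start + pos_in_pep - 1L
  }

  # envelope-correction ratio a_{3k}/a_0 of the light fragment; memoised by
  # fragment composition (prefix fragments repeat across missed-cleavage
  # variants of the same protein region)
  fk <- frag$k_acetyl; fkind <- frag$fragment_kind; fidx <- frag$fragment_index
  frag$correction_ratio <- vapply(seq_len(nrow(frag)), function(i) {
    k <- fk[i]
    cv <- if (fkind[i] == "b") ccomp[fidx[i], ]
          else tot_comp - ccomp[n - fidx[i], ] + .WATER
    key <- paste0("r:", k, ":", paste(cv, collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    env <- .envelope_of_vec(cv, max_iso = max(10L, 3L * k + 2L), cache = cache)
    out <- if (env[1] <= 0) 0 else env[3L * k + 1L] / env[1]
    cache[[key]] <- out
    out
  }, numeric(1))

  out <- data.table::CJ(row = seq_len(nrow(frag)), charge = charges, sorted = FALSE)
  f <- frag[out$row, ]
  data.table::data.table(
    protein_id = acc,
    peptide_start = as.integer(start),
    peptide_end = as.integer(end),
    peptidoform_id = .peptidoform_id(acc, start, end),
    charge = out$charge,
    fragment_kind = f$fragment_kind,
    fragment_index = as.integer(f$fragment_index),
    k_acetyl = as.integer(f$k_acetyl),
    site_position = f$site_position,
    light_mz = (f$neutral_light + out$charge * .PROTON_MASS) / out$charge,
    heavy_mz = (f$neutral_heavy + out$charge * .PROTON_MASS) / out$charge,
    correction_ratio = f$correction_ratio
  )
}
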