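# Fixed isotope tables (IUPAC-2013-style values), shipped with the package so
# that masses and envelopes are reproducible independent of the runtime
# environment. "D" is deuterium at chemically labeled positions, treated as a
# distinct pure element (no natural isotope distribution).

.ELEMENTS <- c("C", "H", "N", "O", "S", "D")

# Monoisotopic masses (Da) of the principal isotope of each element.
.MONO_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  D = 2.0141017780
)

# Natural isotopic abundances indexed by nominal mass offset (0, +1, +2, ...)
# relative to the principal isotope. S-36 sits at offset +4, hence the zero.
.ISOTOPE_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001),
  D = 1
)

# Mass of a proton (charge carrier) and of water, used throughout.
.PROTON_MASS <- 1.007276466
.WATER <- c(C = 0, H = 2, N = 0, O = 1, S = 0, D = 0)

#' Elemental composition
#'
#' Construct an elemental composition, a named count vector over the elements
#' C, H, N, O, S and D (deuterium at labeled positions). Compositions add
#' element-wise with `+`.
#'
#' @param counts Named numeric vector of non-negative integer counts; names
#'   must be element symbols from `C, H, N, O, S, D`. Elements not mentioned
#'   are zero.
#' @return An object of class `elemental_composition`: a named numeric vector
#'   over all six supported elements.
#' @examples
#' gly <- elemental_composition(c(C = 2, H = 5, N = 1, O = 2))
#' mass_of(gly)
#' @export
elemental_composition <- function(counts = numeric(0)) {
  x <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("'counts' must be a named vector of element counts")
    }
    bad <- setdiff(names(counts), .ELEMENTS)
    if (length(bad)) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    }
    for (el in names(counts)) x[[el]] <- x[[el]] + counts[[el]]
  }
  if (any(x < 0)) stop("element counts must be non-negative")
  if (any(x != round(x))) stop("element counts must be integers")
  structure(x, class = "elemental_composition")
}

#' @export
`+.elemental_composition` <- function(e1, e2) {
  elemental_composition(.as_comp_vec(e1) + .as_comp_vec(e2))
}

#' @export
print.elemental_composition <- function(x, ...) {
  nz <- x[x > 0]
  cat("<elemental_composition> ",
      paste0(names(nz), ifelse(nz == 1, "", nz), collapse = " "),
      "  (", format(mass_of(x), nsmall = 6), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' @param comp An [elemental_composition()] (or a named count vector over
#'   C, H, N, O, S, D).
#' @return Monoisotopic mass in Da.
#' @examples
#' mass_of(elemental_composition(c(C = 2, H = 2, O = 1)))  # acetyl delta
#' @export
mass_of <- function(comp) {
  v <- .as_comp_vec(comp)
  sum(v * .MONO_MASS[names(v)])
}

# Coerce to a plain full-length named numeric vector over .ELEMENTS.
# Internal arithmetic (e.g. the heavy-acetyl H deficit) may go through
# transiently negative counts; validation happens in elemental_composition().
.as_comp_vec <- function(comp) {
  if (inherits(comp, "elemental_composition")) return(unclass(comp))
  x <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  if (length(comp)) {
    bad <- setdiff(names(comp), .ELEMENTS)
    if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    x[names(comp)] <- comp
  }
  x
}

# Truncated linear convolution of two abundance vectors (offset-0 based),
# keeping offsets 0..max_iso.
.convolve_trunc <- function(a, b, max_iso) {
  n <- max_iso + 1L
  out <- numeric(n)
  la <- min(length(a), n)
  for (j in seq_len(la)) {
    if (a[j] == 0) next
    lb <- min(length(b), n - j + 1L)
    if (lb > 0L) {
      idx <- j:(j + lb - 1L)
      out[idx] <- out[idx] + a[j] * b[seq_len(lb)]
    }
  }
  out
}

# n-fold self-convolution of a single-element abundance vector by binary
# exponentiation, truncated at max_iso. Optionally memoised via `cache`.
.element_power <- function(el, n, max_iso, cache = NULL) {
  key <- paste(el, n, max_iso, sep = ":")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  d <- .ISOTOPE_ABUNDANCE[[el]]
  acc <- 1          # delta at offset 0
  base <- d
  m <- n
  while (m > 0L) {
    if (m %% 2L == 1L) acc <- .convolve_trunc(acc, base, max_iso)
    m <- m %/% 2L
    if (m > 0L) base <- .convolve_trunc(base, base, max_iso)
  }
  if (!is.null(cache)) cache[[key]] <- acc
  acc
}

#' Natural isotope envelope of a composition
#'
#' Computes the isotopologue abundance distribution of a molecule by repeated
#' convolution of the per-element isotope distributions, aggregated by nominal
#' mass offset (integer Da; index 0 is the monoisotopic species). Deuterium at
#' labeled positions ("D") is treated as isotopically pure and contributes no
#' spread. Abundances are absolute probabilities: the untruncated distribution
#' sums to 1, so the returned vector sums to 1 minus the (tiny) truncated
#' tail mass; values are not renormalised.
#'
#' @param comp An [elemental_composition()] or named count vector.
#' @param max_iso Largest nominal offset retained; the result has
#'   `max_iso + 1` entries for offsets `0..max_iso`.
#' @return Numeric vector of isotopologue abundances indexed by nominal mass
#'   offset (first element = offset 0).
#' @examples
#' env <- isotope_envelope(c(C = 2, H = 5, N = 1, O = 2))  # glycine
#' env[1]   # monoisotopic fraction, ~0.970
#' @export
isotope_envelope <- function(comp, max_iso = 10L) {
  if (max_iso < 0) stop("'max_iso' must be >= 0")
  v <- .as_comp_vec(comp)
  if (any(v < 0)) stop("element counts must be non-negative")
  .envelope_of_vec(v, max_iso, cache = NULL)
}

# Envelope of a plain composition vector, with optional element-power
# memoisation (used by build_pair_table, which computes many envelopes with
# recurring element counts).
.envelope_of_vec <- function(v, max_iso, cache = NULL) {
  env <- numeric(max_iso + 1L)
  env[1] <- 1
  for (el in names(v)) {
    if (v[[el]] > 0 && length(.ISOTOPE_ABUNDANCE[[el]]) > 1L) {
      env <- .convolve_trunc(env, .element_power(el, v[[el]], max_iso, cache),
                             max_iso)
    }
  }
  env
}
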