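# Independent oracles used across the suite. These deliberately avoid the
# package's convolution/summation code paths: envelopes are computed by
# exhaustive multinomial enumeration, ANOVA by direct sums of squares, and
# hypergeometric tails by enumerating draws.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All weak compositions of n into k non-negative parts.
enumerate_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (i in 0:n) {
    sub <- enumerate_compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

# Isotope envelope by exhaustive multinomial enumeration over all
# isotopologue assignments per element, combined across elements by direct
# summation over offset pairs (no polynomial convolution).
envelope_oracle <- function(comp, max_iso) {
  abund <- acstoich:::.ISOTOPE_ABUNDANCE
  dist <- 1   # P(offset = 0..) so far
  for (el in names(comp)) {
    n <- comp[[el]]
    if (is.na(n) || n == 0) next
    ab <- abund[[el]]
    if (length(ab) == 1L) next
    cc <- enumerate_compositions(n, length(ab))
    offs <- 0:(length(ab) - 1L)
    el_off <- as.vector(cc %*% offs)
    el_p <- apply(cc, 1, function(r) {
      factorial(n) / prod(factorial(r)) * prod(ab^r)
    })
    nd <- numeric(length(dist) + max(el_off))
    for (i in seq_along(dist)) {
      for (j in seq_along(el_p)) {
        o <- (i - 1L) + el_off[j]
        nd[o + 1L] <- nd[o + 1L] + dist[i] * el_p[j]
      }
    }
    dist <- nd
  }
  out <- numeric(max_iso + 1L)
  l <- min(length(dist), max_iso + 1L)
  out[seq_len(l)] <- dist[seq_len(l)]
  out
}

# Random small composition (<= max_atoms atoms) over C/H/N/O/S.
random_small_composition <- function(max_atoms = 12L) {
  repeat {
    v <- c(C = sample(0:4, 1), H = sample(0:6, 1), N = sample(0:3, 1),
           O = sample(0:3, 1), S = sample(0:2, 1))
    if (sum(v) >= 1 && sum(v) <= max_atoms) return(v)
  }
}

# One-way ANOVA F by direct sums of squares.
anova_F_oracle <- function(groups) {
  y <- unlist(groups)
  gm <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  k <- length(groups); n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Upper-tail hypergeometric by enumerating all C(N, n) draws.
hypergeom_oracle <- function(k, n, m, N) {
  marked <- seq_len(m)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Random peptidoform with every K acetylated (light or heavy at random).
random_peptidoform <- function(len = sample(6:15, 1), charge = sample(1:2, 1)) {
  aas <- rownames(acstoich:::.RESIDUE_COMP)
  seqc <- sample(aas, len, replace = TRUE)
  k_pos <- which(seqc == "K")
  mods <- data.frame(pos = integer(), name = character())
  if (length(k_pos)) {
    mods <- data.frame(pos = k_pos,
                       name = sample(c("acetyl-light", "acetyl-heavy"),
                                     length(k_pos), replace = TRUE))
  }
  peptidoform("RND", 1L, len, paste(seqc, collapse = ""), mods = mods,
              charge = charge)
}

# Neutral (uncharged) fragment mass from a peptidoform's fragment m/z.
neutral_mass <- function(p, kind, index) {
  fragment_mz(p, kind, index) * p$charge - p$charge * acstoich:::.PROTON_MASS
}

# Small noise-free study shared by quantify tests.
noise_free_study <- function(seed = 7L, n_proteins = 25L, n_sites = 30L) {
  make_study(study_config(n_proteins = n_proteins, n_sites = n_sites,
                          cv = 0, eta = 1, missing_rate = 0, seed = seed))
}
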