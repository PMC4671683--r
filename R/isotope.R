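# Fixed isotope table (monoisotopic masses in Da, natural abundances).
# Kept as a versioned constant so envelope computations are bit-reproducible.
# Offsets are neutron counts above the lightest isotope of each element.
.ISOTOPES <- list(
  C = list(mass = c(12.0,            13.00335483507),
           abundance = c(0.9893, 0.0107), offset = c(0L, 1L)),
  H = list(mass = c(1.00782503224,   2.01410177812),
           abundance = c(0.999885, 0.000115), offset = c(0L, 1L)),
  N = list(mass = c(14.00307400446, 15.00010889894),
           abundance = c(0.99636, 0.00364), offset = c(0L, 1L)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205), offset = c(0L, 1L, 2L)),
  S = list(mass = c(31.97207117441, 32.97145890985, 33.96786701,
                    35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
           offset = c(0L, 1L, 2L, 4L))
)

.MASS_PROTON  <- 1.007276466622
# Default neutron spacing inside an envelope: the 13C-12C mass difference,
# the dominant isotopologue step for peptides.
.DELTA_NEUTRON <- 1.0033548378

# Residue (not free amino acid) elemental formulas for the 20 standard
# one-letter codes; a peptide is the residue sum plus one water.
.RESIDUES <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Elemental composition of a peptide
#'
#' Sums the residue formulas of a peptide sequence (20 standard one-letter
#' codes) and adds one water for the termini.
#'
#' @param sequence Character scalar, e.g. \code{"PEPTIDE"}.
#' @return Named integer vector with elements \code{C, H, N, O, S}.
#' @examples
#' peptide_composition("G")   # glycine: C2 H5 N O2
#' @export
peptide_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L)
    stop("`sequence` must be a nonempty character scalar", call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  unknown <- setdiff(unique(aa), names(.RESIDUES))
  if (length(unknown))
    stop("unknown residue code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  comp <- Reduce(`+`, .RESIDUES[aa])
  comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O
  storage.mode(comp) <- "integer"
  comp
}

# Abundance vector (indexed by neutron offset, starting at 0) and base mass
# for `n` atoms of one element, honouring 15N enrichment for nitrogen.
.element_channel <- function(element, n, n15_enrichment = NULL) {
  iso <- .ISOTOPES[[element]]
  ab <- iso$abundance
  mass0 <- iso$mass[1L]
  if (element == "N" && !is.null(n15_enrichment)) {
    e <- n15_enrichment
    if (e >= 1) {                      # degenerate: pure 15N
      return(list(poly = 1, base_mass = n * iso$mass[2L],
                  mean_mass = n * iso$mass[2L]))
    }
    ab <- c(1 - e, e)
    iso <- list(mass = iso$mass[1:2], abundance = ab, offset = c(0L, 1L))
  }
  poly <- numeric(max(iso$offset) + 1L)
  poly[iso$offset + 1L] <- iso$abundance
  list(poly = poly, base_mass = n * mass0,
       mean_mass = n * sum(iso$abundance * iso$mass))
}

#' Theoretical isotope distribution by Fourier-domain convolution
#'
#' Computes the isotopologue envelope of an elemental composition as the
#' convolution of per-atom isotope abundance vectors. The convolution of all
#' atoms is carried out in the Fourier domain: each element's abundance
#' polynomial is transformed once, raised elementwise to its atom count, the
#' per-element transforms are multiplied, and a single inverse FFT returns
#' the envelope. Nitrogen abundances can be replaced by \code{(1 - e, e)} to
#' model \eqn{^{15}}N metabolic labeling at enrichment \code{e}.
#'
#' @param comp Named nonnegative integer vector (subset of C, H, N, O, S),
#'   e.g. from [peptide_composition()].
#' @param n15_enrichment \code{NULL} for natural-abundance nitrogen, or a
#'   number in \eqn{[0, 1]}: the fraction of nitrogen atoms that are
#'   \eqn{^{15}}N.
#' @param tail_mass Probability mass allowed in the truncated upper tail
#'   (default \code{1e-9}); the envelope is renormalized after truncation.
#' @return Object of class \code{"isotope_distribution"}: a list with
#'   \code{abundance} (relative abundance by neutron offset 0, 1, 2, ...),
#'   \code{monoisotopic_mass} (mass of the offset-0 species, Da),
#'   \code{mean_mass} (exact abundance-weighted mass, Da), and
#'   \code{labeling} (\code{"natural"} or the enrichment value).
#' @export
isotope_distribution <- function(comp, n15_enrichment = NULL,
                                 tail_mass = 1e-9) {
  comp <- comp[comp > 0]
  if (length(comp) == 0L)
    stop("composition must contain at least one atom", call. = FALSE)
  bad <- setdiff(names(comp), names(.ISOTOPES))
  if (length(bad))
    stop("unknown element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(n15_enrichment)) {
    if (!is.numeric(n15_enrichment) || length(n15_enrichment) != 1L ||
        is.na(n15_enrichment) || n15_enrichment < 0 || n15_enrichment > 1)
      stop("`n15_enrichment` must be a single number in [0, 1]",
           call. = FALSE)
  }

  channels <- lapply(names(comp), function(el)
    .element_channel(el, comp[[el]], n15_enrichment))
  names(channels) <- names(comp)

  # Upper bound on the support we need: mean + wide guard band. The guard is
  # generous because FFT convolution is circular; wrap-around would corrupt
  # the head of the envelope.
  mean_off <- 0; var_off <- 0; max_off <- 0
  for (el in names(comp)) {
    p <- channels[[el]]$poly
    if (length(p) == 1L) next
    off <- seq_along(p) - 1
    m1 <- sum(off * p); m2 <- sum(off^2 * p)
    mean_off <- mean_off + comp[[el]] * m1
    var_off  <- var_off  + comp[[el]] * (m2 - m1^2)
    max_off  <- max_off  + comp[[el]] * (length(p) - 1L)
  }
  need <- min(max_off, ceiling(mean_off + 12 * sqrt(var_off) + 64)) + 1
  L <- 2^ceiling(log2(need + 1))

  acc <- complex(real = rep(1, L))
  for (el in names(comp)) {
    p <- channels[[el]]$poly
    if (length(p) == 1L) next
    fp <- stats::fft(c(p, numeric(L - length(p))))
    acc <- acc * fp^comp[[el]]
  }
  ab <- Re(stats::fft(acc, inverse = TRUE)) / L
  ab[ab < 0] <- 0

  # Truncate the upper tail, then renormalize to unit mass.
  keep <- which(rev(cumsum(rev(ab))) > tail_mass)
  if (length(keep)) ab <- ab[seq_len(max(keep))]
  ab <- ab / sum(ab)

  mono <- sum(vapply(channels, `[[`, numeric(1), "base_mass"))
  mean_mass <- sum(vapply(channels, `[[`, numeric(1), "mean_mass"))
  structure(list(abundance = ab,
                 monoisotopic_mass = mono,
                 mean_mass = mean_mass,
                 labeling = if (is.null(n15_enrichment)) "natural"
                            else n15_enrichment),
            class = "isotope_distribution")
}

#' @export
print.isotope_distribution <- function(x, ...) {
  cat("Isotope distribution (", length(x$abundance), " offsets, labeling: ",
      format(x$labeling), ")\n", sep = "")
  cat("  monoisotopic mass:", format(x$monoisotopic_mass, digits = 10),
      "Da\n")
  cat("  mean mass:        ", format(x$mean_mass, digits = 10), "Da\n")
  top <- utils::head(order(x$abundance, decreasing = TRUE), 5L)
  cat("  top offsets:",
      paste0(top - 1L, " (", signif(x$abundance[top], 3), ")",
             collapse = ", "), "\n")
  invisible(x)
}
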