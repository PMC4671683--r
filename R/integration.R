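# round half away from zero, matching how the printed percentages round
.round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Venn partition sizes for two sets
#'
#' @param a,b Character vectors (id sets).
#' @return Named integer vector \code{c(a_only, b_only, shared)}.
#' @export
venn_counts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b))
  c(a_only = length(a) - shared, b_only = length(b) - shared,
    shared = shared)
}

#' Overlap of bound-transcript calls with expression and splicing calls
#'
#' For each direction of differential binding (transcripts whose
#' association with the immunoprecipitated protein goes up or down on
#' activation), reports the fraction that is differentially expressed in
#' the same direction, the fraction that is also alternatively spliced,
#' and the fraction spliced but not differentially expressed. Percentages
#' are the exact fractions rounded half-away-from-zero to integers, as in
#' printed figure legends.
#'
#' @param bound_up,bound_down Character vectors of gene ids.
#' @param de [differential_expression()] result (needs \code{gene} and
#'   \code{direction}).
#' @param spliced_genes Character vector of alternatively spliced genes.
#' @return Object of class \code{"overlap_report"}: nested list with one
#'   entry per direction carrying \code{n}, counts, exact fractions, and
#'   integer percentages.
#' @export
overlap_bound_expression <- function(bound_up, bound_down, de,
                                     spliced_genes) {
  de_up <- de$gene[de$direction == "up"]
  de_down <- de$gene[de$direction == "down"]
  de_any <- c(de_up, de_down)

  one <- function(bound, de_same) {
    n <- length(bound)
    conc <- length(intersect(bound, de_same))
    spl <- length(intersect(bound, spliced_genes))
    spl_not_de <- length(setdiff(intersect(bound, spliced_genes), de_any))
    list(n = n,
         concordant = conc,
         concordant_fraction = if (n) conc / n else NA_real_,
         concordant_pct = if (n) .round_half_away(100 * conc / n) else NA,
         spliced = spl,
         spliced_fraction = if (n) spl / n else NA_real_,
         spliced_pct = if (n) .round_half_away(100 * spl / n) else NA,
         spliced_not_de = spl_not_de,
         spliced_not_de_pct = if (n)
           .round_half_away(100 * spl_not_de / n) else NA)
  }
  structure(list(up = one(bound_up, de_up),
                 down = one(bound_down, de_down)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  for (d in c("up", "down")) {
    r <- x[[d]]
    cat(sprintf(
      "bound-%s (n=%d): %d%% DE same direction, %d%% also spliced, %d%% spliced-not-DE\n",
      d, r$n, r$concordant_pct, r$spliced_pct, r$spliced_not_de_pct))
  }
  invisible(x)
}

#' Percentage of one set within another, as printed
#'
#' @param numerator,denominator Counts (or id sets, in which case sizes
#'   are used with the numerator intersected into the denominator set).
#' @return List with \code{fraction} and integer \code{pct}.
#' @export
reported_percentage <- function(numerator, denominator) {
  if (!is.numeric(numerator)) {
    numerator <- length(intersect(numerator, denominator))
  }
  if (!is.numeric(denominator)) denominator <- length(unique(denominator))
  list(fraction = numerator / denominator,
       pct = .round_half_away(100 * numerator / denominator))
}

#' Run the full synthetic pipeline end to end
#'
#' Generates every input with [sim_config()] defaults overridden by
#' \code{cfg}, then runs each analysis stage: differential expression on
#' the simulated counts, SILAC quantification on the simulated spectra,
#' interactome assembly on the simulated hit tables, and hypergeometric
#' enrichment on the simulated gene sets. Deterministic for a fixed
#' config.
#'
#' @param cfg [sim_config()] object.
#' @return List with per-stage inputs, results, and the planted truths.
#' @export
run_pipeline <- function(cfg = sim_config()) {
  counts_sim <- simulate_counts(cfg)
  de <- differential_expression(counts_sim$counts, counts_sim$groups,
                                alpha = 0.05)

  silac_sim <- simulate_silac_spectra(cfg)
  quant <- quantify_silac(silac_sim$features, silac_sim$windows,
                          n15_enrichment = cfg$n15_enrichment,
                          fwhm = cfg$fwhm_mz)

  prot_sim <- simulate_protein_table(cfg)
  filtered <- lapply(prot_sim$tables, function(cell)
    lapply(cell, filter_protein_hits, fdr_max = 0.01,
           contaminants = default_contaminants()))
  detected <- lapply(filtered, detection_call)
  sets <- assemble_interactome(detected$resting_minus,
                               detected$activated_minus,
                               detected$resting_plus,
                               detected$activated_plus)

  gs_sim <- simulate_genesets(cfg)
  enr <- hypergeometric_enrichment(gs_sim$query, gs_sim$sets,
                                   gs_sim$universe)

  list(counts = counts_sim, de = de,
       silac = silac_sim, quant = quant,
       proteins = prot_sim, interactome = sets,
       genesets = gs_sim, enrichment = enr)
}

#' Quantify SILAC peptide ratios from features and spectrum windows
#'
#' Convenience wrapper over the full quantification chain: pair matching
#' ([match_peak_pairs()]), theoretical envelopes
#' ([isotope_distribution()]), least-squares envelope fitting
#' ([fit_ls_ftc()]), quality filtering ([filter_fits()]), and per-protein
#' statistics ([protein_ratio_stats()]).
#'
#' @param features Feature table (see [match_peak_pairs()]); a
#'   \code{protein} column, when present, feeds the protein-level test.
#' @param windows Long data.frame with columns \code{pair_id}, \code{mz},
#'   \code{intensity}.
#' @param n15_enrichment Heavy-channel \eqn{^{15}}N enrichment
#'   (default 1.0).
#' @param rt_tolerance,fwhm,snr_min,residual_fraction_max,alpha,orientation
#'   Tuning knobs passed to the respective stages.
#' @return List with \code{pairs}, \code{rejects}, \code{fits} (table),
#'   and \code{proteins} ([protein_ratio_stats()] output, or \code{NULL}
#'   when no protein column is available).
#' @export
quantify_silac <- function(features, windows, n15_enrichment = 1.0,
                           rt_tolerance = 30, fwhm = 0.02, snr_min = 10,
                           residual_fraction_max = 0.2, alpha = 0.05,
                           orientation = "light/heavy") {
  matched <- match_peak_pairs(features, rt_tolerance)
  pairs <- matched$pairs
  win_by_pair <- split(windows[c("mz", "intensity")], windows$pair_id)
  fits <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    w <- win_by_pair[[pairs$pair_id[i]]]
    if (is.null(w))
      stop("no spectrum window for pair ", pairs$pair_id[i], call. = FALSE)
    comp <- peptide_composition(pairs$peptide[i])
    dl <- isotope_distribution(comp)
    dh <- isotope_distribution(comp, n15_enrichment)
    fits[[i]] <- fit_ls_ftc(w, dl, dh, pairs$charge[i], fwhm = fwhm,
                            pair_id = pairs$pair_id[i])
  }
  fits <- filter_fits(fits, snr_min, residual_fraction_max)
  ft <- fits_table(fits)

  proteins <- NULL
  if ("protein" %in% names(features)) {
    prot_of <- features$protein[match(pairs$light_id, features$feature_id)]
    ok <- ft$accepted & is.finite(ft$ratio)
    if (any(ok))
      proteins <- protein_ratio_stats(ft$ratio[ok], prot_of[ok],
                                      alpha = alpha,
                                      orientation = orientation)
  }
  list(pairs = pairs, rejects = matched$rejects, fits = ft,
       proteins = proteins)
}
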