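#' Simulation configuration
#'
#' Validated parameter bundle shared by all four simulators. Defaults
#' emulate the study designs this package targets: RIP-seq/RNA-seq count
#' matrices with six samples per condition, \eqn{^{14}}N/\eqn{^{15}}N SILAC
#' peptide pairs with three-per-group mixing, replicated protein hit tables
#' (six whole-interactome replicates, four RNase-treated per condition),
#' and an immune-flavored gene-set collection.
#'
#' @param seed Integer RNG seed; every simulator seeds from it, so equal
#'   configs give identical outputs.
#' @param n_genes Number of genes (also the enrichment universe size).
#' @param n_samples_per_group Samples per condition for the count matrix.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\phi}
#'   (variance \eqn{\mu + \phi\mu^2}).
#' @param de_fraction Fraction of genes with planted differential
#'   expression/binding.
#' @param de_log2fc_magnitude Absolute planted log2 fold change.
#' @param library_sizes Expected total counts per sample (scalar recycled
#'   or length \code{2 * n_samples_per_group}).
#' @param n_proteins Number of proteins for the SILAC and hit-table
#'   simulators.
#' @param peptides_per_protein Mean quantifiable peptides per protein
#'   (Poisson, shifted to a 1 minimum).
#' @param ratio_log2_mean,ratio_log2_sd Mean and sd of planted per-protein
#'   log2 abundance ratios.
#' @param noise_sd Gaussian intensity noise added to spectrum windows
#'   (arbitrary units; the clean base peak is ~300 units, so the default 6
#'   gives a signal-to-noise ratio near 50).
#' @param n15_enrichment Heavy-channel \eqn{^{15}}N enrichment in
#'   \eqn{[0, 1]} (default 1.0: labeling efficiency is a free parameter).
#' @param contaminant_fraction Contaminant hits added to each hit table,
#'   as a fraction of \code{n_proteins}.
#' @param replicate_dropout Per-replicate probability that a truly present
#'   protein goes undetected.
#' @param n_pathways Number of simulated pathways.
#' @param pathway_size_range Length-2 integer range of pathway sizes.
#' @param planted_enriched Number of pathways made over-represented in the
#'   query list.
#' @param query_size Size of the enrichment query gene list.
#' @param decoy_fraction Fraction of peptide pairs violating the
#'   co-elution rule, to exercise rejection paths.
#' @param rt_tolerance_s Co-elution tolerance used when planting
#'   retention-time jitter (seconds).
#' @param n_replicates_whole,n_replicates_rnase Replicates per condition
#'   without / with RNase.
#' @param core_fraction Fraction of true interactome members that are
#'   core (RNase-resistant).
#' @param scope_shared,scope_activated Probabilities that a true member is
#'   present in both conditions, or only the activated one (the remainder
#'   is resting-only).
#' @param fwhm_mz,grid_step_mz Spectrum line width and grid spacing (m/z).
#' @return Object of class \code{"sim_config"} (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_samples_per_group = 6L,
                       nb_dispersion = 0.1,
                       de_fraction = 0.2,
                       de_log2fc_magnitude = 2,
                       library_sizes = 3e5,
                       n_proteins = 20L,
                       peptides_per_protein = 5,
                       ratio_log2_mean = 1,
                       ratio_log2_sd = 0.2,
                       noise_sd = 6,
                       n15_enrichment = 1.0,
                       contaminant_fraction = 0.1,
                       replicate_dropout = 0.1,
                       n_pathways = 40L,
                       pathway_size_range = c(20L, 80L),
                       planted_enriched = 4L,
                       query_size = 300L,
                       decoy_fraction = 0,
                       rt_tolerance_s = 30,
                       n_replicates_whole = 6L,
                       n_replicates_rnase = 4L,
                       core_fraction = 0.3,
                       scope_shared = 0.8,
                       scope_activated = 0.15,
                       fwhm_mz = 0.02,
                       grid_step_mz = 0.005) {
  cfg <- as.list(environment())
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(all(cond))) stop(msg, call. = FALSE)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
      "`seed` must be a single integer")
  for (f in c("de_fraction", "n15_enrichment", "contaminant_fraction",
              "replicate_dropout", "decoy_fraction", "core_fraction",
              "scope_shared", "scope_activated"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1,
        paste0("`", f, "` must lie in [0, 1]"))
  chk(cfg$scope_shared + cfg$scope_activated <= 1,
      "`scope_shared` + `scope_activated` must not exceed 1")
  for (f in c("n_genes", "n_samples_per_group", "n_proteins",
              "n_pathways", "planted_enriched", "query_size",
              "n_replicates_whole", "n_replicates_rnase"))
    chk(cfg[[f]] >= 1 || (f == "planted_enriched" && cfg[[f]] >= 0),
        paste0("`", f, "` must be a positive count"))
  for (f in c("nb_dispersion", "de_log2fc_magnitude",
              "peptides_per_protein", "rt_tolerance_s", "fwhm_mz",
              "grid_step_mz"))
    chk(cfg[[f]] > 0, paste0("`", f, "` must be positive"))
  chk(cfg$noise_sd >= 0, "`noise_sd` must be nonnegative")
  chk(all(cfg$library_sizes >= 1), "`library_sizes` must be positive")
  chk(length(cfg$pathway_size_range) == 2L &&
        cfg$pathway_size_range[1] >= 1 &&
        cfg$pathway_size_range[2] >= cfg$pathway_size_range[1],
      "`pathway_size_range` must be an increasing count pair")
  chk(cfg$pathway_size_range[2] <= cfg$n_genes,
      "pathways cannot be larger than the gene universe")
  chk(cfg$planted_enriched <= cfg$n_pathways,
      "`planted_enriched` must not exceed `n_pathways`")
  invisible(cfg)
}

#' Simulate a two-group count matrix with planted differential expression
#'
#' Gene counts are negative-binomial with variance \eqn{\mu + \phi\mu^2}.
#' Relative gene abundances are log-normal and scaled to the configured
#' library sizes; a \code{de_fraction} of genes gets a planted log2 fold
#' change of \code{de_log2fc_magnitude}, half up and half down, applied to
#' the second group. Exon-model lengths are drawn uniform on
#' \eqn{[500, 5000]} bp for FPKM computation.
#'
#' @param cfg [sim_config()] object.
#' @return List with \code{counts} (integer matrix, genes x samples),
#'   \code{groups} (\code{"groupA"}/\code{"groupB"} per column),
#'   \code{lengths} (named vector, bp), and \code{truth} (data.frame
#'   \code{gene}, \code{is_de}, \code{log2fc}).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes; m <- cfg$n_samples_per_group
  genes <- sprintf("gene%05d", seq_len(n))
  lib <- rep_len(cfg$library_sizes, 2L * m)

  q <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  q <- q / sum(q)

  n_de <- round(cfg$de_fraction * n)
  lfc <- numeric(n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    sgn <- rep(c(1, -1), length.out = n_de)
    lfc[idx] <- sgn * cfg$de_log2fc_magnitude
  }

  mu_a <- outer(q, lib[seq_len(m)])
  mu_b <- outer(q * 2^lfc, lib[m + seq_len(m)])
  mu <- cbind(mu_a, mu_b)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = n,
                   dimnames = list(genes,
                                   paste0(rep(c("A", "B"), each = m),
                                          seq_len(m))))
  lengths <- stats::setNames(round(stats::runif(n, 500, 5000)), genes)
  list(counts = counts,
       groups = rep(c("groupA", "groupB"), each = m),
       lengths = lengths,
       truth = data.frame(gene = genes, is_de = lfc != 0, log2fc = lfc,
                          stringsAsFactors = FALSE))
}

.AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
           "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

#' Simulate SILAC peptide features and mini-spectra with planted ratios
#'
#' Each protein gets a planted log2 light/heavy abundance ratio drawn from
#' \code{N(ratio_log2_mean, ratio_log2_sd)}; each of its peptides (random
#' sequences of 8-20 standard residues) yields one light (natural
#' nitrogen) and one heavy (\eqn{^{15}}N-enriched) feature sharing charge
#' and co-eluting within the tolerance, plus one spectrum window whose
#' intensities are \eqn{A_L P_L + A_H P_H} plus Gaussian noise with
#' \eqn{A_L / A_H} equal to the planted ratio. A \code{decoy_fraction} of
#' pairs is given a retention-time offset violating the co-elution rule.
#'
#' @param cfg [sim_config()] object.
#' @return List with \code{features} (data.frame: \code{feature_id},
#'   \code{protein}, \code{peptide}, \code{charge}, \code{rt_s},
#'   \code{mz}, \code{label}), \code{windows} (long data.frame:
#'   \code{pair_id}, \code{mz}, \code{intensity}), and \code{truth}
#'   (data.frame: \code{pair_id}, \code{peptide}, \code{protein},
#'   \code{true_ratio}, \code{a_light}, \code{a_heavy}, \code{decoy}).
#' @export
simulate_silac_spectra <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  base_amp <- 1000

  feats <- list(); wins <- list(); truth <- list()
  k <- 0L
  for (pr in seq_len(cfg$n_proteins)) {
    protein <- sprintf("prot%04d", pr)
    log2r <- stats::rnorm(1, cfg$ratio_log2_mean, cfg$ratio_log2_sd)
    ratio <- 2^log2r
    n_pep <- 1L + stats::rpois(1, max(0, cfg$peptides_per_protein - 1))
    for (j in seq_len(n_pep)) {
      k <- k + 1L
      len <- sample(8:20, 1L)
      pep <- paste(sample(.AA20, len, replace = TRUE), collapse = "")
      z <- sample(2:3, 1L)
      comp <- peptide_composition(pep)
      dl <- isotope_distribution(comp)
      dh <- isotope_distribution(comp, cfg$n15_enrichment)

      rt <- stats::runif(1, 300, 3000)
      jitter <- stats::runif(1, -cfg$rt_tolerance_s / 2,
                             cfg$rt_tolerance_s / 2)
      decoy <- stats::runif(1) < cfg$decoy_fraction
      rt_heavy <- rt + jitter +
        if (decoy) 3 * cfg$rt_tolerance_s * sample(c(-1, 1), 1) else 0

      span <- range(.envelope_span(dl, z), .envelope_span(dh, z))
      grid <- seq(span[1] - 0.5, span[2] + 0.5, by = cfg$grid_step_mz)
      a_heavy <- base_amp
      a_light <- ratio * a_heavy
      y <- a_light * project_distribution(dl, grid, z, cfg$fwhm_mz) +
        a_heavy * project_distribution(dh, grid, z, cfg$fwhm_mz)
      if (cfg$noise_sd > 0)
        y <- y + stats::rnorm(length(grid), 0, cfg$noise_sd)

      pair_id <- paste0(pep, "/", z)
      mz_l <- (dl$monoisotopic_mass + z * .MASS_PROTON) / z
      mz_h <- (dh$monoisotopic_mass + z * .MASS_PROTON) / z
      feats[[2 * k - 1]] <- data.frame(
        feature_id = sprintf("f%05dL", k), protein = protein,
        peptide = pep, charge = z, rt_s = rt, mz = mz_l, label = "light",
        stringsAsFactors = FALSE)
      feats[[2 * k]] <- data.frame(
        feature_id = sprintf("f%05dH", k), protein = protein,
        peptide = pep, charge = z, rt_s = rt_heavy, mz = mz_h,
        label = "heavy", stringsAsFactors = FALSE)
      wins[[k]] <- data.frame(pair_id = pair_id, mz = grid, intensity = y,
                              stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        pair_id = pair_id, peptide = pep, protein = protein,
        true_ratio = ratio, a_light = a_light, a_heavy = a_heavy,
        decoy = decoy, stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, feats),
       windows = do.call(rbind, wins),
       truth = do.call(rbind, truth))
}

#' Simulate replicated protein hit tables with planted memberships
#'
#' True interactome members are split into core (RNase-resistant) and
#' peripheral (RNase-sensitive) layers and given a condition scope
#' (shared, activated-only, or resting-only). Core members can appear in
#' all four design cells of their scope; peripheral members only in the
#' RNase-minus cells. Contaminant hits (drawn from
#' [default_contaminants()]) and non-human / high-FDR background hits are
#' added to every table, and per-replicate detection dropout is applied.
#'
#' @param cfg [sim_config()] object.
#' @return List with \code{tables} (nested list:
#'   \code{resting_minus}, \code{activated_minus}, \code{resting_plus},
#'   \code{activated_plus}, each a list of per-replicate data.frames with
#'   columns \code{accession}, \code{species}, \code{fdr}) and
#'   \code{truth} (data.frame: \code{accession}, \code{membership},
#'   \code{scope}).
#' @export
simulate_protein_table <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_proteins
  acc <- sprintf("P%05d_HUMAN", seq_len(n))
  n_core <- max(1L, round(cfg$core_fraction * n))
  membership <- c(rep("core", n_core), rep("peripheral", n - n_core))
  scope <- sample(c("both", "activated", "resting"), n, replace = TRUE,
                  prob = c(cfg$scope_shared, cfg$scope_activated,
                           1 - cfg$scope_shared - cfg$scope_activated))

  n_cont <- round(cfg$contaminant_fraction * n)
  cont <- sample(default_contaminants(), min(n_cont,
                                             length(default_contaminants())))
  n_bg <- max(0L, round(0.1 * n))
  bg_acc <- sprintf("B%05d", seq_len(n_bg))
  bg_species <- sample(c("human", "mouse", "bovine"), n_bg, replace = TRUE,
                       prob = c(0.5, 0.25, 0.25))

  in_condition <- function(a_scope, condition)
    a_scope == "both" | a_scope == condition

  make_table <- function(condition, rnase) {
    eligible <- in_condition(scope, condition) &
      (membership == "core" | !rnase)
    present <- which(eligible &
                       stats::runif(n) >= cfg$replicate_dropout)
    members <- data.frame(accession = acc[present],
                          species = rep("human", length(present)),
                          fdr = stats::runif(length(present), 0, 0.009),
                          stringsAsFactors = FALSE)
    contam <- data.frame(accession = cont,
                         species = rep("human", length(cont)),
                         fdr = stats::runif(length(cont), 0, 0.009),
                         stringsAsFactors = FALSE)
    bg <- data.frame(accession = bg_acc, species = bg_species,
                     fdr = ifelse(bg_species == "human",
                                  stats::runif(n_bg, 0.011, 0.4),
                                  stats::runif(n_bg, 0, 0.009)),
                     stringsAsFactors = FALSE)
    out <- rbind(members, contam, bg)
    rownames(out) <- NULL
    out
  }

  tables <- list(
    resting_minus = lapply(seq_len(cfg$n_replicates_whole),
                           function(i) make_table("resting", FALSE)),
    activated_minus = lapply(seq_len(cfg$n_replicates_whole),
                             function(i) make_table("activated", FALSE)),
    resting_plus = lapply(seq_len(cfg$n_replicates_rnase),
                          function(i) make_table("resting", TRUE)),
    activated_plus = lapply(seq_len(cfg$n_replicates_rnase),
                            function(i) make_table("activated", TRUE)))

  truth <- rbind(
    data.frame(accession = acc, membership = membership, scope = scope,
               stringsAsFactors = FALSE),
    if (length(cont)) data.frame(accession = cont,
                                 membership = "contaminant", scope = "both",
                                 stringsAsFactors = FALSE),
    if (n_bg) data.frame(accession = bg_acc, membership = "background",
                         scope = "both", stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  list(tables = tables, truth = truth)
}

#' Simulate a gene-set collection with planted enrichment
#'
#' Draws pathways of random sizes from a gene universe, then builds a
#' query list: for each planted-enriched pathway, half of its genes are
#' put in the query; the rest of the query is drawn uniformly from the
#' remaining universe. With \code{planted_enriched = 0} the query is a
#' uniform draw, giving a null collection for calibration.
#'
#' @param cfg [sim_config()] object.
#' @return List with \code{sets} (named list of gene vectors),
#'   \code{universe}, \code{query}, and \code{truth} (data.frame:
#'   \code{pathway}, \code{is_enriched}).
#' @export
simulate_genesets <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  universe <- sprintf("gene%05d", seq_len(cfg$n_genes))
  sizes <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2],
                  cfg$n_pathways, replace = TRUE)
  nm <- sprintf("pathway%03d", seq_len(cfg$n_pathways))
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- nm
  enriched <- nm[seq_len(cfg$planted_enriched)]

  query <- character(0)
  for (p in enriched)
    query <- union(query, sample(sets[[p]],
                                 ceiling(length(sets[[p]]) / 2)))
  pool <- setdiff(universe, query)
  fill <- max(0L, cfg$query_size - length(query))
  query <- c(query, sample(pool, min(fill, length(pool))))

  list(sets = structure(sets,
                        descriptions = stats::setNames(rep("simulated", length(nm)),
                                                       nm),
                        class = "gene_set_collection"),
       universe = universe, query = query,
       truth = data.frame(pathway = nm, is_enriched = nm %in% enriched,
                          stringsAsFactors = FALSE))
}
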