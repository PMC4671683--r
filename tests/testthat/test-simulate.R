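test_that("simulation config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(pathway_size_range = c(50, 20)), "increasing")
  expect_error(sim_config(pathway_size_range = c(10, 5000)),
               "larger than the gene universe")
  expect_error(sim_config(planted_enriched = 99), "n_pathways")
})

test_that("all four simulators are deterministic in the seed", {
  cfg <- sim_config(n_genes = 100, n_proteins = 5, seed = 42)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_silac_spectra(cfg),
                   simulate_silac_spectra(cfg))
  expect_identical(simulate_protein_table(cfg),
                   simulate_protein_table(cfg))
  expect_identical(simulate_genesets(cfg), simulate_genesets(cfg))
  # a different seed changes the draw
  cfg2 <- sim_config(n_genes = 100, n_proteins = 5, seed = 43)
  expect_false(identical(simulate_counts(cfg)$counts,
                         simulate_counts(cfg2)$counts))
})

test_that("planted truth covers every emitted entity exactly once", {
  cfg <- sim_config(n_genes = 150, n_proteins = 8, seed = 2)
  cs <- simulate_counts(cfg)
  expect_setequal(cs$truth$gene, rownames(cs$counts))
  expect_false(any(duplicated(cs$truth$gene)))

  ss <- simulate_silac_spectra(cfg)
  expect_setequal(ss$truth$pair_id, unique(ss$windows$pair_id))
  expect_false(any(duplicated(ss$truth$pair_id)))

  ps <- simulate_protein_table(cfg)
  seen <- unique(unlist(lapply(unlist(ps$tables, recursive = FALSE),
                               `[[`, "accession")))
  expect_true(all(seen %in% ps$truth$accession))
  expect_false(any(duplicated(ps$truth$accession)))

  gs <- simulate_genesets(cfg)
  expect_setequal(gs$truth$pathway, names(gs$sets))
})

test_that("null configuration plants no differential expression", {
  cs <- simulate_counts(sim_config(n_genes = 200, de_fraction = 0,
                                   seed = 4))
  expect_equal(sum(cs$truth$is_de), 0L)
  expect_true(all(cs$truth$log2fc == 0))
})

test_that("expected column sums track configured library sizes", {
  lib <- 5e4
  n_rep <- 100
  sums <- t(vapply(seq_len(n_rep), function(s)
    colSums(simulate_counts(sim_config(n_genes = 500, de_fraction = 0,
                                       n_samples_per_group = 2,
                                       library_sizes = lib,
                                       seed = 1000 + s))$counts),
    numeric(4)))
  mean_colsum <- colMeans(sums)
  se <- apply(sums, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(mean_colsum - lib) < 3 * se))
})

test_that("light and heavy features share charge and co-elute", {
  cfg <- sim_config(n_proteins = 6, seed = 6)
  ss <- simulate_silac_spectra(cfg)
  m <- match_peak_pairs(ss$features, cfg$rt_tolerance_s)
  # no decoys by default: every peptide pairs up
  expect_equal(nrow(m$pairs), nrow(ss$truth))
  expect_equal(nrow(m$rejects), 0L)

  # decoys violate co-elution and get rejected
  cfgd <- sim_config(n_proteins = 10, decoy_fraction = 0.5, seed = 6)
  ssd <- simulate_silac_spectra(cfgd)
  md <- match_peak_pairs(ssd$features, cfgd$rt_tolerance_s)
  n_decoy <- sum(ssd$truth$decoy)
  expect_gt(n_decoy, 0)
  expect_equal(nrow(md$pairs), nrow(ssd$truth) - n_decoy)
  expect_setequal(md$rejects$reason, "rt_mismatch")
})

test_that("heavy envelopes carry the planted mass shift", {
  cfg <- sim_config(n_proteins = 3, seed = 8)
  ss <- simulate_silac_spectra(cfg)
  dm <- 15.00010889894 - 14.00307400446
  for (pid in ss$truth$pair_id[1:3]) {
    pep <- ss$truth$peptide[ss$truth$pair_id == pid]
    z <- as.integer(sub(".*/", "", pid))
    f <- ss$features[ss$features$peptide == pep, ]
    nn <- peptide_composition(pep)[["N"]]
    expect_equal(f$mz[f$label == "heavy"] - f$mz[f$label == "light"],
                 nn * dm / z, tolerance = 1e-9)
  }
})

test_that("peripheral members never appear in RNase-treated tables", {
  cfg <- sim_config(n_proteins = 40, replicate_dropout = 0, seed = 10)
  ps <- simulate_protein_table(cfg)
  peri <- ps$truth$accession[ps$truth$membership == "peripheral"]
  plus_acc <- unique(unlist(lapply(c(ps$tables$resting_plus,
                                     ps$tables$activated_plus),
                                   `[[`, "accession")))
  expect_length(intersect(peri, plus_acc), 0)
})

test_that("lossless protein tables round-trip the planted sets", {
  cfg <- sim_config(n_proteins = 60, replicate_dropout = 0,
                    contaminant_fraction = 0, seed = 12)
  ps <- simulate_protein_table(cfg)
  filt <- lapply(ps$tables, function(cell)
    lapply(cell, filter_protein_hits, fdr_max = 0.01,
           contaminants = default_contaminants()))
  det <- lapply(filt, detection_call)
  sets <- assemble_interactome(det$resting_minus, det$activated_minus,
                               det$resting_plus, det$activated_plus)
  truth <- ps$truth
  expect_setequal(sets$core, truth$accession[truth$membership == "core"])
  expect_setequal(sets$peripheral,
                  truth$accession[truth$membership == "peripheral"])
})

test_that("an empty enrichment query yields all-unit p-values", {
  g <- simulate_genesets(sim_config(seed = 14))
  res <- hypergeometric_enrichment(character(0), g$sets, g$universe)
  expect_true(all(res$p == 1))
})

test_that("a fully captured pathway attains the minimum p-value", {
  g <- simulate_genesets(sim_config(n_pathways = 12, planted_enriched = 0,
                                    seed = 15))
  target <- names(g$sets)[1]
  query <- g$sets[[target]]
  res <- hypergeometric_enrichment(query, g$sets, g$universe)
  expect_equal(res$pathway[which.min(res$p)], target)
})

test_that("simulated inputs materialize as the documented TSV files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 50, n_proteins = 4, n_pathways = 5,
                    pathway_size_range = c(5L, 10L), query_size = 10,
                    planted_enriched = 1, seed = 16)
  write_sim_inputs(cfg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("counts.tsv", "lengths.tsv", "features.tsv", "windows.tsv",
           "sets.gmt", "truth_counts.tsv", "hits_resting_minus_1.tsv",
           "hits_activated_plus_4.tsv")))))
  counts <- read_tsv(file.path(dir, "counts.tsv"))
  expect_equal(nrow(counts), 50L)
  sets <- read_gmt(file.path(dir, "sets.gmt"))
  expect_length(sets, 5L)
})
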