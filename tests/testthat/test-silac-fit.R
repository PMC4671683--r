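make_features <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(feature_id = r[[1]], peptide = r[[2]],
               charge = as.integer(r[[3]]), rt_s = as.numeric(r[[4]]),
               mz = 500, label = r[[5]], stringsAsFactors = FALSE)))
}

test_that("co-eluting same-charge light/heavy features pair up", {
  f <- make_features(list("f1", "PEPTIDEK", 2, 100, "light"),
                     list("f2", "PEPTIDEK", 2, 101, "heavy"))
  m <- match_peak_pairs(f, rt_tolerance = 30)
  expect_equal(nrow(m$pairs), 1L)
  expect_equal(m$pairs$charge, 2L)
  expect_equal(nrow(m$rejects), 0L)
})

test_that("charge mismatch, ambiguity, and late elution are rejected", {
  f <- make_features(list("f1", "PEPTIDEK", 2, 100, "light"),
                     list("f2", "PEPTIDEK", 3, 101, "heavy"))
  m <- match_peak_pairs(f, 30)
  expect_equal(nrow(m$pairs), 0L)
  expect_setequal(m$rejects$reason, "charge_mismatch")

  f2 <- make_features(list("f1", "PEPTIDEK;OTHERSEQ", 2, 100, "light"),
                      list("f2", "PEPTIDEK", 2, 101, "heavy"))
  m2 <- match_peak_pairs(f2, 30)
  expect_equal(nrow(m2$pairs), 0L)
  expect_true("ambiguous_identity" %in% m2$rejects$reason)

  f3 <- make_features(list("f1", "PEPTIDEK", 2, 100, "light"),
                      list("f2", "PEPTIDEK", 2, 200, "heavy"))
  m3 <- match_peak_pairs(f3, 30)
  expect_equal(nrow(m3$pairs), 0L)
  expect_setequal(m3$rejects$reason, "rt_mismatch")
})

# shared fixtures for fitting tests
pep <- "SAMPLEPTIDEK"
comp <- peptide_composition(pep)
dl <- isotope_distribution(comp)
dh <- isotope_distribution(comp, 1.0)
span <- range(ripitome:::.envelope_span(dl, 2),
              ripitome:::.envelope_span(dh, 2))
grid <- seq(span[1] - 0.5, span[2] + 0.5, by = 0.005)

test_that("single-component window recovers its amplitude exactly", {
  y <- 3.0 * project_distribution(dl, grid, 2)
  f <- fit_ls_ftc(list(mz = grid, intensity = y), dl, dh, 2)
  expect_equal(f$a_light, 3.0, tolerance = 1e-10)
  expect_equal(f$a_heavy, 0, tolerance = 1e-10)
  expect_true(is.na(f$ratio))
  expect_lt(f$rss, 1e-16)
})

test_that("noiseless two-component window recovers the exact ratio", {
  y <- 1.0 * project_distribution(dl, grid, 2) +
    0.5 * project_distribution(dh, grid, 2)
  f <- fit_ls_ftc(list(mz = grid, intensity = y), dl, dh, 2)
  expect_equal(f$ratio, 2.0, tolerance = 1e-10)
  expect_lt(f$rss, 1e-16)
  expect_equal(filter_fits(list(f))[[1]]$accepted, TRUE)
})

test_that("grid coverage and singular designs are rejected", {
  short <- grid[grid < mean(span)]          # light envelope only
  y <- project_distribution(dl, short, 2)
  expect_error(fit_ls_ftc(list(mz = short, intensity = y), dl, dh, 2),
               "does not cover")
  expect_error(fit_ls_ftc(list(mz = grid,
                               intensity = numeric(length(grid))),
                          dl, dl, 2), "singular")
})

test_that("low-SNR and overlapping fits are flagged and rejected", {
  set.seed(4)
  y <- 1.0 * project_distribution(dl, grid, 2) +
    0.5 * project_distribution(dh, grid, 2) + rnorm(length(grid), 0, 0.2)
  f <- fit_ls_ftc(list(mz = grid, intensity = y), dl, dh, 2)
  out <- filter_fits(list(f), snr_min = 10)[[1]]
  expect_false(out$accepted)
  expect_equal(out$reason, "low_snr")

  # at low labeling efficiency the heavy envelope shifts by well under
  # one neutron per nitrogen and lands on top of the light isotopologues
  comp1 <- peptide_composition("GAVLIFPG")
  d1l <- isotope_distribution(comp1)
  d1h <- isotope_distribution(comp1, 0.1)
  sp <- range(ripitome:::.envelope_span(d1l, 2),
              ripitome:::.envelope_span(d1h, 2))
  g1 <- seq(sp[1] - 0.5, sp[2] + 0.5, by = 0.005)
  y1 <- project_distribution(d1l, g1, 2) + project_distribution(d1h, g1, 2)
  f1 <- fit_ls_ftc(list(mz = g1, intensity = y1), d1l, d1h, 2)
  expect_true(f1$overlap)
  expect_equal(filter_fits(list(f1))[[1]]$reason, "spectral_overlap")
})

test_that("noiseless simulated spectra give machine-accurate amplitudes", {
  cfg <- sim_config(n_proteins = 4, peptides_per_protein = 3,
                    noise_sd = 0, ratio_log2_mean = 0, ratio_log2_sd = 0,
                    seed = 3)
  ss <- simulate_silac_spectra(cfg)
  q <- quantify_silac(ss$features, ss$windows)
  ft <- merge(q$fits, ss$truth, by = "pair_id")
  expect_true(all(abs(ft$ratio / ft$true_ratio - 1) < 1e-8))
  expect_true(all(abs(ft$a_light.x / ft$a_light.y - 1) < 1e-8))
})

test_that("protein ratio statistics match the closed-form t-test", {
  r <- c(2.0, 2.1, 1.9, 2.0)
  x <- log2(r)
  res <- protein_ratio_stats(r, rep("p1", 4))
  expect_equal(res$mean_log2, mean(x), tolerance = 1e-12)
  expect_equal(res$t, mean(x) / (sd(x) / 2), tolerance = 1e-12)
  expect_equal(res$t, 33.89289, tolerance = 1e-5)
  expect_lt(res$p, 0.001)
  expect_equal(res$status, "tested")
})

test_that("degenerate and single-peptide proteins are untestable", {
  res <- protein_ratio_stats(c(1, 1, 1, 1), rep("p1", 4))
  expect_equal(res$status, "untestable-degenerate")
  expect_false(res$significant)

  res2 <- protein_ratio_stats(c(2.0), "p1")
  expect_equal(res2$status, "untestable")

  # orientation flips the sign of the mean log-ratio
  r <- c(2, 2.2, 1.9)
  a <- protein_ratio_stats(r, rep("p", 3), orientation = "light/heavy")
  b <- protein_ratio_stats(r, rep("p", 3), orientation = "heavy/light")
  expect_equal(a$mean_log2, -b$mean_log2, tolerance = 1e-12)
})

test_that("BH-adjusted protein p-values are monotone in raw rank", {
  set.seed(8)
  r <- 2^rnorm(60, 0, 0.3)
  prot <- rep(sprintf("p%02d", 1:20), each = 3)
  res <- protein_ratio_stats(r, prot)
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
  expect_equal(res$p_adj, stats::p.adjust(res$p, "BH"), tolerance = 1e-12)
})
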