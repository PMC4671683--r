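test_that("FPKM unit conversion and edge cases", {
  counts <- matrix(c(100L, 0L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  counts["g2", 1] <- 1e6L - 100L   # library total 1e6
  counts["g1", 1] <- 100L
  lengths <- c(g1 = 1000, g2 = 2000)
  f <- compute_fpkm(counts, lengths)
  expect_equal(f["g1", 1], 100.0)

  zero <- matrix(c(0L, 10L), nrow = 2,
                 dimnames = list(c("a", "b"), "s1"))
  fz <- compute_fpkm(zero, c(a = 500, b = 500))
  expect_equal(fz["a", 1], 0)

  expect_error(compute_fpkm(zero, c(a = 500)), "missing exon-model length")
})

test_that("FPKM is invariant under uniform count scaling of a sample", {
  set.seed(2)
  counts <- matrix(rpois(40, 50), nrow = 10,
                   dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  lengths <- setNames(runif(10, 500, 3000), rownames(counts))
  f1 <- compute_fpkm(counts, lengths)
  doubled <- counts; doubled[, 2] <- 2L * doubled[, 2]
  f2 <- compute_fpkm(doubled, lengths)
  expect_equal(f1[, 2], f2[, 2], tolerance = 1e-12)
})

test_that("FPKM round-trips back to counts", {
  set.seed(3)
  counts <- matrix(rpois(60, 80), nrow = 15,
                   dimnames = list(sprintf("g%d", 1:15), sprintf("s%d", 1:4)))
  lengths <- setNames(runif(15, 500, 3000), rownames(counts))
  f <- compute_fpkm(counts, lengths)
  back <- sweep(sweep(f, 1, lengths / 1e3, "*"), 2, colSums(counts) / 1e6,
                "*")
  expect_equal(back, counts + 0, tolerance = 1e-9)
})

test_that("expression filter keeps strict-majority passers per group", {
  groups <- c("a", "a", "a", "a", "b", "b", "b", "b")
  fpkm <- rbind(
    near  = rep(2^-1.9, 8),          # just above threshold everywhere
    tie   = c(1, 1, 2^-3, 2^-3, 1, 1, 2^-3, 2^-3),  # exactly half
    zero  = rep(0, 8),
    onegrp = c(rep(1, 3), 2^-3, rep(2^-3, 4)))      # 3/4 in group a
  colnames(fpkm) <- paste0("s", 1:8)
  kept <- filter_expressed(fpkm, groups, rule = "rnaseq")
  expect_true("near" %in% kept)
  expect_false("tie" %in% kept)
  expect_false("zero" %in% kept)
  expect_true("onegrp" %in% kept)

  # ripseq rule defaults to the +2 threshold
  kept2 <- filter_expressed(fpkm, groups, rule = "ripseq")
  expect_false("near" %in% kept2)
})

test_that("identical groups give zero fold changes and no calls", {
  set.seed(5)
  col <- rpois(50, 100)
  counts <- matrix(rep(col, 6), nrow = 50,
                   dimnames = list(sprintf("g%d", 1:50),
                                   sprintf("s%d", 1:6)))
  de <- differential_expression(counts, rep(c("x", "y"), each = 3))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$direction == "none"))
  expect_true(all(de$p == 1))
})

test_that("NB exact test equals brute-force conditional enumeration", {
  cases <- expand.grid(sa = c(0, 3, 10, 25), sb = c(2, 8, 30),
                       phi = c(0.05, 0.2), nA = c(2, 3), nB = c(3, 6))
  cases <- cases[cases$sa + cases$sb <= 60, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- ripitome:::.nb_exact_pvalue(cs$sa, cs$sb, cs$nA, cs$nB, cs$phi)
    want <- oracle_nb_conditional_p(cs$sa, cs$sb, cs$nA, cs$nB, cs$phi)
    expect_equal(got, want, tolerance = 1e-12,
                 label = paste("case", i))
  }
})

test_that("planted strong fold changes are recovered at FDR 0.05", {
  cfg <- sim_config(n_genes = 2000, de_fraction = 0.2,
                    de_log2fc_magnitude = 2, nb_dispersion = 0.1,
                    n_samples_per_group = 3, seed = 1)
  cs <- simulate_counts(cfg)
  de <- differential_expression(cs$counts, cs$groups)
  called <- de$gene[de$p_adj < 0.05]
  mean_count <- rowMeans(cs$counts)
  strong <- cs$truth$gene[cs$truth$is_de &
                            mean_count[cs$truth$gene] >= 50]
  recall <- mean(strong %in% called)
  fdp <- if (length(called))
    mean(!(called %in% cs$truth$gene[cs$truth$is_de])) else 0
  expect_gte(recall, 0.7)
  expect_lte(fdp, 0.10)
})

test_that("splicing index follows the control-negative sign convention", {
  tab <- data.frame(
    gene = rep(c("g1", "g2"), each = 3),
    role = rep(c("inclusion", "exclusion", "gene"), 2),
    intensity_a = c(200, 100, 50, 80, 80, 40),
    intensity_b = c(100, 200, 50, 80, 80, 40))
  res <- splicing_scores(tab, threshold = 0.2)
  r1 <- res[res$gene == "g1", ]
  expect_equal(r1$si_inclusion, -1)
  expect_equal(r1$si_exclusion, 1)
  expect_equal(r1$reciprocity, -1)
  expect_true(r1$spliced)

  r2 <- res[res$gene == "g2", ]      # identical intensities: all zero
  expect_equal(r2$si_inclusion, 0)
  expect_equal(r2$reciprocity, 0)
  expect_false(r2$spliced)

  # a feature stronger in control alone is negative
  tab3 <- data.frame(gene = "g3",
                     role = c("inclusion", "exclusion", "gene"),
                     intensity_a = c(300, 100, 50),
                     intensity_b = c(150, 100, 50))
  expect_lt(splicing_scores(tab3)$si_inclusion, 0)

  expect_error(splicing_scores(transform(tab3, intensity_a = c(-1, 1, 1))),
               "positive")
})

test_that("reciprocity is antisymmetric under condition swap", {
  set.seed(9)
  tab <- data.frame(
    gene = rep(sprintf("g%d", 1:5), each = 3),
    role = rep(c("inclusion", "exclusion", "gene"), 5),
    intensity_a = runif(15, 10, 500),
    intensity_b = runif(15, 10, 500))
  fwd <- splicing_scores(tab)
  swapped <- data.frame(gene = tab$gene, role = tab$role,
                        intensity_a = tab$intensity_b,
                        intensity_b = tab$intensity_a)
  rev_ <- splicing_scores(swapped)
  expect_equal(fwd$reciprocity, -rev_$reciprocity, tolerance = 1e-12)
})

test_that("gene classes partition the analyzed universe", {
  cls <- classify_genes(c("a", "b"), c("b", "c"))
  got <- setNames(cls$class, cls$gene)
  expect_equal(got[["a"]], "DE_only")
  expect_equal(got[["b"]], "DE_and_AS")
  expect_equal(got[["c"]], "AS_only")

  cls2 <- classify_genes(c("a"), c("b"), universe = c("a", "b", "z"))
  expect_equal(sum(cls2$class == "DE_and_AS"), 0L)
  expect_equal(cls2$class[cls2$gene == "z"], "neither")
  expect_equal(nrow(cls2), 3L)
  expect_false(any(duplicated(cls2$gene)))
})
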