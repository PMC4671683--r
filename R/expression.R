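#' Convert gene counts to FPKM
#'
#' \deqn{FPKM_{gs} = \frac{c_{gs}}{(\ell_g / 10^3)\,(L_s / 10^6)}}
#' with \eqn{\ell_g} the exon-model length of gene \eqn{g} (bp) and
#' \eqn{L_s} the column sum (total assigned fragments) of sample \eqn{s}.
#'
#' @param counts Integer matrix, genes x samples, with rownames.
#' @param lengths Named numeric vector of exon-model lengths (bp), covering
#'   every gene in \code{counts}.
#' @return Numeric matrix of FPKM values, same dimensions and dimnames.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing exon-model length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  len <- lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs nonzero total counts",
                          call. = FALSE)
  sweep(sweep(counts, 1, len / 1e3, "/"), 2, lib / 1e6, "/")
}

#' Filter genes by expression level
#'
#' Retains a gene when \eqn{\log_2(\mathrm{FPKM})} exceeds the threshold in
#' strictly more than half of the samples of at least one group. The
#' RNA-seq rule uses threshold \eqn{-2}; the RIP-seq "bound transcript"
#' rule uses \eqn{+2}. All-zero genes are always dropped
#' (\eqn{\log_2 0 = -\infty}).
#'
#' @param fpkm FPKM matrix from [compute_fpkm()].
#' @param groups Character/factor vector of group labels, one per column.
#' @param log2_threshold Threshold on the log2(FPKM) scale; default
#'   \code{-2} for \code{rule = "rnaseq"}, \code{+2} for
#'   \code{rule = "ripseq"}.
#' @param rule \code{"rnaseq"} or \code{"ripseq"} (sets the default
#'   threshold only; the rule structure is identical).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(fpkm, groups,
                             log2_threshold = NULL,
                             rule = c("rnaseq", "ripseq")) {
  rule <- match.arg(rule)
  if (is.null(log2_threshold))
    log2_threshold <- if (rule == "rnaseq") -2 else 2
  stopifnot(length(groups) == ncol(fpkm))
  lf <- log2(fpkm)  # zeros -> -Inf, never pass
  keep <- rep(FALSE, nrow(fpkm))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    npass <- rowSums(lf[, cols, drop = FALSE] > log2_threshold)
    keep <- keep | npass > length(cols) / 2
  }
  rownames(fpkm)[keep]
}

# Per-gene method-of-moments dispersion terms on normalized counts:
# E[s2 - m] = phi * mu^2 within each group, pooled over groups.
.dispersion_moments <- function(x, groups) {
  num <- 0; den <- 0
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    m <- rowMeans(x[, cols, drop = FALSE])
    v <- apply(x[, cols, drop = FALSE], 1, stats::var)
    w <- length(cols) - 1L
    num <- num + w * (v - m)
    # m^2 overestimates mu^2 by Var(mean) = sigma^2/n; debias with v/n
    den <- den + w * pmax(0, m^2 - v / length(cols))
  }
  c(num = sum(num), den = sum(den))
}

#' Common negative-binomial dispersion by method of moments
#'
#' Estimates a single dispersion \eqn{\phi} shared across genes under the
#' parameterization \eqn{\mathrm{Var} = \mu + \phi \mu^2}, by pooling
#' within-group moment contributions \eqn{(s^2 - \bar y)} against
#' \eqn{\bar y^2} over all genes and groups.
#'
#' @param x Numeric matrix of (normalized) counts, genes x samples.
#' @param groups Group label per column.
#' @return Nonnegative dispersion estimate.
#' @export
estimate_common_dispersion <- function(x, groups) {
  mom <- .dispersion_moments(x, groups)
  max(0, unname(mom["num"] / mom["den"]))
}

# Median-of-ratios size factors (robust to a minority of changed genes).
.size_factors <- function(counts) {
  logref <- rowMeans(log(counts + 0.5))
  sf <- apply(counts, 2, function(y) {
    use <- rowSums(counts) > 0
    exp(stats::median(log(y[use] + 0.5) - logref[use]))
  })
  sf / exp(mean(log(sf)))  # geometric mean 1
}

# Conditional NB exact test: P-value for the split (sa, sb) of the total
# s = sa + sb between nA and nB samples with common dispersion phi. Uses
# the closed-form identity that a sum of n iid NB(mu, phi) is
# NB(n*mu, phi/n). Two-sided p sums the probabilities of all splits at
# most as likely as the observed one.
.nb_exact_pvalue <- function(sa, sb, nA, nB, phi) {
  s <- sa + sb
  if (s == 0) return(1)
  a <- 0:s
  if (phi <= 0) {
    lp <- stats::dbinom(a, s, nA / (nA + nB), log = TRUE)
  } else {
    mu <- s / (nA + nB)
    la <- stats::dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE)
    lb <- stats::dnbinom(s - a, size = nB / phi, mu = nB * mu, log = TRUE)
    lp <- la + lb
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  pobs <- lp[sa + 1L]
  min(1, sum(exp(lp[lp <= pobs + 1e-10])))
}

#' Differential expression / binding by a conditional NB exact test
#'
#' Two-group differential test for count data. Samples are normalized with
#' median-of-ratios size factors and scaled to a common pseudo-library; a
#' common dispersion is estimated across genes by method of moments
#' ([estimate_common_dispersion()]); each gene's pseudo-count split between
#' the groups is then tested exactly, conditional on the gene total, using
#' the negative-binomial convolution identity (a sum of \eqn{n} iid
#' NB(\eqn{\mu, \phi}) variables is NB(\eqn{n\mu, \phi/n})). The two-sided
#' p-value sums all splits whose conditional probability does not exceed
#' the observed one. P-values are BH-adjusted.
#'
#' @param counts Integer matrix, genes x samples, rownames required.
#' @param groups Group label per column; exactly two groups, each with at
#'   least 2 samples. The first level (sorted unique order) is the
#'   reference: positive \code{log2fc} means higher in the second group.
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @param dispersion Optional fixed common dispersion; estimated when
#'   \code{NULL}.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{p_adj}, \code{direction} (\code{"up"}, \code{"down"},
#'   \code{"none"}); attribute \code{dispersion} carries the common
#'   dispersion used.
#' @export
differential_expression <- function(counts, groups, alpha = 0.05,
                                    dispersion = NULL) {
  stopifnot(is.matrix(counts), length(groups) == ncol(counts))
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  gA <- which(groups == lev[1L]); gB <- which(groups == lev[2L])
  if (length(gA) < 2L || length(gB) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)

  sf <- .size_factors(counts)
  pseudo <- round(sweep(counts, 2, sf, "/"))

  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(pseudo, groups)

  sa <- rowSums(pseudo[, gA, drop = FALSE])
  sb <- rowSums(pseudo[, gB, drop = FALSE])
  nA <- length(gA); nB <- length(gB)

  p <- vapply(seq_len(nrow(pseudo)), function(i)
    .nb_exact_pvalue(sa[i], sb[i], nA, nB, dispersion), numeric(1))
  log2fc <- log2((sb / nB + 0.5) / (sa / nA + 0.5))
  p_adj <- bh_adjust(p)
  direction <- ifelse(p_adj < alpha,
                      ifelse(log2fc > 0, "up", "down"), "none")
  out <- data.frame(gene = rownames(counts), log2fc = log2fc, p = p,
                    p_adj = p_adj, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dispersion") <- dispersion
  out
}

#' Splicing index and reciprocity score for inclusion/exclusion features
#'
#' For each gene-normalized feature intensity, the splicing index between
#' condition B (e.g. knockdown) and condition A (control) is
#' \deqn{SI = \log_2\frac{(I_f / I_g)_B}{(I_f / I_g)_A},}
#' so a feature with greater intensity in the control is negative. A
#' reciprocal isoform switch moves the inclusion and exclusion features in
#' opposite directions; the reciprocity score
#' \eqn{(SI_{incl} - SI_{excl}) / 2} captures it, and a gene is flagged
#' alternatively spliced when its absolute reciprocity exceeds the
#' threshold.
#'
#' @param intensities data.frame with columns \code{gene}, \code{role}
#'   (\code{"inclusion"}, \code{"exclusion"}, \code{"gene"}),
#'   \code{intensity_a} (condition A / control), \code{intensity_b}
#'   (condition B). One row per role per gene; all intensities must be
#'   positive.
#' @param threshold Absolute-reciprocity cutoff for the alternatively
#'   spliced flag (default 0.2).
#' @return data.frame with columns \code{gene}, \code{si_inclusion},
#'   \code{si_exclusion}, \code{reciprocity}, \code{spliced}.
#' @export
splicing_scores <- function(intensities, threshold = 0.2) {
  need <- c("gene", "role", "intensity_a", "intensity_b")
  miss <- setdiff(need, names(intensities))
  if (length(miss))
    stop("intensities is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(intensities$intensity_a <= 0 | intensities$intensity_b <= 0))
    stop("intensities must be positive", call. = FALSE)

  rows <- lapply(split(intensities, intensities$gene), function(d) {
    pick <- function(role, col) {
      v <- d[[col]][d$role == role]
      if (length(v) != 1L)
        stop("gene ", d$gene[1L], ": need exactly one '", role,
             "' intensity per condition", call. = FALSE)
      v
    }
    si <- function(role)
      log2((pick(role, "intensity_b") / pick("gene", "intensity_b")) /
             (pick(role, "intensity_a") / pick("gene", "intensity_a")))
    si_i <- si("inclusion"); si_e <- si("exclusion")
    rec <- (si_i - si_e) / 2
    data.frame(gene = d$gene[1L], si_inclusion = si_i, si_exclusion = si_e,
               reciprocity = rec, spliced = abs(rec) > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign genes to expression/splicing classes
#'
#' Partitions the analyzed gene universe into the three activation-response
#' classes plus the remainder: differentially expressed only, both
#' differentially expressed and alternatively spliced, alternatively
#' spliced only, or neither.
#'
#' @param de_genes Character vector: significantly DE genes.
#' @param spliced_genes Character vector: alternatively spliced genes.
#' @param universe Optional character vector of all analyzed genes;
#'   defaults to the union of the two lists.
#' @return data.frame with columns \code{gene} and \code{class}
#'   (\code{"DE_only"}, \code{"DE_and_AS"}, \code{"AS_only"},
#'   \code{"neither"}).
#' @export
classify_genes <- function(de_genes, spliced_genes,
                           universe = union(de_genes, spliced_genes)) {
  de <- universe %in% de_genes
  as_ <- universe %in% spliced_genes
  cls <- ifelse(de & as_, "DE_and_AS",
                ifelse(de, "DE_only",
                       ifelse(as_, "AS_only", "neither")))
  data.frame(gene = universe, class = cls, stringsAsFactors = FALSE)
}
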