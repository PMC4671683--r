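#' Match light/heavy peptide features into quantifiable pairs
#'
#' Pairs \eqn{^{14}}N (light) and \eqn{^{15}}N (heavy) features of the same
#' peptide. A valid pair shares the peptide identity and charge state and
#' co-elutes within \code{rt_tolerance} seconds. Features annotated with more
#' than one candidate peptide identity (semicolon-separated) are discarded
#' before pairing.
#'
#' @param features data.frame with columns \code{feature_id}, \code{peptide},
#'   \code{charge}, \code{rt_s}, \code{mz}, \code{label}
#'   (\code{"light"}/\code{"heavy"}).
#' @param rt_tolerance Maximum retention-time difference within a pair,
#'   seconds (default 30).
#' @return List with \code{pairs} (data.frame: \code{pair_id},
#'   \code{peptide}, \code{charge}, \code{light_id}, \code{heavy_id},
#'   \code{rt_light}, \code{rt_heavy}) and \code{rejects} (data.frame:
#'   \code{feature_id}, \code{reason}). Reject reasons are
#'   \code{"ambiguous_identity"}, \code{"charge_mismatch"},
#'   \code{"rt_mismatch"}, \code{"no_partner"}, \code{"duplicate_feature"}.
#' @export
match_peak_pairs <- function(features, rt_tolerance = 30) {
  stopifnot(is.data.frame(features))
  need <- c("feature_id", "peptide", "charge", "rt_s", "label")
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("features is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  rejects <- list()
  ambiguous <- grepl(";", features$peptide, fixed = TRUE)
  if (any(ambiguous))
    rejects[["amb"]] <- data.frame(
      feature_id = features$feature_id[ambiguous],
      reason = "ambiguous_identity", stringsAsFactors = FALSE)
  feats <- features[!ambiguous, , drop = FALSE]

  pairs <- list()
  for (pep in unique(feats$peptide)) {
    f <- feats[feats$peptide == pep, , drop = FALSE]
    light <- f[f$label == "light", , drop = FALSE]
    heavy <- f[f$label == "heavy", , drop = FALSE]
    done <- character(0)
    for (z in unique(f$charge)) {
      lz <- light[light$charge == z, , drop = FALSE]
      hz <- heavy[heavy$charge == z, , drop = FALSE]
      if (nrow(lz) == 1L && nrow(hz) == 1L) {
        if (abs(lz$rt_s - hz$rt_s) <= rt_tolerance) {
          pairs[[paste0(pep, "/", z)]] <- data.frame(
            pair_id = paste0(pep, "/", z), peptide = pep, charge = z,
            light_id = lz$feature_id, heavy_id = hz$feature_id,
            rt_light = lz$rt_s, rt_heavy = hz$rt_s,
            stringsAsFactors = FALSE)
          done <- c(done, lz$feature_id, hz$feature_id)
        } else {
          rejects[[paste0(pep, z)]] <- data.frame(
            feature_id = c(lz$feature_id, hz$feature_id),
            reason = "rt_mismatch", stringsAsFactors = FALSE)
          done <- c(done, lz$feature_id, hz$feature_id)
        }
      } else if (nrow(lz) > 1L || nrow(hz) > 1L) {
        ids <- c(lz$feature_id, hz$feature_id)
        rejects[[paste0(pep, z, "dup")]] <- data.frame(
          feature_id = ids, reason = "duplicate_feature",
          stringsAsFactors = FALSE)
        done <- c(done, ids)
      }
    }
    left <- setdiff(f$feature_id, done)
    if (length(left)) {
      # a same-peptide partner exists at a different charge -> charge
      # mismatch; otherwise the feature is simply unpartnered
      lf <- f[f$feature_id %in% left, , drop = FALSE]
      reason <- vapply(seq_len(nrow(lf)), function(i) {
        other <- f[f$label != lf$label[i], , drop = FALSE]
        if (nrow(other) > 0L) "charge_mismatch" else "no_partner"
      }, character(1))
      rejects[[paste0(pep, "left")]] <- data.frame(
        feature_id = lf$feature_id, reason = reason,
        stringsAsFactors = FALSE)
    }
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(pair_id = character(0), peptide = character(0),
               charge = integer(0), light_id = character(0),
               heavy_id = character(0), rt_light = numeric(0),
               rt_heavy = numeric(0), stringsAsFactors = FALSE)
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(feature_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(rejects) <- NULL
  list(pairs = pairs, rejects = rejects)
}

#' Project an isotope distribution onto an m/z grid
#'
#' Peak \code{k} of a distribution with monoisotopic mass \code{M} falls at
#' \code{(M + k * delta_neutron + z * m_proton) / z}. Each peak is rendered
#' either as a unit-height Gaussian of the given FWHM (profile mode) or
#' snapped to the nearest grid point (centroid mode), scaled by its relative
#' abundance.
#'
#' @param dist [isotope_distribution()] object.
#' @param grid Strictly increasing numeric m/z grid.
#' @param charge Positive integer charge state.
#' @param fwhm Gaussian full width at half maximum in m/z units
#'   (default 0.02). Ignored in centroid mode.
#' @param mode \code{"profile"} or \code{"centroid"}.
#' @param delta_neutron Neutron spacing in Da (default the 13C-12C mass
#'   difference).
#' @return Numeric vector of the same length as \code{grid}.
#' @export
project_distribution <- function(dist, grid, charge, fwhm = 0.02,
                                 mode = c("profile", "centroid"),
                                 delta_neutron = .DELTA_NEUTRON) {
  mode <- match.arg(mode)
  stopifnot(inherits(dist, "isotope_distribution"),
            charge >= 1, all(diff(grid) > 0))
  k <- seq_along(dist$abundance) - 1
  centers <- (dist$monoisotopic_mass + k * delta_neutron +
                charge * .MASS_PROTON) / charge
  out <- numeric(length(grid))
  if (mode == "centroid") {
    ok <- centers >= grid[1L] & centers <= grid[length(grid)]
    for (i in which(ok)) {
      idx <- which.min(abs(grid - centers[i]))
      out[idx] <- out[idx] + dist$abundance[i]
    }
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    for (i in seq_along(centers)) {
      if (dist$abundance[i] < 1e-12) next
      lo <- centers[i] - 6 * sigma; hi <- centers[i] + 6 * sigma
      j <- which(grid >= lo & grid <= hi)
      if (length(j))
        out[j] <- out[j] +
          dist$abundance[i] * exp(-((grid[j] - centers[i])^2) / (2 * sigma^2))
    }
  }
  out
}

# m/z span (min, max peak center) of a projected distribution
.envelope_span <- function(dist, charge, delta_neutron = .DELTA_NEUTRON) {
  k <- c(0, length(dist$abundance) - 1)
  (dist$monoisotopic_mass + k * delta_neutron + charge * .MASS_PROTON) /
    charge
}

#' Least-squares Fourier-transform-convolution envelope fit
#'
#' Fits an observed mini-spectrum as a nonnegative linear combination of the
#' projected light and heavy theoretical envelopes (both computed by
#' Fourier-domain convolution, see [isotope_distribution()]), minimizing
#' \deqn{\sum_i (y_i - A_L P_L(m_i) - A_H P_H(m_i))^2, \quad A_L, A_H \ge 0.}
#' The amplitude ratio \eqn{R = A_L / A_H} is the light/heavy peptide
#' abundance ratio.
#'
#' @param window List or data.frame with \code{mz} (strictly increasing) and
#'   \code{intensity}.
#' @param d_light,d_heavy [isotope_distribution()] objects for the
#'   \eqn{^{14}}N and \eqn{^{15}}N species.
#' @param charge Charge state shared by the pair.
#' @param fwhm,mode,delta_neutron Passed to [project_distribution()].
#' @param pair_id Identifier carried into the result.
#' @return Object of class \code{"ftc_fit"}: list with \code{pair_id},
#'   \code{a_light}, \code{a_heavy}, \code{ratio} (\code{A_L/A_H}; \code{NA}
#'   if either amplitude is 0), \code{rss}, \code{snr} (max fitted signal
#'   over residual standard deviation; \code{Inf} for an exact fit),
#'   \code{residual_fraction} (RSS over total signal sum of squares),
#'   \code{overlap} (TRUE when the two projected envelopes share most of
#'   their grid support), \code{accepted}, \code{reason}.
#' @export
fit_ls_ftc <- function(window, d_light, d_heavy, charge, fwhm = 0.02,
                       mode = "profile", delta_neutron = .DELTA_NEUTRON,
                       pair_id = NA_character_) {
  mz <- window$mz; y <- window$intensity
  stopifnot(length(mz) == length(y), all(is.finite(y)))
  if (is.unsorted(mz, strictly = TRUE))
    stop("window m/z grid must be strictly increasing", call. = FALSE)

  span_l <- .envelope_span(d_light, charge, delta_neutron)
  span_h <- .envelope_span(d_heavy, charge, delta_neutron)
  if (min(span_l[1], span_h[1]) < mz[1L] ||
      max(span_l[2], span_h[2]) > mz[length(mz)])
    stop("window grid does not cover both projected envelopes",
         call. = FALSE)

  xl <- project_distribution(d_light, mz, charge, fwhm, mode, delta_neutron)
  xh <- project_distribution(d_heavy, mz, charge, fwhm, mode, delta_neutron)

  # spectral overlap: fraction of the smaller envelope's support shared
  sup_l <- xl > 1e-3 * max(xl); sup_h <- xh > 1e-3 * max(xh)
  overlap_frac <- sum(sup_l & sup_h) / max(1L, min(sum(sup_l), sum(sup_h)))
  overlap <- overlap_frac > 0.5

  g <- c(sum(xl * xl), sum(xl * xh), sum(xh * xh))
  det <- g[1] * g[3] - g[2]^2
  if (g[1] == 0 || g[3] == 0 || det / (g[1] * g[3]) < 1e-12)
    stop("singular design: projected envelopes are indistinguishable",
         call. = FALSE)

  b <- c(sum(xl * y), sum(xh * y))
  a <- c(g[3] * b[1] - g[2] * b[2], g[1] * b[2] - g[2] * b[1]) / det
  # active-set step for the 2-variable nonnegative problem
  if (a[1] < 0 && a[2] < 0) a <- c(0, 0)
  else if (a[1] < 0) a <- c(0, max(0, b[2] / g[3]))
  else if (a[2] < 0) a <- c(max(0, b[1] / g[1]), 0)

  fitted <- a[1] * xl + a[2] * xh
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum(y^2)
  sigma <- stats::sd(resid)
  snr <- if (isTRUE(sigma > 0)) max(fitted) / sigma else Inf
  ratio <- if (a[1] > 0 && a[2] > 0) a[1] / a[2] else NA_real_

  structure(list(pair_id = pair_id, a_light = a[1], a_heavy = a[2],
                 ratio = ratio, rss = rss,
                 residual_fraction = if (tss > 0) rss / tss else 0,
                 snr = snr, overlap = overlap, accepted = NA,
                 reason = NA_character_),
            class = "ftc_fit")
}

#' @export
print.ftc_fit <- function(x, ...) {
  cat("LS-FTC fit", if (!is.na(x$pair_id)) paste0("[", x$pair_id, "]"),
      "\n  A_light =", signif(x$a_light, 6),
      " A_heavy =", signif(x$a_heavy, 6),
      " ratio =", signif(x$ratio, 6),
      "\n  RSS =", signif(x$rss, 4),
      " SNR =", signif(x$snr, 4),
      " overlap =", x$overlap, "\n")
  invisible(x)
}

#' Quality-filter a list of envelope fits
#'
#' Automates the acceptance decision with two explicit thresholds: a fit is
#' accepted iff its signal-to-noise ratio is at least \code{snr_min}, its
#' residual fraction is at most \code{residual_fraction_max}, and the
#' light/heavy envelopes do not substantially overlap on the grid.
#'
#' @param fits List of [fit_ls_ftc()] results.
#' @param snr_min Minimum signal-to-noise ratio (default 10).
#' @param residual_fraction_max Maximum RSS / total-signal fraction
#'   (default 0.2).
#' @return The same list with \code{accepted} and \code{reason}
#'   (\code{"low_snr"}, \code{"high_residual"}, \code{"spectral_overlap"})
#'   filled in.
#' @export
filter_fits <- function(fits, snr_min = 10, residual_fraction_max = 0.2) {
  stopifnot(snr_min > 0, residual_fraction_max > 0)
  lapply(fits, function(f) {
    stopifnot(inherits(f, "ftc_fit"))
    if (f$overlap) {
      f$accepted <- FALSE; f$reason <- "spectral_overlap"
    } else if (!isTRUE(f$snr >= snr_min)) {
      f$accepted <- FALSE; f$reason <- "low_snr"
    } else if (f$residual_fraction > residual_fraction_max) {
      f$accepted <- FALSE; f$reason <- "high_residual"
    } else {
      f$accepted <- TRUE
    }
    f
  })
}

#' Fits as a data.frame
#'
#' @param fits List of [fit_ls_ftc()] results.
#' @return data.frame with one row per fit.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(pair_id = f$pair_id, a_light = f$a_light,
               a_heavy = f$a_heavy, ratio = f$ratio, rss = f$rss,
               residual_fraction = f$residual_fraction, snr = f$snr,
               overlap = f$overlap, accepted = f$accepted,
               reason = f$reason, stringsAsFactors = FALSE)))
}

#' Per-protein ratio statistics from peptide fits
#'
#' Log-transforms accepted peptide light/heavy (or re-oriented) ratios,
#' then tests each protein's mean log-ratio against 0 — equivalently the
#' ratio against 1 — with a one-sample two-sided t-test, followed by
#' Benjamini-Hochberg adjustment across tested proteins.
#'
#' Proteins with fewer than two finite peptide ratios are reported with
#' status \code{"untestable"}; proteins whose log-ratios have zero standard
#' deviation are reported \code{"untestable-degenerate"} rather than being
#' assigned p = 0.
#'
#' @param ratios Numeric vector of positive peptide ratios.
#' @param protein Character vector, same length: protein id per peptide.
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param orientation \code{"light/heavy"} (as fitted) or
#'   \code{"heavy/light"} (reciprocal), letting the caller map the isotope
#'   channels onto biological conditions, e.g. activated/resting.
#' @return data.frame with columns \code{protein}, \code{n_peptides},
#'   \code{mean_log2}, \code{sd_log2}, \code{t}, \code{p}, \code{p_adj},
#'   \code{significant}, \code{direction} (\code{"up"}/\code{"down"}/
#'   \code{"none"}), \code{status}.
#' @export
protein_ratio_stats <- function(ratios, protein, alpha = 0.05,
                                orientation = c("light/heavy",
                                                "heavy/light")) {
  orientation <- match.arg(orientation)
  stopifnot(length(ratios) == length(protein), alpha > 0, alpha < 1)
  keep <- is.finite(ratios) & ratios > 0
  ratios <- ratios[keep]; protein <- protein[keep]
  if (orientation == "heavy/light") ratios <- 1 / ratios
  lr <- log2(ratios)

  res <- lapply(split(lr, protein), function(x) {
    n <- length(x)
    if (n < 2L)
      return(data.frame(n_peptides = n, mean_log2 = mean(x),
                        sd_log2 = NA_real_, t = NA_real_, p = NA_real_,
                        status = "untestable", stringsAsFactors = FALSE))
    s <- stats::sd(x)
    # zero or numerically-constant spread: no valid t-test
    if (s == 0 || s / sqrt(n) <= 10 * .Machine$double.eps * abs(mean(x)))
      return(data.frame(n_peptides = n, mean_log2 = mean(x), sd_log2 = s,
                        t = NA_real_, p = NA_real_,
                        status = "untestable-degenerate",
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(x, mu = 0, alternative = "two.sided")
    data.frame(n_peptides = n, mean_log2 = mean(x), sd_log2 = s,
               t = unname(tt$statistic), p = tt$p.value, status = "tested",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(protein = names(res), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL

  out$p_adj <- NA_real_
  tested <- out$status == "tested"
  if (any(tested)) out$p_adj[tested] <- bh_adjust(out$p[tested])
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$direction <- ifelse(out$significant,
                          ifelse(out$mean_log2 > 0, "up", "down"), "none")
  out
}
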