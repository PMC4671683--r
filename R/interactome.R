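#' Filter mass-spectrometry protein identifications
#'
#' Keeps a hit iff its identification FDR is strictly below \code{fdr_max},
#' its species is human, and its accession is not on the contaminant list
#' (keratins, trypsin, immunoglobulin chains and similar).
#'
#' @param hits data.frame with columns \code{accession}, \code{species}
#'   (\code{"human"} or anything else), \code{fdr} in \eqn{[0, 1]}; extra
#'   columns pass through.
#' @param fdr_max Strict FDR threshold (default 0.01).
#' @param contaminants Character vector of contaminant accessions (may be
#'   empty); see [default_contaminants()].
#' @return The filtered data.frame (same columns).
#' @export
filter_protein_hits <- function(hits, fdr_max = 0.01,
                                contaminants = character(0)) {
  stopifnot(is.data.frame(hits))
  need <- c("accession", "species", "fdr")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hits is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- hits$fdr < fdr_max & hits$species == "human" &
    !(hits$accession %in% contaminants)
  hits[keep, , drop = FALSE]
}

#' Built-in mass-spectrometry contaminant accessions
#'
#' A small default list of proteins routinely identified as background in
#' affinity-purification mass spectrometry: keratins, trypsin, and common
#' immunoglobulin chains.
#'
#' @return Character vector of accessions.
#' @export
default_contaminants <- function() {
  c(paste0("KRT", c(1, 2, 5, 6, 9, 10, 14, 16, 17), "_HUMAN"),
    "TRYP_PIG", "TRY1_BOVIN", "ALBU_BOVIN",
    "IGHG1_HUMAN", "IGHG2_HUMAN", "IGKC_HUMAN", "IGLC1_HUMAN")
}

#' Call protein detection across replicates
#'
#' An accession counts as detected in one (condition, RNase-state) cell of
#' the design when it survives filtering in at least \code{min_replicates}
#' of the cell's replicate runs; the default is \eqn{\lceil n/2 \rceil}.
#'
#' @param replicate_hits List of filtered hit data.frames, one per
#'   replicate run of a single (condition, RNase-state) cell.
#' @param min_replicates Minimum replicate count; \code{NULL} (default)
#'   uses \eqn{\lceil n/2 \rceil} where \eqn{n} is the number of tables.
#' @return Character vector of detected accessions.
#' @export
detection_call <- function(replicate_hits, min_replicates = NULL) {
  n <- length(replicate_hits)
  if (is.null(min_replicates)) min_replicates <- ceiling(n / 2)
  if (min_replicates > n)
    stop("min_replicates exceeds the number of replicates", call. = FALSE)
  acc <- unlist(lapply(replicate_hits, function(h) unique(h$accession)))
  tab <- table(acc)
  names(tab)[tab >= min_replicates]
}

#' Assemble the interactome: whole/core/peripheral layers and Venn regions
#'
#' The whole interactome is the union of proteins detected in either
#' condition without RNase; the core (CIM) layer is the union of proteins
#' whose detection survives RNase treatment, i.e. proteins bound via
#' protein-protein contacts; peripheral members (PIM) are the RNase-
#' sensitive remainder, associated through the RNA scaffold. A
#' core-detected accession missing from the whole layer (possible under
#' replicate dropout) is added to the whole layer with a warning, since
#' RNase-resistant detection implies association.
#'
#' @param resting_minus,activated_minus Detected accessions per condition,
#'   no RNase.
#' @param resting_plus,activated_plus Detected accessions per condition,
#'   RNase-treated.
#' @return Object of class \code{"interactome_sets"}: list with
#'   \code{whole}, \code{core}, \code{peripheral} (character vectors) and
#'   \code{venn} (list of \code{whole} and \code{core} Venn triples from
#'   [venn_counts()]), plus the four input sets under \code{detected}.
#' @export
assemble_interactome <- function(resting_minus, activated_minus,
                                 resting_plus, activated_plus) {
  whole <- union(resting_minus, activated_minus)
  core <- union(resting_plus, activated_plus)
  extra <- setdiff(core, whole)
  if (length(extra)) {
    warning(length(extra),
            " core-detected accession(s) absent from the whole ",
            "interactome; added (RNase-resistant detection implies ",
            "association)")
    whole <- union(whole, extra)
  }
  peripheral <- setdiff(whole, core)
  structure(list(
    whole = whole, core = core, peripheral = peripheral,
    venn = list(
      whole = venn_counts(resting_minus, activated_minus),
      core = venn_counts(resting_plus, activated_plus)),
    detected = list(resting_minus = resting_minus,
                    activated_minus = activated_minus,
                    resting_plus = resting_plus,
                    activated_plus = activated_plus)),
    class = "interactome_sets")
}

#' @export
print.interactome_sets <- function(x, ...) {
  cat("Interactome:", length(x$whole), "proteins total\n")
  cat("  core (RNase-resistant):   ", length(x$core), "\n")
  cat("  peripheral (RNase-sensitive):", length(x$peripheral), "\n")
  v <- x$venn$whole
  cat("  whole Venn: resting-only", v["a_only"], "| activated-only",
      v["b_only"], "| shared", v["shared"], "\n")
  invisible(x)
}

#' Tally post-translational modifications per protein
#'
#' Counts modification records of the four tracked types per protein and
#' flags highly modified proteins (three or more total modifications).
#'
#' @param records data.frame with columns \code{accession}, \code{position},
#'   \code{type} (one of \code{"PhosphoT"}, \code{"PhosphoS"},
#'   \code{"Acetyl"}, \code{"Methyl"}); extra columns ignored.
#' @param flag_min Total-modification threshold for the high-modification
#'   flag (default 3).
#' @return List with \code{by_type} (data.frame \code{accession},
#'   \code{type}, \code{count}), \code{totals} (data.frame
#'   \code{accession}, \code{total}, \code{flagged}), and
#'   \code{high_modification} (accessions with \code{total >= flag_min}).
#' @export
tally_ptms <- function(records, flag_min = 3L) {
  types <- c("PhosphoT", "PhosphoS", "Acetyl", "Methyl")
  if (nrow(records) == 0L)
    return(list(by_type = data.frame(accession = character(0),
                                     type = character(0),
                                     count = integer(0)),
                totals = data.frame(accession = character(0),
                                    total = integer(0),
                                    flagged = logical(0)),
                high_modification = character(0)))
  bad <- setdiff(unique(records$type), types)
  if (length(bad))
    stop("unknown modification type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tab <- as.data.frame(table(accession = records$accession,
                             type = records$type),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tot <- as.data.frame(table(accession = records$accession),
                       stringsAsFactors = FALSE)
  names(tot)[2L] <- "total"
  tot$flagged <- tot$total >= flag_min
  list(by_type = tab, totals = tot,
       high_modification = tot$accession[tot$flagged])
}
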