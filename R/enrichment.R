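#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH false-discovery-rate adjusted p-values:
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, m\, p_{(j)} / j)}, returned
#' in the input order.
#'
#' @param pvalues Numeric vector of p-values in \eqn{[0, 1]}.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("`pvalues` must be numeric", call. = FALSE)
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1] and be non-missing", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * pvalues[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Read a gene-set collection from a GMT file
#'
#' Each line is \code{name<TAB>description<TAB>gene1<TAB>gene2...};
#' duplicate genes within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return Object of class \code{"gene_set_collection"}: a named list of
#'   character gene vectors, with a \code{descriptions} attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i,
           ": expected at least 3 tab-separated fields", call. = FALSE)
    nm[i] <- f[1L]; desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets Named list of character gene vectors (or a
#'   \code{gene_set_collection}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test across a gene-set collection
#'
#' For each pathway, tests whether the query list overlaps the pathway more
#' than expected under uniform sampling from the universe: the upper-tail
#' hypergeometric probability \eqn{P(X \ge k)} with \code{N} universe genes,
#' \code{K} pathway genes in the universe, \code{n} query genes in the
#' universe, and overlap \code{k}. P-values are BH-adjusted across all
#' pathways in the collection.
#'
#' Query genes outside the universe are dropped (their count is reported in
#' the \code{dropped_query} attribute); pathways are intersected with the
#' universe.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of character gene vectors
#'   (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene universe, e.g. the
#'   expressed-gene list from [filter_expressed()].
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @return data.frame with columns \code{pathway}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_adj}, \code{significant}, ordered
#'   as in \code{sets}; attribute \code{dropped_query} counts query genes
#'   outside the universe.
#' @export
hypergeometric_enrichment <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  dropped <- sum(!query %in% universe)
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)

  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(unique(sets[[nm]]), universe)
    K <- length(genes)
    k <- length(intersect(genes, query))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  attr(out, "dropped_query") <- dropped
  out
}

#' Export a bipartite pathway-gene network
#'
#' Builds SIF-format edges \code{pathway<TAB>contains<TAB>gene} for every
#' significant pathway and each of its member genes present in the query
#' list, plus a node-attribute table annotating each gene's direction of
#' change.
#'
#' @param results [hypergeometric_enrichment()] output.
#' @param sets The gene-set collection used for the test.
#' @param query The query gene list.
#' @param gene_directions Named character vector mapping gene id to a
#'   direction label (\code{"up"}, \code{"down"}, \code{"spliced"},
#'   \code{"mixed"}); genes absent from the map get \code{NA}.
#' @param sif_path,nodes_path Optional output file paths; when given, the
#'   SIF lines and a tab-separated node table are written there.
#' @return List with \code{edges} (data.frame \code{pathway}, \code{gene}),
#'   \code{nodes} (data.frame \code{gene}, \code{direction}), and
#'   \code{sif} (character vector of SIF lines).
#' @export
export_network <- function(results, sets, query,
                           gene_directions = character(0),
                           sif_path = NULL, nodes_path = NULL) {
  sig <- results$pathway[results$significant]
  edges <- list()
  for (nm in sig) {
    genes <- intersect(unique(sets[[nm]]), unique(query))
    if (length(genes))
      edges[[nm]] <- data.frame(pathway = nm, gene = genes,
                                stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(pathway = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  genes <- unique(edges$gene)
  nodes <- data.frame(
    gene = genes,
    direction = ifelse(genes %in% names(gene_directions),
                       unname(gene_directions[genes]), NA_character_),
    stringsAsFactors = FALSE)
  sif <- if (nrow(edges)) paste(edges$pathway, "contains", edges$gene,
                                sep = "\t") else character(0)
  if (!is.null(sif_path)) writeLines(sif, sif_path)
  if (!is.null(nodes_path))
    utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(edges = edges, nodes = nodes, sif = sif)
}
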