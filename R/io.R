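#' Read / write the package's TSV dialect
#'
#' All tables move through one dialect: UTF-8, tab-separated, header row,
#' \code{'.'} decimal separator, no quoting.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return \code{read_tsv()} returns a data.frame; \code{write_tsv()}
#'   returns \code{path} invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a full set of simulated pipeline inputs to a directory
#'
#' Materializes the outputs of the four simulators as the package's
#' on-disk interchange files: \code{counts.tsv} + \code{lengths.tsv} +
#' \code{truth_counts.tsv}, \code{features.tsv} + \code{windows.tsv} +
#' \code{truth_silac.tsv}, one \code{hits_<condition>_<rnase>_<rep>.tsv}
#' per replicate table + \code{truth_proteins.tsv}, and \code{sets.gmt} +
#' \code{query.txt} + \code{universe.txt} + \code{truth_pathways.tsv}.
#'
#' @param cfg [sim_config()] object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sim_inputs <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  cs <- simulate_counts(cfg)
  write_tsv(data.frame(gene = rownames(cs$counts), cs$counts,
                       check.names = FALSE), p("counts.tsv"))
  write_tsv(data.frame(gene = names(cs$lengths), exon_bp = cs$lengths),
            p("lengths.tsv"))
  write_tsv(cs$truth, p("truth_counts.tsv"))

  ss <- simulate_silac_spectra(cfg)
  write_tsv(ss$features, p("features.tsv"))
  write_tsv(ss$windows, p("windows.tsv"))
  write_tsv(ss$truth, p("truth_silac.tsv"))

  ps <- simulate_protein_table(cfg)
  for (cell in names(ps$tables)) {
    reps <- ps$tables[[cell]]
    for (i in seq_along(reps))
      write_tsv(reps[[i]], p(sprintf("hits_%s_%d.tsv", cell, i)))
  }
  write_tsv(ps$truth, p("truth_proteins.tsv"))

  gs <- simulate_genesets(cfg)
  write_gmt(gs$sets, p("sets.gmt"))
  writeLines(gs$query, p("query.txt"))
  writeLines(gs$universe, p("universe.txt"))
  write_tsv(gs$truth, p("truth_pathways.tsv"))

  invisible(dir)
}
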