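#' The packaged benchmark manifest
#'
#' The benchmark of monomeric enzyme crystal structures with mechanistically
#' bound ligands: PDB code, sequence length, catalytic residues (author
#' numbering), EC number, description, and the percent identity of the
#' nearest modeling template. Lengths span 131-583 residues, catalytic-residue
#' counts 2-6, and template identities from easy (>60%) to hard (<30%).
#'
#' @param path Optional path to an alternative manifest TSV; default: the
#'   table shipped with the package.
#' @return data.frame with columns pdb_code, length, catalytic_residues
#'   (comma-separated author numbers), ec, detail, pid_nearest_template, plus
#'   a parsed list-column `residues` and its length `n_catalytic`.
#' @export
benchmark_manifest <- function(path = NULL) {
  path <- path %||% system.file("extdata", "benchmark_manifest.tsv",
                                package = "catgeo", mustWork = TRUE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$residues <- lapply(strsplit(m$catalytic_residues, ","), as.integer)
  m$n_catalytic <- lengths(m$residues)
  m
}
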