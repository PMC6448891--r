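#' Pairwise alignment between a target and a template sequence
#'
#' Constructs the aligned pair used to transfer catalytic-residue identities
#' from a target sequence to a homolog. Rows are gapped strings of equal
#' length with '-' as the gap character.
#'
#' @param target_id,template_id Sequence labels.
#' @param target_row,template_row Gapped rows (equal length).
#' @return An `cg_alignment` object.
#' @export
alignment_pair <- function(target_id, template_id, target_row, template_row) {
  if (nchar(target_row) != nchar(template_row))
    cg_stop(sprintf("alignment rows differ in length (%d vs %d)",
                    nchar(target_row), nchar(template_row)),
            "catgeo_format_error")
  structure(list(target_id = target_id, template_id = template_id,
                 target_row = toupper(target_row),
                 template_row = toupper(template_row)),
            class = "cg_alignment")
}

#' @export
print.cg_alignment <- function(x, ...) {
  cat(sprintf("<cg_alignment %s / %s: %d columns, PID %.1f%%>\n",
              x$target_id, x$template_id, nchar(x$target_row),
              percent_identity(x)))
  invisible(x)
}

#' Read a target/template alignment pair from a file
#'
#' Supports aligned FASTA and Clustal formats (auto-detected from the file
#' head). The two requested records are extracted by identifier.
#'
#' @param path Alignment file.
#' @param target_id,template_id Record identifiers to extract.
#' @param format "auto" (default), "fasta" or "clustal".
#' @return An `cg_alignment`.
#' @export
read_alignment <- function(path, target_id, template_id,
                           format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path))
    cg_stop(sprintf("cannot read '%s': no such file", path), "catgeo_io_error")
  if (format == "auto") {
    head1 <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*>", head1)) "fasta" else "clustal"
  }
  seqs <- if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    as.character(Biostrings::readAAMultipleAlignment(path, format = "clustal"))
  }
  for (id in c(target_id, template_id))
    if (!id %in% names(seqs))
      cg_stop(sprintf("identifier '%s' not present in '%s'", id, path),
              "catgeo_key_error")
  alignment_pair(target_id, template_id,
                 seqs[[target_id]], seqs[[template_id]])
}

#' Residue correspondence implied by an alignment
#'
#' One entry per column where both rows are non-gap, as 1-based ungapped
#' sequence positions.
#'
#' @param a An `cg_alignment`.
#' @return data.frame with columns `target_pos`, `template_pos`, both strictly
#'   increasing.
#' @export
residue_correspondence <- function(a) {
  tr <- strsplit(a$target_row, "")[[1L]]
  qr <- strsplit(a$template_row, "")[[1L]]
  t_gap <- tr == "-"
  q_gap <- qr == "-"
  both <- !t_gap & !q_gap
  data.frame(target_pos = cumsum(!t_gap)[both],
             template_pos = cumsum(!q_gap)[both])
}

#' Percent identity of an alignment pair
#'
#' Identical doubly-ungapped columns over all doubly-ungapped columns (the
#' default), or over the full ungapped target length.
#'
#' @param a An `cg_alignment`.
#' @param denominator "aligned" (default) or "target".
#' @return Percentage in \[0, 100\]; 0 when no columns align.
#' @export
percent_identity <- function(a, denominator = c("aligned", "target")) {
  denominator <- match.arg(denominator)
  tr <- strsplit(a$target_row, "")[[1L]]
  qr <- strsplit(a$template_row, "")[[1L]]
  both <- tr != "-" & qr != "-"
  n_ident <- sum(tr[both] == qr[both])
  den <- if (denominator == "aligned") sum(both) else sum(tr != "-")
  if (den == 0L) return(0)
  100 * n_ident / den
}

#' Select templates below the identity ceiling
#'
#' Drops every candidate whose percent identity exceeds `cutoff` (strictly;
#' a candidate at exactly the cutoff is retained), then keeps at most `max_n`
#' of the remainder ranked by descending identity, ties broken by template id.
#'
#' @param candidates List of `cg_alignment` objects.
#' @param cutoff Identity ceiling in percent (default 80).
#' @param max_n Maximum number of templates kept (default 10).
#' @param denominator Passed to [percent_identity()].
#' @return Character vector of template ids in rank order; the full decision
#'   table is attached as attribute "report" (template_id, pid, selected).
#' @export
select_templates <- function(candidates, cutoff = 80, max_n = 10,
                             denominator = "aligned") {
  if (!(cutoff > 0 && cutoff <= 100))
    cg_stop("cutoff must be in (0, 100]", "catgeo_argument_error")
  if (max_n < 1) cg_stop("max_n must be >= 1", "catgeo_argument_error")
  ids <- vapply(candidates, function(a) a$template_id, character(1))
  pid <- vapply(candidates, percent_identity, numeric(1),
                denominator = denominator)
  ord <- order(-pid, ids)
  ids <- ids[ord]; pid <- pid[ord]
  eligible <- pid <= cutoff
  keep <- ids[eligible][seq_len(min(max_n, sum(eligible)))]
  report <- data.frame(template_id = ids, pid = pid,
                       selected = ids %in% keep)
  structure(keep, report = report)
}

#' Terminal coverage range of a target under a set of templates
#'
#' The modeled region of the target sequence: everything outside the first and
#' last position covered by any template is trimmed (internal gaps are never
#' trimmed).
#'
#' @param target_length Ungapped target length.
#' @param maps List of residue-correspondence data.frames
#'   (see [residue_correspondence()]).
#' @return List with `start` and `end`, 1-based inclusive target positions.
#' @export
trim_to_coverage <- function(target_length, maps) {
  pos <- unlist(lapply(maps, function(m) m$target_pos))
  if (length(pos) == 0L)
    cg_stop("no template covers any target position", "catgeo_coverage_error")
  if (max(pos) > target_length)
    cg_stop("coverage position exceeds target length", "catgeo_argument_error")
  list(start = min(pos), end = max(pos))
}
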