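#' Constraint rendering parameters
#'
#' Parameters of the harmonic AtomPair restraints: the harmonic tolerance
#' (standard deviation of the well, Angstrom), the scalar weight that
#' up-weights these restraints over everything else in the energy function,
#' and whether residues are written with author numbers or 1-based pose
#' numbers over the (possibly trimmed) modeling sequence.
#'
#' @param tolerance Harmonic sd in Angstrom (> 0); default 0.5, the empirical
#'   conservation level of catalytic atom-pair distances.
#' @param weight Scalar restraint weight (> 0); default 1000.
#' @param numbering "author" (default) or "pose".
#' @return A `cg_cst_spec`.
#' @export
cst_spec <- function(tolerance = 0.5, weight = 1000,
                     numbering = c("author", "pose")) {
  if (!(is.numeric(tolerance) && length(tolerance) == 1L && tolerance > 0))
    cg_stop("tolerance must be a single positive number",
            "catgeo_argument_error")
  if (!(is.numeric(weight) && length(weight) == 1L && weight > 0))
    cg_stop("weight must be a single positive number", "catgeo_argument_error")
  structure(list(tolerance = tolerance, weight = weight,
                 numbering = match.arg(numbering)),
            class = "cg_cst_spec")
}

#' Measure reference catalytic atom-pair distances
#'
#' Euclidean distances between every enumerated catalytic Calpha/Cbeta atom
#' pair, measured on a solved structure in a catalytically viable arrangement
#' (the benchmark target itself, or in production a solved homolog).
#'
#' @param reference A `cg_structure`.
#' @param site A `cg_site` on `reference`.
#' @return data.frame: res_a, res_b (keys), resno_a, resno_b (author numbers),
#'   atom_a, atom_b, distance (Angstrom, full precision).
#' @export
measure_reference_distances <- function(reference, site) {
  pairs <- enumerate_pairs(site, reference)
  if (nrow(pairs) == 0L)
    return(data.frame(res_a = character(), res_b = character(),
                      resno_a = integer(), resno_b = integer(),
                      atom_a = character(), atom_b = character(),
                      distance = numeric()))
  d <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- atom_coord(reference, pairs$res_a[i], pairs$atom_a[i])
    b <- atom_coord(reference, pairs$res_b[i], pairs$atom_b[i])
    vec3_norm(a - b)
  }, numeric(1))
  data.frame(res_a = pairs$res_a, res_b = pairs$res_b,
             resno_a = key_resno(pairs$res_a),
             resno_b = key_resno(pairs$res_b),
             atom_a = pairs$atom_a, atom_b = pairs$atom_b,
             distance = d)
}

key_resno <- function(key) as.integer(sub("^.*:(-?[0-9]+).*$", "\\1", key))

#' Author-to-pose residue numbering map
#'
#' Pose numbers are 1-based and contiguous over the modeled region of the
#' sequence (after terminal trimming to template coverage); author numbers
#' are those of the PDB file.
#'
#' @param structure A `cg_structure`.
#' @param range Optional coverage range (list with `start`, `end`, 1-based
#'   polymer positions, see [trim_to_coverage()]); default: the full chain.
#' @return data.frame: key, resno (author), pose.
#' @export
numbering_map <- function(structure, range = NULL) {
  keys <- residue_keys(structure)
  range <- range %||% list(start = 1L, end = length(keys))
  idx <- seq(range$start, range$end)
  data.frame(key = keys[idx], resno = key_resno(keys[idx]),
             pose = seq_along(idx))
}

#' Render harmonic AtomPair constraints
#'
#' One Rosetta-dialect constraint line per reference distance:
#' `AtomPair <atom_a> <res_a> <atom_b> <res_b> SCALARWEIGHTEDFUNC <weight>
#' HARMONIC <distance> <tolerance>`, single-space separated, distance printed
#' to 2 decimals and tolerance to 1, lines in canonical pair order, trailing
#' newline. Output is byte-identical across runs for identical inputs.
#'
#' @param refs Reference distances from [measure_reference_distances()].
#' @param spec A `cg_cst_spec` (defaults: tolerance 0.5 A, weight 1000,
#'   author numbering).
#' @param map Required when `spec$numbering == "pose"`: a [numbering_map()]
#'   table covering every referenced residue.
#' @return Constraint-file text (single character scalar).
#' @export
render_cst <- function(refs, spec = cst_spec(), map = NULL) {
  if (nrow(refs) == 0L) return("")
  num_a <- refs$resno_a
  num_b <- refs$resno_b
  if (spec$numbering == "pose") {
    if (is.null(map))
      cg_stop("pose numbering requires a numbering map", "catgeo_numbering_error")
    pa <- map$pose[match(refs$res_a, map$key)]
    pb <- map$pose[match(refs$res_b, map$key)]
    bad <- unique(c(refs$res_a[is.na(pa)], refs$res_b[is.na(pb)]))
    if (length(bad) > 0L)
      cg_stop(sprintf("residue(s) missing from numbering map: %s",
                      paste(bad, collapse = ", ")), "catgeo_numbering_error")
    num_a <- pa; num_b <- pb
  }
  atom_rank <- function(a) match(a, c("CA", "CB"))
  ord <- order(num_a, num_b, atom_rank(refs$atom_a), atom_rank(refs$atom_b))
  lines <- sprintf("AtomPair %s %d %s %d SCALARWEIGHTEDFUNC %s HARMONIC %.2f %.1f",
                   refs$atom_a[ord], num_a[ord],
                   refs$atom_b[ord], num_b[ord],
                   format_weight(spec$weight),
                   refs$distance[ord], spec$tolerance)
  paste0(paste(lines, collapse = "\n"), "\n")
}

format_weight <- function(w) {
  if (abs(w - round(w)) < 1e-9) sprintf("%d", as.integer(round(w)))
  else sprintf("%g", w)
}

#' Write a constraint file
#'
#' @inheritParams render_cst
#' @param path Output .cst path.
#' @return `path`, invisibly.
#' @export
write_cst <- function(refs, path, spec = cst_spec(), map = NULL) {
  cat(render_cst(refs, spec, map), file = path, sep = "")
  invisible(path)
}

#' Parse a harmonic AtomPair constraint file
#'
#' Reads the dialect written by [render_cst()] back into a table; the inverse
#' of rendering at the printed precisions.
#'
#' @param x Constraint text, or a file path.
#' @return data.frame: atom_a, resno_a, atom_b, resno_b, weight, distance,
#'   tolerance.
#' @export
parse_cst <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
  else unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) != 10L || tok[1L] != "AtomPair" ||
        tok[6L] != "SCALARWEIGHTEDFUNC" || tok[8L] != "HARMONIC")
      cg_stop(sprintf("unrecognized constraint line: '%s'", ln),
              "catgeo_format_error")
    data.frame(atom_a = tok[2L], resno_a = as.integer(tok[3L]),
               atom_b = tok[4L], resno_b = as.integer(tok[5L]),
               weight = as.numeric(tok[7L]),
               distance = as.numeric(tok[9L]),
               tolerance = as.numeric(tok[10L]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
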