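#' Coordinate model of a PDB entry
#'
#' A `cg_structure` holds the polymer residues (ATOM records) of one chain and
#' the non-water heteroatom groups (HETATM records) of a PDB file, keeping the
#' author residue numbering. Only the first MODEL of a multi-model file is
#' used, and alternate locations are resolved to the highest-occupancy record
#' (ties go to the altloc label that sorts first).
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier to keep. `NULL` (default) keeps the first
#'   polymer chain in file order; the benchmark entries are monomeric so this
#'   is normally the only chain.
#' @param id Entry code stored on the object; defaults to the file base name.
#' @return A `cg_structure`: list with `id`, `atoms` (polymer atom table with
#'   columns chain, resno, icode, resname, atom, element, x, y, z, occ) and
#'   `het` (same columns for non-water heteroatoms).
#' @examples
#' toy <- make_toy_enzyme(synthetic_spec(n_res = 10, catalytic = c(3, 7)))
#' f <- tempfile(fileext = ".pdb")
#' write_structure(toy$structure, f)
#' s <- read_structure(f)
#' length(residue_keys(s))
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path))
    cg_stop(sprintf("cannot read '%s': no such file", path), "catgeo_io_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) cg_stop(
      sprintf("'%s' is not parseable as PDB: %s", path, conditionMessage(e)),
      "catgeo_format_error"))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    cg_stop(sprintf("'%s' contains no coordinate records", path),
            "catgeo_format_error")
  df <- data.frame(
    record  = at$type,
    chain   = ifelse(is.na(at$chain), "_", at$chain),
    resno   = at$resno,
    icode   = ifelse(is.na(at$insert), "", at$insert),
    resname = at$resid,
    atom    = toupper(trimws(at$elety)),
    element = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
    alt     = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  # Infer the element from the atom name when the element column is blank
  # (common in minimal hand-written files).
  blank <- !nzchar(df$element)
  df$element[blank] <- substr(gsub("[0-9']", "", df$atom[blank]), 1, 1)
  df <- resolve_altloc(df)

  poly <- df[df$record == "ATOM", , drop = FALSE]
  het <- df[df$record == "HETATM" &
              !(df$resname %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  if (nrow(poly) > 0L) {
    keep_chain <- chain %||% poly$chain[1L]
    if (!keep_chain %in% poly$chain)
      cg_stop(sprintf("chain '%s' not present in polymer", keep_chain),
              "catgeo_key_error")
    poly <- poly[poly$chain == keep_chain, , drop = FALSE]
  } else if (!is.null(chain)) {
    cg_stop("no polymer records from which to select a chain",
            "catgeo_key_error")
  }
  cols <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ")
  new_cg_structure(id = id %||% tools::file_path_sans_ext(basename(path)),
                   atoms = poly[, cols, drop = FALSE],
                   het = het[, cols, drop = FALSE])
}

# Keep, per (chain, resno, icode, atom name), the highest-occupancy altloc;
# ties broken by the altloc label sorting first.
resolve_altloc <- function(df) {
  key <- paste(df$record, df$chain, df$resno, df$icode, df$atom, sep = "\r")
  if (!anyDuplicated(key)) return(df[, setdiff(names(df), "alt")])
  ord <- order(key, -df$occ, df$alt)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(as.integer(rownames(df))), , drop = FALSE]
  df[, setdiff(names(df), "alt")]
}

new_cg_structure <- function(id, atoms, het) {
  rownames(atoms) <- NULL
  rownames(het) <- NULL
  keys <- make_res_key(atoms$chain, atoms$resno, atoms$icode)
  structure(list(id = id, atoms = atoms, het = het,
                 residue_order = unique(keys)),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat(sprintf("<cg_structure '%s': %d polymer residues (%d atoms), %d ligand group(s)>\n",
              x$id, length(x$residue_order), nrow(x$atoms),
              length(ligands(x))))
  invisible(x)
}

#' Residue keys of the polymer, in file order
#'
#' @param s A `cg_structure`.
#' @return Character vector of "chain:resno\[icode\]" keys.
#' @export
residue_keys <- function(s) s$residue_order

# Atom table rows for one residue key.
residue_atoms <- function(s, res_key) {
  keys <- make_res_key(s$atoms$chain, s$atoms$resno, s$atoms$icode)
  s$atoms[keys == res_key, , drop = FALSE]
}

#' One-letter polymer sequence
#'
#' Non-standard residues become "X".
#'
#' @param s A `cg_structure`.
#' @return Character scalar (one letter per polymer residue, file order).
#' @export
polymer_sequence <- function(s) {
  keys <- make_res_key(s$atoms$chain, s$atoms$resno, s$atoms$icode)
  resn <- s$atoms$resname[match(s$residue_order, keys)]
  paste(suppressWarnings(bio3d::aa321(resn)), collapse = "")
}

#' Residue names of the polymer, in file order
#' @param s A `cg_structure`.
#' @return Character vector of 3-letter residue names.
#' @export
residue_names <- function(s) {
  keys <- make_res_key(s$atoms$chain, s$atoms$resno, s$atoms$icode)
  s$atoms$resname[match(s$residue_order, keys)]
}

#' Look up one atom coordinate
#'
#' @param s A `cg_structure`.
#' @param res_key Residue key ("chain:resno\[icode\]"), or an author residue
#'   number which is resolved on the structure's polymer chain.
#' @param atom_name Atom label, e.g. "CA" or "CB".
#' @return Numeric length-3 coordinate (x, y, z) in Angstrom.
#' @export
atom_coord <- function(s, res_key, atom_name) {
  if (is.numeric(res_key))
    res_key <- make_res_key(s$atoms$chain[1L], as.integer(res_key))
  if (!res_key %in% s$residue_order)
    cg_stop(sprintf("residue '%s' not found in structure '%s'", res_key, s$id),
            "catgeo_key_error")
  ra <- residue_atoms(s, res_key)
  hit <- which(ra$atom == toupper(atom_name))
  if (length(hit) == 0L)
    cg_stop(sprintf("residue '%s' (%s) has no atom '%s'",
                    res_key, ra$resname[1L], atom_name),
            "catgeo_missing_atom")
  as.numeric(ra[hit[1L], c("x", "y", "z")])
}

# TRUE if the residue has the named atom.
has_atom <- function(s, res_key, atom_name) {
  ra <- residue_atoms(s, res_key)
  any(ra$atom == toupper(atom_name))
}

#' Heteroatom (ligand) groups of a structure
#'
#' Waters are never included; hydrogens are excluded by element symbol so the
#' atom sets are heavy atoms only.
#'
#' @param s A `cg_structure`.
#' @return Named list of ligand groups, each a list with `het_code` and
#'   `atoms` (heavy-atom table).
#' @export
ligands <- function(s) {
  if (nrow(s$het) == 0L) return(list())
  heavy <- s$het[!(s$het$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(heavy) == 0L) return(list())
  grp <- make_res_key(heavy$chain, heavy$resno, heavy$icode)
  out <- lapply(split(heavy, factor(grp, levels = unique(grp))), function(a)
    list(het_code = a$resname[1L], atoms = a))
  out
}

#' Polymer residues near a set of center atoms
#'
#' Returns the keys of polymer residues having at least one heavy atom within
#' `cutoff` (inclusive) of at least one center atom. This is the neighborhood
#' query behind the 8-Angstrom active-site shell.
#'
#' @param s A `cg_structure`.
#' @param center_coords Numeric matrix (n x 3) of center atom coordinates, or
#'   a data.frame with x, y, z columns.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @return Character vector of residue keys in structure order.
#' @export
residues_within <- function(s, center_coords, cutoff) {
  if (is.data.frame(center_coords))
    center_coords <- as.matrix(center_coords[, c("x", "y", "z")])
  center_coords <- matrix(as.numeric(center_coords), ncol = 3L)
  if (nrow(center_coords) == 0L)
    cg_stop("center atom set is empty", "catgeo_argument_error")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    cg_stop("cutoff must be a single positive number", "catgeo_argument_error")
  heavy <- s$atoms[!(s$atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(heavy) == 0L) return(character())
  xyz <- as.matrix(heavy[, c("x", "y", "z")])
  # squared distance from every heavy atom to its nearest center
  d2min <- rep(Inf, nrow(xyz))
  for (i in seq_len(nrow(center_coords))) {
    d2 <- (xyz[, 1] - center_coords[i, 1])^2 +
      (xyz[, 2] - center_coords[i, 2])^2 +
      (xyz[, 3] - center_coords[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  keys <- make_res_key(heavy$chain, heavy$resno, heavy$icode)
  hit <- unique(keys[d2min <= cutoff^2])
  s$residue_order[s$residue_order %in% hit]
}

#' Write a structure back to PDB format
#'
#' @param s A `cg_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  all <- rbind(cbind(s$atoms, record = "ATOM"),
               if (nrow(s$het) > 0L) cbind(s$het, record = "HETATM"))
  type <- all$record
  bio3d::write.pdb(file = path,
                   type = type,
                   xyz = as.numeric(t(as.matrix(all[, c("x", "y", "z")]))),
                   resno = all$resno,
                   resid = all$resname,
                   eleno = seq_len(nrow(all)),
                   elety = all$atom,
                   chain = ifelse(all$chain == "_", "", all$chain),
                   insert = all$icode,
                   o = all$occ,
                   b = rep(0, nrow(all)),
                   elesy = all$element)
  invisible(path)
}

# CA coordinate matrix for a vector of residue keys (rows in key order).
ca_coords <- function(s, keys) {
  t(vapply(keys, function(k) atom_coord(s, k, "CA"), numeric(3)))
}
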