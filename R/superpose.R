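#' Optimal rigid superposition of two coordinate sets (Kabsch)
#'
#' Least-squares rigid-body fit of `mobile` onto `fixed` using the SVD of the
#' cross-covariance matrix. Reflections are forbidden: the recovered rotation
#' is always proper (determinant +1), as required for chiral biomolecules.
#'
#' @param fixed,mobile Numeric n x 3 coordinate matrices, n >= 3, matched row
#'   by row.
#' @return A `cg_superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` (Angstrom, after the fit) and `n_atoms`. The fitted
#'   mobile coordinates are `mobile %*% t(rotation) + translation` (rowwise).
#' @export
kabsch_fit <- function(fixed, mobile) {
  fixed <- as_coord_matrix(fixed)
  mobile <- as_coord_matrix(mobile)
  if (nrow(fixed) != nrow(mobile))
    cg_stop(sprintf("coordinate sets differ in length (%d vs %d)",
                    nrow(fixed), nrow(mobile)), "catgeo_argument_error")
  n <- nrow(fixed)
  if (n < 3L)
    cg_stop("at least 3 atom pairs are required for a determined fit",
            "catgeo_argument_error")
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)   # mobile, centered
  Q <- sweep(fixed, 2, cf)    # fixed, centered
  H <- crossprod(P, Q)        # 3x3 cross-covariance
  sv <- svd(H)
  # collinear (rank < 2) input leaves the rotation underdetermined
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300))
    cg_stop("degenerate (collinear) geometry: superposition underdetermined",
            "catgeo_conditioning_error")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  translation <- as.numeric(cf - R %*% cm)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_atoms = n),
            class = "cg_superposition")
}

#' @export
print.cg_superposition <- function(x, ...) {
  cat(sprintf("<cg_superposition: %d atoms, rmsd %.4f A>\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A `cg_superposition` (or list with `rotation` and
#'   `translation`).
#' @param coords n x 3 matrix or length-3 vector.
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, coords) {
  vec <- is.null(dim(coords))
  m <- as_coord_matrix(coords)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

as_coord_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L, byrow = TRUE)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L || any(!is.finite(x)))
    cg_stop("coordinates must be finite n x 3", "catgeo_argument_error")
  x
}

coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' C-alpha RMSD over a residue subset after superposition
#'
#' Measures how well a model reproduces a reference over a chosen residue set
#' (e.g. the catalytic residues). In `"global"` mode (default) the model is
#' superposed on all mapped CA atoms and the subset RMSD is read out in that
#' frame without refitting, i.e. subset error is judged in the context of the
#' whole-protein overlay. In `"local"` mode the fit itself uses only the
#' subset atoms.
#'
#' @param reference,model `cg_structure` objects.
#' @param map Residue correspondence (data.frame `target_pos`,
#'   `template_pos`) from reference polymer positions to model polymer
#'   positions; see [residue_correspondence()].
#' @param subset Character vector of reference residue keys (default: all
#'   mapped residues).
#' @param mode "global" or "local".
#' @return RMSD in Angstrom.
#' @export
subset_ca_rmsd <- function(reference, model, map, subset = NULL,
                           mode = c("global", "local")) {
  mode <- match.arg(mode)
  pairs <- mapped_ca_pairs(reference, model, map)
  subset <- subset %||% pairs$ref_key
  missing <- setdiff(subset, pairs$ref_key)
  if (length(missing) > 0L)
    cg_stop(sprintf("subset residues not mapped with CA in both structures: %s",
                    paste(missing, collapse = ", ")), "catgeo_coverage_error")
  in_sub <- pairs$ref_key %in% subset
  if (mode == "local") {
    fit <- kabsch_fit(pairs$ref_xyz[in_sub, , drop = FALSE],
                      pairs$mod_xyz[in_sub, , drop = FALSE])
    return(fit$rmsd)
  }
  fit <- kabsch_fit(pairs$ref_xyz, pairs$mod_xyz)
  moved <- apply_transform(fit, pairs$mod_xyz[in_sub, , drop = FALSE])
  coord_rmsd(pairs$ref_xyz[in_sub, , drop = FALSE], moved)
}

# Matched CA coordinates for all mapped residue pairs where both structures
# have a CA atom. Returns ref_key, ref_xyz, mod_xyz.
mapped_ca_pairs <- function(reference, model, map) {
  rk <- residue_keys(reference)
  mk <- residue_keys(model)
  if (max(map$target_pos) > length(rk) || max(map$template_pos) > length(mk))
    cg_stop("correspondence map indexes beyond the structures",
            "catgeo_argument_error")
  ref_key <- rk[map$target_pos]
  mod_key <- mk[map$template_pos]
  ok <- vapply(seq_along(ref_key), function(i)
    has_atom(reference, ref_key[i], "CA") && has_atom(model, mod_key[i], "CA"),
    logical(1))
  list(ref_key = ref_key[ok],
       ref_xyz = ca_coords(reference, ref_key[ok]),
       mod_xyz = ca_coords(model, mod_key[ok]))
}

#' Identity residue map between two same-length structures
#'
#' Convenience for models built on the full target sequence: position i maps
#' to position i.
#'
#' @param n Number of polymer residues.
#' @return Correspondence data.frame.
#' @export
identity_map <- function(n) data.frame(target_pos = seq_len(n),
                                       template_pos = seq_len(n))
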