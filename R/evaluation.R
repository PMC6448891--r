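#' Residues forming the active-site shell
#'
#' Polymer residues with any heavy atom within `cutoff` of the reference
#' center: the ligand's heavy atoms when a ligand is present (the default
#' center), otherwise the heavy atoms of the catalytic residues.
#'
#' @param structure A `cg_structure`.
#' @param site Optional `cg_site`; required when `center = "catalytic"` or no
#'   ligand exists.
#' @param cutoff Shell radius in Angstrom (default 8).
#' @param center "ligand" (default) or "catalytic".
#' @return Character vector of residue keys.
#' @export
active_site_residues <- function(structure, site = NULL, cutoff = 8,
                                 center = c("ligand", "catalytic")) {
  center <- match.arg(center)
  lig <- ligands(structure)
  use_ligand <- center == "ligand" && length(lig) > 0L
  coords <- if (use_ligand) {
    do.call(rbind, lapply(lig, function(l)
      as.matrix(l$atoms[, c("x", "y", "z")])))
  } else {
    if (is.null(site))
      cg_stop("no ligand present: a catalytic site is required as center",
              "catgeo_argument_error")
    do.call(rbind, lapply(site$keys, function(k) {
      ra <- residue_atoms(structure, k)
      as.matrix(ra[!(ra$element %in% c("H", "D")), c("x", "y", "z")])
    }))
  }
  residues_within(structure, coords, cutoff)
}

#' Ligand heavy-atom RMSD after protein superposition
#'
#' Superposes the model onto the reference over all mapped polymer CA atoms,
#' then (without refitting) measures the RMSD between the reference and model
#' ligand heavy atoms, paired by atom name within the het group. This is the
#' docking-accuracy metric: it penalizes both ligand misplacement and the
#' protein-frame error that carried it there.
#'
#' @param reference,model `cg_structure` objects, each holding a ligand of
#'   identical heavy-atom composition.
#' @param map Residue correspondence reference -> model.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(reference, model, map) {
  ref_lig <- first_ligand(reference)
  mod_lig <- first_ligand(model)
  a <- ref_lig$atoms; b <- mod_lig$atoms
  unmatched <- c(setdiff(a$atom, b$atom), setdiff(b$atom, a$atom))
  if (length(unmatched) > 0L)
    cg_stop(sprintf("ligand atom names do not pair: %s",
                    paste(unique(unmatched), collapse = ", ")),
            "catgeo_pairing_error")
  b <- b[match(a$atom, b$atom), , drop = FALSE]
  pairs <- mapped_ca_pairs(reference, model, map)
  fit <- kabsch_fit(pairs$ref_xyz, pairs$mod_xyz)
  moved <- apply_transform(fit, as.matrix(b[, c("x", "y", "z")]))
  coord_rmsd(as.matrix(a[, c("x", "y", "z")]), moved)
}

first_ligand <- function(s) {
  lig <- ligands(s)
  if (length(lig) == 0L)
    cg_stop(sprintf("structure '%s' has no ligand", s$id),
            "catgeo_pairing_error")
  lig[[1L]]
}

#' Evaluate one model against its reference crystal structure
#'
#' Computes the accuracy metrics in a single global frame: the model is
#' superposed on all mapped CA atoms, then the Calpha RMSD is read out over
#' (a) the catalytic residues, (b) the active-site shell and (c) the whole
#' mapped chain, plus the ligand heavy-atom RMSD when both structures carry a
#' ligand.
#'
#' @param reference Reference `cg_structure` (crystal).
#' @param model Candidate `cg_structure`.
#' @param map Residue correspondence reference -> model.
#' @param site `cg_site` on the reference.
#' @param active_site Character vector of reference residue keys for the
#'   shell; default: computed by [active_site_residues()] at 8 Angstrom.
#' @return One-row data.frame: model_id, catalytic_ca_rmsd,
#'   active_site_ca_rmsd, global_ca_rmsd, ligand_rmsd (NA when either
#'   structure lacks a ligand).
#' @export
evaluate_model <- function(reference, model, map, site, active_site = NULL) {
  active_site <- active_site %||%
    active_site_residues(reference, site = site)
  lr <- if (length(ligands(reference)) > 0L && length(ligands(model)) > 0L)
    ligand_rmsd(reference, model, map) else NA_real_
  data.frame(
    model_id = model$id,
    catalytic_ca_rmsd = subset_ca_rmsd(reference, model, map, site$keys),
    active_site_ca_rmsd = subset_ca_rmsd(reference, model, map, active_site),
    global_ca_rmsd = subset_ca_rmsd(reference, model, map),
    ligand_rmsd = lr)
}

#' Count targets modeled to atomic accuracy
#'
#' Per target, the best (minimum) value of `metric` over its `best_of`
#' top-ranked models is taken; a target succeeds when that minimum is
#' strictly below `threshold`. `best_of = 1` scores only the top-ranked
#' model; `best_of = 5` mirrors multi-submission assessment.
#'
#' @param reports data.frame with a `target` column and the metric column;
#'   rows per target are assumed ranked (best-first by energy).
#' @param threshold Success cutoff in Angstrom (default 1.0, strict `<`).
#' @param metric Metric column name (default "ligand_rmsd").
#' @param best_of Models considered per target (default 5).
#' @return List: `n_targets`, `n_success`, `threshold`, `minima` (named
#'   per-target minima).
#' @export
success_summary <- function(reports, threshold = 1.0, metric = "ligand_rmsd",
                            best_of = 5) {
  if (is.null(reports) || nrow(reports) == 0L)
    cg_stop("no evaluation reports", "catgeo_empty_error")
  require_cols(reports, c("target", metric))
  if (best_of < 1) cg_stop("best_of must be >= 1", "catgeo_argument_error")
  minima <- vapply(split(reports, reports$target), function(g)
    min(utils::head(g[[metric]], best_of), na.rm = TRUE), numeric(1))
  list(n_targets = length(minima),
       n_success = sum(minima < threshold),
       threshold = threshold,
       minima = minima)
}
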