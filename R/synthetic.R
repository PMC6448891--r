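#' Specification for a synthetic enzyme fixture
#'
#' Controls the toy-enzyme generator and its homolog ensemble. The defaults
#' encode the study conditions the toolkit targets: up to 10 homolog
#' templates spanning 20-80 percent identity, catalytic-site geometry
#' conserved to a deviation sd of 0.5 Angstrom (per-coordinate sigma_cat =
#' 0.5 / sqrt(2), since a distance deviation between two independently
#' perturbed template atoms has sd sigma * sqrt(2)), and an ordinary level of
#' global structural divergence elsewhere (sigma_global 1.0 Angstrom).
#'
#' @param n_res Polymer length (residues).
#' @param catalytic Indices (sequence positions) of the catalytic residues,
#'   2 to 6 of them.
#' @param sigma_global Per-coordinate Gaussian noise, Angstrom, applied to
#'   non-catalytic residues when deriving homologs.
#' @param sigma_cat Same, for catalytic residues.
#' @param n_templates Number of homolog templates to derive.
#' @param pid_range Range (lo, hi) of target percent identities as fractions.
#' @param glycine Indices of residues generated as glycine (no CB);
#'   default none.
#' @param seed Integer seed fixing all randomness.
#' @return A `cg_synthetic_spec`.
#' @export
synthetic_spec <- function(n_res = 50, catalytic = c(10, 25, 40),
                           sigma_global = 1.0, sigma_cat = 0.5 / sqrt(2),
                           n_templates = 10, pid_range = c(0.2, 0.8),
                           glycine = integer(0), seed = 1) {
  if (length(catalytic) < 2L || length(catalytic) > 6L)
    cg_stop("between 2 and 6 catalytic residues are supported",
            "catgeo_argument_error")
  if (n_res < max(catalytic))
    cg_stop("n_res must cover all catalytic indices", "catgeo_generation_error")
  if (sigma_global < 0 || sigma_cat < 0)
    cg_stop("noise sigmas must be >= 0", "catgeo_argument_error")
  structure(list(n_res = as.integer(n_res),
                 catalytic = sort(as.integer(catalytic)),
                 sigma_global = sigma_global, sigma_cat = sigma_cat,
                 n_templates = as.integer(n_templates),
                 pid_range = pid_range, glycine = as.integer(glycine),
                 seed = as.integer(seed)),
            class = "cg_synthetic_spec")
}

# ---- backbone construction -------------------------------------------------
# The toy fold places the catalytic CA atoms on a small circle (radius 4 A)
# around the origin -- an idealized convergent active site -- and threads the
# rest of the chain through them: inter-catalytic segments are circular arcs
# bulging away from the site in per-segment tilted planes, and terminal tails
# extend outward in straight runs. Every consecutive CA-CA distance is
# exactly 3.8 A by chord construction. The geometry is deterministic (no RNG).

CA_STEP <- 3.8
CB_LENGTH <- 1.53
SITE_RADIUS <- 4.0

# points A..B via M equal chords of length s on a circular arc bulging
# toward unit vector w (perpendicular to B-A)
arc_points <- function(A, B, M, s = CA_STEP, w) {
  D <- vec3_norm(B - A)
  if (M * s < D - 1e-9)
    cg_stop("segment too short to span the gap", "catgeo_generation_error")
  if (M == 1L) return(NULL)  # no intermediate points
  e1 <- (B - A) / D
  w <- unit3(w - sum(w * e1) * e1)
  # central angle Phi: s/D = sin(Phi/(2M)) / sin(Phi/2)
  f <- function(phi) sin(phi / (2 * M)) / sin(phi / 2) - s / D
  phi <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-6), tol = 1e-13)$root
  rho <- s / (2 * sin(phi / (2 * M)))
  h <- rho * cos(phi / 2)
  mid <- (A + B) / 2
  O <- mid - w * h
  th_A <- atan2(sum((A - O) * w), sum((A - O) * e1))
  t <- seq_len(M - 1L)
  th <- th_A - phi * t / M
  pts <- t(vapply(th, function(a) O + rho * (cos(a) * e1 + sin(a) * w),
                  numeric(3)))
  pts
}

toy_ca_positions <- function(spec) {
  k <- length(spec$catalytic)
  ang <- 2 * pi * (seq_len(k) - 1L) / k
  anchors <- cbind(SITE_RADIUS * cos(ang), SITE_RADIUS * sin(ang), 0)
  ca <- matrix(NA_real_, spec$n_res, 3L)
  ca[spec$catalytic, ] <- anchors
  # inter-catalytic arcs, tilted alternately out of the site plane
  if (k >= 2L) for (j in seq_len(k - 1L)) {
    i0 <- spec$catalytic[j]; i1 <- spec$catalytic[j + 1L]
    m <- i1 - i0  # number of chords
    A <- ca[i0, ]; B <- ca[i1, ]
    outward <- unit3((A + B) / 2 + c(1e-6, 2e-6, 0))
    e1 <- unit3(B - A)
    axis_t <- unit3(cross3(e1, outward))
    beta <- (0.5 + 0.35 * j) * (-1)^j
    w <- outward * cos(beta) + axis_t * sin(beta)
    if (m > 1L) ca[(i0 + 1L):(i1 - 1L), ] <- arc_points(A, B, m, w = w)
  }
  # straight terminal tails, tilted off the z axis so they stay apart
  n_head <- spec$catalytic[1L] - 1L
  if (n_head > 0L) {
    u <- unit3(unit3(ca[spec$catalytic[1L], ]) + c(0, 0, 1.2))
    for (t in seq_len(n_head))
      ca[spec$catalytic[1L] - t, ] <- ca[spec$catalytic[1L], ] + t * CA_STEP * u
  }
  n_tail <- spec$n_res - spec$catalytic[k]
  if (n_tail > 0L) {
    u <- unit3(unit3(ca[spec$catalytic[k], ]) + c(0, 0, -1.2))
    for (t in seq_len(n_tail))
      ca[spec$catalytic[k] + t, ] <- ca[spec$catalytic[k], ] + t * CA_STEP * u
  }
  ca
}

toy_cb_positions <- function(ca) {
  n <- nrow(ca)
  cb <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    prev <- if (i > 1L) ca[i, ] - ca[i - 1L, ] else NULL
    nxt <- if (i < n) ca[i, ] - ca[i + 1L, ] else NULL
    u <- if (!is.null(prev) && !is.null(nxt)) prev + nxt
    else if (!is.null(prev)) prev else nxt
    if (vec3_norm(u) < 1e-6) {
      # locally straight backbone: pick any perpendicular
      ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      base <- if (!is.null(nxt)) nxt else prev
      u <- cross3(base, ref)
    }
    cb[i, ] <- ca[i, ] + CB_LENGTH * unit3(u)
  }
  cb
}

#' Generate a toy enzyme structure with a planted active site
#'
#' Builds a deterministic idealized fold: catalytic CA atoms on a 4-Angstrom
#' circle around the origin, connecting loops arcing away from the site,
#' consecutive CA-CA spacing exactly 3.8 Angstrom, CB atoms at an idealized
#' 1.53-Angstrom offset, and a small rigid 4-heavy-atom ligand at the
#' catalytic centroid -- guaranteeing every catalytic residue sits inside the
#' default 8-Angstrom active-site shell. Catalytic residues are CYS, others
#' ALA (or GLY where requested, which drops the CB).
#'
#' @param spec A [synthetic_spec()].
#' @return List: `structure` (a `cg_structure`, ligand included as het group),
#'   `site` (a `cg_site`).
#' @export
make_toy_enzyme <- function(spec) {
  ca <- toy_ca_positions(spec)
  cb <- toy_cb_positions(ca)
  resname <- rep("ALA", spec$n_res)
  resname[spec$catalytic] <- "CYS"
  resname[spec$glycine] <- "GLY"
  rows <- list()
  for (i in seq_len(spec$n_res)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = i, icode = "", resname = resname[i],
      atom = "CA", element = "C",
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], occ = 1)
    if (resname[i] != "GLY")
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = i, icode = "", resname = resname[i],
        atom = "CB", element = "C",
        x = cb[i, 1], y = cb[i, 2], z = cb[i, 3], occ = 1)
  }
  atoms <- do.call(rbind, rows)
  centroid <- colMeans(ca[spec$catalytic, , drop = FALSE])
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (0.9 / sqrt(3))
  het <- data.frame(chain = "X", resno = 1L, icode = "", resname = "LIG",
                    atom = paste0("C", 1:4), element = "C",
                    x = centroid[1] + tetra[, 1],
                    y = centroid[2] + tetra[, 2],
                    z = centroid[3] + tetra[, 3], occ = 1)
  s <- new_cg_structure(id = sprintf("toy%03d", spec$seed),
                        atoms = atoms, het = het)
  site <- catalytic_site(s, spec$catalytic)
  d_site <- vapply(site$keys, function(k)
    vec3_norm(atom_coord(s, k, "CA") - centroid), numeric(1))
  if (any(d_site > 8))
    cg_stop("infeasible site: a catalytic residue lies outside the 8 A shell",
            "catgeo_generation_error")
  list(structure = s, site = site)
}

#' Derive one noisy homolog template from a toy enzyme
#'
#' Adds independent per-coordinate Gaussian noise (`sigma_cat` on catalytic
#' residues, `sigma_global` elsewhere), applies a random rigid motion, and
#' mutates non-catalytic residue identities to hit a percent identity drawn
#' from `pid_range`; catalytic residues stay conserved. The homolog is apo
#' (no ligand) and comes with its (gapless) alignment to the target. The
#' rigid motion makes the superposition machinery do real work while leaving
#' intra-structure distances untouched.
#'
#' @param base The `structure` element from [make_toy_enzyme()].
#' @param spec The same [synthetic_spec()].
#' @param k Template index (1-based); randomness is a deterministic function
#'   of `spec$seed` and `k`.
#' @return List: `structure` (the homolog), `alignment` (an `cg_alignment`
#'   target/template), `pid` (realized percent identity).
#' @export
perturb_homolog <- function(base, spec, k = 1L) {
  with_seed(spec$seed * 10000 + k, {
    atoms <- base$atoms
    keys <- make_res_key(atoms$chain, atoms$resno, atoms$icode)
    cat_keys <- make_res_key(atoms$chain[1L], spec$catalytic)
    is_cat <- keys %in% cat_keys
    sig <- ifelse(is_cat, spec$sigma_cat, spec$sigma_global)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, sig)
    atoms$y <- atoms$y + stats::rnorm(n, 0, sig)
    atoms$z <- atoms$z + stats::rnorm(n, 0, sig)
    # random proper rotation (normalized quaternion) + translation
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    tr <- stats::runif(3, -20, 20)
    xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R) +
      matrix(tr, n, 3, byrow = TRUE)
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]

    # sequence mutations on non-catalytic positions
    target_seq <- strsplit(paste(
      suppressWarnings(bio3d::aa321(residue_names(base))), collapse = ""),
      "")[[1L]]
    pid_goal <- stats::runif(1, spec$pid_range[1L], spec$pid_range[2L])
    n_mut <- round((1 - pid_goal) * spec$n_res)
    mutable <- setdiff(seq_len(spec$n_res), c(spec$catalytic, spec$glycine))
    n_mut <- min(n_mut, length(mutable))
    mut_pos <- sort(sample(mutable, n_mut))
    alphabet <- c("R", "N", "D", "E", "Q", "H", "I", "L", "K", "M",
                  "F", "P", "S", "T", "W", "Y", "V")
    tmpl_seq <- target_seq
    for (p in mut_pos)
      tmpl_seq[p] <- sample(setdiff(alphabet, target_seq[p]), 1L)
    # rewrite residue names on the homolog to match the mutated sequence
    new_names <- suppressWarnings(bio3d::aa123(tmpl_seq))
    res_pos <- match(keys, unique(keys))
    atoms$resname <- new_names[res_pos]

    hom <- new_cg_structure(id = sprintf("%s_t%02d", base$id, k),
                            atoms = atoms,
                            het = base$het[0L, , drop = FALSE])
    aln <- alignment_pair(base$id, hom$id,
                          paste(target_seq, collapse = ""),
                          paste(tmpl_seq, collapse = ""))
    list(structure = hom, alignment = aln, pid = percent_identity(aln))
  })
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Generate a planted Rosetta-style score table
#'
#' Emulates the docking bookkeeping: `n_groups` starting apo models times
#' `n_per_group` docking simulations (defaults 5 x 100 = 500 rows). Scores
#' are correlated Gaussians; the ligand RMSD column is generated with a
#' configurable correlation to the interface score so that energy-based
#' selection is informative but imperfect. Optional planted features make
#' filter behavior verifiable by construction: `n_violations` rows that are
#' guaranteed stage-1 survivors carry a mechanism-constraint penalty above
#' 1 REU.
#'
#' @param n_groups Number of starting models (default 5).
#' @param n_per_group Simulations per starting model (default 100).
#' @param planted List of options: `n_violations` (default 0),
#'   `rmsd_cor` in \[0, 1\) (default 0.6).
#' @param seed Integer seed.
#' @return data.frame: description, group, total_score, mech_cst_1..3,
#'   active_site_energy, interface_score, ligand_rmsd. Deterministic per seed.
#' @export
make_score_table <- function(n_groups = 5, n_per_group = 100,
                             planted = list(), seed = 1) {
  if (n_groups < 1 || n_per_group < 1)
    cg_stop("counts must be >= 1", "catgeo_argument_error")
  n_violations <- planted$n_violations %||% 0L
  rmsd_cor <- planted$rmsd_cor %||% 0.6
  with_seed(seed, {
    n <- n_groups * n_per_group
    group <- rep(sprintf("g%d", seq_len(n_groups)), each = n_per_group)
    id <- sprintf("%s_m%04d", group, rep(seq_len(n_per_group), n_groups))
    total <- stats::rnorm(n, -300, 15)
    mech <- matrix(abs(stats::rnorm(3 * n, 0, 0.25)), n, 3)
    active <- 0.3 * total + stats::rnorm(n, 0, 3)
    interface <- stats::rnorm(n, -15, 3)
    z <- (interface - mean(interface)) / stats::sd(interface)
    noise <- stats::rnorm(n)
    ligand <- pmax(0.05, 1.5 + 0.9 * (rmsd_cor * z +
                                        sqrt(1 - rmsd_cor^2) * noise))
    df <- data.frame(description = id, group = group, total_score = total,
                     mech_cst_1 = mech[, 1], mech_cst_2 = mech[, 2],
                     mech_cst_3 = mech[, 3],
                     active_site_energy = active,
                     interface_score = interface,
                     ligand_rmsd = ligand)
    if (n_violations > 0L) {
      # plant violations on guaranteed stage-1 survivors: the lowest
      # total_score rows of group 1
      g1 <- which(df$group == "g1")
      ord <- g1[order(df$total_score[g1])]
      n_violations <- min(n_violations,
                          ceiling(0.10 * n_per_group))
      df$mech_cst_1[ord[seq_len(n_violations)]] <- 1.5
    }
    df
  })
}
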