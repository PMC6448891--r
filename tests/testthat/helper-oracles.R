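# Independent oracles and fixture builders shared across the test files.

# Quaternion (characteristic-matrix) superposition oracle: the optimal-fit
# RMSD from the largest eigenvalue of the 4x4 key matrix, an independent
# route from the SVD used by the package.
quaternion_rmsd <- function(fixed, mobile) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(fixed, 2, colMeans(fixed))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  F <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(F, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / n
  sqrt(max(msd, 0))
}

# A random proper rotation + translation.
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  list(rotation = R, translation = runif(3, -30, 30))
}

# Apply a rigid motion to every atom of a cg_structure.
transform_structure <- function(s, rigid) {
  move <- function(df) {
    if (nrow(df) == 0L) return(df)
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rigid$rotation) +
      matrix(rigid$translation, nrow(df), 3, byrow = TRUE)
    df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
    df
  }
  s$atoms <- move(s$atoms)
  s$het <- move(s$het)
  s
}

# Brute-force re-implementation of the four-stage cascade: selection by
# repeated minimum search, no vectorized sorting.
brute_force_cascade <- function(table, cfg) {
  pick_lowest <- function(df, col, n_keep) {
    kept <- integer(0)
    avail <- seq_len(nrow(df))
    while (length(kept) < n_keep) {
      best <- avail[1]
      for (i in avail)
        if (df[[col]][i] < df[[col]][best] ||
            (df[[col]][i] == df[[col]][best] &&
             df[[cfg$id_col]][i] < df[[cfg$id_col]][best]))
          best <- i
      kept <- c(kept, best)
      avail <- setdiff(avail, best)
    }
    df[kept, , drop = FALSE]
  }
  pool <- NULL
  for (g in unique(sort(table[[cfg$group_col]]))) {
    sub <- table[table[[cfg$group_col]] == g, , drop = FALSE]
    keep <- pick_lowest(sub, cfg$total_col,
                        ceiling(cfg$pool_fraction * nrow(sub)))
    pool <- rbind(pool, keep)
  }
  pen_cols <- grep(cfg$penalty_pattern, names(table), value = TRUE)
  ok <- vapply(seq_len(nrow(pool)), function(i)
    max(as.numeric(pool[i, pen_cols])) <= cfg$mechanism_threshold, logical(1))
  pool <- pool[ok, , drop = FALSE]
  if (nrow(pool) > 0L)
    pool <- pick_lowest(pool, cfg$active_site_col,
                        ceiling(cfg$active_site_fraction * nrow(pool)))
  pool <- pick_lowest(pool, cfg$interface_col, nrow(pool))
  rownames(pool) <- NULL
  pool
}

# Minimal hand-written PDB text: three alanine residues plus an optional
# 4-heavy-atom LIG group. Exercises the fixed-column format directly.
pdb_line <- function(record, eleno, name, alt, resname, chain, resno, icode,
                     x, y, z, occ = 1, b = 0, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, paste0(" ", name), alt, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

minimal_pdb_text <- function(with_ligand = FALSE, glycine_at = NULL) {
  lines <- character(0)
  k <- 0L
  for (i in 1:3) {
    resname <- if (!is.null(glycine_at) && i %in% glycine_at) "GLY" else "ALA"
    k <- k + 1L
    lines <- c(lines, pdb_line("ATOM", k, "CA", " ", resname, "A", i, " ",
                               i * 3.8, 0, 0))
    if (resname != "GLY") {
      k <- k + 1L
      lines <- c(lines, pdb_line("ATOM", k, "CB", " ", resname, "A", i, " ",
                                 i * 3.8, 1.53, 0))
    }
  }
  if (with_ligand) {
    for (j in 1:4) {
      k <- k + 1L
      lines <- c(lines, pdb_line("HETATM", k, paste0("C", j), " ", "LIG",
                                 "X", 1, " ", 5 + j * 0.5, 5, 5))
    }
    # a water, which the reader must drop
    k <- k + 1L
    lines <- c(lines, pdb_line("HETATM", k, "O", " ", "HOH", "X", 2, " ",
                               20, 20, 20, element = "O"))
  }
  paste(c(lines, "END"), collapse = "\n")
}

write_pdb_text <- function(text) {
  f <- tempfile(fileext = ".pdb")
  writeLines(text, f)
  f
}

# Default toy fixture shared by several files (deterministic).
toy_fixture <- function(...) {
  spec <- synthetic_spec(...)
  c(make_toy_enzyme(spec), list(spec = spec))
}
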