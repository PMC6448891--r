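test_that("toy enzyme construction is deterministic with ideal geometry", {
  spec <- synthetic_spec(n_res = 50, catalytic = c(10, 25, 40), seed = 1)
  a <- make_toy_enzyme(spec)
  b <- make_toy_enzyme(spec)
  expect_identical(a$structure$atoms, b$structure$atoms)

  s <- a$structure
  ca <- t(sapply(residue_keys(s), function(k) atom_coord(s, k, "CA")))
  steps <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_equal(steps, rep(3.8, 49), tolerance = 1e-6, ignore_attr = TRUE)

  # CB at the idealized offset wherever present
  for (k in residue_keys(s)[c(1, 10, 25, 50)])
    expect_equal(sqrt(sum((atom_coord(s, k, "CB") - atom_coord(s, k, "CA"))^2)),
                 1.53, tolerance = 1e-6)

  # ligand centroid within 8 A of every catalytic residue
  lig <- ligands(s)[[1]]
  cen <- colMeans(as.matrix(lig$atoms[, c("x", "y", "z")]))
  for (k in a$site$keys)
    expect_lte(sqrt(sum((atom_coord(s, k, "CA") - cen)^2)), 8)

  expect_error(synthetic_spec(n_res = 20, catalytic = c(10, 25)),
               class = "catgeo_generation_error")
  expect_error(synthetic_spec(catalytic = 5), class = "catgeo_argument_error")
})

test_that("noise-free homologs deviate by exactly zero despite rigid motion", {
  spec <- synthetic_spec(n_res = 30, catalytic = c(5, 15, 25),
                         sigma_cat = 0, sigma_global = 0, seed = 2)
  toy <- make_toy_enzyme(spec)
  hom <- perturb_homolog(toy$structure, spec, 3)
  # the homolog really is rigidly moved
  expect_gt(sum(abs(hom$structure$atoms$x - toy$structure$atoms$x)), 1)
  recs <- deviation_records(toy$structure, toy$site, hom$structure,
                            residue_correspondence(hom$alignment))
  expect_equal(recs$delta, rep(0, nrow(recs)), tolerance = 1e-9)
})

test_that("realized homolog identity tracks the requested range", {
  spec <- synthetic_spec(n_res = 100, catalytic = c(20, 50, 80),
                         pid_range = c(0.5, 0.5), seed = 3)
  toy <- make_toy_enzyme(spec)
  for (k in 1:5) {
    hom <- perturb_homolog(toy$structure, spec, k)
    expect_lt(abs(hom$pid - 50), 2)  # within 2 percentage points
    # catalytic residues are never mutated
    tr <- strsplit(hom$alignment$target_row, "")[[1]]
    qr <- strsplit(hom$alignment$template_row, "")[[1]]
    expect_identical(tr[spec$catalytic], qr[spec$catalytic])
  }
  # determinism per (seed, k); different k differ
  h1 <- perturb_homolog(toy$structure, spec, 1)
  h1b <- perturb_homolog(toy$structure, spec, 1)
  expect_identical(h1$structure$atoms, h1b$structure$atoms)
  h2 <- perturb_homolog(toy$structure, spec, 2)
  expect_false(identical(h1$structure$atoms, h2$structure$atoms))
})

test_that("generated fixtures survive the PDB round trip", {
  spec <- synthetic_spec(n_res = 25, catalytic = c(6, 12, 20), seed = 4)
  toy <- make_toy_enzyme(spec)
  hom <- perturb_homolog(toy$structure, spec, 1)
  f <- tempfile(fileext = ".pdb")
  write_structure(hom$structure, f)
  back <- read_structure(f)
  expect_identical(residue_names(back), residue_names(hom$structure))
  expect_equal(back$atoms$x, hom$structure$atoms$x, tolerance = 1e-3)
})

test_that("score-table generator honors dimensions, determinism and planting", {
  tab <- make_score_table(seed = 1)
  expect_identical(dim(tab), c(500L, 9L))
  expect_identical(tab, make_score_table(seed = 1))
  expect_false(identical(tab$total_score, make_score_table(seed = 2)$total_score))
  planted <- make_score_table(planted = list(n_violations = 20), seed = 1)
  expect_identical(sum(planted$mech_cst_1 > 1), 10L)  # capped at stage-1 pool size
  planted5 <- make_score_table(planted = list(n_violations = 5), seed = 1)
  expect_identical(sum(planted5$mech_cst_1 > 1), 5L)
})

test_that("generator parameter recovery: catalytic sigma is identifiable", {
  # the pooled deviation sd must recover sigma_cat * sqrt(2) independently of
  # the (much larger) global noise
  spec <- synthetic_spec(n_res = 30, catalytic = c(5, 15, 25),
                         sigma_cat = 0.25, sigma_global = 1.5, seed = 6)
  toy <- make_toy_enzyme(spec)
  recs <- do.call(rbind, lapply(1:150, function(k) {
    hom <- perturb_homolog(toy$structure, spec, k)
    deviation_records(toy$structure, toy$site, hom$structure,
                      residue_correspondence(hom$alignment))
  }))
  expect_equal(summarize_deviations(recs)$sd, 0.25 * sqrt(2),
               tolerance = 0.07)
})
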