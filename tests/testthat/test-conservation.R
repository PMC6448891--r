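test_that("atom-pair enumeration counts 4 pairs per residue pair, minus missing CBs", {
  toy <- toy_fixture(n_res = 30, catalytic = c(5, 15, 25), seed = 1)
  pairs <- enumerate_pairs(toy$site, toy$structure)
  expect_identical(nrow(pairs), 12L)  # 3 residue pairs x 4 atom pairs

  gly <- toy_fixture(n_res = 30, catalytic = c(5, 15, 25), glycine = 15,
                     seed = 1)
  expect_message(p2 <- enumerate_pairs(gly$site, gly$structure), "missing CB")
  expect_identical(nrow(p2), 8L)  # 4 pairs involving the absent CB dropped

  # brute-force count check across site sizes, 4*C(k,2) - 2*(k-1) per CB-less residue
  for (k in 2:6) {
    cat_idx <- seq(5, by = 6, length.out = k)
    tk <- toy_fixture(n_res = 40, catalytic = cat_idx, seed = k)
    expect_identical(nrow(enumerate_pairs(tk$site, tk$structure)),
                     as.integer(4 * choose(k, 2)))
    tg <- toy_fixture(n_res = 40, catalytic = cat_idx, glycine = cat_idx[1],
                      seed = k)
    suppressMessages(
      expect_identical(nrow(enumerate_pairs(tg$site, tg$structure)),
                       as.integer(4 * choose(k, 2) - 2 * (k - 1))))
  }
})

test_that("deviations are zero for self-comparison and track planted shifts", {
  toy <- toy_fixture(n_res = 30, catalytic = c(5, 15, 25), seed = 4)
  s <- toy$structure
  map <- identity_map(30)
  self <- deviation_records(s, toy$site, s, map, pid = 100)
  expect_true(all(self$delta == 0))
  expect_true(all(self$d > 0))

  # move one catalytic residue on the "template" so the CB(5)-CB(15) distance
  # grows by exactly 0.2 A: delta = d - d' = -0.2 for that record
  tmpl <- s
  a <- atom_coord(s, "A:5", "CB")
  b <- atom_coord(s, "A:15", "CB")
  u <- (b - a) / sqrt(sum((b - a)^2))
  sel <- tmpl$atoms$resno == 15 & tmpl$atoms$atom == "CB"
  tmpl$atoms[sel, c("x", "y", "z")] <- tmpl$atoms[sel, c("x", "y", "z")] +
    as.list(0.2 * u)
  recs <- deviation_records(s, toy$site, tmpl, map, pid = 100)
  hit <- recs$res_a == "A:5" & recs$res_b == "A:15" &
    recs$atom_a == "CB" & recs$atom_b == "CB"
  expect_equal(recs$delta[hit], -0.2, tolerance = 1e-9)
  untouched <- recs$res_a == "A:5" & recs$res_b == "A:25"
  expect_true(all(abs(recs$delta[untouched]) < 1e-9))
})

test_that("deviation records are antisymmetric and rigid-motion invariant", {
  spec <- synthetic_spec(n_res = 30, catalytic = c(5, 15, 25), seed = 6)
  toy <- make_toy_enzyme(spec)
  hom <- perturb_homolog(toy$structure, spec, 1)
  map <- residue_correspondence(hom$alignment)
  fwd <- deviation_records(toy$structure, toy$site, hom$structure, map)

  # swapped roles negate every delta
  site_rev <- catalytic_site(hom$structure, spec$catalytic)
  rev_map <- data.frame(target_pos = map$template_pos,
                        template_pos = map$target_pos)
  bwd <- deviation_records(hom$structure, site_rev, toy$structure, rev_map)
  expect_equal(bwd$delta, -fwd$delta, tolerance = 1e-10)
  expect_equal(bwd$d, fwd$d_prime, tolerance = 1e-10)

  # distances need no superposition: rigid motion of either side is invisible
  set.seed(99)
  moved <- transform_structure(hom$structure, random_rigid())
  fwd2 <- deviation_records(toy$structure, toy$site, moved, map)
  expect_equal(fwd2$delta, fwd$delta, tolerance = 1e-8)
})

test_that("deviation summaries report sample statistics and histograms", {
  toy <- toy_fixture(n_res = 30, catalytic = c(5, 15, 25), seed = 4)
  map <- identity_map(30)
  self <- deviation_records(toy$structure, toy$site, toy$structure, map)
  sm <- summarize_deviations(self)
  expect_equal(sm$mean, 0)
  expect_equal(sm$sd, 0)
  expect_identical(sm$n, sum(sm$counts))
  expect_error(summarize_deviations(self[0, ]), class = "catgeo_empty_error")
  # per-target stratification
  by_t <- summarize_deviations(self, by = "target")
  expect_named(by_t, toy$structure$id)
})

test_that("recovered deviation sd matches a Monte-Carlo oracle within 5%", {
  spec <- synthetic_spec(n_res = 40, catalytic = c(10, 20, 30),
                         sigma_cat = 0.29, sigma_global = 0.8, seed = 8)
  toy <- make_toy_enzyme(spec)
  recs <- do.call(rbind, lapply(1:200, function(k) {
    hom <- perturb_homolog(toy$structure, spec, k)
    deviation_records(toy$structure, toy$site, hom$structure,
                      residue_correspondence(hom$alignment), pid = hom$pid)
  }))
  observed_sd <- summarize_deviations(recs)$sd

  # oracle: direct simulation of |x + e1 - (y + e2)| distance differences
  # for each reference pair geometry, 1e4 draws each
  self <- deviation_records(toy$structure, toy$site, toy$structure,
                            identity_map(40))
  set.seed(123)
  oracle <- unlist(lapply(self$d, function(d) {
    e <- matrix(rnorm(6 * 1e4, sd = spec$sigma_cat), ncol = 6)
    dp <- sqrt((d + e[, 1] - e[, 4])^2 + (e[, 2] - e[, 5])^2 +
                 (e[, 3] - e[, 6])^2)
    d - dp
  }))
  expect_equal(observed_sd, sd(oracle), tolerance = 0.05)
})
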