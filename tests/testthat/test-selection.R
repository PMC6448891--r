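test_that("default cascade on a clean 5x100 table keeps 50 then 25 models", {
  tab <- make_score_table(seed = 42)  # no planted violations
  expect_identical(nrow(tab), 500L)
  expect_identical(as.integer(table(tab$group)), rep(100L, 5))
  res <- apply_filter_cascade(tab, filter_config())
  expect_identical(unname(res$trace),
                   c(500L, 50L, 50L, 25L, 25L))
  expect_true(all(diff(res$table$interface_score) >= 0))
  # trace counts never increase along the cascade
  expect_true(all(diff(res$trace) <= 0))
})

test_that("mechanism filter removes planted violators; saturation empties the pool", {
  tab <- make_score_table(planted = list(n_violations = 7), seed = 7)
  res <- apply_filter_cascade(tab, filter_config())
  expect_identical(unname(res$trace[["after_pool"]] -
                            res$trace[["after_mechanism"]]), 7L)

  # every row violating: empty result, non-empty trace (no mechanism-
  # consistent model exists for such a target)
  tab$mech_cst_2 <- 2.0
  res2 <- apply_filter_cascade(tab, filter_config())
  expect_identical(nrow(res2$table), 0L)
  expect_identical(unname(res2$trace[["after_mechanism"]]), 0L)
  expect_identical(select_final(res2$table, filter_config()), character(0))
})

test_that("cascade handles single rows, missing columns, empty input", {
  tab <- make_score_table(n_groups = 1, n_per_group = 1, seed = 1)
  res <- apply_filter_cascade(tab, filter_config())
  expect_identical(nrow(res$table), 1L)
  expect_error(apply_filter_cascade(tab[0, ], filter_config()),
               class = "catgeo_empty_error")
  bad <- tab; bad$total_score <- NULL
  expect_error(apply_filter_cascade(bad, filter_config()),
               class = "catgeo_schema_error")
  nop <- tab[, !grepl("^mech_cst", names(tab))]
  expect_error(apply_filter_cascade(nop, filter_config()),
               class = "catgeo_schema_error")
  # explicit opt-out of mechanism filtering is allowed
  ok <- apply_filter_cascade(nop, filter_config(mechanism_threshold = Inf))
  expect_identical(nrow(ok$table), 1L)
})

test_that("cascade output is invariant to input row order and matches brute force", {
  cfg <- filter_config()
  for (seed in c(3, 14, 15)) {
    n_per <- sample(c(40, 100, 200), 1)
    tab <- make_score_table(n_per_group = n_per,
                            planted = list(n_violations = 3), seed = seed)
    res1 <- apply_filter_cascade(tab, cfg)
    shuffled <- tab[sample(nrow(tab)), ]
    res2 <- apply_filter_cascade(shuffled, cfg)
    expect_identical(res1$table$description, res2$table$description)
    expect_identical(res1$trace, res2$trace)
    # independent O(N^2) selector
    brute <- brute_force_cascade(tab, cfg)
    expect_identical(res1$table$description, brute$description)
    # final pool bound from the stated default fractions
    expect_lte(res1$trace[["final"]],
               ceiling(0.5 * ceiling(0.1 * nrow(tab))))
  }
})

test_that("final selection picks lowest interface or best-of-n lowest RMSD", {
  tab <- data.frame(description = sprintf("m%02d", 1:10),
                    group = "g1",
                    total_score = -(10:1),
                    mech_cst_1 = 0,
                    active_site_energy = -(10:1),
                    interface_score = seq(-20, -11),
                    ligand_rmsd = c(2, 3, 4, 0.3, 5, 0.1, 6, 7, 8, 9))
  cfg_i <- filter_config(final_mode = "lowest_interface")
  expect_identical(select_final(tab, cfg_i), "m01")
  # planted minimum at interface rank 4 within the best-of-5 window
  cfg_r <- filter_config(final_mode = "lowest_rmsd", final_n = 5)
  expect_identical(select_final(tab, cfg_r), "m04")
  # final_n = 1 degenerates to lowest interface
  cfg_1 <- filter_config(final_mode = "lowest_rmsd", final_n = 1)
  expect_identical(select_final(tab, cfg_1), "m01")
  # rmsd mode without the column is a schema error
  norm <- tab; norm$ligand_rmsd <- NULL
  expect_error(select_final(norm, cfg_r), class = "catgeo_schema_error")
})

test_that("scorefile writer/reader round-trips tables through the SCORE: dialect", {
  tab <- make_score_table(n_groups = 2, n_per_group = 10, seed = 5)
  f <- tempfile(fileext = ".sc")
  write_scorefile(tab, f)
  expect_true(all(grepl("^SCORE:", readLines(f))))
  back <- read_scorefile(f)
  expect_identical(names(back), names(tab))
  expect_identical(back$description, tab$description)
  expect_equal(back$total_score, tab$total_score, tolerance = 1e-3)
  expect_error(read_scorefile(tempfile()), class = "catgeo_io_error")
})
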