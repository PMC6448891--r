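#' Filter-cascade configuration
#'
#' Parameters of the four-stage selection over docked-model score tables:
#' (1) per starting model, keep the lowest `pool_fraction` by total score and
#' pool; (2) drop models whose largest single mechanism-constraint penalty
#' exceeds `mechanism_threshold` (in Rosetta Energy Units) -- such a model is
#' inconsistent with the reaction chemistry; (3) keep the lowest
#' `active_site_fraction` by active-site energy; (4) sort by ligand interface
#' score. Final selection takes either the single lowest-interface model or
#' the lowest-RMSD model among the `final_n` lowest-interface ones.
#'
#' Column names follow the synthetic scorefile dialect by default and are
#' configurable for other runs; `penalty_pattern` is a regular expression
#' matching the per-constraint penalty columns.
#'
#' @param pool_fraction Fraction kept per group at stage 1 (default 0.10).
#' @param mechanism_threshold Max tolerated single-constraint penalty, REU
#'   (default 1.0). Set to `Inf` to disable mechanism filtering.
#' @param active_site_fraction Fraction kept at stage 3 (default 0.50).
#' @param final_n Pool size for final selection (default 5).
#' @param final_mode "lowest_interface" or "lowest_rmsd".
#' @param total_col,active_site_col,interface_col,rmsd_col,group_col,id_col
#'   Column names in the score table.
#' @param penalty_pattern Regex for mechanism-constraint penalty columns.
#' @return A `cg_filter_config`.
#' @export
filter_config <- function(pool_fraction = 0.10, mechanism_threshold = 1.0,
                          active_site_fraction = 0.50, final_n = 5,
                          final_mode = c("lowest_interface", "lowest_rmsd"),
                          total_col = "total_score",
                          active_site_col = "active_site_energy",
                          interface_col = "interface_score",
                          rmsd_col = "ligand_rmsd",
                          group_col = "group",
                          id_col = "description",
                          penalty_pattern = "^mech_cst") {
  for (f in c(pool_fraction, active_site_fraction))
    if (!(f > 0 && f <= 1))
      cg_stop("fractions must be in (0, 1]", "catgeo_argument_error")
  if (final_n < 1) cg_stop("final_n must be >= 1", "catgeo_argument_error")
  structure(list(pool_fraction = pool_fraction,
                 mechanism_threshold = mechanism_threshold,
                 active_site_fraction = active_site_fraction,
                 final_n = final_n, final_mode = match.arg(final_mode),
                 total_col = total_col, active_site_col = active_site_col,
                 interface_col = interface_col, rmsd_col = rmsd_col,
                 group_col = group_col, id_col = id_col,
                 penalty_pattern = penalty_pattern),
            class = "cg_filter_config")
}

require_cols <- function(table, cols) {
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0L)
    cg_stop(sprintf("score table lacks required column(s): %s",
                    paste(miss, collapse = ", ")), "catgeo_schema_error")
}

#' Apply the four-stage filter cascade to a score table
#'
#' @param table data.frame of per-model scores (one row per docked model).
#' @param cfg A [filter_config()].
#' @return List with `table` (surviving rows, sorted ascending by interface
#'   score, ties by model id) and `trace` (named counts: input, after_pool,
#'   after_mechanism, after_active_site, final).
#' @export
apply_filter_cascade <- function(table, cfg = filter_config()) {
  if (nrow(table) == 0L)
    cg_stop("empty score table", "catgeo_empty_error")
  require_cols(table, c(cfg$total_col, cfg$active_site_col, cfg$interface_col,
                        cfg$group_col, cfg$id_col))
  pen_cols <- grep(cfg$penalty_pattern, names(table), value = TRUE)
  if (length(pen_cols) == 0L && is.finite(cfg$mechanism_threshold))
    cg_stop(sprintf("no mechanism-penalty columns match '%s' (set mechanism_threshold = Inf to disable)",
                    cfg$penalty_pattern), "catgeo_schema_error")
  # canonical internal order so results do not depend on input row order
  table <- table[order(table[[cfg$id_col]]), , drop = FALSE]
  n_input <- nrow(table)

  # stage 1: lowest pool_fraction by total score, per starting-model group
  pool <- do.call(rbind, lapply(
    split(table, table[[cfg$group_col]]), function(g) {
      keep_n <- ceiling(cfg$pool_fraction * nrow(g))
      g[order(g[[cfg$total_col]], g[[cfg$id_col]])[seq_len(keep_n)], ,
        drop = FALSE]
    }))
  n_pool <- nrow(pool)

  # stage 2: mechanism consistency -- max single constraint penalty
  if (length(pen_cols) > 0L && is.finite(cfg$mechanism_threshold)) {
    maxpen <- do.call(pmax, c(pool[pen_cols], na.rm = TRUE))
    pool <- pool[maxpen <= cfg$mechanism_threshold, , drop = FALSE]
  }
  n_mech <- nrow(pool)

  # stage 3: lowest active_site_fraction by active-site energy
  if (n_mech > 0L) {
    keep_n <- ceiling(cfg$active_site_fraction * n_mech)
    pool <- pool[order(pool[[cfg$active_site_col]],
                       pool[[cfg$id_col]])[seq_len(keep_n)], , drop = FALSE]
  }
  n_as <- nrow(pool)

  # stage 4: sort by ligand interface score
  pool <- pool[order(pool[[cfg$interface_col]], pool[[cfg$id_col]]), ,
               drop = FALSE]
  rownames(pool) <- NULL
  trace <- c(input = n_input, after_pool = n_pool, after_mechanism = n_mech,
             after_active_site = n_as, final = nrow(pool))
  list(table = pool, trace = trace)
}

#' Final model selection from a filtered, interface-sorted table
#'
#' @param table Score table sorted ascending by interface score (the `table`
#'   element returned by [apply_filter_cascade()]).
#' @param cfg A [filter_config()]; `final_mode` decides between the single
#'   lowest-interface model and the lowest-ligand-RMSD model among the
#'   `final_n` lowest-interface ones.
#' @return The selected model id (character scalar), or `character(0)` for an
#'   empty table.
#' @export
select_final <- function(table, cfg = filter_config()) {
  if (nrow(table) == 0L) return(character(0))
  if (cfg$final_mode == "lowest_interface" || cfg$final_n == 1L)
    return(as.character(table[[cfg$id_col]][1L]))
  require_cols(table, cfg$rmsd_col)
  head_n <- utils::head(table, cfg$final_n)
  pick <- order(head_n[[cfg$rmsd_col]], head_n[[cfg$id_col]])[1L]
  as.character(head_n[[cfg$id_col]][pick])
}

#' Read a Rosetta-style scorefile
#'
#' Whitespace-delimited rows tagged "SCORE:", the first such row being the
#' header. Columns are converted to numeric where possible.
#'
#' @param path One or more scorefile paths (rows are concatenated; the
#'   provenance attribute records the sources).
#' @return data.frame of scores.
#' @export
read_scorefile <- function(path) {
  read_one <- function(p) {
    if (!file.exists(p))
      cg_stop(sprintf("cannot read '%s': no such file", p), "catgeo_io_error")
    lines <- readLines(p, warn = FALSE)
    lines <- lines[grepl("^SCORE:", lines)]
    if (length(lines) < 2L)
      cg_stop(sprintf("'%s' has no SCORE: header + data rows", p),
              "catgeo_format_error")
    tok <- lapply(lines, function(l) strsplit(trimws(sub("^SCORE:", "", l)),
                                              "\\s+")[[1L]])
    header <- tok[[1L]]
    body <- tok[-1L]
    bad <- vapply(body, length, integer(1)) != length(header)
    if (any(bad))
      cg_stop(sprintf("'%s': %d row(s) do not match the header width",
                      p, sum(bad)), "catgeo_format_error")
    df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
    names(df) <- header
    for (j in seq_along(df)) {
      v <- suppressWarnings(as.numeric(df[[j]]))
      if (!anyNA(v)) df[[j]] <- v
    }
    df
  }
  out <- do.call(rbind, lapply(path, read_one))
  attr(out, "provenance") <- path
  out
}

#' Write a score table in Rosetta scorefile dialect
#'
#' @param table data.frame of scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorefile <- function(table, path) {
  fmt_cell <- function(x) if (is.numeric(x)) sprintf("%.3f", x) else as.character(x)
  cells <- vapply(table, fmt_cell, character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste("SCORE:", paste(names(table), collapse = " ")),
             paste("SCORE:", apply(cells, 1L, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
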