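#' Catalytic site of a target structure
#'
#' The ordered set of catalytic residues (author numbering) whose mutual
#' Calpha/Cbeta geometry is conserved within the enzyme family.
#'
#' @param target A `cg_structure`.
#' @param resno Integer vector of author residue numbers (>= 2 residues).
#' @param chain Chain id; defaults to the structure's polymer chain.
#' @return A `cg_site`: list with `target_id`, `keys`, `resno`.
#' @export
catalytic_site <- function(target, resno, chain = NULL) {
  if (length(resno) < 2L)
    cg_stop("a catalytic site needs at least 2 residues",
            "catgeo_argument_error")
  chain <- chain %||% target$atoms$chain[1L]
  keys <- make_res_key(chain, as.integer(resno))
  missing <- setdiff(keys, residue_keys(target))
  if (length(missing) > 0L)
    cg_stop(sprintf("catalytic residue(s) not in structure '%s': %s",
                    target$id, paste(missing, collapse = ", ")),
            "catgeo_key_error")
  structure(list(target_id = target$id, keys = keys,
                 resno = as.integer(resno)),
            class = "cg_site")
}

#' @export
print.cg_site <- function(x, ...) {
  cat(sprintf("<cg_site '%s': residues %s>\n", x$target_id,
              paste(x$resno, collapse = ",")))
  invisible(x)
}

#' Enumerate catalytic Calpha/Cbeta atom pairs
#'
#' For every unordered pair of catalytic residues, the four cross-residue atom
#' pairs CA-CA, CA-CB, CB-CA and CB-CB are emitted (CA-CB and CB-CA are
#' distinct measurements). Pairs referencing a CB the target does not have
#' (glycine) are omitted with a message.
#'
#' @param site A `cg_site`.
#' @param target The `cg_structure` the site belongs to.
#' @return data.frame with columns `res_a`, `res_b` (residue keys,
#'   res_a before res_b in site order), `atom_a`, `atom_b`, in deterministic
#'   canonical order.
#' @export
enumerate_pairs <- function(site, target) {
  keys <- site$keys
  missing <- setdiff(keys, residue_keys(target))
  if (length(missing) > 0L)
    cg_stop(sprintf("site residue(s) absent from structure: %s",
                    paste(missing, collapse = ", ")), "catgeo_key_error")
  # site order follows ascending author number
  ord <- order(site$resno)
  keys <- keys[ord]
  k <- length(keys)
  rows <- list()
  atoms <- c("CA", "CB")
  n_dropped <- 0L
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    for (aa in atoms) for (ab in atoms) {
      if ((aa == "CB" && !has_atom(target, keys[i], "CB")) ||
          (ab == "CB" && !has_atom(target, keys[j], "CB"))) {
        n_dropped <- n_dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        res_a = keys[i], res_b = keys[j], atom_a = aa, atom_b = ab)
    }
  }
  if (n_dropped > 0L)
    message(sprintf("enumerate_pairs: dropped %d pair(s) involving a missing CB",
                    n_dropped))
  if (length(rows) == 0L)
    return(data.frame(res_a = character(), res_b = character(),
                      atom_a = character(), atom_b = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distance deviations between a target and one template
#'
#' For every catalytic atom pair, measures the target distance d, the distance
#' d' between the alignment-equivalent atoms on the template, and the
#' deviation delta = d - d'. Distances are Euclidean in each structure's own
#' frame, so no superposition is involved and the records are invariant under
#' rigid motion of either structure.
#'
#' @param target `cg_structure` with the catalytic site.
#' @param site A `cg_site` on `target`.
#' @param template Homolog `cg_structure`.
#' @param map Residue correspondence target -> template
#'   (see [residue_correspondence()]).
#' @param pid Percent identity of the template to the target (carried on each
#'   record so deviations can be stratified by homology).
#' @return A `cg_deviations` data.frame: target, template, pid, res_a, atom_a,
#'   res_b, atom_b, d, d_prime, delta. Pairs whose template atoms are missing
#'   are skipped with a message.
#' @export
deviation_records <- function(target, site, template, map, pid = NA_real_) {
  pairs <- enumerate_pairs(site, target)
  tkeys <- residue_keys(target)
  qkeys <- residue_keys(template)
  site_pos <- match(site$keys, tkeys)
  mapped <- match(site_pos, map$target_pos)
  if (anyNA(mapped))
    cg_stop(sprintf("catalytic residue(s) not covered by the alignment: %s",
                    paste(site$keys[is.na(mapped)], collapse = ", ")),
            "catgeo_coverage_error")
  tmpl_key_of <- stats::setNames(qkeys[map$template_pos[mapped]], site$keys)

  n <- nrow(pairs)
  keep <- logical(n)
  d <- d_prime <- numeric(n)
  n_skipped <- 0L
  for (i in seq_len(n)) {
    ta <- atom_coord(target, pairs$res_a[i], pairs$atom_a[i])
    tb <- atom_coord(target, pairs$res_b[i], pairs$atom_b[i])
    qa_key <- tmpl_key_of[[pairs$res_a[i]]]
    qb_key <- tmpl_key_of[[pairs$res_b[i]]]
    if (!has_atom(template, qa_key, pairs$atom_a[i]) ||
        !has_atom(template, qb_key, pairs$atom_b[i])) {
      n_skipped <- n_skipped + 1L
      next
    }
    qa <- atom_coord(template, qa_key, pairs$atom_a[i])
    qb <- atom_coord(template, qb_key, pairs$atom_b[i])
    d[i] <- vec3_norm(ta - tb)
    d_prime[i] <- vec3_norm(qa - qb)
    keep[i] <- TRUE
  }
  if (n_skipped > 0L)
    message(sprintf("deviation_records: skipped %d pair(s) missing atoms on template '%s'",
                    n_skipped, template$id))
  out <- data.frame(target = target$id, template = template$id, pid = pid,
                    pairs[keep, , drop = FALSE],
                    d = d[keep], d_prime = d_prime[keep],
                    delta = d[keep] - d_prime[keep])
  rownames(out) <- NULL
  class(out) <- c("cg_deviations", "data.frame")
  out
}

#' Summarize a pool of distance deviations
#'
#' Sample mean and standard deviation (n-1 denominator) of delta = d - d',
#' with a fixed-width histogram, optionally restricted to one atom-pair class
#' and optionally per target before pooling.
#'
#' @param records A `cg_deviations` data.frame (rows from one or many
#'   target/template couples may be concatenated with `rbind`).
#' @param atom_class "all" (default), "CA-CA", "CB-CB" or "CA-CB" (the mixed
#'   class, covering both orientations).
#' @param bin_width Histogram bin width in Angstrom (default 0.1).
#' @param by "pool" (default) for one pooled summary, or "target" for a named
#'   list of per-target summaries.
#' @return A `cg_deviation_summary`: list with `n`, `mean`, `sd`, `breaks`,
#'   `counts`, `atom_class` (or a named list of them when `by = "target"`).
#' @export
summarize_deviations <- function(records,
                                 atom_class = c("all", "CA-CA", "CB-CB", "CA-CB"),
                                 bin_width = 0.1, by = c("pool", "target")) {
  atom_class <- match.arg(atom_class)
  by <- match.arg(by)
  cls <- pair_class(records$atom_a, records$atom_b)
  keep <- if (atom_class == "all") rep(TRUE, nrow(records)) else cls == atom_class
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L)
    cg_stop(sprintf("no deviation records in class '%s'", atom_class),
            "catgeo_empty_error")
  if (by == "target")
    return(lapply(split(records, records$target), summarize_deviations,
                  atom_class = "all", bin_width = bin_width))
  delta <- records$delta
  lo <- floor(min(delta) / bin_width) * bin_width
  hi <- ceiling(max(delta) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(delta, breaks = breaks, plot = FALSE)
  structure(list(n = length(delta), mean = mean(delta),
                 sd = if (length(delta) > 1L) stats::sd(delta) else 0,
                 breaks = h$breaks, counts = h$counts,
                 atom_class = atom_class),
            class = "cg_deviation_summary")
}

pair_class <- function(atom_a, atom_b) {
  ifelse(atom_a == atom_b,
         paste(atom_a, atom_b, sep = "-"),
         "CA-CB")
}

#' @export
print.cg_deviation_summary <- function(x, ...) {
  cat(sprintf("<cg_deviation_summary [%s]: n = %d, mean = %.3f A, sd = %.3f A>\n",
              x$atom_class, x$n, x$mean, x$sd))
  invisible(x)
}

#' @method plot cg_deviation_summary
#' @export
plot.cg_deviation_summary <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$counts, names.arg = sprintf("%.1f", mids),
                    xlab = expression(Delta ~ "(A)"), ylab = "count",
                    main = sprintf("distance deviations (%s)", x$atom_class),
                    ...)
  invisible(x)
}
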