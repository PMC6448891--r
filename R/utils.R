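# Internal helpers: classed conditions and scoped RNG.

cg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "catgeo_error"), call = call))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    cg_stop("seed must be a single finite number", "catgeo_argument_error")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Residue keys are "chain:resno" with an optional insertion-code suffix,
# e.g. "A:73" or "A:100A".
make_res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  chain <- ifelse(is.na(chain) | chain == " ", "_", chain)
  paste0(chain, ":", resno, icode)
}

vec3_norm <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- vec3_norm(v)
  if (n < 1e-12) cg_stop("cannot normalize zero vector", "catgeo_argument_error")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
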