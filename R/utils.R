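# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All randomness in the package flows through explicit seeds so that a run
#' is reproducible from a single integer; the global RNG stream of the caller
#' is never perturbed.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Derive a named substream seed from a master seed; kept below 2^31.
substream_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483629L
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("invalid CohortSpec: '%s' must be a positive integer count", name),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Alignment of sample rosters across matrices/tables is by identifier, never
# by position. Returns the common ordered roster (order of `ref`), erroring
# with the symmetric difference when rosters disagree.
align_roster <- function(ref, other, what = "matrix") {
  missing_in_other <- setdiff(ref, other)
  extra_in_other <- setdiff(other, ref)
  if (length(missing_in_other) || length(extra_in_other)) {
    stop(sprintf(
      "sample roster mismatch for %s: missing [%s]; unexpected [%s]",
      what,
      paste(missing_in_other, collapse = ", "),
      paste(extra_in_other, collapse = ", ")
    ), call. = FALSE)
  }
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a
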