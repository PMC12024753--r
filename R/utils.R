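# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's `.Random.seed`, so
#' seeded package functions never perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Population (1/n) standard deviation
#' @noRd
sd_pop <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

stop_input <- function(...) stop(..., call. = FALSE)

#' Check that a matrix has unique, non-missing dimnames
#' @noRd
check_ids <- function(ids, what) {
  if (is.null(ids)) stop_input("missing ", what, " identifiers")
  if (anyNA(ids) || any(!nzchar(ids)))
    stop_input("missing or empty ", what, " identifiers")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_input("duplicate ", what, " identifiers: ",
               paste(utils::head(dup, 5L), collapse = ", "))
  }
  invisible(ids)
}

# Derive a stream-specific child seed from a base seed, kept inside the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(offset) %% 2011L
}
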