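#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

abort_config <- function(msg) stop(errorCondition(msg, class = c("acylomics_invalid_config", "error")))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort_config(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x) && x >= 1

#' Derive a per-stage child seed from a global seed
#'
#' Every stochastic stage draws its RNG seed from the global run seed and its
#' own stage name, so stages are independently reproducible: re-running one
#' stage with the same global seed gives identical output regardless of what
#' ran before it.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"null"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1, "null")
#' @export
derive_seed <- function(seed, stage) {
  assert_that(is_count(seed + 1), "seed must be a single integer")
  codes <- utf8ToInt(as.character(stage))
  h <- as.double(seed) %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Run a block with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
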