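#' Canonicalize species identifiers
#'
#' Species names arrive from flora lists, diet references and field logs with
#' inconsistent whitespace and capitalisation. All ingestion boundaries in the
#' package pass identifiers through this function: leading/trailing whitespace
#' is trimmed, internal runs of whitespace are collapsed to a single space,
#' and the result is case-folded to lower case.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of canonical identifiers, same length as `x`.
#' @examples
#' canonicalize_species(c("  Astrocaryum   aculeatissimum ", "STERCULIA chicha"))
#' @export
canonicalize_species <- function(x) {
  if (!is.character(x)) {
    stop("species identifiers must be character, got ", class(x)[1])
  }
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps package functions from clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based replicate seed: reproducible independently and in any order,
# always below 2^31.
derive_seed <- function(seed, counter) {
  as.integer((as.double(abs(seed)) * 1000003 + as.double(counter)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
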