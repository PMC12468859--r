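# Internal helpers shared across modules.

#' Coerce group labels to the NM/PC factor
#'
#' Labels must take values in \{"NM", "PC"\}; anything else is an error naming
#' the offending values. NM is the negative (healthy) class, PC the positive
#' (pancreatic cancer) class throughout the package.
#' @param labels character/factor vector of group labels.
#' @return factor with levels NM, PC.
#' @keywords internal
as_group <- function(labels) {
  x <- as.character(labels)
  bad <- setdiff(unique(x[!is.na(x)]), c("NM", "PC"))
  if (length(bad) > 0L) {
    stop("group labels must be 'NM' or 'PC'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = c("NM", "PC"))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# round-to-nearest with a deterministic half-up rule and a guard against
# floating-point representation of fractions like 0.7 * n
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

`%||%` <- function(a, b) if (is.null(a)) b else a

# safe ratio: 0/0 reported as NA, never 0
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
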