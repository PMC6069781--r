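# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_mora <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warn_mora <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Modal value of an integer vector; ties broken by the first element's value
# (callers warn where the tie-break matters biologically).
#' @noRd
modal_value <- function(x) {
  tab <- table(x)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1L) x[[1L]] else top
}

#' @noRd
is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x)

# Format a numeric for TSV output at 4 decimals, keeping NA as "NA".
#' @noRd
fmt4 <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
#' @noRd
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
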