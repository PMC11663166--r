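# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a temporary RNG seed
#'
#' Sets the seed if one is supplied, restoring the caller's RNG state on
#' exit so library code never perturbs the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage seed from a root seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

# Coerce labels to logical, failing loudly on anything ambiguous.
as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1, NA)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(labels == 1)
  }
  if (is.character(labels)) {
    up <- toupper(labels)
    if (all(up %in% c("TRUE", "FALSE", NA)))
      return(up == "TRUE")
  }
  stop("labels must be logical, 0/1, or TRUE/FALSE strings", call. = FALSE)
}

check_direction <- function(direction) {
  match.arg(direction, c("above", "below"))
}

fmt_mean_sd <- function(m, s, digits = 2) {
  sprintf(paste0("%.", digits, "f (± %.", digits, "f)"), m, s)
}
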