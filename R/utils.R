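#' @keywords internal
"_PACKAGE"

# internal helpers -------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop(what, " has (near-)zero length", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a finite numeric scalar", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  invisible(x)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic small-integer seed derived from components (kept < 2^31).
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) sum(utf8ToInt(paste(x, collapse = ""))) else as.numeric(x)
  }))
  s <- 104729
  for (p in parts) s <- (s * 69069 + p * 7919 + 1) %% 2147483563
  as.integer(s)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical/0-1 arrays of identical dimension.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
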