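#' Paired firefly/Renilla luminescence replicates
#'
#' Bundle paired luminescence measurements for one construct in one condition.
#' Each replicate i contributes a Renilla reading R_i (the co-transfected
#' internal control) and a firefly reading F_i (the experimental reporter),
#' both in relative luminescence units (RLU). Negative values are allowed:
#' background subtraction and simulated measurement noise can drive readings
#' below zero.
#'
#' @param renilla Numeric vector of Renilla luminescence values (RLU).
#' @param firefly Numeric vector of firefly luminescence values (RLU), same
#'   length as `renilla`.
#' @return An object of class `replicate_set`: a list with elements `renilla`,
#'   `firefly`, and `n` (the replicate count).
#' @examples
#' rs <- replicate_set(renilla = c(1, 2, 4), firefly = c(10, 20, 40))
#' rs$n
#' @export
replicate_set <- function(renilla, firefly) {
  if (!is.numeric(renilla) || !is.numeric(firefly)) {
    stop("'renilla' and 'firefly' must be numeric vectors", call. = FALSE)
  }
  renilla <- as.numeric(renilla)
  firefly <- as.numeric(firefly)
  if (length(renilla) != length(firefly)) {
    stop(sprintf("'renilla' (length %d) and 'firefly' (length %d) must have equal length",
                 length(renilla), length(firefly)), call. = FALSE)
  }
  if (length(renilla) < 1L) {
    stop("at least one replicate is required", call. = FALSE)
  }
  if (!all(is.finite(renilla)) || !all(is.finite(firefly))) {
    stop("luminescence values must be finite", call. = FALSE)
  }
  structure(
    list(renilla = renilla, firefly = firefly, n = length(renilla)),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %d replicate%s\n", x$n, if (x$n == 1L) "" else "s"))
  show_n <- min(x$n, 6L)
  df <- data.frame(Ren = x$renilla[seq_len(show_n)], Luc = x$firefly[seq_len(show_n)])
  print(df, row.names = FALSE)
  if (x$n > show_n) cat(sprintf("... and %d more\n", x$n - show_n))
  invisible(x)
}

as_replicate_set <- function(x) {
  if (inherits(x, "replicate_set")) return(x)
  stop("expected a 'replicate_set' object; see replicate_set()", call. = FALSE)
}
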