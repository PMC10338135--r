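#' Specify an (m,n)-mer feature family
#'
#' An (m,n)-mer conditions the frequency of an n-mer suffix on its
#' immediately preceding m-mer context. `mer_spec(0, k)` denotes the plain
#' (unconditional) k-mer. The derived quantities are `k = m + n`,
#' `M = 4^m` contexts, `N = 4^n` suffixes and `K = 4^(m+n)` features.
#'
#' @param m Context length, integer >= 0. `m = 0` selects plain k-mer mode.
#' @param n Suffix length, integer >= 1.
#' @param max_k Cap on `m + n` (memory grows as `4^(m+n)`; the default 12
#'   bounds a dense vector at ~16.8M entries).
#' @return An object of class `"mer_spec"`: a list with elements
#'   `m`, `n`, `k`, `M`, `N`, `K`.
#' @examples
#' mer_spec(1, 1)   # dinucleotide transition frequencies
#' mer_spec(0, 4)   # plain tetranucleotide frequencies
#' @export
mer_spec <- function(m, n, max_k = 12L) {
  stopifnot(length(m) == 1L, length(n) == 1L, is.numeric(m), is.numeric(n))
  m <- as.integer(m)
  n <- as.integer(n)
  if (is.na(m) || m < 0L) stop("'m' must be an integer >= 0", call. = FALSE)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  k <- m + n
  if (k > max_k) {
    stop(sprintf("m + n = %d exceeds the cap of %d (dense storage needs 4^(m+n) entries)",
                 k, max_k), call. = FALSE)
  }
  structure(
    list(m = m, n = n, k = k, M = as.integer(4^m), N = as.integer(4^n),
         K = as.integer(4^k)),
    class = "mer_spec"
  )
}

#' @export
print.mer_spec <- function(x, ...) {
  kind <- if (x$m == 0L) "plain k-mer" else "conditional"
  cat(sprintf("(%d,%d)-mer spec [%s]: k = %d, %d contexts x %d suffixes = %d features\n",
              x$m, x$n, kind, x$k, x$M, x$N, x$K))
  invisible(x)
}

#' @export
format.mer_spec <- function(x, ...) sprintf("(%d,%d)-mer", x$m, x$n)

is_mer_spec <- function(x) inherits(x, "mer_spec")

# Coerce a list(m, n) / c(m, n) shorthand to a mer_spec.
as_mer_spec <- function(x) {
  if (is_mer_spec(x)) return(x)
  if (is.numeric(x) && length(x) == 2L) return(mer_spec(x[1L], x[2L]))
  stop("expected a mer_spec or a length-2 numeric c(m, n)", call. = FALSE)
}
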