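#' Encode a mer as its base-4 integer code
#'
#' Every ACGT word of length k maps to a unique integer in `[0, 4^k)` under
#' the digit map A=0, C=1, G=2, T=3, with the leftmost base most
#' significant. The 6-mer ACCTGA, for example, has base-4 digits 011320 and
#' decimal code 376.
#'
#' @param mer A single ACGT string (case-insensitive).
#' @return The integer code of the mer.
#' @seealso [decode_mer()], [mer_digits()]
#' @examples
#' encode_mer("ACCTGA")  # 376
#' encode_mer("TTT")     # 63
#' @export
encode_mer <- function(mer) {
  digits <- mer_to_digit_vector(mer)
  k <- length(digits)
  code <- 0
  for (d in digits) code <- code * 4 + d
  as.integer(code)
}

#' Base-4 digit string of a mer
#'
#' The digits of the mer's base-4 code, leading zeros included, so that
#' `mer_digits("ACCTGA")` is `"011320"`.
#'
#' @inheritParams encode_mer
#' @return A string of digits 0-3, one per base.
#' @export
mer_digits <- function(mer) {
  paste(mer_to_digit_vector(mer), collapse = "")
}

# A=0, C=1, G=2, T=3; error names the first offending position.
mer_to_digit_vector <- function(mer) {
  stopifnot(is.character(mer), length(mer) == 1L)
  if (!nzchar(mer)) stop("mer must be non-empty", call. = FALSE)
  chars <- strsplit(toupper(mer), "", fixed = TRUE)[[1L]]
  digits <- match(chars, DNA_BASES) - 1L
  if (anyNA(digits)) {
    pos <- which(is.na(digits))[1L]
    stop(sprintf("illegal base '%s' at position %d (expected A, C, G or T)",
                 chars[pos], pos), call. = FALSE)
  }
  digits
}

#' Decode a base-4 integer code back to its mer
#'
#' Inverse of [encode_mer()]: left-pads with 'A' (digit 0) to length `k`.
#'
#' @param code Integer in `[0, 4^k)`.
#' @param k Mer length.
#' @return The ACGT string of length `k`.
#' @examples
#' decode_mer(376, 6)  # "ACCTGA"
#' @export
decode_mer <- function(code, k) {
  stopifnot(length(code) == 1L, length(k) == 1L, k >= 1)
  if (is.na(code) || code < 0 || code >= 4^k) {
    stop(sprintf("code %s out of range [0, 4^%d)", format(code), k), call. = FALSE)
  }
  digits <- integer(k)
  for (i in k:1) {
    digits[i] <- code %% 4
    code <- code %/% 4
  }
  paste(DNA_BASES[digits + 1L], collapse = "")
}

# All 4^k mers of length k in code order (lexicographic, since A<C<G<T
# matches digit order). all_mers(0) is "".
all_mers <- function(k) {
  mers <- ""
  for (i in seq_len(k)) {
    mers <- as.vector(t(outer(mers, DNA_BASES, paste0)))
  }
  mers
}

# Sequence string -> integer digit vector with NA at non-ACGT positions.
seq_to_digits <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  match(chars, DNA_BASES) - 1L
}

#' Count k-mer windows in a sequence
#'
#' Slides a width-k window with step 1 over the sequence. Every window made
#' solely of A/C/G/T increments the count of its code; any window containing
#' another character (N, gaps, ...) is skipped entirely and does not count
#' toward the total. A sequence shorter than k yields an empty table with
#' total 0.
#'
#' @param seq A nucleotide string (case-insensitive; non-ACGT characters
#'   allowed, their windows are skipped).
#' @param k Window width, integer >= 1.
#' @return An object of class `"count_table"`: list with `k`, `counts`
#'   (integer vector of length 4^k, named by mer) and `total` (number of
#'   valid windows).
#' @examples
#' ct <- count_kmers("ACCTGA", 2)
#' ct$total               # 5
#' ct$counts[["AC"]]      # 1
#' @export
count_kmers <- function(seq, k) {
  stopifnot(length(k) == 1L, k >= 1)
  k <- as.integer(k)
  if (k > 12L) stop("k > 12 unsupported (dense storage is 4^k entries)", call. = FALSE)
  nbins <- as.integer(4^k)
  digits <- seq_to_digits(seq)
  n_win <- length(digits) - k + 1L
  if (n_win < 1L) {
    counts <- integer(nbins)
  } else {
    # Horner accumulation over the k offsets; NA digits poison their windows.
    code <- numeric(n_win)
    for (j in 0:(k - 1L)) {
      code <- code * 4 + digits[(1L + j):(n_win + j)]
    }
    counts <- tabulate(code[!is.na(code)] + 1L, nbins = nbins)
  }
  names(counts) <- all_mers(k)
  structure(list(k = k, counts = counts, total = sum(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  nz <- x$counts[x$counts > 0L]
  cat(sprintf("k-mer count table: k = %d, %d valid windows, %d distinct mers\n",
              x$k, x$total, length(nz)))
  if (length(nz) > 0L && length(nz) <= 20L) print(nz)
  invisible(x)
}

#' Unconditional k-mer frequency vector
#'
#' Divides each count by the total number of valid windows; when the total
#' is zero the whole vector is zero. With at least one valid window the
#' entries sum to 1.
#'
#' @param counts A [count_kmers()] table.
#' @return A named numeric vector of length 4^k with attributes `spec`
#'   (the `(0,k)` [mer_spec()]) and `kind = "unconditional"`.
#' @export
kmer_frequencies <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  vals <- if (counts$total > 0L) counts$counts / counts$total else
    numeric(length(counts$counts))
  names(vals) <- names(counts$counts)
  structure(vals, spec = mer_spec(0L, counts$k), kind = "unconditional")
}

#' Context counts restricted to full-window start positions
#'
#' Counts the m-prefix of every valid (m+n)-window: an m-mer occurrence is
#' counted only where a full (m+n)-window of unambiguous bases begins. These
#' are the denominators that make the conditional (m,n)-mer rows exactly
#' stochastic (the trailing m-mers of the sequence, and m-mers whose
#' following suffix is ambiguous, are excluded). The table's total equals
#' the (m+n)-window total.
#'
#' @param seq A nucleotide string.
#' @param spec A [mer_spec()] with `m >= 1`.
#' @return A `"count_table"` of order m.
#' @export
context_counts <- function(seq, spec) {
  spec <- as_mer_spec(spec)
  if (spec$m < 1L) stop("context_counts requires m >= 1", call. = FALSE)
  joint <- count_kmers(seq, spec$k)
  # marginalize the joint over suffixes: context u = code %/% 4^n
  counts <- as.integer(rowSums(matrix(joint$counts, nrow = spec$M,
                                      ncol = spec$N, byrow = TRUE)))
  names(counts) <- all_mers(spec$m)
  structure(list(k = spec$m, counts = counts, total = joint$total),
            class = "count_table")
}

#' Conditional (m,n)-mer frequency vector
#'
#' Element (u, v) is the frequency of suffix v among the valid
#' (m+n)-windows whose context is u: the joint (m+n)-mer count at code
#' `4^n * u + v` divided by the context count of u. Rows of unobserved
#' contexts are all zero. The result is the row-major flattening of the
#' M x N conditional matrix; its entries sum to the number of observed
#' contexts (at most `4^m`), and each observed context's row sums to 1.
#' With `m = 0` the result equals the plain n-mer frequency vector.
#'
#' @param seq A nucleotide string.
#' @param spec A [mer_spec()]; `m = 0` is legal and selects plain k-mer mode.
#' @param context Denominator convention. `"window"` (default) restricts
#'   context counts to (m+n)-window start positions, making every observed
#'   row sum to exactly 1. `"sequence"` divides the joint (m+n)-mer
#'   frequency by the whole-sequence m-mer frequency instead; edge effects
#'   then break exact row-stochasticity (kept for parity experiments).
#' @return A named numeric vector of length 4^(m+n) with attributes `spec`
#'   and `kind = "conditional"`. Names are `"context|suffix"` for m >= 1.
#' @examples
#' v <- mn_frequencies("ACCTGA", mer_spec(1, 1))
#' v[["C|C"]]  # 0.5: C is followed by C in one of its two windows
#' sum(v)      # 4: all four contexts observed
#' @export
mn_frequencies <- function(seq, spec, context = c("window", "sequence")) {
  spec <- as_mer_spec(spec)
  context <- match.arg(context)
  if (spec$m == 0L) {
    vals <- as.numeric(kmer_frequencies(count_kmers(seq, spec$n)))
  } else {
    joint <- count_kmers(seq, spec$k)
    jmat <- matrix(joint$counts, nrow = spec$M, ncol = spec$N, byrow = TRUE)
    if (context == "window") {
      denom <- rowSums(jmat)                      # context counts, window-start restricted
      vals <- jmat / ifelse(denom > 0, denom, 1)  # zero rows stay zero
      vals[denom == 0, ] <- 0
    } else {
      jfreq <- if (joint$total > 0L) jmat / joint$total else jmat * 0
      ctx <- count_kmers(seq, spec$m)
      mfreq <- if (ctx$total > 0L) ctx$counts / ctx$total else ctx$counts * 0
      vals <- jfreq / ifelse(mfreq > 0, mfreq, 1)
      vals[mfreq == 0, ] <- 0
    }
    vals <- as.numeric(t(vals))  # row-major: index N*u + v
  }
  names(vals) <- feature_labels(spec)
  structure(vals, spec = spec, kind = "conditional")
}

#' Normalize a conditional vector to the k-mer range
#'
#' Divides every element of a conditional (m,n)-mer vector by `M = 4^m`.
#' The result sums to (observed contexts)/M, lies in `[0, 1]`, and has the
#' same length and range as the plain (m+n)-mer frequency vector — the
#' property that makes (m,n)-mer features a drop-in replacement.
#'
#' @param vec A conditional vector from [mn_frequencies()].
#' @return The normalized vector, `kind = "normalized_conditional"`.
#' @export
normalize_conditional <- function(vec) {
  kind <- attr(vec, "kind")
  spec <- attr(vec, "spec")
  if (is.null(kind) || kind != "conditional" || !is_mer_spec(spec)) {
    stop("expected a conditional feature vector from mn_frequencies()", call. = FALSE)
  }
  structure(as.numeric(vec) / spec$M,
            names = names(vec), spec = spec, kind = "normalized_conditional")
}

#' Feature labels of a mer spec, in code order
#'
#' Labels are `"context|suffix"` (e.g. `"A|C"`) for m >= 1 and the plain
#' mer string (e.g. `"AC"`) for m = 0. Label i corresponds to the decoded
#' (m+n)-mer of code i.
#'
#' @param spec A [mer_spec()].
#' @return Character vector of length 4^(m+n).
#' @export
feature_labels <- function(spec) {
  spec <- as_mer_spec(spec)
  if (spec$m == 0L) return(all_mers(spec$n))
  ctx <- all_mers(spec$m)
  suf <- all_mers(spec$n)
  paste(rep(ctx, each = spec$N), rep(suf, times = spec$M), sep = "|")
}

#' Concatenated feature vector over several mer specs
#'
#' Computes the per-spec feature vectors on one sequence and concatenates
#' them in the given order, the combined-feature construction used when a
#' single mer family is not enough. Conditional specs (m >= 1) are
#' normalized first so every entry lies in `[0, 1]`. With more than one
#' spec the labels get an `"m<m>n<n>."` prefix to stay unique.
#'
#' @param seq A nucleotide string.
#' @param specs A list of [mer_spec()]s (or length-2 `c(m, n)` shorthands);
#'   duplicates are rejected.
#' @inheritParams mn_frequencies
#' @return A named numeric vector of length `sum(4^(m_i + n_i))`.
#' @examples
#' length(concat_features("ACCTGA", list(mer_spec(0, 2), mer_spec(1, 1))))  # 32
#' @export
concat_features <- function(seq, specs, context = c("window", "sequence")) {
  context <- match.arg(context)
  if (is_mer_spec(specs)) specs <- list(specs)
  stopifnot(is.list(specs), length(specs) >= 1L)
  specs <- lapply(specs, as_mer_spec)
  keys <- vapply(specs, format, character(1L))
  if (anyDuplicated(keys)) {
    stop(sprintf("duplicate spec %s would create duplicate feature columns",
                 keys[duplicated(keys)][1L]), call. = FALSE)
  }
  parts <- lapply(specs, function(sp) {
    v <- mn_frequencies(seq, sp, context = context)
    if (sp$m >= 1L) v <- normalize_conditional(v)
    v
  })
  if (length(parts) == 1L) return(parts[[1L]])
  labs <- unlist(lapply(specs, function(sp)
    paste0("m", sp$m, "n", sp$n, ".", feature_labels(sp))), use.names = FALSE)
  structure(unlist(parts, use.names = FALSE), names = labs,
            kind = "composite", specs = specs)
}
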