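#' Fraction of ambiguous (non-ACGT) bases
#'
#' @param seq A non-empty nucleotide string (case-insensitive).
#' @return Fraction of characters outside {A, C, G, T}, in `[0, 1]`.
#' @export
ambiguous_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("cannot compute ambiguous fraction of an empty sequence",
                         call. = FALSE)
  digits <- seq_to_digits(seq)
  sum(is.na(digits)) / length(digits)
}

#' Filter records by ambiguous-base content
#'
#' Keeps records whose ambiguous fraction does not exceed the threshold;
#' records strictly exceeding it are dropped (a record sitting exactly at
#' the threshold is kept). The drop report lists each removed record with
#' its fraction.
#'
#' @param records A records data frame from [read_fasta()] (columns `id`,
#'   `description`, `sequence`).
#' @param threshold Maximum tolerated ambiguous fraction (default 0.02,
#'   i.e. 2% of the sequence length).
#' @return A list with `kept` (filtered records data frame) and `dropped`
#'   (data frame `id`, `fraction`, `reason`).
#' @export
filter_records <- function(records, threshold = 0.02) {
  records <- as_records(records)
  frac <- vapply(records$sequence, ambiguous_fraction, numeric(1L),
                 USE.NAMES = FALSE)
  drop <- frac > threshold
  dropped <- data.frame(
    id = records$id[drop],
    fraction = frac[drop],
    reason = sprintf("ambiguous fraction %.4f exceeds %.4f", frac[drop], threshold),
    stringsAsFactors = FALSE
  )
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

#' Write a tab-separated drop report
#'
#' @param dropped The `dropped` data frame from [filter_records()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_drop_report <- function(dropped, path) {
  utils::write.table(dropped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fragmentation policy
#'
#' Describes how to cut fixed-length fragments out of a longer record: the
#' fragment length in bp, the cap on fragments per record (default 3), and
#' the placement rule — head-anchored consecutive windows from position 0
#' (deterministic, the default) or seeded random non-overlapping placement.
#'
#' @param fragment_length Fragment length in bp, >= 1. The benchmark ladder
#'   uses 300, 1000, 3000, 5000 and 10000 bp.
#' @param max_fragments Maximum fragments emitted per record, >= 1.
#' @param placement `"head"` or `"random"`.
#' @param seed Integer seed, required for random placement.
#' @return An object of class `"fragmentation_policy"`.
#' @export
fragmentation_policy <- function(fragment_length, max_fragments = 3L,
                                 placement = c("head", "random"),
                                 seed = NULL) {
  placement <- match.arg(placement)
  stopifnot(length(fragment_length) == 1L, fragment_length >= 1,
            length(max_fragments) == 1L, max_fragments >= 1)
  if (placement == "random" && is.null(seed)) {
    stop("random placement requires a seed", call. = FALSE)
  }
  structure(list(fragment_length = as.integer(fragment_length),
                 max_fragments = as.integer(max_fragments),
                 placement = placement, seed = seed),
            class = "fragmentation_policy")
}

#' Cut non-overlapping fixed-length fragments from one sequence
#'
#' Emits up to `max_fragments` pairwise non-overlapping windows of exactly
#' `fragment_length` bp. Head-anchored placement takes consecutive windows
#' from position 0; random placement samples non-overlapping start
#' positions under the policy seed. A record shorter than the fragment
#' length yields zero fragments. Coordinates are 0-based half-open and
#' encoded in the fragment ids as `<id>:<start>-<end>`.
#'
#' @param seq A nucleotide string.
#' @param policy A [fragmentation_policy()].
#' @param id Source record id used to derive fragment ids.
#' @return A data frame with columns `id`, `start`, `end`, `sequence`
#'   (possibly zero rows).
#' @examples
#' pol <- fragmentation_policy(300)
#' frs <- fragment_record(strrep("ACGT", 200), pol, id = "rec1")
#' frs$id  # "rec1:0-300" "rec1:300-600"
#' @export
fragment_record <- function(seq, policy, id = "seq") {
  stopifnot(inherits(policy, "fragmentation_policy"),
            is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  flen <- policy$fragment_length
  q <- min(policy$max_fragments, L %/% flen)
  if (q < 1L) {
    return(data.frame(id = character(0), start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  if (policy$placement == "head") {
    starts <- (seq_len(q) - 1L) * flen
  } else {
    # q non-overlapping windows: draw q sorted offsets from the slack
    # [0, L - q*flen], then shift the i-th by (i-1)*flen.
    set.seed(policy$seed)
    slack <- L - q * flen
    offs <- sort(sample.int(slack + 1L, q, replace = TRUE) - 1L)
    starts <- offs + (seq_len(q) - 1L) * flen
  }
  ends <- starts + flen
  data.frame(
    id = sprintf("%s:%d-%d", id, starts, ends),
    start = starts, end = ends,
    sequence = substring(seq, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Fragment every record of a dataset
#'
#' Applies [fragment_record()] per record and stacks the results into a
#' records data frame usable by [build_feature_matrix()] or [write_fasta()].
#'
#' @param records A records data frame (columns `id`, `sequence`).
#' @param policy A [fragmentation_policy()].
#' @return A records data frame of fragments (`id`, `description`,
#'   `sequence`), with coordinates embedded in the ids.
#' @export
fragment_records <- function(records, policy) {
  records <- as_records(records)
  parts <- lapply(seq_len(nrow(records)), function(i) {
    fragment_record(records$sequence[i], policy, id = records$id[i])
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  data.frame(id = out$id,
             description = "",
             sequence = out$sequence,
             stringsAsFactors = FALSE)
}
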