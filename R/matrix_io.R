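#' Read a multi-record nucleotide FASTA file
#'
#' Parses with Biostrings; supports line-wrapped sequences, CRLF endings and
#' lowercase bases (uppercased on read). The record id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description. Duplicate ids and empty sequence bodies are rejected.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A records data frame with columns `id`, `description`,
#'   `sequence`, in input order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop(sprintf("record %d has an empty header", which(!nzchar(ids))[1L]),
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate record id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (any(!nzchar(seqs))) {
    stop(sprintf("record '%s' has an empty sequence body",
                 ids[!nzchar(seqs)][1L]), call. = FALSE)
  }
  data.frame(id = unname(ids), description = unname(desc),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records A records data frame (columns `id`, `sequence`, optional
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_records(records)
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Normalize to the canonical records data frame; accepts a data frame with
# at least id + sequence, or a named character vector.
as_records <- function(x) {
  if (is.character(x) && !is.null(names(x))) {
    x <- data.frame(id = names(x), description = "", sequence = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  if (is.null(x$description)) x$description <- ""
  x[, c("id", "description", "sequence", intersect("class", names(x)))]
}

#' Build a feature matrix from sequence records
#'
#' One row per record, columns given by [concat_features()] over the spec
#' list (conditional specs normalized to the `[0, 1]` k-mer range), plus an
#' optional `class` column — the table that downstream classifiers and
#' clustering consume.
#'
#' @param records A records data frame (columns `id`, `sequence`); a
#'   `class` column, if present, is carried through when `label` is NULL.
#' @param specs A [mer_spec()] or list of specs.
#' @param label Optional single class label applied to every row.
#' @inheritParams mn_frequencies
#' @return A data frame of class `"feature_matrix"`: column `seqid`, one
#'   numeric column per feature, and a trailing `class` column when labels
#'   are present.
#' @examples
#' recs <- data.frame(id = c("s1", "s2"), description = "",
#'                    sequence = c("ACCTGA", "TTGACC"))
#' fm <- build_feature_matrix(recs, mer_spec(1, 1), label = "phage")
#' dim(fm)  # 2 rows, 1 + 16 + 1 columns
#' @export
build_feature_matrix <- function(records, specs, label = NULL,
                                 context = c("window", "sequence")) {
  context <- match.arg(context)
  records <- as_records(records)
  if (nrow(records) == 0L) stop("no records to build a feature matrix from",
                                call. = FALSE)
  rows <- lapply(records$sequence, concat_features, specs = specs,
                 context = context)
  vals <- do.call(rbind, rows)
  fm <- data.frame(seqid = records$id, vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(label)) {
    stopifnot(length(label) == 1L)
    fm$class <- as.character(label)
  } else if (!is.null(records$class)) {
    fm$class <- as.character(records$class)
  }
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Stack feature matrices row-wise
#'
#' @param ... Feature matrices with identical feature columns (e.g. one per
#'   class).
#' @return The combined `"feature_matrix"`.
#' @export
rbind_feature_matrices <- function(...) {
  mats <- list(...)
  labs <- lapply(mats, names)
  if (!all(vapply(labs, identical, logical(1L), labs[[1L]]))) {
    stop("feature matrices have mismatched columns", call. = FALSE)
  }
  out <- do.call(rbind, lapply(mats, as.data.frame))
  class(out) <- c("feature_matrix", "data.frame")
  out
}

feature_columns <- function(fm) {
  setdiff(names(fm), c("seqid", "class"))
}

#' Write a feature matrix to CSV
#'
#' Header row is `seqid`, the feature labels, then `class` when present.
#' Values are written with full double precision (`%.15g`) so a write/read
#' round trip is faithful to well below 1e-12 per cell.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matrix_csv <- function(fm, path) {
  stopifnot(is.data.frame(fm), "seqid" %in% names(fm))
  out <- fm
  for (cn in feature_columns(out)) {
    out[[cn]] <- sprintf("%.15g", out[[cn]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Inverse of [write_matrix_csv()]. Ragged rows and non-numeric feature
#' cells are rejected with the offending row number.
#'
#' @param path Path to a feature-matrix CSV.
#' @return A `"feature_matrix"` data frame.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]), call. = FALSE)
  }
  fm <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"seqid" %in% names(fm)) stop("missing 'seqid' column", call. = FALSE)
  for (cn in feature_columns(fm)) {
    num <- suppressWarnings(as.numeric(fm[[cn]]))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop(sprintf("non-numeric value '%s' in column '%s', data row %d",
                   fm[[cn]][bad], cn, bad), call. = FALSE)
    }
    fm[[cn]] <- num
  }
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  nfeat <- length(feature_columns(x))
  cat(sprintf("feature matrix: %d sequences x %d features%s\n",
              nrow(x), nfeat,
              if ("class" %in% names(x))
                sprintf(" (%d classes)", length(unique(x$class))) else ""))
  NextMethod()
}
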