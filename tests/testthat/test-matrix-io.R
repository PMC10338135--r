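write_lines <- function(lines, sep = "\n") {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path, sep = sep)
  path
}

test_that("FASTA reading handles wrapping, case, CRLF and header parsing", {
  p <- write_lines(c(">seq1 first record", "ACGTAC", "GTACGT",
                     ">seq2", "acgtn"))
  recs <- read_fasta(p)
  expect_identical(recs$id, c("seq1", "seq2"))
  expect_identical(recs$description, c("first record", ""))
  expect_identical(recs$sequence, c("ACGTACGTACGT", "ACGTN"))

  crlf <- write_lines(c(">a desc", "ACGT", ">b", "GGCC"), sep = "\r\n")
  recs2 <- read_fasta(crlf)
  expect_identical(recs2$sequence, c("ACGT", "GGCC"))
  expect_identical(recs2$id, c("a", "b"))
})

test_that("FASTA reading rejects duplicates, empty bodies and missing files", {
  dup <- write_lines(c(">x", "ACGT", ">x", "GGCC"))
  expect_error(read_fasta(dup), "duplicate")
  empty <- write_lines(c(">x", "ACGT", ">y", ">z", "ACGT"))
  expect_error(read_fasta(empty), "empty sequence|malformed")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("FASTA write/read round-trips records", {
  recs <- data.frame(id = c("s1", "s2"), description = c("first", ""),
                     sequence = c(random_seq(201), random_seq(85)),
                     stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".fa")
  write_fasta(recs, p)
  back <- read_fasta(p)
  expect_identical(back$id, recs$id)
  expect_identical(back$sequence, recs$sequence)
  expect_identical(back$description, recs$description)
})

test_that("feature matrices carry one row per record plus class labels", {
  recs <- data.frame(id = c("a", "b", "c"), description = "",
                     sequence = c("ACCTGA", "TTGACC", "ACGTACGT"),
                     stringsAsFactors = FALSE)
  fm <- build_feature_matrix(recs, mer_spec(1, 1), label = "phage")
  expect_identical(dim(fm), c(3L, 18L))  # seqid + 16 + class
  expect_identical(fm$class, rep("phage", 3))
  expect_identical(fm$seqid, recs$id)

  # reduction: a (0,k) row equals the record's plain k-mer vector
  fm2 <- build_feature_matrix(recs[1, ], mer_spec(0, 2))
  expect_equal(as.numeric(fm2[1, feature_labels(mer_spec(0, 2))]),
               as.numeric(kmer_frequencies(count_kmers("ACCTGA", 2))))

  # values stay in [0, 1] for conditional features (normalized)
  vals <- as.matrix(fm[, setdiff(names(fm), c("seqid", "class"))])
  expect_true(all(vals >= 0 & vals <= 1))

  stacked <- rbind_feature_matrices(
    build_feature_matrix(recs[1:2, ], mer_spec(1, 1), label = "A"),
    build_feature_matrix(recs[3, ], mer_spec(1, 1), label = "B"))
  expect_identical(nrow(stacked), 3L)
  expect_identical(sort(unique(stacked$class)), c("A", "B"))
})

test_that("matrix built from (0,k) matches an independent k-mer counter", {
  set.seed(37)
  recs <- data.frame(id = sprintf("s%d", 1:5), description = "",
                     sequence = replicate(5, random_seq(120)),
                     stringsAsFactors = FALSE)
  fm <- build_feature_matrix(recs, mer_spec(0, 3))
  for (i in 1:5) {
    ref <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(recs$sequence[i]), 3, as.prob = TRUE)
    expect_equal(as.numeric(fm[i, -1]), unname(as.numeric(ref)),
                 tolerance = 1e-12)
  }
})

test_that("CSV persistence round-trips within 1e-12 and validates input", {
  set.seed(41)
  recs <- data.frame(id = sprintf("s%d", 1:4), description = "",
                     sequence = replicate(4, random_seq(90)),
                     stringsAsFactors = FALSE)
  fm <- build_feature_matrix(recs, list(mer_spec(0, 2), mer_spec(2, 1)),
                             label = "X")
  p <- tempfile(fileext = ".csv")
  write_matrix_csv(fm, p)
  back <- read_matrix_csv(p)
  expect_identical(back$seqid, fm$seqid)
  expect_identical(names(back), names(fm))
  expect_equal(as.matrix(back[, -c(1, ncol(back))]),
               as.matrix(fm[, -c(1, ncol(fm))]), tolerance = 1e-12)
  expect_identical(back$class, fm$class)

  # no class column -> no class header
  fm0 <- build_feature_matrix(recs, mer_spec(1, 1))
  p0 <- tempfile(fileext = ".csv")
  write_matrix_csv(fm0, p0)
  expect_false("class" %in% names(read_matrix_csv(p0)))

  # a hand-written one-row CSV parses into a usable matrix
  hand <- tempfile(fileext = ".csv")
  writeLines(c(paste(c("seqid", feature_labels(mer_spec(1, 1)), "class"),
                     collapse = ","),
               paste(c("s1", sprintf("%.4f", rep(1 / 16, 16)), "A"),
                     collapse = ",")), hand)
  hm <- read_matrix_csv(hand)
  expect_identical(nrow(hm), 1L)
  expect_equal(sum(as.numeric(hm[1, 2:17])), 1, tolerance = 1e-3)

  ragged <- tempfile(fileext = ".csv")
  writeLines(c("seqid,AA,AC", "s1,0.5,0.5", "s2,0.5"), ragged)
  expect_error(read_matrix_csv(ragged), "row 3")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("seqid,AA,AC", "s1,0.5,oops"), bad)
  expect_error(read_matrix_csv(bad), "non-numeric")
})
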