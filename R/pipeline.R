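#' Extract features from a FASTA file to CSV
#'
#' The end-to-end feature subcommand: read a FASTA file, optionally drop
#' records whose ambiguous-base fraction exceeds the threshold, build the
#' (m,n)-mer feature matrix and write it as CSV. `m` and `n` may be
#' vectors of equal length to concatenate several mer families into one
#' matrix.
#'
#' @param fasta Input FASTA path.
#' @param m,n Context and suffix lengths (equal-length integer vectors;
#'   `m = 0` selects plain k-mers).
#' @param out_csv Output CSV path.
#' @param label Optional class label for every record.
#' @param filter Drop records with > `threshold` ambiguous bases first.
#' @param threshold Ambiguity threshold (default 0.02).
#' @param drop_report Optional path for the tab-separated drop report.
#' @return The feature matrix, invisibly.
#' @export
run_features <- function(fasta, m, n, out_csv, label = NULL,
                         filter = FALSE, threshold = 0.02,
                         drop_report = NULL) {
  stopifnot(length(m) == length(n), length(m) >= 1L)
  specs <- mapply(mer_spec, m, n, SIMPLIFY = FALSE)
  records <- read_fasta(fasta)
  if (filter) {
    fl <- filter_records(records, threshold = threshold)
    records <- fl$kept
    if (!is.null(drop_report)) write_drop_report(fl$dropped, drop_report)
  }
  fm <- build_feature_matrix(records, specs, label = label)
  write_matrix_csv(fm, out_csv)
  invisible(fm)
}

#' Fragment every record of a FASTA file
#'
#' @param fasta Input FASTA path.
#' @param length Fragment length in bp.
#' @param out_fasta Output FASTA path for the fragments.
#' @param max_fragments Cap per record (default 3).
#' @param placement `"head"` or `"random"`.
#' @param seed Seed for random placement.
#' @return The fragment records, invisibly.
#' @export
run_fragment <- function(fasta, length, out_fasta, max_fragments = 3L,
                         placement = "head", seed = NULL) {
  policy <- fragmentation_policy(length, max_fragments, placement, seed)
  frags <- fragment_records(read_fasta(fasta), policy)
  write_fasta(frags, out_fasta)
  invisible(frags)
}

#' Simulate a labeled two-class benchmark dataset to FASTA
#'
#' Builds a random order-`order` chain, perturbs it by `epsilon` to make
#' the second class, simulates `n_per_class` sequences per class and
#' writes a FASTA file plus a two-column label file. The defaults mirror
#' the package's benchmark preset: order-2 chains at separation 0.15.
#'
#' @param out_fasta,out_labels Output paths.
#' @param n_per_class Sequences per class.
#' @param length Sequence length in bp.
#' @param seed Master seed (drives the base model, the perturbation and
#'   every sequence).
#' @param order Markov order of the generating chains.
#' @param epsilon Class separation in `[0, 1]` (see [perturb_model()]).
#' @return The simulated records, invisibly.
#' @export
run_simulate <- function(out_fasta, out_labels, n_per_class = 500L,
                         length = 1000L, seed = 1L, order = 2L,
                         epsilon = 0.15) {
  model_a <- random_transition_model(order, seed = derive_seed(seed, 101L))
  model_b <- perturb_model(model_a, epsilon, seed = derive_seed(seed, 202L))
  records <- make_two_class_dataset(model_a, model_b, n_per_class, length,
                                    seed = seed)
  write_fasta(records, out_fasta)
  write_labels(records, out_labels)
  invisible(records)
}

#' Benchmark feature matrices against each other
#'
#' Runs [resample_classify()] on every listed feature-matrix CSV (all must
#' carry the same rows in the sense of identical class composition), takes
#' the first as the baseline and reports the ternary win/tie/loss verdict
#' of every other matrix against it. Writes a tidy per-resample CSV
#' (`feature, resample, metric`) and a summary CSV (`feature, mean,
#' ci_low, ci_high, verdict_vs_baseline`).
#'
#' @param matrix_csvs Character vector of feature-matrix CSV paths; names,
#'   if set, become the feature names.
#' @param out_prefix Output prefix; writes `<prefix>_resamples.csv` and
#'   `<prefix>_summary.csv`.
#' @inheritParams resample_classify
#' @param alpha Significance level for the ternary test.
#' @return A list with `reports` and the `summary` data frame, invisibly.
#' @export
run_benchmark <- function(matrix_csvs, out_prefix, classifier = "knn",
                          n_resamples = 50L, per_class = 500L, seed = 1L,
                          alpha = 0.05) {
  stopifnot(length(matrix_csvs) >= 1L)
  feature_names <- names(matrix_csvs)
  if (is.null(feature_names)) {
    feature_names <- sub("\\.csv$", "", basename(matrix_csvs))
  }
  reports <- lapply(seq_along(matrix_csvs), function(i) {
    fm <- read_matrix_csv(matrix_csvs[[i]])
    resample_classify(fm, n_resamples = n_resamples, per_class = per_class,
                      classifier = classifier, seed = seed,
                      feature_name = feature_names[i])
  })
  tidy <- do.call(rbind, lapply(reports, function(rp) {
    data.frame(feature = rp$feature_name,
               resample = seq_len(rp$n_resamples),
               metric = rp$per_resample_metric)
  }))
  summary_df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]
    verdict <- if (i == 1L) "baseline" else
      mean_difference_test(rp, reports[[1L]], alpha = alpha)$verdict
    data.frame(feature = rp$feature_name, mean = rp$mean,
               ci_low = rp$ci95[1L], ci_high = rp$ci95[2L],
               verdict_vs_baseline = verdict)
  }))
  utils::write.csv(tidy, paste0(out_prefix, "_resamples.csv"), row.names = FALSE)
  utils::write.csv(summary_df, paste0(out_prefix, "_summary.csv"),
                   row.names = FALSE)
  invisible(list(reports = reports, summary = summary_df))
}

#' Cluster a feature matrix and score it by mean ARI
#'
#' @param matrix_csv Feature-matrix CSV with a `class` column.
#' @param out_csv Output CSV (`algorithm, replicate, ari` rows plus the
#'   mean).
#' @inheritParams cluster_eval
#' @return The [cluster_eval()] result, invisibly.
#' @export
run_cluster_eval <- function(matrix_csv, out_csv, algorithm = "kmeans",
                             n_clusters = NULL, replicates = 3L, seed = 1L) {
  fm <- read_matrix_csv(matrix_csv)
  res <- cluster_eval(fm, algorithm = algorithm, n_clusters = n_clusters,
                      replicates = replicates, seed = seed)
  out <- data.frame(algorithm = res$algorithm,
                    replicate = c(seq_along(res$per_replicate_ari), NA),
                    ari = c(res$per_replicate_ari, res$mean_ari))
  out$replicate <- ifelse(is.na(out$replicate), "mean", out$replicate)
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(res)
}
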