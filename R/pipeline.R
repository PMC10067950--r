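# Glue between phantom studies, preprocessing and model datasets, and the
# seeded phantom benchmark comparing the bilateral symmetry model with the
# single-side baseline.

#' Preprocess one study into a paired network input
#'
#' @param view an `APView` (e.g. `study$ap_view`).
#' @param target `c(rows, cols)` single-ear input size.
#' @return a `PairedInput`.
#' @export
prepare_pair <- function(view, target = c(384L, 256L)) {
  crops <- crop_ears(view)
  compose_pair(crops$right, crops$left, target = target)
}

studies_to_bilateral_examples <- function(studies, target) {
  lapply(studies, function(s) {
    pair <- prepare_pair(s$ap_view, target)
    list(subject_id = s$truth$subject_id,
         right_image = pair$right_image, left_image = pair$left_image,
         right = s$truth$right, left = s$truth$left,
         grade = s$truth$grade)
  })
}

# two per-ear examples per subject; the left ear is already flipped to the
# right-ear orientation by compose_pair
studies_to_single_examples <- function(studies, target) {
  out <- list()
  for (s in studies) {
    pair <- prepare_pair(s$ap_view, target)
    out <- c(out,
             list(list(subject_id = s$truth$subject_id, side = "right",
                       image = pair$right_image, cat = s$truth$right)),
             list(list(subject_id = s$truth$subject_id, side = "left",
                       image = pair$left_image, cat = s$truth$left)))
  }
  out
}

#' One replicate of the phantom benchmark
#'
#' Generates a benchmark cohort, splits it (stratified by symmetry grade)
#' into 600 training / 120 validation / 200 test subjects, trains the
#' bilateral symmetry model and the single-side baseline under identical
#' conditions, and evaluates both on the held-out test subjects (per-ear
#' dichotomized AUC).
#'
#' @param seed integer seed driving cohort generation, splits and training.
#' @param n_train,n_val,n_test subject counts per partition.
#' @param verbose print progress.
#' @return list with `auc_bilateral`, `auc_single`, and the two
#'   `DiagnosticReport`s.
#' @export
phantom_benchmark_replicate <- function(seed, n_train = 600L, n_val = 120L,
                                        n_test = 200L, verbose = FALSE) {
  n_total <- n_train + n_val + n_test
  params <- default_benchmark_params(n_subjects = n_total, seed = seed * 1009L)
  cohort <- generate_cohort(params)
  labels <- read_truth(cohort)
  sp1 <- stratified_split(labels, ratio = c(n_train + n_val, n_test), seed = seed)
  rest <- labels[labels$subject_id %in% sp1$train, , drop = FALSE]
  sp2 <- stratified_split(rest, ratio = c(n_train, n_val), seed = seed + 1L)
  pick <- function(ids) cohort$studies[match(ids, labels$subject_id)]
  cfg <- benchmark_stream_config()
  target <- cfg$input_shape
  tr_b <- studies_to_bilateral_examples(pick(sp2$train), target)
  va_b <- studies_to_bilateral_examples(pick(sp2$validation), target)
  te <- pick(sp1$validation)
  te_b <- studies_to_bilateral_examples(te, target)
  tcfg <- benchmark_train_config(seed = seed)
  if (verbose) message("training bilateral model (seed ", seed, ")")
  mb <- train_model(build_bilateral(cfg), tr_b, va_b, tcfg, verbose = verbose)
  tr_s <- studies_to_single_examples(pick(sp2$train), target)
  va_s <- studies_to_single_examples(pick(sp2$validation), target)
  te_s <- studies_to_single_examples(te, target)
  if (verbose) message("training single-side model (seed ", seed, ")")
  ms <- train_model(build_single_side(cfg), tr_s, va_s, tcfg, verbose = verbose)

  preds_b <- lapply(te_b, function(ex)
    forward_bilateral(mb, ex))
  lab_df <- data.frame(
    subject_id = vapply(te_b, `[[`, character(1), "subject_id"),
    right = vapply(te_b, `[[`, integer(1), "right"),
    left = vapply(te_b, `[[`, integer(1), "left"))
  rep_b <- evaluate(preds_b, lab_df)
  probs_s <- lapply(te_s, function(ex) forward_single(ms, ex$image))
  truth_s <- vapply(te_s, `[[`, integer(1), "cat")
  rep_s <- report_from_ears(probs_s, truth_s)
  list(auc_bilateral = rep_b$auc, auc_single = rep_s$auc,
       report_bilateral = rep_b, report_single = rep_s)
}

read_truth <- function(cohort) {
  data.frame(subject_id = cohort$labels$subject_id,
             right = cohort$labels$right_category,
             left = cohort$labels$left_category,
             grade = abs(cohort$labels$right_category -
                           cohort$labels$left_category),
             excluded = cohort$labels$right_category == 3L |
               cohort$labels$left_category == 3L,
             stringsAsFactors = FALSE)
}
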