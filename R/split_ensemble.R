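# Block-stratified repeated train/val/test splitting and pooling of
# out-of-sample predictions.

#' Block-stratified 2/1/1 patient-level split
#'
#' Patients are sorted by vital status (censored before deceased), then
#' follow-up time ascending, then patient id; consecutive blocks of 4 are
#' formed and within each block a random permutation assigns 2 patients to
#' training and 1 each to validation and test. Remainder patients
#' (`n mod 4`) go to training, so the test group is always exactly a
#' quarter of the cohort. Splitting is at patient level: no slide of a
#' patient can cross groups. Deterministic given `seed`.
#'
#' @param clinical clinical table with patient_id, followup_time, event.
#' @param seed integer seed.
#' @return data.frame (patient_id, group) with group in train/val/test.
#' @export
block_split <- function(clinical, seed) {
  n <- nrow(clinical)
  if (n < 4) stop("block splitting needs at least 4 patients", call. = FALSE)
  ord <- order(clinical$event, clinical$followup_time, clinical$patient_id)
  ids <- clinical$patient_id[ord]
  n_blocks <- n %/% 4L
  group <- rep("train", n)
  with_seed(seed, {
    for (b in seq_len(n_blocks)) {
      pos <- (b - 1L) * 4L + 1:4
      group[pos] <- sample(c("train", "train", "val", "test"))
    }
  })
  data.frame(patient_id = ids, group = group, stringsAsFactors = FALSE)
}

#' Generate the repeated split assignments
#'
#' Produces `n_tune + n_eval` independent block splits with seeds derived
#' as `master_seed + repeat_id` (counter-based), so adding evaluation
#' repeats never changes the tuning splits. The first `n_tune` repeats are
#' flagged as hyperparameter-tuning repeats.
#'
#' @param clinical clinical table.
#' @param n_tune number of tuning repetitions (8 at full scale).
#' @param n_eval number of evaluation repetitions (24 at full scale).
#' @param master_seed master seed.
#' @return data.frame (repeat_id, patient_id, group, is_tuning).
#' @export
run_repeats <- function(clinical, n_tune = 8, n_eval = 24, master_seed = 1) {
  n_tune <- check_count(n_tune, "n_tune", min = 0)
  n_eval <- check_count(n_eval, "n_eval", min = 0)
  total <- n_tune + n_eval
  out <- vector("list", total)
  for (r in seq_len(total)) {
    sp <- block_split(clinical, seed = master_seed + r)
    out[[r]] <- data.frame(repeat_id = r, sp, is_tuning = r <= n_tune,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Select the best hyperparameter candidate
#'
#' Returns the candidate with the highest mean validation metric across
#' tuning repeats; ties are broken by candidate declaration order.
#'
#' @param candidates list of candidate configs (declaration order matters).
#' @param metrics data.frame (candidate, repeat_id, metric) with one row
#'   per candidate per tuning repeat; a missing cell is an error.
#' @return list with `config` (the winner), `index`, and `summary`
#'   (candidate, mean_metric).
#' @export
select_hyperparameters <- function(candidates, metrics) {
  stopifnot(length(candidates) >= 1)
  repeats <- sort(unique(metrics$repeat_id))
  means <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    rows <- metrics[metrics$candidate == ci, , drop = FALSE]
    missing <- setdiff(repeats, rows$repeat_id)
    if (length(missing) > 0 || nrow(rows) < length(repeats))
      stop(sprintf("missing validation metric for candidate %d, repeat %s",
                   ci, paste(missing, collapse = ",")), call. = FALSE)
    means[ci] <- mean(rows$metric)
  }
  idx <- which.max(means)  # which.max returns the earliest maximum
  list(config = candidates[[idx]], index = idx,
       summary = data.frame(candidate = seq_along(candidates),
                            mean_metric = means))
}

#' Pool out-of-sample predictions across repetitions
#'
#' Groups test-split predictions by patient and averages them into the
#' final ensemble score. Under the block scheme each patient enters the
#' test group with probability 1/4 per repeat, so the per-patient count of
#' out-of-sample predictions is Binomial(R, 1/4) with mean R/4.
#'
#' @param predictions data.frame (patient_id, repeat_id, score); a patient
#'   may appear at most once per repeat.
#' @param cohort_ids optional full roster; patients with no out-of-sample
#'   prediction trigger a warning (not an error).
#' @return data.frame (patient_id, n_oos, ensemble_score).
#' @export
pool_out_of_sample <- function(predictions, cohort_ids = NULL) {
  key <- paste(predictions$patient_id, predictions$repeat_id)
  if (anyDuplicated(key))
    stop("duplicate (patient, repeat) prediction rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(score ~ patient_id, data = predictions,
                          FUN = mean)
  cnt <- as.data.frame(table(predictions$patient_id),
                       stringsAsFactors = FALSE)
  names(cnt) <- c("patient_id", "n_oos")
  out <- merge(cnt, agg, by = "patient_id")
  names(out)[names(out) == "score"] <- "ensemble_score"
  if (!is.null(cohort_ids)) {
    missing <- setdiff(cohort_ids, out$patient_id)
    if (length(missing) > 0)
      warning(length(missing), " patient(s) with no out-of-sample ",
              "prediction: ", paste(missing, collapse = ", "),
              call. = FALSE)
  }
  out[order(out$patient_id), ]
}
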