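# End-to-end experiment driver: simulate -> tile -> split -> train x R ->
# ensemble -> evaluate -> report, with per-stage resume keyed on the
# config hash.

#' Assemble a full experiment configuration
#'
#' Bundles the cohort, tiling, training, splitting and bootstrap settings
#' of one experiment. Defaults give the desk profile: a small synthetic
#' cohort, 64-px tiles, the scaled-down training schedule, 2 tuning + 4
#' evaluation repeats, and a reduced bootstrap count.
#'
#' @param cohort a [cohort_spec()].
#' @param tiling a [tiling_config()].
#' @param training a [training_config()] (ignored when
#'   `training_candidates` is given).
#' @param training_candidates optional list of [training_config()]s for
#'   hyperparameter selection over the tuning repeats.
#' @param n_tune,n_eval numbers of tuning / evaluation repetitions.
#' @param n_boot bootstrap replicates for the model comparisons.
#' @param tasks subset of "survival", "biomarker",
#'   "biomarker_probability" (the last reuses the biomarker model's
#'   predicted probability as a survival covariate).
#' @param base_covariates list of base covariate sets for the comparisons
#'   (character vectors; `character(0)` = image score alone).
#' @param master_seed master seed for the whole experiment.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(n_patients = 60, slide_px = 512,
                                            beta_risk = 1.0, seed = 11),
                       tiling = tiling_config(),
                       training = training_config(),
                       training_candidates = NULL,
                       n_tune = 2, n_eval = 4,
                       n_boot = 500,
                       tasks = c("survival", "biomarker",
                                 "biomarker_probability"),
                       base_covariates = list(character(0), "age"),
                       master_seed = 1) {
  cfg <- list(cohort = cohort, tiling = tiling, training = training,
              training_candidates = training_candidates,
              n_tune = check_count(n_tune, "n_tune", min = 0),
              n_eval = check_count(n_eval, "n_eval", min = 0),
              n_boot = check_count(n_boot, "n_boot", min = 1),
              tasks = tasks, base_covariates = base_covariates,
              master_seed = check_count(master_seed, "master_seed", min = 0))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' @param config a [run_config()] (or a plain list with the same fields).
#' @return `TRUE` invisibly; errors name the offending field.
#' @export
validate_run_config <- function(config) {
  if (!inherits(config$cohort, "cohort_spec"))
    stop("field 'cohort' must be a cohort_spec", call. = FALSE)
  if (!inherits(config$tiling, "tiling_config"))
    stop("field 'tiling' must be a tiling_config", call. = FALSE)
  if (!inherits(config$training, "training_config"))
    stop("field 'training' must be a training_config", call. = FALSE)
  if (!is.null(config$training_candidates)) {
    ok <- vapply(config$training_candidates, inherits, logical(1),
                 "training_config")
    if (!all(ok))
      stop("field 'training_candidates' must be a list of training_config",
           call. = FALSE)
  }
  bad <- setdiff(config$tasks,
                 c("survival", "biomarker", "biomarker_probability"))
  if (length(bad) > 0)
    stop("unknown task(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (config$cohort$tile_px != config$tiling$tile_px)
    stop("cohort tile_px and tiling tile_px disagree", call. = FALSE)
  if (config$n_tune + config$n_eval < 1)
    stop("need at least one repetition", call. = FALSE)
  invisible(TRUE)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_rec(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_rec <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_rec)
  } else x
}

stage_fresh <- function(out_dir, stage, hash, outputs) {
  hf <- file.path(out_dir, paste0(stage, ".hash"))
  file.exists(hf) && identical(readLines(hf, warn = FALSE)[1], hash) &&
    all(file.exists(outputs))
}

stage_mark <- function(out_dir, stage, hash) {
  writeLines(hash, file.path(out_dir, paste0(stage, ".hash")))
}

run_stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

comparison_row <- function(cmp) {
  s <- cmp$summary
  data.frame(
    base = if (length(cmp$base)) paste(cmp$base, collapse = "+") else "none",
    added = cmp$added,
    without = s$mean[1], without_lo = s$ci_low[1], without_hi = s$ci_high[1],
    with = s$mean[2], with_lo = s$ci_low[2], with_hi = s$ci_high[2],
    difference = s$mean[3], diff_lo = s$ci_low[3], diff_hi = s$ci_high[3],
    significant = cmp$significant,
    full_data_without = unname(cmp$full_data["without"]),
    full_data_with = unname(cmp$full_data["with"]),
    n_redrawn = cmp$n_redrawn,
    stringsAsFactors = FALSE)
}

#' Run the full experiment
#'
#' Executes every stage of the pipeline into `out_dir`. Stage outputs are
#' keyed by a hash of the configuration: re-running with an unchanged
#' config skips completed stages; changing the config re-runs them. The
#' same config and seed reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param validate_only if `TRUE`, validate the config and return without
#'   producing outputs.
#' @return (invisibly) a list with the main artifacts: clinical, manifest,
#'   splits, ensembles per task, comparison tables, and the report path.
#' @export
run_experiment <- function(config, out_dir, validate_only = FALSE) {
  validate_run_config(config)
  if (validate_only) return(invisible(TRUE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$master_seed

  # ---- simulate ----
  sim_dir <- file.path(out_dir, "simulate")
  clin_path <- file.path(sim_dir, "clinical.csv")
  run_stage("simulate", {
    if (!stage_fresh(out_dir, "simulate", hash, clin_path)) {
      generate_cohort(config$cohort, sim_dir)
      stage_mark(out_dir, "simulate", hash)
    }
  })
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  truth <- utils::read.csv(file.path(sim_dir, "truth.csv"),
                           stringsAsFactors = FALSE)

  # ---- tile ----
  man_path <- file.path(out_dir, "manifest.tsv")
  run_stage("tile", {
    if (!stage_fresh(out_dir, "tile", hash, man_path)) {
      build_manifest(file.path(sim_dir, "slides"), clinical, config$tiling,
                     out = man_path)
      stage_mark(out_dir, "tile", hash)
    }
  })
  manifest <- read_manifest(man_path)

  # ---- split ----
  split_path <- file.path(out_dir, "splits.tsv")
  run_stage("split", {
    if (!stage_fresh(out_dir, "split", hash, split_path)) {
      write_tsv(run_repeats(clinical, config$n_tune, config$n_eval,
                            master_seed = seed), split_path)
      stage_mark(out_dir, "split", hash)
    }
  })
  splits <- read_tsv(split_path)
  repeat_ids <- sort(unique(splits$repeat_id))

  # ---- train + out-of-sample predictions ----
  model_tasks <- intersect(c("survival", "biomarker"),
                           unique(c(config$tasks,
                                    if ("biomarker_probability" %in%
                                        config$tasks) "biomarker")))
  pred_paths <- file.path(out_dir, sprintf("pred_%s.tsv", model_tasks))
  names(pred_paths) <- model_tasks
  run_stage("train", {
    if (!stage_fresh(out_dir, "train", hash, pred_paths)) {
      store <- build_patch_store(file.path(sim_dir, "slides"), manifest,
                                 config$tiling$tile_px)
      for (task in model_tasks) {
        tcfg <- config$training
        cands <- config$training_candidates
        if (!is.null(cands) && length(cands) > 1 && config$n_tune > 0) {
          tune_ids <- repeat_ids[seq_len(config$n_tune)]
          cells <- NULL
          for (ci in seq_along(cands)) for (r in tune_ids) {
            sp <- splits[splits$repeat_id == r, ]
            cc <- cands[[ci]]
            cc$seed <- mix_seed(seed, 31, r, ci)
            tr <- train_model(sp, store, clinical, cc, task = task)
            m <- if (nrow(tr$evals) > 0) max(tr$evals$metric) else NA_real_
            cells <- rbind(cells, data.frame(candidate = ci, repeat_id = r,
                                             metric = m))
          }
          tcfg <- select_hyperparameters(cands, cells)$config
        }
        preds <- NULL
        for (r in repeat_ids) {
          sp <- splits[splits$repeat_id == r, ]
          rcfg <- tcfg
          rcfg$seed <- mix_seed(seed, 37, r,
                                match(task, c("survival", "biomarker")))
          tr <- train_model(sp, store, clinical, rcfg, task = task)
          test_pts <- sp$patient_id[sp$group == "test"]
          test_pts <- intersect(test_pts, names(store))
          pr <- predict_patients(tr, test_pts, mode = "test", store = store)
          preds <- rbind(preds,
                         data.frame(patient_id = pr$patient_id,
                                    repeat_id = r, group = "test",
                                    score = pr$score,
                                    stringsAsFactors = FALSE))
        }
        write_tsv(preds, pred_paths[[task]])
      }
      stage_mark(out_dir, "train", hash)
    }
  })

  # ---- ensemble ----
  ens_paths <- file.path(out_dir, sprintf("ensemble_%s.tsv", model_tasks))
  names(ens_paths) <- model_tasks
  ensembles <- list()
  run_stage("ensemble", {
    for (task in model_tasks) {
      preds <- read_tsv(pred_paths[[task]])
      ens <- pool_out_of_sample(preds, cohort_ids = clinical$patient_id)
      write_tsv(ens, ens_paths[[task]])
      ensembles[[task]] <- ens
    }
    stage_mark(out_dir, "ensemble", hash)
  })

  # ---- evaluate ----
  eval_dir <- file.path(out_dir, "evaluate")
  dir.create(eval_dir, showWarnings = FALSE)
  tables <- list()
  run_stage("evaluate", {
    dat <- clinical
    if ("survival" %in% model_tasks) {
      es <- ensembles$survival
      dat$wsi_risk_score <- es$ensemble_score[match(dat$patient_id,
                                                    es$patient_id)]
    }
    if ("biomarker" %in% model_tasks) {
      eb <- ensembles$biomarker
      dat$idh_probability <- eb$ensemble_score[match(dat$patient_id,
                                                     eb$patient_id)]
    }
    if ("survival" %in% config$tasks) {
      rows <- NULL
      for (i in seq_along(config$base_covariates)) {
        cmp <- bootstrap_compare(dat, config$base_covariates[[i]],
                                 "wsi_risk_score", task = "survival",
                                 n_boot = config$n_boot,
                                 seed = mix_seed(seed, 41, i))
        rows <- rbind(rows, comparison_row(cmp))
      }
      tables$table1_survival <- rows
      write_tsv(rows, file.path(eval_dir, "table1_survival.tsv"))
      # KM + log-rank by tertiles of the image risk score
      ok <- !is.na(dat$wsi_risk_score)
      tert <- tertile_categorize(dat$wsi_risk_score[ok])
      km <- km_estimate(dat$followup_time[ok], dat$event[ok], tert$labels)
      write_tsv(km, file.path(eval_dir, "km_wsi_score.tsv"))
      lr <- logrank_test(dat$followup_time[ok], dat$event[ok], tert$labels)
      tables$logrank_wsi <- lr
      write_tsv(data.frame(statistic = lr$statistic, df = lr$df,
                           p_value = lr$p_value),
                file.path(eval_dir, "logrank_wsi_score.tsv"))
    }
    if ("biomarker" %in% config$tasks) {
      lab_ok <- !is.na(dat$biomarker) & !is.na(dat$idh_probability)
      ra <- roc_auc(dat$biomarker[lab_ok], dat$idh_probability[lab_ok])
      tables$biomarker_auc <- ra$auc
      write_tsv(ra$roc, file.path(eval_dir, "roc_biomarker.tsv"))
      bdat <- dat[lab_ok, ]
      bdat$label <- bdat$biomarker
      rows <- NULL
      for (i in seq_along(config$base_covariates)) {
        cmp <- bootstrap_compare(bdat, config$base_covariates[[i]],
                                 "idh_probability", task = "binary",
                                 n_boot = config$n_boot,
                                 seed = mix_seed(seed, 43, i))
        rows <- rbind(rows, comparison_row(cmp))
      }
      tables$table1_biomarker <- rows
      write_tsv(rows, file.path(eval_dir, "table1_biomarker.tsv"))
    }
    if ("biomarker_probability" %in% config$tasks) {
      rows <- NULL
      bases <- config$base_covariates
      if ("survival" %in% model_tasks)
        bases <- c(bases, list("wsi_risk_score",
                               c("age", "wsi_risk_score")))
      for (i in seq_along(bases)) {
        cmp <- bootstrap_compare(dat, bases[[i]], "idh_probability",
                                 task = "survival",
                                 n_boot = config$n_boot,
                                 seed = mix_seed(seed, 47, i))
        rows <- rbind(rows, comparison_row(cmp))
      }
      tables$table2 <- rows
      write_tsv(rows, file.path(eval_dir, "table2_idh_probability.tsv"))
    }
    stage_mark(out_dir, "evaluate", hash)
  })

  report <- run_stage("report", write_report(out_dir, config, hash))
  invisible(list(clinical = clinical, truth = truth, manifest = manifest,
                 splits = splits, ensembles = ensembles, tables = tables,
                 report = report, hash = hash))
}

#' Write the human-readable experiment report
#'
#' Summarizes the stage artifacts of a completed [run_experiment()] run
#' into `report.md`; every number in the report is read back from a stage
#' TSV, and the config hash and master seed are embedded for provenance.
#' A referenced artifact that does not exist is an error naming the file.
#'
#' @param out_dir the experiment output directory.
#' @param config the [run_config()] used.
#' @param hash optional config hash (recomputed when `NULL`).
#' @return the report path, invisibly.
#' @export
write_report <- function(out_dir, config, hash = NULL) {
  if (is.null(hash)) hash <- config_hash(config)
  need <- function(path) {
    if (!file.exists(path)) stop("missing artifact: ", path, call. = FALSE)
    path
  }
  lines <- c("# Experiment report", "",
             sprintf("- config hash: `%s`", hash),
             sprintf("- master seed: %d", config$master_seed),
             sprintf("- tasks: %s", paste(config$tasks, collapse = ", ")))
  clin <- utils::read.csv(need(file.path(out_dir, "simulate",
                                         "clinical.csv")))
  man <- read_manifest(need(file.path(out_dir, "manifest.tsv")))
  splits <- read_tsv(need(file.path(out_dir, "splits.tsv")))
  lines <- c(lines,
             sprintf("- patients: %d (events: %d)", nrow(clin),
                     sum(clin$event)),
             sprintf("- candidate tiles: %d; kept: %d", nrow(man),
                     sum(man$kept)),
             sprintf("- repetitions: %d (%d tuning)",
                     length(unique(splits$repeat_id)),
                     length(unique(splits$repeat_id[splits$is_tuning]))),
             "")
  fmt_table <- function(df, title, path) {
    c(sprintf("## %s", title), sprintf("(source: `%s`)", path), "",
      paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(r, collapse = " | ")), "")
  }
  for (task in config$tasks) {
    fn <- switch(task,
                 survival = "evaluate/table1_survival.tsv",
                 biomarker = "evaluate/table1_biomarker.tsv",
                 biomarker_probability = "evaluate/table2_idh_probability.tsv")
    path <- file.path(out_dir, fn)
    if (length(config$tasks) > 0) {
      df <- read_tsv(need(path))
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) round(x, 4))
      lines <- c(lines, fmt_table(df, paste("Comparisons:", task), fn))
    }
  }
  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
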