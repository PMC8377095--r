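# Evaluation statistics and the bootstrap model-comparison procedure.

#' Harrell's concordance index
#'
#' Proportion of concordant pairs among all comparable pairs. A pair is
#' comparable when the shorter observed time is an event (an event tied
#' with a censored time counts, the event being the shorter); pairs of
#' tied event times are not comparable. A pair is concordant when the
#' shorter-time patient has the higher score; tied scores contribute 0.5.
#' Higher scores are interpreted as higher risk.
#'
#' @param times observed follow-up times.
#' @param events event indicators (1 = event).
#' @param scores risk scores.
#' @return concordance proportion in \[0, 1\].
#' @export
c_index <- function(times, events, scores) {
  n <- length(times)
  stopifnot(length(events) == n, length(scores) == n)
  tm <- matrix(times, n, n)
  ev <- matrix(as.logical(events), n, n)
  comp <- (tm < t(tm) & ev) | (tm == t(tm) & ev & !t(ev))
  sm <- matrix(scores, n, n)
  conc <- (sm > t(sm)) + 0.5 * (sm == t(sm))
  n_comp <- sum(comp)
  if (n_comp == 0)
    stop("no comparable pairs for the concordance index", call. = FALSE)
  sum(conc[comp]) / n_comp
}

#' ROC curve and area under the curve
#'
#' AUC is the Mann-Whitney probability that a random positive scores above
#' a random negative, with the usual 0.5 credit for ties (computed from
#' mid-ranks). Curve points are emitted at every distinct threshold.
#'
#' @param labels binary labels (0/1); both classes must be present.
#' @param scores predicted scores (higher = more likely positive).
#' @return list with `auc` and `roc` (data.frame threshold, fpr, tpr).
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  list(auc = auc, roc = roc)
}

# Dummy-encode a covariate data.frame: characters/factors against a
# declared (or first-level) reference; numerics pass through.
encode_covariates <- function(covariates, reference_levels = NULL) {
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      f <- factor(df[[nm]])
      ref <- reference_levels[[nm]]
      if (!is.null(ref)) f <- stats::relevel(f, ref = ref)
      df[[nm]] <- f
    }
    if (length(unique(df[[nm]])) < 2)
      stop("constant covariate: ", nm, call. = FALSE)
  }
  df
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) via
#' [survival::coxph()]. Categorical covariates are dummy-encoded against a
#' declared reference level. Non-convergence or unidentifiable
#' coefficients raise an error rather than returning silently.
#'
#' @param covariates data.frame of covariates.
#' @param times,events outcome vectors.
#' @param reference_levels optional named list of reference levels for
#'   categorical covariates.
#' @return list with `coefficients`, `linear_predictor` (per patient,
#'   centered as returned by coxph), and the `fit` object.
#' @export
fit_cox <- function(covariates, times, events, reference_levels = NULL) {
  if (sum(events) < 2)
    stop("need at least 2 events to fit a Cox model", call. = FALSE)
  df <- encode_covariates(covariates, reference_levels)
  df$.time <- times; df$.event <- events
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df,
                         ties = "breslow")
  if (any(is.na(stats::coef(fit)))) {
    # exact collinearity: drop the aliased columns and refit, so a
    # redundant covariate degrades to the base model instead of failing
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    keep <- setdiff(names(df), c(aliased, ".time", ".event"))
    if (length(keep) == 0)
      stop("Cox fit produced no identifiable coefficients", call. = FALSE)
    df2 <- df[, c(keep, ".time", ".event"), drop = FALSE]
    fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = df2,
                           ties = "breslow")
    if (any(is.na(stats::coef(fit))))
      stop("Cox fit produced unidentifiable coefficients", call. = FALSE)
  }
  list(coefficients = stats::coef(fit),
       linear_predictor = unname(fit$linear.predictors),
       fit = fit)
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic fit via [stats::glm()], with the same
#' covariate encoding rules as [fit_cox()]. Perfect separation (fitted
#' probabilities collapsing to 0/1) is flagged as an error.
#'
#' @param covariates data.frame of covariates.
#' @param labels binary labels (0/1).
#' @param reference_levels optional named list of reference levels.
#' @return list with `coefficients`, `probabilities`, and the `fit`.
#' @export
fit_logistic <- function(covariates, labels, reference_levels = NULL) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present to fit a logistic model",
         call. = FALSE)
  df <- encode_covariates(covariates, reference_levels)
  df$.y <- labels
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged)
    stop("logistic fit failed (separation or non-convergence)",
         call. = FALSE)
  list(coefficients = stats::coef(fit),
       probabilities = unname(stats::fitted(fit)),
       fit = fit)
}

predict_lp <- function(fit, newdata) {
  unname(stats::predict(fit, newdata = newdata, type = "lp"))
}

#' Bootstrap comparison of models with and without an added covariate
#'
#' Per replicate, `n` patients are drawn with replacement as the training
#' set (covering about 63% of distinct patients); the out-of-bag patients
#' form the test set. A base model and a base+added model (Cox for the
#' survival task, logistic for the binary task) are fit on the training
#' draw and evaluated on the out-of-bag patients by C-index or AUC.
#' Degenerate replicates (out-of-bag with no comparable pairs or a single
#' class, or a failed fit) are redrawn, keeping the effective number of
#' replicates exact; redraws are counted. Point estimates are means over
#' replicates with percentile (2.5/97.5) confidence intervals, and the
#' difference is declared significant when its CI excludes 0. Full-data
#' fits are also evaluated and reported separately. Deterministic given
#' `seed` (including redraws).
#'
#' @param data data.frame containing the covariates plus `followup_time` +
#'   `event` (survival) or `label` (binary).
#' @param base character vector of base covariate names (may be empty).
#' @param added the added covariate name.
#' @param task "survival" or "binary".
#' @param n_boot number of bootstrap replicates (10,000 at full scale).
#' @param seed integer seed.
#' @param reference_levels optional named list passed to the fitters.
#' @return object of class `comparison_result`: a list with `summary`
#'   (data.frame rows without/with/difference: mean, ci_low, ci_high),
#'   `significant`, `full_data` (point estimates from the full-data fit),
#'   `n_redrawn`, `n_boot`, and the per-replicate draws.
#' @export
bootstrap_compare <- function(data, base, added,
                              task = c("survival", "binary"),
                              n_boot = 10000, seed = 1,
                              reference_levels = NULL) {
  task <- match.arg(task)
  n <- nrow(data)
  covs_with <- c(base, added)
  for (v in covs_with)
    if (!v %in% names(data)) stop("covariate not in data: ", v, call. = FALSE)
  keep <- stats::complete.cases(data[, covs_with, drop = FALSE])
  if (task == "survival") keep <- keep & !is.na(data$followup_time) &
      !is.na(data$event) else keep <- keep & !is.na(data$label)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)

  metric_on <- function(fit_obj, rows, covs) {
    nd <- encode_covariates(data[, covs, drop = FALSE], reference_levels)
    if (task == "survival") {
      lp <- predict_lp(fit_obj$fit, nd[rows, , drop = FALSE])
      c_index(data$followup_time[rows], data$event[rows], lp)
    } else {
      pr <- stats::predict(fit_obj$fit, newdata = nd[rows, , drop = FALSE],
                           type = "response")
      roc_auc(data$label[rows], unname(pr))$auc
    }
  }
  fit_on <- function(rows, covs) {
    if (length(covs) == 0) return(NULL)
    d <- data[rows, covs, drop = FALSE]
    if (task == "survival")
      fit_cox(d, data$followup_time[rows], data$event[rows],
              reference_levels)
    else
      fit_logistic(d, data$label[rows], reference_levels)
  }

  without <- with_m <- diff_m <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      ok <- FALSE
      tries <- 0L
      while (!ok) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("bootstrap replicate failed 200 consecutive redraws; ",
               "the cohort cannot support the requested comparison",
               call. = FALSE)
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        res <- tryCatch({
          if (length(oob) < 2) stop("tiny out-of-bag")
          f0 <- fit_on(idx, base)
          f1 <- fit_on(idx, covs_with)
          m0 <- if (is.null(f0)) NA_real_ else metric_on(f0, oob, base)
          m1 <- metric_on(f1, oob, covs_with)
          list(m0 = m0, m1 = m1)
        }, error = function(e) NULL)
        if (!is.null(res)) ok <- TRUE else n_redrawn <- n_redrawn + 1L
      }
      without[b] <- res$m0; with_m[b] <- res$m1
      diff_m[b] <- res$m1 - res$m0
    }
  })

  summarize <- function(x) {
    if (all(is.na(x))) return(c(mean = NA, ci_low = NA, ci_high = NA))
    q <- stats::quantile(x, c(0.025, 0.975), type = 7, na.rm = TRUE)
    c(mean = mean(x), ci_low = unname(q[1]), ci_high = unname(q[2]))
  }
  s0 <- summarize(without); s1 <- summarize(with_m); sd_ <- summarize(diff_m)
  significant <- !is.na(sd_["ci_low"]) &&
    (sd_["ci_low"] > 0 || sd_["ci_high"] < 0)

  all_rows <- seq_len(n)
  fd0 <- if (length(base) > 0) metric_on(fit_on(all_rows, base), all_rows,
                                         base) else NA_real_
  fd1 <- metric_on(fit_on(all_rows, covs_with), all_rows, covs_with)

  structure(list(
    base = base, added = added, task = task,
    metric = if (task == "survival") "c_index" else "auc",
    summary = data.frame(
      quantity = c("without", "with", "difference"),
      mean = c(s0["mean"], s1["mean"], sd_["mean"]),
      ci_low = c(s0["ci_low"], s1["ci_low"], sd_["ci_low"]),
      ci_high = c(s0["ci_high"], s1["ci_high"], sd_["ci_high"]),
      row.names = NULL),
    significant = unname(significant),
    full_data = c(without = fd0, with = fd1),
    n_boot = n_boot, n = n, n_redrawn = n_redrawn,
    replicates = data.frame(without = without, with = with_m,
                            difference = diff_m)),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Bootstrap comparison (%s, %d replicates, n = %d)\n",
              x$metric, x$n_boot, x$n))
  cat(sprintf("  base: %s | added: %s\n",
              if (length(x$base)) paste(x$base, collapse = " + ") else "none",
              x$added))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %6.3f [%6.3f, %6.3f]\n", s$quantity[i], s$mean[i],
                s$ci_low[i], s$ci_high[i]))
  cat(sprintf("  significant: %s (redrawn replicates: %d)\n",
              x$significant, x$n_redrawn))
  invisible(x)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group via [survival::survfit()].
#'
#' @param times,events outcome vectors.
#' @param groups optional group labels (single curve when `NULL`).
#' @return data.frame (group, time, n_risk, n_event, survival) of curve
#'   steps, including the implicit S(0) = 1 step.
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(times))
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  d <- data.frame(.t = times, .e = events, .g = factor(groups))
  out <- NULL
  for (g in levels(d$.g)) {
    sub <- d[d$.g == g, ]
    sf <- survival::survfit(survival::Surv(.t, .e) ~ 1, data = sub)
    out <- rbind(out, data.frame(group = g,
                                 time = c(0, sf$time),
                                 n_risk = c(nrow(sub), sf$n.risk),
                                 n_event = c(0, sf$n.event),
                                 survival = c(1, sf$surv),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Log-rank test
#'
#' Standard k-group log-rank chi-square with k-1 degrees of freedom via
#' [survival::survdiff()].
#'
#' @param times,events outcome vectors.
#' @param groups group labels (at least 2 non-empty groups, at least one
#'   event overall).
#' @return list(statistic, df, p_value).
#' @export
logrank_test <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (sum(events) < 1) stop("no events: log-rank test undefined",
                            call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Tertile categorization with reusable cut points
#'
#' Cuts a continuous predictor at its 33rd and 67th percentiles (linear
#' interpolation between order statistics, quantile type 7) into the
#' intervals (-Inf, q33], (q33, q67], (q67, Inf). The cut points are
#' returned so another cohort can be categorized with the same cut-offs.
#'
#' @param values numeric vector (at least 3 distinct values when cuts are
#'   computed).
#' @param cuts optional precomputed cut points c(q33, q67) for reuse.
#' @return list with `labels` (factor low/intermediate/high) and `cuts`.
#' @export
tertile_categorize <- function(values, cuts = NULL) {
  if (is.null(cuts)) {
    if (length(unique(values)) < 3)
      stop("need at least 3 distinct values for tertile cuts",
           call. = FALSE)
    cuts <- unname(stats::quantile(values, c(0.33, 0.67), type = 7))
    if (cuts[1] >= cuts[2])
      stop("degenerate tertile cut points (too many duplicate values)",
           call. = FALSE)
  }
  labels <- cut(values, breaks = c(-Inf, cuts, Inf),
                labels = c("low", "intermediate", "high"), right = TRUE)
  list(labels = labels, cuts = cuts)
}
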