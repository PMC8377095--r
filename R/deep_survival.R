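# Patient-bag deep survival model: losses, bag sampling, training loop,
# and prediction.

#' Negative log Cox partial likelihood loss
#'
#' Implements
#' \deqn{J = -\frac{1}{n} \sum_i y_i \left[x_i -
#'   \log \sum_{j \in R(T_i)} e^{x_j}\right]}
#' normalized by the batch size `n` (not the event count), with risk set
#' \eqn{R(T_i) = \{j : T_j \ge T_i\}}. Tied event times share the full risk
#' set (Breslow convention). The log-sum-exp is computed with a max shift
#' for numerical stability. Returns 0 when the batch has no events.
#'
#' @param scores risk scores \eqn{x_i} (finite; `NaN` is an error).
#' @param times observed follow-up times \eqn{T_i}.
#' @param events event indicators \eqn{y_i} (1 = death observed).
#' @param gradient if `TRUE`, also return the gradient with respect to the
#'   scores.
#' @return the scalar loss, or `list(loss, grad)` when `gradient = TRUE`.
#' @examples
#' cox_loss(c(1, 0), times = c(1, 2), events = c(1, 1))  # (log(1+e)-1)/2
#' @export
cox_loss <- function(scores, times, events, gradient = FALSE) {
  n <- length(scores)
  stopifnot(n >= 1, length(times) == n, length(events) == n)
  if (any(is.nan(scores)) || any(!is.finite(scores)))
    stop("scores must be finite (no NaN)", call. = FALSE)
  ys <- as.integer(events)
  if (sum(ys) == 0) {
    if (gradient) return(list(loss = 0, grad = numeric(n)))
    return(0)
  }
  ord <- order(times, decreasing = TRUE)
  ts <- times[ord]; xs <- scores[ord]; ye <- ys[ord]
  m <- max(xs)
  ex <- exp(xs - m)
  cs <- cumsum(ex)
  lens <- rle(ts)$lengths
  ends <- cumsum(lens)                    # risk set of group g = 1..ends[g]
  grp <- rep(seq_along(lens), lens)
  dg <- as.vector(rowsum(ye, grp))        # events per tied-time group
  log_s <- m + log(cs[ends])
  loss <- -(sum(ye * xs) - sum(dg * log_s)) / n
  if (!gradient) return(loss)
  vg <- dg / cs[ends]
  suffix <- rev(cumsum(rev(vg)))          # sum over groups whose risk set
  gp <- suffix[grp]                       # contains this position
  grad_sorted <- -(ye - ex * gp) / n
  grad <- numeric(n)
  grad[ord] <- grad_sorted
  list(loss = loss, grad = grad)
}

#' Weighted cross-entropy loss for binary classification
#'
#' Weighted mean of per-sample negative log softmax probabilities, with
#' weights indexed by the true label and normalized by the sum of applied
#' weights. Assigning a larger weight to the minority class counters label
#' imbalance.
#'
#' @param logits n x 2 matrix of class logits.
#' @param labels integer labels in \{0, 1\}.
#' @param class_weights length-2 non-negative weights (for labels 0 and 1).
#' @param gradient if `TRUE`, also return the gradient w.r.t. the logits.
#' @return scalar loss, or `list(loss, grad)`.
#' @export
weighted_ce_loss <- function(logits, labels, class_weights = c(1, 1),
                             gradient = FALSE) {
  logits <- rbind(logits)
  n <- nrow(logits)
  stopifnot(ncol(logits) == 2, length(labels) == n)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be in {0, 1}", call. = FALSE)
  if (any(class_weights < 0) || sum(class_weights) == 0)
    stop("class_weights must be non-negative and not both zero",
         call. = FALSE)
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  logp <- logits - lse
  w <- class_weights[labels + 1]
  nll <- -logp[cbind(seq_len(n), labels + 1)]
  loss <- sum(w * nll) / sum(w)
  if (!gradient) return(loss)
  soft <- exp(logp)
  onehot <- cbind(1 - labels, labels)
  grad <- (soft - onehot) * (w / sum(w))
  list(loss = loss, grad = grad)
}

#' Sample a patch bag for one patient
#'
#' Draws `k` patches uniformly without replacement when the pool has at
#' least `k` patches, with replacement otherwise, pooled across all the
#' patient's slides. Deterministic given `seed`.
#'
#' @param patches array n x px x px x 3 of the patient's kept patches.
#' @param k bag size.
#' @param seed integer seed.
#' @param patient_id used in the error message for an empty pool.
#' @return array k x px x px x 3.
#' @export
sample_bag <- function(patches, k, seed, patient_id = "?") {
  n <- if (is.null(dim(patches))) 0 else dim(patches)[1]
  if (n == 0)
    stop(sprintf("patient %s has zero kept patches", patient_id),
         call. = FALSE)
  idx <- with_seed(seed, {
    if (n >= k) sample(n, k) else sample(n, k, replace = TRUE)
  })
  patches[idx, , , , drop = FALSE]
}

#' Forward one patient bag through the model
#'
#' Embeds each patch with the backbone, average-pools the embeddings over
#' the bag, and applies the head. Permutation-invariant in the bag by
#' construction.
#'
#' @param bag array k x px x px x 3 (or list of px x px x 3 patches, which
#'   must share dimensions).
#' @param model a [risk_model()].
#' @return numeric vector: length 1 (risk score) or 2 (class logits).
#' @export
forward_patient <- function(bag, model) {
  if (is.list(bag)) {
    dims <- lapply(bag, dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) > 1)
      stop("mixed image sizes in bag", call. = FALSE)
    arr <- array(0, dim = c(length(bag), dim(bag[[1]])))
    for (i in seq_along(bag)) arr[i, , , ] <- bag[[i]]
    bag <- arr
  }
  stopifnot(length(dim(bag)) == 4, dim(bag)[1] >= 1)
  emb <- backbone_forward(model, bag)$E
  pooled <- matrix(colMeans(emb), 1)
  drop(head_forward(model, pooled)$scores)
}

#' Load kept patches into an in-memory store
#'
#' Reads each slide once and extracts all kept tiles per the manifest,
#' grouped by patient. The store is the image interface for training and
#' prediction.
#'
#' @param slide_dir directory of slide PNGs.
#' @param manifest manifest from [build_manifest()].
#' @param tile_px tile side length (must match the manifest's grid).
#' @return object of class `patch_store`: per patient, `patches`
#'   (n x px x px x 3 array, 0-255) and `coords` (slide_id, x, y).
#' @export
build_patch_store <- function(slide_dir, manifest, tile_px) {
  kept <- manifest[manifest$kept, , drop = FALSE]
  store <- list()
  for (sid in unique(kept$slide_id)) {
    img <- read_slide_image(file.path(slide_dir, paste0(sid, ".png")))
    rows <- kept[kept$slide_id == sid, , drop = FALSE]
    arr <- array(0, dim = c(nrow(rows), tile_px, tile_px, 3))
    for (i in seq_len(nrow(rows))) {
      arr[i, , , ] <- img[(rows$y[i] + 1):(rows$y[i] + tile_px),
                          (rows$x[i] + 1):(rows$x[i] + tile_px), ]
    }
    pid <- rows$patient_id[1]
    if (is.null(store[[pid]])) {
      store[[pid]] <- list(patches = arr,
                           coords = rows[, c("slide_id", "x", "y")])
    } else {
      old <- store[[pid]]
      comb <- array(0, dim = c(dim(old$patches)[1] + nrow(rows), tile_px,
                               tile_px, 3))
      comb[seq_len(dim(old$patches)[1]), , , ] <- old$patches
      comb[dim(old$patches)[1] + seq_len(nrow(rows)), , , ] <- arr
      store[[pid]] <- list(patches = comb,
                           coords = rbind(old$coords,
                                          rows[, c("slide_id", "x", "y")]))
    }
  }
  attr(store, "tile_px") <- tile_px
  class(store) <- "patch_store"
  store
}

#' Training configuration for the patient-bag model
#'
#' The `"paper"` profile freezes the full-scale hyperparameters (224-px
#' tiles, batch of n = 8 patients x k = 8 patches, learning rates 1e-4
#' (head) / 3e-7 (backbone), L1 strength 0.01, evaluation every 20,480
#' patches, 96,000 steps) for documentation and large-scale use. The
#' `"desk"` profile scales the schedule down to a single-CPU size and is
#' the tested default.
#'
#' @param profile "desk" or "paper".
#' @param n_patients_per_batch,k_patches batch geometry (n patients, k
#'   patches each).
#' @param lr_head,lr_backbone initial Adam learning rates for the fully
#'   connected head and the conv backbone; cosine-annealed to 0 over
#'   `max_steps` (no restarts).
#' @param l1_strength L1 penalty applied to both head weight matrices.
#' @param eval_every_patches validation cadence in patches; must be
#'   divisible by `n_patients_per_batch * k_patches`.
#' @param max_steps total training steps.
#' @param augment apply random horizontal/vertical flips and color jitter
#'   during training.
#' @param jitter color jitter magnitude (relative brightness/contrast).
#' @param class_balance imbalance handling for the binary task:
#'   inverse-frequency down-weighting (default), minority oversampling, or
#'   none.
#' @param checkpoint return the checkpoint with the best validation metric
#'   (default) or the last one.
#' @param stem_pool backbone stem downsampling factor passed to
#'   [risk_model()] (4 by default, mirroring the 4x stem of standard
#'   residual image backbones).
#' @param n_val_patches patches pooled per patient when scoring the
#'   validation group (all, if the patient has fewer).
#' @param seed training seed; fixes batch sampling, augmentation and
#'   initialization.
#' @return object of class `training_config`.
#' @export
training_config <- function(profile = c("desk", "paper"),
                            n_patients_per_batch = NULL,
                            k_patches = NULL,
                            lr_head = NULL,
                            lr_backbone = NULL,
                            l1_strength = NULL,
                            eval_every_patches = NULL,
                            max_steps = NULL,
                            augment = TRUE,
                            jitter = 0.05,
                            class_balance = c("downweight", "oversample",
                                              "none"),
                            checkpoint = c("best", "last"),
                            stem_pool = 4,
                            n_val_patches = 100,
                            seed = 1) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") {
    list(n_patients_per_batch = 8, k_patches = 8, lr_head = 1e-4,
         lr_backbone = 3e-7, l1_strength = 0.01,
         eval_every_patches = 20480, max_steps = 96000)
  } else {
    list(n_patients_per_batch = 8, k_patches = 8, lr_head = 1e-3,
         lr_backbone = 3e-4, l1_strength = 1e-4,
         eval_every_patches = 5120, max_steps = 200)
  }
  cfg <- list(
    profile = profile,
    n_patients_per_batch = n_patients_per_batch %||%
      defaults$n_patients_per_batch,
    k_patches = k_patches %||% defaults$k_patches,
    lr_head = lr_head %||% defaults$lr_head,
    lr_backbone = lr_backbone %||% defaults$lr_backbone,
    l1_strength = l1_strength %||% defaults$l1_strength,
    eval_every_patches = eval_every_patches %||% defaults$eval_every_patches,
    max_steps = max_steps %||% defaults$max_steps,
    augment = isTRUE(augment),
    jitter = jitter,
    class_balance = match.arg(class_balance),
    checkpoint = match.arg(checkpoint),
    stem_pool = stem_pool,
    n_val_patches = check_count(n_val_patches, "n_val_patches", min = 1),
    seed = check_count(seed, "seed", min = 0)
  )
  check_count(cfg$n_patients_per_batch, "n_patients_per_batch", min = 1)
  check_count(cfg$k_patches, "k_patches", min = 1)
  check_positive(cfg$lr_head, "lr_head")
  check_positive(cfg$lr_backbone, "lr_backbone")
  check_positive(cfg$l1_strength, "l1_strength", allow_zero = TRUE)
  check_count(cfg$max_steps, "max_steps", min = 0)
  bp <- cfg$n_patients_per_batch * cfg$k_patches
  if (cfg$eval_every_patches %% bp != 0)
    stop("eval_every_patches must be divisible by the batch patch count (",
         bp, ")", call. = FALSE)
  class(cfg) <- "training_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random flips plus brightness/contrast jitter, training-time only.
# Vectorized over the batch: the batch is the fastest-varying array
# dimension, so per-patch scalars recycle correctly.
augment_patches <- function(patches, jitter) {
  b <- dim(patches)[1]; px <- dim(patches)[2]
  hflip <- stats::runif(b) < 0.5
  vflip <- stats::runif(b) < 0.5
  if (any(hflip))
    patches[hflip, px:1, , ] <- patches[hflip, , , , drop = FALSE]
  if (any(vflip))
    patches[vflip, , px:1, ] <- patches[vflip, , , , drop = FALSE]
  if (jitter > 0) {
    bshift <- stats::runif(b, -jitter, jitter) * 255
    cscale <- exp(stats::runif(b, -jitter, jitter))
    patches <- (patches - 127.5) * cscale + 127.5 + bshift
    patches <- pmin(pmax(patches, 0), 255)   # first arg keeps the dims
  }
  patches
}

#' Train the patient-bag model on one split
#'
#' Per step, `n_patients_per_batch` patients are drawn from the training
#' group and a bag of `k_patches` is sampled per patient; the total loss is
#' the task loss (Cox partial likelihood or weighted cross-entropy) plus an
#' L1 penalty on the head weight matrices. Optimization is Adam with
#' cosine-annealed learning rates (separate rates for head and backbone).
#' The validation metric (C-index or AUC) is computed every
#' `eval_every_patches` patches using a fixed per-patient patch stream, and
#' the checkpoint with the best validation metric is returned (switchable
#' to the last). Deterministic given `config$seed`.
#'
#' @param split data.frame (patient_id, group) for one repetition.
#' @param store a [build_patch_store()] result.
#' @param clinical the clinical table.
#' @param config a [training_config()].
#' @param task "survival" (Cox loss, C-index monitoring) or "biomarker"
#'   (weighted cross-entropy, AUC monitoring).
#' @param model optional pre-built [risk_model()]; one is created otherwise.
#' @return object of class `trained_risk_model`: the selected `model`,
#'   `trace` (per-step loss), `evals` (validation metric trace),
#'   `best_step`, and the config.
#' @export
train_model <- function(split, store, clinical, config,
                        task = c("survival", "biomarker"), model = NULL) {
  task <- match.arg(task)
  tile_px <- attr(store, "tile_px")
  groups <- list(train = split$patient_id[split$group == "train"],
                 val = split$patient_id[split$group == "val"],
                 test = split$patient_id[split$group == "test"])
  train_pts <- intersect(groups$train, names(store))
  dropped <- setdiff(groups$train, names(store))
  if (length(dropped) > 0)
    warning("training patients with zero kept patches dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  ci <- clinical[match(train_pts, clinical$patient_id), ]
  if (task == "biomarker") {
    keep <- !is.na(ci$biomarker)
    train_pts <- train_pts[keep]; ci <- ci[keep, ]
    if (length(unique(ci$biomarker)) < 2)
      stop("training group has a single biomarker class", call. = FALSE)
  } else {
    if (sum(ci$event) < 1)
      stop("no events in training group: Cox loss has no learning signal",
           call. = FALSE)
  }
  if (length(train_pts) < 2)
    stop("training group must contain at least 2 usable patients",
         call. = FALSE)

  if (is.null(model))
    model <- risk_model(input_px = tile_px,
                        output_size = if (task == "survival") 1 else 2,
                        stem_pool = config$stem_pool %||% 4,
                        seed = mix_seed(config$seed, 7))

  class_weights <- c(1, 1)
  sample_prob <- NULL
  if (task == "biomarker") {
    n_by_class <- table(factor(ci$biomarker, levels = 0:1))
    if (config$class_balance == "downweight") {
      class_weights <- as.vector(length(train_pts) / (2 * n_by_class))
    } else if (config$class_balance == "oversample") {
      sample_prob <- as.vector(1 / n_by_class[ci$biomarker + 1])
    }
  }

  state <- adam_init(model$params)
  nb <- config$n_patients_per_batch; k <- config$k_patches
  eval_every <- config$eval_every_patches %/% (nb * k)
  val_pts <- intersect(groups$val, names(store))
  if (task == "biomarker") {
    vb <- clinical$biomarker[match(val_pts, clinical$patient_id)]
    val_pts <- val_pts[!is.na(vb)]
  }

  trace <- data.frame(step = integer(0), loss = numeric(0))
  evals <- data.frame(step = integer(0), metric = numeric(0))
  best <- list(metric = -Inf, params = model$params, step = 0L)

  eval_now <- function(step) {
    if (length(val_pts) == 0) return(invisible(NULL))
    preds <- predict_patients(model, val_pts, mode = "validation",
                              store = store, seed = config$seed,
                              n_val_patches = config$n_val_patches)
    vcl <- clinical[match(preds$patient_id, clinical$patient_id), ]
    metric <- if (task == "survival") {
      if (sum(vcl$event) == 0) return(invisible(NULL))
      c_index(vcl$followup_time, vcl$event, preds$score)
    } else {
      if (length(unique(vcl$biomarker)) < 2) return(invisible(NULL))
      roc_auc(vcl$biomarker, preds$score)$auc
    }
    evals[nrow(evals) + 1L, ] <<- list(step, metric)
    if (metric > best$metric)
      best <<- list(metric = metric, params = model$params, step = step)
    invisible(NULL)
  }

  if (config$max_steps > 0) {
    for (step in seq_len(config$max_steps)) {
      set.seed(mix_seed(config$seed, 11, step))
      take <- sample(seq_along(train_pts), nb,
                     replace = nb > length(train_pts), prob = sample_prob)
      batch_pts <- train_pts[take]
      patches <- array(0, dim = c(nb * k, tile_px, tile_px, 3))
      for (j in seq_len(nb)) {
        bag <- sample_bag(store[[batch_pts[j]]]$patches, k,
                          seed = mix_seed(config$seed, 13, step, j),
                          patient_id = batch_pts[j])
        patches[(j - 1) * k + seq_len(k), , , ] <- bag
      }
      if (config$augment)
        patches <- augment_patches(patches, config$jitter)

      fwd <- backbone_forward(model, patches, keep_cache = TRUE)
      pool_map <- rep(seq_len(nb), each = k)
      pooled <- rowsum(fwd$E, pool_map) / k
      hf <- head_forward(model, pooled)
      bcl <- ci[take, ]
      if (task == "survival") {
        lg <- cox_loss(drop(hf$scores), bcl$followup_time, bcl$event,
                       gradient = TRUE)
        d_scores <- matrix(lg$grad, ncol = 1)
      } else {
        lg <- weighted_ce_loss(hf$scores, bcl$biomarker,
                               class_weights, gradient = TRUE)
        d_scores <- lg$grad
      }
      hb <- head_backward(model, hf, d_scores)
      dE <- hb$dP[pool_map, , drop = FALSE] / k
      grads <- backbone_backward(model, fwd$cache, dE)
      grads[["head1.W"]] <- hb[["head1.W"]]
      grads[["head1.b"]] <- hb[["head1.b"]]
      grads[["head2.W"]] <- hb[["head2.W"]]
      grads[["head2.b"]] <- hb[["head2.b"]]
      pen <- 0
      if (config$l1_strength > 0) {
        pen <- config$l1_strength * (sum(abs(model$params[["head1.W"]])) +
                                     sum(abs(model$params[["head2.W"]])))
        grads[["head1.W"]] <- grads[["head1.W"]] +
          config$l1_strength * sign(model$params[["head1.W"]])
        grads[["head2.W"]] <- grads[["head2.W"]] +
          config$l1_strength * sign(model$params[["head2.W"]])
      }
      lr_by_group <- list(
        head = cosine_lr(config$lr_head, step, config$max_steps),
        backbone = cosine_lr(config$lr_backbone, step, config$max_steps))
      upd <- adam_step(model$params, grads, state, lr_by_group,
                       model$lr_group, step)
      model$params <- upd$params
      state <- upd$state
      trace[nrow(trace) + 1L, ] <- list(step, lg$loss + pen)
      if (step %% eval_every == 0) eval_now(step)
    }
    if (nrow(evals) == 0 || evals$step[nrow(evals)] != config$max_steps)
      eval_now(config$max_steps)
  }

  final_params <- model$params
  if (config$checkpoint == "best" && best$step > 0)
    model$params <- best$params
  if (task == "survival" && config$max_steps > 0) {
    # Anchor the score level: a Cox risk score is identified only up to an
    # additive constant (the partial likelihood is shift-invariant), so the
    # output bias is set to make the mean training-cohort score zero --
    # the same centering convention coxph applies to linear predictors.
    # Without it, independently trained repeats carry arbitrary levels and
    # their pooled out-of-sample means are not comparable across patients.
    tp <- predict_patients(model, train_pts, mode = "test", store = store)
    model$params[["head2.b"]] <- model$params[["head2.b"]] - mean(tp$score)
  }
  structure(list(model = model, final_params = final_params,
                 trace = trace, evals = evals, best_step = best$step,
                 task = task, config = config),
            class = "trained_risk_model")
}

#' Score patients with a trained model
#'
#' Validation mode pools `n_val_patches` randomly sampled patches per
#' patient (all, if the patient has fewer), drawn from a fixed per-patient
#' stream so the monitored metric is comparable across evaluations; test
#' mode pools every kept patch. For a 2-class model the score is the
#' softmax probability of class 1.
#'
#' @param model a [risk_model()] or [train_model()] result.
#' @param patients character vector of patient ids.
#' @param mode "validation" or "test".
#' @param store a [build_patch_store()].
#' @param seed seed for validation-mode patch sampling.
#' @param n_val_patches validation-mode bag cap (100 at full scale).
#' @return data.frame (patient_id, score).
#' @export
predict_patients <- function(model, patients, mode = c("validation", "test"),
                             store, seed = 1, n_val_patches = 100) {
  if (inherits(model, "trained_risk_model")) model <- model$model
  mode <- match.arg(mode)
  scores <- numeric(length(patients))
  for (i in seq_along(patients)) {
    pid <- patients[i]
    entry <- store[[pid]]
    if (is.null(entry) || dim(entry$patches)[1] == 0)
      stop(sprintf("patient %s has zero kept patches", pid), call. = FALSE)
    n <- dim(entry$patches)[1]
    bag <- if (mode == "validation" && n > n_val_patches) {
      idx <- with_seed(mix_seed(seed, 17, string_key(pid)),
                       sample(n, n_val_patches))
      entry$patches[idx, , , , drop = FALSE]
    } else {
      entry$patches
    }
    out <- forward_patient(bag, model)
    scores[i] <- if (model$output_size == 2) {
      1 / (1 + exp(out[1] - out[2]))   # softmax probability of class 1
    } else out
  }
  data.frame(patient_id = patients, score = scores, stringsAsFactors = FALSE)
}

#' Score every kept patch of a slide (heatmap input)
#'
#' Each kept patch is scored as a singleton bag. Because the head is
#' nonlinear, the mean of patch scores does not generally equal the
#' patient-level score of the pooled bag.
#'
#' @param model a [risk_model()] or [train_model()] result.
#' @param store a [build_patch_store()].
#' @param slide_id slide identifier present in the store.
#' @return data.frame (slide_id, x, y, score).
#' @export
score_patches <- function(model, store, slide_id) {
  if (inherits(model, "trained_risk_model")) model <- model$model
  rows <- NULL
  for (pid in names(store)) {
    co <- store[[pid]]$coords
    hit <- which(co$slide_id == slide_id)
    if (length(hit) == 0) next
    sc <- vapply(hit, function(j) {
      out <- forward_patient(store[[pid]]$patches[j, , , , drop = FALSE],
                             model)
      if (model$output_size == 2) 1 / (1 + exp(out[1] - out[2])) else out
    }, numeric(1))
    rows <- rbind(rows, data.frame(slide_id = slide_id, x = co$x[hit],
                                   y = co$y[hit], score = sc,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(rows)) stop("slide has no kept patches: ", slide_id,
                          call. = FALSE)
  rows
}
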