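# Synthetic cohort generator: clinical table, latent risk truth, and slide
# images whose cellularity carries the hazard signal.

#' Specify a synthetic lower-grade-glioma-like cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' emulate the marginal statistics of the TCGA-LGG grade-2 development
#' cohort: 296 patients of whom 49 die during follow-up (event fraction
#' 0.166), 85% biomarker (IDH-mutant) prevalence, age 40.9 +/- 13.0 years,
#' 55.7% men, 91.6% white, and primary diagnoses split
#' 19.9/43.9/36.1% between astrocytoma, oligoastrocytoma and
#' oligodendroglioma.
#'
#' Survival follows a proportional-hazards model: the event time is Weibull
#' (exponential by default, `weibull_shape = 1`) with hazard
#' `baseline_hazard * exp(beta_risk * z + beta_age * age_std)` where `z` is a
#' standardized latent risk covariate, and censoring is administrative,
#' uniform on `(0, censor_horizon)` and independent of covariates. When
#' `baseline_hazard` is `NULL` (the default) it is calibrated by
#' root-finding so the expected event fraction equals
#' `event_target_fraction` given the drawn covariates.
#'
#' Biomarker-positive patients have `z` shifted down by `biomarker_shift`
#' standard deviations (mutants carry a favorable prognosis); the shift is
#' centered so `z` keeps mean zero. Slide images encode `z` through nuclear
#' density (`nuclei_per_tile * exp(density_slope * z)` expected nuclei per
#' fully-tissue tile) and nuclear size (`exp(atypia_slope * z)` radius
#' scale), both strictly increasing in `z`.
#'
#' @param n_patients number of patients.
#' @param event_target_fraction target fraction of observed deaths.
#' @param biomarker_prevalence Bernoulli probability of biomarker = 1.
#' @param biomarker_missing_fraction fraction with missing biomarker status.
#' @param age_mean,age_sd Gaussian age distribution (years).
#' @param male_fraction,white_fraction demographic marginals.
#' @param diagnosis_probs named probabilities over primary diagnoses.
#' @param beta_risk log hazard ratio per unit latent risk `z`.
#' @param beta_age log hazard ratio per standardized age.
#' @param biomarker_shift downward shift of `z` (in SD) for biomarker = 1.
#' @param baseline_hazard events per day, or `NULL` to calibrate against
#'   `event_target_fraction`.
#' @param censor_horizon administrative censoring horizon (days).
#' @param weibull_shape Weibull shape of the event-time distribution
#'   (1 = exponential baseline).
#' @param slide_px slide side length in pixels.
#' @param tile_px tile side length used for nucleus bookkeeping (matches the
#'   tiling grid).
#' @param slides_per_patient number of slides rendered per patient.
#' @param tissue_fraction approximate fraction of the slide covered by
#'   tissue (0 gives an all-background slide).
#' @param nuclei_per_tile expected nuclei per fully-tissue tile at z = 0.
#' @param density_slope log-linear slope of nuclear density in `z`.
#' @param atypia_slope log-linear slope of nuclear radius in `z`.
#' @param seed master seed; per-patient and per-slide streams are derived
#'   from it with counters, so enlarging the cohort never reshuffles
#'   existing patients.
#' @return an object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_patients = 20, slide_px = 256)
#' cohort <- generate_clinical(spec)
#' head(cohort$clinical)
#' @export
cohort_spec <- function(n_patients = 296,
                        event_target_fraction = 49 / 296,
                        biomarker_prevalence = 0.85,
                        biomarker_missing_fraction = 0,
                        age_mean = 40.9,
                        age_sd = 13.0,
                        male_fraction = 0.557,
                        white_fraction = 0.916,
                        diagnosis_probs = c(astrocytoma = 0.199,
                                            oligoastrocytoma = 0.439,
                                            oligodendroglioma = 0.361),
                        beta_risk = 0.7,
                        beta_age = 0.3,
                        biomarker_shift = 0.5,
                        baseline_hazard = NULL,
                        censor_horizon = 3650,
                        weibull_shape = 1,
                        slide_px = 1024,
                        tile_px = 64,
                        slides_per_patient = 1,
                        tissue_fraction = 0.3,
                        nuclei_per_tile = 12,
                        density_slope = 0.35,
                        atypia_slope = 0.12,
                        seed = 1L) {
  spec <- list(
    n_patients = check_count(n_patients, "n_patients", min = 0),
    event_target_fraction = check_proportion(event_target_fraction,
                                             "event_target_fraction"),
    biomarker_prevalence = check_proportion(biomarker_prevalence,
                                            "biomarker_prevalence"),
    biomarker_missing_fraction = check_proportion(
      biomarker_missing_fraction, "biomarker_missing_fraction"),
    age_mean = check_positive(age_mean, "age_mean"),
    age_sd = check_positive(age_sd, "age_sd"),
    male_fraction = check_proportion(male_fraction, "male_fraction"),
    white_fraction = check_proportion(white_fraction, "white_fraction"),
    diagnosis_probs = diagnosis_probs,
    beta_risk = beta_risk,
    beta_age = beta_age,
    biomarker_shift = biomarker_shift,
    baseline_hazard = baseline_hazard,
    censor_horizon = check_positive(censor_horizon, "censor_horizon"),
    weibull_shape = check_positive(weibull_shape, "weibull_shape"),
    slide_px = check_count(slide_px, "slide_px", min = 1),
    tile_px = check_count(tile_px, "tile_px", min = 1),
    slides_per_patient = check_count(slides_per_patient,
                                     "slides_per_patient", min = 1),
    tissue_fraction = check_proportion(tissue_fraction, "tissue_fraction"),
    nuclei_per_tile = check_positive(nuclei_per_tile, "nuclei_per_tile"),
    density_slope = density_slope,
    atypia_slope = atypia_slope,
    seed = check_count(seed, "seed", min = 0)
  )
  if (!is.null(baseline_hazard))
    check_positive(baseline_hazard, "baseline_hazard")
  if (!is.numeric(spec$diagnosis_probs) || is.null(names(spec$diagnosis_probs)) ||
      any(spec$diagnosis_probs < 0) ||
      abs(sum(spec$diagnosis_probs) - 1) > 0.01)
    stop("field 'diagnosis_probs' must be named non-negative probabilities summing to 1",
         call. = FALSE)
  spec$diagnosis_probs <- spec$diagnosis_probs / sum(spec$diagnosis_probs)
  if (!is.numeric(spec$beta_risk) || !is.numeric(spec$beta_age) ||
      !is.finite(spec$beta_risk) || !is.finite(spec$beta_age))
    stop("fields 'beta_risk'/'beta_age' must be finite numbers", call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

empty_clinical <- function() {
  data.frame(patient_id = character(0), followup_time = numeric(0),
             event = integer(0), age = numeric(0), gender = character(0),
             race = character(0), primary_diagnosis = character(0),
             biomarker = integer(0), stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(patient_id = character(0), z_risk = numeric(0),
             true_event_time = numeric(0), nuclear_density = numeric(0),
             atypia_scale = numeric(0), stringsAsFactors = FALSE)
}

# Expected event probability P(T <= C) for Weibull-PH event time with
# rate lambda (scale), shape a, and C ~ Uniform(0, H):
#   P = 1 - (1/H) * int_0^H exp(-lambda * c^a) dc
# Closed form for a = 1, Gauss-Legendre quadrature otherwise.
event_probability <- function(lambda, shape, horizon) {
  if (shape == 1) {
    p <- 1 - (1 - exp(-lambda * horizon)) / (lambda * horizon)
    p[lambda * horizon < 1e-12] <- 0
    return(p)
  }
  k <- 64
  j <- seq_len(k)
  u <- (j - 0.5) / k          # midpoint rule on (0, 1), smooth integrand
  cs <- horizon * u
  surv <- vapply(seq_along(lambda), function(i)
    mean(exp(-lambda[i] * cs^shape)), numeric(1))
  1 - surv
}

# Root-find the baseline hazard whose expected event fraction over the
# drawn covariates equals the target.
calibrate_baseline_hazard <- function(lp, spec) {
  target <- spec$event_target_fraction
  if (target <= 0) return(1e-12)
  f <- function(log_h0) {
    lambda <- exp(log_h0 + lp)
    mean(event_probability(lambda, spec$weibull_shape, spec$censor_horizon)) -
      target
  }
  root <- stats::uniroot(f, lower = log(1e-10), upper = log(10),
                         tol = 1e-10)
  exp(root$root)
}

#' Draw right-censored survival outcomes under the generator's hazard model
#'
#' Event times are Weibull with hazard
#' `baseline_hazard * exp(beta_risk * z_risk + beta_age * age_std)`
#' (exponential when `weibull_shape = 1`); censoring times are uniform on
#' `(0, censor_horizon)`. Returns the observed follow-up `min(T, C)` and the
#' event indicator `1[T <= C]`. Draws use the current RNG state; seed the
#' stream with [set.seed()] (or see [generate_clinical()] which manages
#' per-patient streams).
#'
#' @param z_risk latent risk covariate vector.
#' @param age_std standardized age vector (same length).
#' @param spec a [cohort_spec()]; if `baseline_hazard` is `NULL` it is
#'   calibrated against `event_target_fraction` for the supplied covariates.
#' @return data.frame with columns `followup_time`, `event`, and
#'   `true_event_time` (the uncensored latent time, for oracle checks).
#' @export
sample_survival <- function(z_risk, age_std, spec) {
  stopifnot(length(z_risk) == length(age_std))
  if (!all(is.finite(z_risk)) || !all(is.finite(age_std)))
    stop("covariates must be finite", call. = FALSE)
  lp <- spec$beta_risk * z_risk + spec$beta_age * age_std
  h0 <- spec$baseline_hazard
  if (is.null(h0)) h0 <- calibrate_baseline_hazard(lp, spec)
  lambda <- h0 * exp(lp)
  e <- stats::rexp(length(lp))
  t_event <- (e / lambda)^(1 / spec$weibull_shape)
  c_time <- stats::runif(length(lp), 0, spec$censor_horizon)
  data.frame(followup_time = pmin(t_event, c_time),
             event = as.integer(t_event <= c_time),
             true_event_time = t_event)
}

#' Generate the clinical and latent-truth tables of a synthetic cohort
#'
#' Draws demographics, biomarker status and latent risk per patient from
#' independent counter-derived streams, calibrates the baseline hazard so
#' the expected event fraction matches `spec$event_target_fraction`, and
#' draws right-censored proportional-hazards outcomes. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `clinical` (patient_id, followup_time, event,
#'   age, gender, race, primary_diagnosis, biomarker) and `truth`
#'   (patient_id, z_risk, true_event_time, nuclear_density, atypia_scale),
#'   plus the calibrated `baseline_hazard` as an attribute of `truth`.
#' @export
generate_clinical <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  if (n == 0) return(list(clinical = empty_clinical(), truth = empty_truth()))

  diagnoses <- names(spec$diagnosis_probs)
  cum_diag <- cumsum(spec$diagnosis_probs)

  age <- numeric(n); male <- logical(n); white <- logical(n)
  diagnosis <- character(n); biomarker <- integer(n); missing_bm <- logical(n)
  z0 <- numeric(n); e_draw <- numeric(n); u_censor <- numeric(n)

  for (i in seq_len(n)) {
    with_seed(mix_seed(spec$seed, 101, i), {
      age[i] <- stats::rnorm(1, spec$age_mean, spec$age_sd)
      male[i] <- stats::runif(1) < spec$male_fraction
      white[i] <- stats::runif(1) < spec$white_fraction
      diagnosis[i] <- diagnoses[findInterval(stats::runif(1), cum_diag) + 1L]
      biomarker[i] <- as.integer(stats::runif(1) < spec$biomarker_prevalence)
      missing_bm[i] <- stats::runif(1) < spec$biomarker_missing_fraction
      z0[i] <- stats::rnorm(1)
      e_draw[i] <- stats::rexp(1)
      u_censor[i] <- stats::runif(1)
    })
  }

  # Centered biomarker shift keeps z mean-zero while giving biomarker = 1
  # patients systematically lower latent risk.
  z <- z0 - spec$biomarker_shift * (biomarker - spec$biomarker_prevalence)
  age_std <- (age - spec$age_mean) / spec$age_sd
  lp <- spec$beta_risk * z + spec$beta_age * age_std
  h0 <- spec$baseline_hazard
  if (is.null(h0)) h0 <- calibrate_baseline_hazard(lp, spec)

  lambda <- h0 * exp(lp)
  t_event <- (e_draw / lambda)^(1 / spec$weibull_shape)
  c_time <- u_censor * spec$censor_horizon
  followup <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)

  ids <- sprintf("P%04d", seq_len(n))
  clinical <- data.frame(
    patient_id = ids,
    followup_time = followup,
    event = event,
    age = age,
    gender = ifelse(male, "male", "female"),
    race = ifelse(white, "white", "other"),
    primary_diagnosis = diagnosis,
    biomarker = ifelse(missing_bm, NA_integer_, biomarker),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = ids,
    z_risk = z,
    true_event_time = t_event,
    nuclear_density = spec$nuclei_per_tile * exp(spec$density_slope * z),
    atypia_scale = exp(spec$atypia_slope * z),
    stringsAsFactors = FALSE
  )
  attr(truth, "baseline_hazard") <- h0
  list(clinical = clinical, truth = truth)
}

# Boolean tissue mask built from 1-3 random ellipses whose combined area
# approximates tissue_fraction of the slide. Returns an sp x sp matrix.
make_tissue_mask <- function(sp, tissue_fraction) {
  mask <- matrix(FALSE, sp, sp)
  if (tissue_fraction <= 0) return(mask)
  n_blob <- sample(1:3, 1)
  area_each <- tissue_fraction * sp^2 / n_blob
  xs <- matrix(rep(seq_len(sp), each = sp), sp, sp)   # column index
  ys <- matrix(rep(seq_len(sp), sp), sp, sp)          # row index
  for (b in seq_len(n_blob)) {
    ecc <- stats::runif(1, 0.6, 1.6)
    a <- sqrt(area_each / (pi * ecc))        # semi-axes: a, a * ecc
    bax <- a * ecc
    cx <- stats::runif(1, 0.25 * sp, 0.75 * sp)
    cy <- stats::runif(1, 0.25 * sp, 0.75 * sp)
    th <- stats::runif(1, 0, pi)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    mask <- mask | ((u / a)^2 + (v / bax)^2 <= 1)
  }
  mask
}

# Linear pixel indices of one elliptical nucleus centered at (row, col)
# with radius r, in an sp x sp image (column-major).
nucleus_pixels <- function(row, col, r, sp) {
  ecc <- stats::runif(1, 0.65, 1)
  th <- stats::runif(1, 0, pi)
  rmax <- ceiling(r / min(ecc, 1)) + 1L
  r0 <- max(1L, row - rmax); r1 <- min(sp, row + rmax)
  c0 <- max(1L, col - rmax); c1 <- min(sp, col + rmax)
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rep(rr - row, length(cc)), length(rr), length(cc))
  dx <- matrix(rep(cc - col, each = length(rr)), length(rr), length(cc))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / r)^2 + (v / (r * ecc))^2 <= 1
  lin <- outer(rr, (cc - 1L) * sp, `+`)
  lin[inside]
}

#' Render one synthetic slide image for a patient
#'
#' Produces an RGB image with a near-white background and one or more
#' eosin-pink tissue regions containing dark elliptical nuclei. Per tile of
#' the tiling grid, the nucleus count is Poisson with mean
#' `nuclear_density * (tile tissue fraction)`; nucleus radii scale with
#' `atypia_scale`. The returned count record lists exactly the drawn nuclei
#' per tile. Deterministic given `seed`.
#'
#' @param truth one row of the truth table from [generate_clinical()] (or
#'   any list with `z_risk`, `nuclear_density`, `atypia_scale`).
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this slide.
#' @param path optional PNG output path; written when non-`NULL`.
#' @return list with `image` (slide_px x slide_px x 3 array, 0-255),
#'   `counts` (data.frame tile_x, tile_y, n_nuclei; 0-based pixel origins),
#'   and `n_total`.
#' @export
render_slide <- function(truth, spec, seed, path = NULL) {
  sp <- spec$slide_px; tp <- spec$tile_px
  if (sp < tp)
    stop("slide_px is smaller than one tile", call. = FALSE)
  with_seed(seed, {
    # background: near-white with slight sensor noise
    chans <- lapply(1:3, function(ch)
      matrix(251 + stats::rnorm(sp * sp, 0, 1.5), sp, sp))
    mask <- make_tissue_mask(sp, spec$tissue_fraction)
    if (any(mask)) {
      pink <- c(231, 158, 186)  # eosin-like matrix
      for (ch in 1:3) {
        noise <- stats::rnorm(sum(mask), 0, 7)
        chans[[ch]][mask] <- pink[ch] + noise
      }
    }
    nt <- sp %/% tp
    tiles <- expand.grid(tx = seq_len(nt) - 1L, ty = seq_len(nt) - 1L)
    counts <- integer(nrow(tiles))
    nuc_idx <- vector("list", 0)
    nuc_col <- vector("list", 0)
    for (t in seq_len(nrow(tiles))) {
      rows <- (tiles$ty[t] * tp + 1L):(tiles$ty[t] * tp + tp)
      cols <- (tiles$tx[t] * tp + 1L):(tiles$tx[t] * tp + tp)
      sub <- mask[rows, cols]
      tf <- mean(sub)
      if (tf == 0) next
      cnt <- stats::rpois(1, truth$nuclear_density * tf)
      if (cnt == 0) next
      pos <- which(sub)
      centers <- sample(pos, cnt, replace = TRUE)
      cr <- ((centers - 1L) %% tp) + 1L
      cc <- ((centers - 1L) %/% tp) + 1L
      for (m in seq_len(cnt)) {
        r_nuc <- 2.4 * truth$atypia_scale * stats::runif(1, 0.75, 1.3)
        px <- nucleus_pixels(rows[1] - 1L + cr[m], cols[1] - 1L + cc[m],
                             r_nuc, sp)
        nuc_idx[[length(nuc_idx) + 1L]] <- px
        nuc_col[[length(nuc_col) + 1L]] <-
          c(72, 48, 112) + stats::rnorm(3, 0, 6)   # hematoxylin-like
      }
      counts[t] <- cnt
    }
    if (length(nuc_idx) > 0) {
      idx_all <- unlist(nuc_idx)
      lens <- lengths(nuc_idx)
      colm <- do.call(rbind, nuc_col)
      for (ch in 1:3)
        chans[[ch]][idx_all] <- rep(colm[, ch], lens)
    }
    img <- array(0, dim = c(sp, sp, 3))
    for (ch in 1:3) img[, , ch] <- pmin(255, pmax(0, chans[[ch]]))
    if (!is.null(path)) png::writePNG(img / 255, path)
    list(image = img,
         counts = data.frame(tile_x = tiles$tx * tp, tile_y = tiles$ty * tp,
                             n_nuclei = counts),
         n_total = sum(counts))
  })
}

#' Generate a full synthetic cohort on disk
#'
#' Convenience wrapper: generates the clinical and truth tables, renders
#' `slides_per_patient` slides per patient as PNGs named
#' `<patient_id>_<slide_idx>.png`, and writes `clinical.csv` / `truth.csv`.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if missing).
#' @return list with `clinical`, `truth`, `slide_dir`, `counts` (per-slide
#'   nucleus count records, named by slide file).
#' @export
generate_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slide_dir <- file.path(dir, "slides")
  dir.create(slide_dir, showWarnings = FALSE)
  tabs <- generate_clinical(spec)
  counts <- list()
  if (nrow(tabs$clinical) > 0) {
    for (i in seq_len(nrow(tabs$truth))) {
      for (s in seq_len(spec$slides_per_patient)) {
        fn <- sprintf("%s_%d.png", tabs$truth$patient_id[i], s)
        res <- render_slide(tabs$truth[i, ], spec,
                            seed = mix_seed(spec$seed, 202, i, s),
                            path = file.path(slide_dir, fn))
        counts[[fn]] <- res$counts
      }
    }
  }
  utils::write.csv(tabs$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  list(clinical = tabs$clinical, truth = tabs$truth, slide_dir = slide_dir,
       counts = counts)
}
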