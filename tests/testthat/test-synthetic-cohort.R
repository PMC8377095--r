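test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(event_target_fraction = 1.2),
               "event_target_fraction")
  expect_error(cohort_spec(n_patients = -1), "n_patients")
  expect_error(cohort_spec(slide_px = 0), "slide_px")
  expect_error(cohort_spec(baseline_hazard = -2), "baseline_hazard")
  expect_error(cohort_spec(biomarker_prevalence = 2), "biomarker_prevalence")
})

test_that("empty cohort yields two empty tables with the full schema", {
  out <- generate_clinical(cohort_spec(n_patients = 0))
  expect_equal(nrow(out$clinical), 0)
  expect_equal(nrow(out$truth), 0)
  expect_true(all(c("patient_id", "followup_time", "event", "age", "gender",
                    "race", "primary_diagnosis", "biomarker") %in%
                  names(out$clinical)))
  expect_true(all(c("patient_id", "z_risk", "true_event_time",
                    "nuclear_density", "atypia_scale") %in%
                  names(out$truth)))
})

test_that("same spec and seed give byte-identical tables", {
  spec <- cohort_spec(n_patients = 40, seed = 5)
  expect_identical(generate_clinical(spec), generate_clinical(spec))
})

test_that("default marginals calibrate to the cohort targets", {
  n <- 1500
  out <- generate_clinical(cohort_spec(n_patients = n, seed = 3))
  cl <- out$clinical
  # 3 Monte-Carlo standard errors around each target
  tol <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cl$event) - 49 / 296), tol(49 / 296))
  expect_lt(abs(mean(cl$biomarker) - 0.85), tol(0.85))
  expect_lt(abs(mean(cl$gender == "male") - 0.557), tol(0.557))
  expect_lt(abs(mean(cl$race == "white") - 0.916), tol(0.916))
  expect_lt(abs(mean(cl$age) - 40.9), 3 * 13 / sqrt(n))
  expect_lt(abs(sd(cl$age) - 13.0), 1.0)
  # biomarker-positive patients carry lower latent risk
  z <- out$truth$z_risk
  expect_lt(mean(z[cl$biomarker == 1]), mean(z[cl$biomarker == 0]))
})

test_that("survival draws follow the exponential closed form", {
  spec <- cohort_spec(beta_risk = 0, beta_age = 0, baseline_hazard = 1e-3,
                      censor_horizon = 1e9)
  set.seed(11)
  out <- sample_survival(rep(0, 20000), rep(0, 20000), spec)
  expect_true(all(out$event == 1))  # horizon far beyond any event time
  expect_lt(abs(median(out$followup_time) - log(2) / 1e-3), 25)
})

test_that("latent risk orders event times and has null concordance when off", {
  spec <- cohort_spec(beta_risk = 1, beta_age = 0, baseline_hazard = 1e-3,
                      censor_horizon = 1e9)
  set.seed(4)
  z <- rnorm(5000)
  out <- sample_survival(z, rep(0, 5000), spec)
  top <- z >= quantile(z, 2 / 3); bottom <- z <= quantile(z, 1 / 3)
  expect_lt(mean(out$followup_time[top]), mean(out$followup_time[bottom]))

  spec0 <- cohort_spec(beta_risk = 0, beta_age = 0, baseline_hazard = 1e-3)
  set.seed(5)
  out0 <- sample_survival(z, rep(0, 5000), spec0)
  c0 <- c_index(out0$followup_time, out0$event, z)
  expect_lt(abs(c0 - 0.5), 0.03)
})

test_that("nuclear density and atypia increase strictly with latent risk", {
  out <- generate_clinical(cohort_spec(n_patients = 200, seed = 9))
  ord <- order(out$truth$z_risk)
  expect_true(all(diff(out$truth$nuclear_density[ord]) > 0))
  expect_true(all(diff(out$truth$atypia_scale[ord]) > 0))
})

test_that("rendered slides keep exact nucleus bookkeeping and determinism", {
  fx <- tiny_cohort()
  res <- render_slide(fx$cohort$truth[1, ], fx$spec, seed = 77)
  expect_equal(sum(res$counts$n_nuclei), res$n_total)
  res2 <- render_slide(fx$cohort$truth[1, ], fx$spec, seed = 77)
  expect_identical(res$image, res2$image)
  expect_true(all(res$image >= 0 & res$image <= 255))
})

test_that("zero tissue fraction gives an all-background slide", {
  spec0 <- cohort_spec(n_patients = 1, slide_px = 192, tile_px = 64,
                       tissue_fraction = 0, seed = 2)
  tr <- generate_clinical(spec0)$truth
  res <- render_slide(tr[1, ], spec0, seed = 1)
  expect_equal(res$n_total, 0)
  man <- tile_slide(res$image, tiling_config(tile_px = 64))
  expect_equal(sum(man$kept), 0)
})

test_that("a slide smaller than one tile is rejected", {
  spec <- cohort_spec(n_patients = 1, slide_px = 32, tile_px = 64)
  tr <- generate_clinical(spec)$truth
  expect_error(render_slide(tr[1, ], spec, seed = 1), "smaller")
})

test_that("mean per-tile nucleus count increases with latent risk", {
  spec <- cohort_spec(n_patients = 14, slide_px = 256, tile_px = 64,
                      tissue_fraction = 0.5, seed = 6)
  out <- generate_clinical(spec)
  dens <- vapply(seq_len(14), function(i) {
    r <- render_slide(out$truth[i, ], spec, seed = 500 + i)
    tiles <- r$counts$n_nuclei
    mean(tiles)
  }, numeric(1))
  expect_gt(cor(dens, out$truth$z_risk, method = "spearman"), 0.5)
})

test_that("cox fit on true latent risk recovers the generator coefficient", {
  ests <- ses <- numeric(3)
  for (s in 1:3) {
    spec <- cohort_spec(n_patients = 2000, seed = s)
    out <- generate_clinical(spec)
    age_std <- (out$clinical$age - spec$age_mean) / spec$age_sd
    f <- fit_cox(data.frame(z = out$truth$z_risk, age_std = age_std),
                 out$clinical$followup_time, out$clinical$event)
    ests[s] <- f$coefficients["z"]
    ses[s] <- sqrt(diag(f$fit$var))[1]
  }
  # each fit within 3 standard errors; seed-averaged estimate within 15%
  expect_true(all(abs(ests - 0.7) < 3 * ses))
  expect_lt(abs(mean(ests) - 0.7) / 0.7, 0.15)
})
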