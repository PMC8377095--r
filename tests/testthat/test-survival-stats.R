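test_that("concordance index matches hand enumeration and conventions", {
  # perfect anti-ranking of scores and times
  expect_equal(c_index(c(1, 2, 3), c(1, 1, 1), c(9, 5, 1)), 1)
  expect_equal(c_index(c(1, 2, 3), c(1, 1, 1), c(1, 5, 9)), 0)
  # exhaustive hand enumeration: 5 comparable pairs, 3 concordant
  expect_equal(c_index(c(2, 4, 3, 5), c(1, 0, 1, 0), c(3, 1, 0, 2)), 0.6)
  expect_error(c_index(c(1, 2), c(0, 0), c(1, 2)), "comparable")
})

test_that("concordance and AUC match brute-force pair enumeration", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    t_ <- sample(1:6, n, replace = TRUE)
    y <- rbinom(n, 1, 0.6)
    s <- sample(seq(0, 2, 0.5), n, replace = TRUE)  # force score ties
    if (sum(y) == 0) y[1] <- 1
    ci <- tryCatch(c_index(t_, y, s), error = function(e) NULL)
    if (!is.null(ci)) expect_equal(ci, brute_c_index(t_, y, s))
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) == 2)
      expect_equal(roc_auc(lab, s)$auc, brute_auc(lab, s))
  }
})

test_that("c_index(s) + c_index(-s) = 1 without score ties", {
  set.seed(5)
  t_ <- rexp(30); y <- rbinom(30, 1, 0.5); y[1] <- 1; s <- rnorm(30)
  expect_equal(c_index(t_, y, s) + c_index(t_, y, -s), 1)
})

test_that("ROC handles the tie and separation conventions", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0), c(5, 4, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(1, 2)), "both classes")
  roc <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("Kaplan-Meier matches hand product-limit values", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival[km$time %in% c(1, 2, 3)],
               c(2 / 3, 1 / 3, 0))
  # censoring at t=2 shrinks the risk set: S(3) = 2/3 * (1 - 1/1) = 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)
  # all censored: survival stays at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$survival == 1))
  # no censoring: equals the empirical survival function
  set.seed(2)
  t_ <- sort(rexp(40))
  km4 <- km_estimate(t_, rep(1, 40))
  emp <- vapply(km4$time, function(u) mean(t_ > u), numeric(1))
  expect_equal(km4$survival, emp, tolerance = 1e-12)
})

test_that("log-rank test matches the hand-computed two-group statistic", {
  # identical groups: statistic 0, p = 1
  out <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  # A = {1, 2} all events, B = {3, 4} all events; observed-minus-expected
  # table gives O_A = 2, E_A = 1/2 + 1/3, V = 1/4 + 2/9
  oa <- 2; ea <- 1 / 2 + 1 / 3; v <- 1 / 4 + 2 / 9
  out2 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(out2$statistic, (oa - ea)^2 / v, tolerance = 1e-6)
  # label swap symmetry
  out3 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(out2$statistic, out3$statistic)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 groups")
})

test_that("tertile categorization cuts at the 33rd/67th percentiles", {
  out <- tertile_categorize(1:9)
  expect_equal(as.vector(table(out$labels)), c(3L, 3L, 3L))
  expect_equal(out$cuts, unname(quantile(1:9, c(0.33, 0.67))))
  expect_error(tertile_categorize(rep(2, 10)), "distinct")
  # duplicates straddling q33 follow the right-closed interval rule
  v <- c(1, 2, 2, 2, 3, 4, 5, 6, 7)
  out2 <- tertile_categorize(v)
  expect_equal(as.character(out2$labels),
               ifelse(v <= out2$cuts[1], "low",
                      ifelse(v <= out2$cuts[2], "intermediate", "high")))
  # cut points transfer to another cohort unchanged
  out3 <- tertile_categorize(c(0, 3.2, 10), cuts = out2$cuts)
  expect_equal(as.character(out3$labels), c("low", "intermediate", "high"))
})

test_that("cox fitting recovers null and true coefficients with a zero score
           equation", {
  set.seed(13)
  n <- 600
  x <- rnorm(n)
  t_ <- rexp(n, 0.1); y <- rbinom(n, 1, 0.8)
  f <- fit_cox(data.frame(x = x), t_, y)   # x unrelated to outcome
  se <- sqrt(diag(f$fit$var))
  expect_lt(abs(f$coefficients), 3 * se)
  # score equation: brute-force partial-likelihood gradient ~ 0 at beta-hat
  beta <- unname(f$coefficients)
  grad <- 0
  for (i in which(y == 1)) {
    rs <- which(t_ >= t_[i])
    w <- exp(beta * x[rs]); w <- w / sum(w)
    grad <- grad + x[i] - sum(x[rs] * w)
  }
  expect_lt(abs(grad), 1e-5)
  expect_error(fit_cox(data.frame(x = rep(1, n)), t_, y), "constant")
  expect_error(fit_cox(data.frame(x = x), t_, rep(0, n)), "events")
})

test_that("logistic fitting recovers known coefficients and calibrates", {
  set.seed(17)
  n <- 5000
  x <- rnorm(n)
  b0 <- -1.0; b1 <- 0.9   # sized so +/-10% is ~3 standard errors at n=5000
  p <- 1 / (1 + exp(-(b0 + b1 * x)))
  ylab <- rbinom(n, 1, p)
  f <- fit_logistic(data.frame(x = x), ylab)
  expect_lt(abs(f$coefficients["(Intercept)"] - b0) / abs(b0), 0.1)
  expect_lt(abs(f$coefficients["x"] - b1) / b1, 0.1)
  # score-equation identity: mean fitted probability = prevalence
  expect_equal(mean(f$probabilities), mean(ylab), tolerance = 1e-8)
  # null covariate: intercept ~ logit(prevalence), slope ~ 0
  y2 <- rbinom(n, 1, 0.3)
  f2 <- fit_logistic(data.frame(x = x), y2)
  expect_lt(abs(f2$coefficients["x"]), 0.1)
  expect_lt(abs(f2$coefficients["(Intercept)"] -
                log(mean(y2) / (1 - mean(y2)))), 0.15)
  # perfect separation is flagged
  expect_error(fit_logistic(data.frame(x = c(1, 2, 3, 10, 11, 12)),
                            c(0, 0, 0, 1, 1, 1)), "separation")
})

test_that("bootstrap comparison is deterministic and a redundant covariate
           is not flagged", {
  out <- clinical_cohort(150, seed = 23)
  dat <- out$clinical
  dat$z <- out$truth$z_risk
  dat$z_copy <- dat$z
  cmp <- bootstrap_compare(dat, base = "z", added = "z_copy",
                           task = "survival", n_boot = 120, seed = 9)
  expect_false(cmp$significant)
  expect_lte(cmp$summary$ci_low[3], 0)
  expect_gte(cmp$summary$ci_high[3], 0)
  cmp2 <- bootstrap_compare(dat, base = "z", added = "z_copy",
                            task = "survival", n_boot = 120, seed = 9)
  expect_identical(cmp$summary, cmp2$summary)
})

test_that("bootstrap training draws cover ~63% of patients", {
  set.seed(3)
  n <- 296
  fr <- replicate(2000, length(unique(sample.int(n, n, TRUE))) / n)
  expect_lt(abs(mean(fr) - (1 - (1 - 1 / n)^n)), 0.003)
})
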