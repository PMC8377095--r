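test_that("cox loss reproduces hand-enumerated risk sets", {
  # two patients, both events: risk sets {1,2} then {2}
  expect_equal(cox_loss(c(1, 0), times = c(1, 2), events = c(1, 1)),
               (log(1 + exp(1)) - 1) / 2, tolerance = 1e-12)
  # single patient: the risk set is the patient itself
  expect_equal(cox_loss(5, times = 3, events = 1), 0)
  # no events: zero loss and zero gradient
  out <- cox_loss(c(1, 2, 3), times = c(1, 2, 3), events = c(0, 0, 0),
                  gradient = TRUE)
  expect_equal(out$loss, 0)
  expect_equal(out$grad, c(0, 0, 0))
  expect_error(cox_loss(c(NaN, 1), c(1, 2), c(1, 0)), "finite")
})

test_that("cox loss matches the brute-force oracle on random batches", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    x <- rnorm(n, sd = 2)
    t_ <- sample(1:5, n, replace = TRUE)  # force tied times
    y <- rbinom(n, 1, 0.6)
    expect_equal(cox_loss(x, t_, y), brute_cox_loss(x, t_, y),
                 tolerance = 1e-10)
  }
})

test_that("cox loss is invariant to score shifts and gradient is exact", {
  set.seed(7)
  x <- rnorm(8); t_ <- rexp(8); y <- rbinom(8, 1, 0.5); y[1] <- 1
  expect_equal(cox_loss(x, t_, y), cox_loss(x + 3.7, t_, y),
               tolerance = 1e-10)
  g <- cox_loss(x, t_, y, gradient = TRUE)$grad
  for (i in seq_along(x)) {
    e <- 1e-6
    xp <- x; xp[i] <- x[i] + e
    xm <- x; xm[i] <- x[i] - e
    expect_equal(g[i], (cox_loss(xp, t_, y) - cox_loss(xm, t_, y)) / (2 * e),
                 tolerance = 1e-5)
  }
})

test_that("weighted cross-entropy handles weights, masking and hand values", {
  expect_equal(weighted_ce_loss(matrix(0, 4, 2), c(0, 1, 0, 1)), log(2),
               tolerance = 1e-12)
  # hand softmax arithmetic: logits (2,0) label 0 weight 1; (0,1) label 1 w 3
  l <- matrix(c(2, 0, 0, 1), 2, 2, byrow = TRUE)
  hand <- (1 * -log(exp(2) / (exp(2) + 1)) +
           3 * -log(exp(1) / (1 + exp(1)))) / 4
  expect_equal(weighted_ce_loss(l, c(0, 1), c(1, 3)), hand,
               tolerance = 1e-12)
  # zero weight on class 1 masks those samples entirely
  set.seed(1)
  lg <- matrix(rnorm(10), 5, 2)
  lab <- c(0, 1, 0, 1, 0)
  masked <- weighted_ce_loss(lg, lab, c(1, 0))
  only0 <- weighted_ce_loss(lg[lab == 0, ], lab[lab == 0], c(1, 1))
  expect_equal(masked, only0, tolerance = 1e-12)
  expect_error(weighted_ce_loss(lg, c(0, 1, 2, 1, 0)), "labels")
  expect_error(weighted_ce_loss(lg, lab, c(0, 0)), "weights")
})

test_that("bag sampling is exhaustive, fills with replacement, and is deterministic", {
  set.seed(2)
  pool <- array(runif(3 * 8 * 8 * 3), dim = c(3, 8, 8, 3))
  # pool exactly k: the bag is the pool in some order
  b <- sample_bag(pool, 3, seed = 9)
  expect_equal(dim(b), dim(pool))
  expect_equal(apply(b, 1, sum)[order(apply(b, 1, sum))],
               apply(pool, 1, sum)[order(apply(pool, 1, sum))])
  # pool of 3, k = 8: all 8 drawn from the 3 unique patches
  b8 <- sample_bag(pool, 8, seed = 9)
  sums <- apply(b8, 1, sum)
  expect_equal(dim(b8)[1], 8)
  expect_true(all(sums %in% apply(pool, 1, sum)))
  expect_identical(sample_bag(pool, 8, seed = 4), sample_bag(pool, 8, seed = 4))
  expect_error(sample_bag(array(0, c(0, 8, 8, 3)), 4, seed = 1, "P77"),
               "P77")
})

test_that("patient forward pass is a pooled, permutation-invariant bag score", {
  m <- risk_model(input_px = 16, embed_dim = 8, channels = c(2, 2, 2),
                  head_hidden = 4, seed = 3)
  set.seed(4)
  bag <- array(runif(4 * 16 * 16 * 3, 0, 255), dim = c(4, 16, 16, 3))
  s <- forward_patient(bag, m)
  expect_equal(forward_patient(bag[c(3, 1, 4, 2), , , ], m), s)
  # one patch repeated k times equals the singleton bag
  one <- bag[1, , , , drop = FALSE]
  rep4 <- bag[c(1, 1, 1, 1), , , ]
  expect_equal(forward_patient(rep4, m),
               forward_patient(one, m), tolerance = 1e-12)
  # duplicating the whole bag changes nothing
  expect_equal(forward_patient(bag[rep(1:4, 2), , , ], m), s,
               tolerance = 1e-12)
  expect_error(forward_patient(list(array(0, c(8, 8, 3)),
                                    array(0, c(16, 16, 3))), m), "mixed")
})

test_that("a stubbed backbone with fixed head weights gives the hand value", {
  # backbone: per-channel mean; head: identity-ish linear maps
  stub <- function(patch) c(mean(patch[, , 1]), mean(patch[, , 2]),
                            mean(patch[, , 3]))
  m <- risk_model(input_px = 8, output_size = 1, embed_dim = 3,
                  head_hidden = 3, seed = 1, custom_backbone = stub)
  m$params[["head1.W"]] <- diag(3)
  m$params[["head1.b"]] <- rep(0, 3)
  m$params[["head2.W"]] <- matrix(c(0.5, -0.25, 2), 3, 1)
  m$params[["head2.b"]] <- 1
  bag <- array(0, dim = c(2, 8, 8, 3))
  bag[1, , , 1] <- 10; bag[1, , , 2] <- 20; bag[1, , , 3] <- 30
  bag[2, , , 1] <- 50; bag[2, , , 2] <- 40; bag[2, , , 3] <- 10
  # pooled embedding (30, 30, 20); relu passthrough; dot + 1
  expect_equal(forward_patient(bag, m),
               30 * 0.5 - 30 * 0.25 + 20 * 2 + 1, tolerance = 1e-12)
  # mean of patch scores differs from the pooled-bag score once the head
  # is nonlinear: a hidden-unit bias puts one patch below the ReLU cut
  # and the other above it
  m$params[["head1.b"]] <- c(0, -25, 0)
  m$params[["head2.W"]] <- matrix(c(1, 1, 1), 3, 1)
  m$params[["head2.b"]] <- 0
  s_pool <- forward_patient(bag, m)
  s_each <- c(forward_patient(bag[1, , , , drop = FALSE], m),
              forward_patient(bag[2, , , , drop = FALSE], m))
  expect_false(isTRUE(all.equal(mean(s_each), s_pool)))
})

test_that("training with zero steps is a no-op and errors without events", {
  fx <- tiny_cohort()
  split <- block_split(fx$cohort$clinical, seed = 2)
  cfg <- training_config(max_steps = 0, seed = 5)
  mdl <- risk_model(input_px = 64, seed = 77)
  tr <- train_model(split, fx$store, fx$cohort$clinical, cfg,
                    task = "survival", model = mdl)
  expect_identical(tr$model$params, mdl$params)

  clin0 <- fx$cohort$clinical
  clin0$event <- 0
  expect_error(train_model(split, fx$store, clin0, cfg, task = "survival"),
               "events")
})

test_that("training runs deterministically and returns a usable trace", {
  fx <- tiny_cohort()
  split <- block_split(fx$cohort$clinical, seed = 2)
  cfg <- training_config(max_steps = 6, eval_every_patches = 192,
                         n_patients_per_batch = 3, k_patches = 4,
                         seed = 5)
  tr1 <- train_model(split, fx$store, fx$cohort$clinical, cfg,
                     task = "survival")
  tr2 <- train_model(split, fx$store, fx$cohort$clinical, cfg,
                     task = "survival")
  expect_identical(tr1$model$params, tr2$model$params)
  expect_identical(tr1$trace, tr2$trace)
  expect_equal(nrow(tr1$trace), 6)
  expect_true(all(is.finite(tr1$trace$loss)))
})

test_that("prediction modes follow the patch-pooling contract", {
  fx <- tiny_cohort()
  m <- risk_model(input_px = 64, seed = 8)
  pts <- names(fx$store)[1:3]
  # test mode pools every kept patch: equals forward_patient on full pool
  pr <- predict_patients(m, pts, mode = "test", store = fx$store)
  for (i in seq_along(pts))
    expect_equal(pr$score[i],
                 forward_patient(fx$store[[pts[i]]]$patches, m))
  # validation mode with fewer patches than the cap uses all of them
  n1 <- dim(fx$store[[pts[1]]]$patches)[1]
  expect_lt(n1, 100)
  pv <- predict_patients(m, pts, mode = "validation", store = fx$store,
                         seed = 3)
  expect_equal(pv$score[1], pr$score[1])
  # with a cap below the pool size, sampling is seed-deterministic
  pv1 <- predict_patients(m, pts, mode = "validation", store = fx$store,
                          seed = 3, n_val_patches = 2)
  pv2 <- predict_patients(m, pts, mode = "validation", store = fx$store,
                          seed = 3, n_val_patches = 2)
  expect_identical(pv1, pv2)
  expect_error(predict_patients(m, pts, mode = "bogus", store = fx$store))
})

test_that("patch scoring emits one row per kept patch and is constant on
           homogeneous input with a stub backbone", {
  fx <- tiny_cohort()
  m <- risk_model(input_px = 64, seed = 8)
  sid <- fx$manifest$slide_id[which(fx$manifest$kept)[1]]
  rows <- score_patches(m, fx$store, sid)
  expect_equal(nrow(rows), sum(fx$manifest$kept[fx$manifest$slide_id == sid]))

  stub <- function(patch) rep(1, 4)
  ms <- risk_model(input_px = 64, embed_dim = 4, head_hidden = 2, seed = 1,
                   custom_backbone = stub)
  rows2 <- score_patches(ms, fx$store, sid)
  expect_equal(length(unique(rows2$score)), 1)
})

test_that("training config validates batch geometry", {
  expect_error(training_config(eval_every_patches = 100), "divisible")
  cfg <- training_config(profile = "paper")
  expect_equal(cfg$lr_head, 1e-4)
  expect_equal(cfg$lr_backbone, 3e-7)
  expect_equal(cfg$l1_strength, 0.01)
  expect_equal(cfg$eval_every_patches, 20480)
  expect_equal(cfg$max_steps, 96000)
})
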