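# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A tiny rendered cohort on disk with manifest and patch store.
tiny_cohort <- function() {
  memo("tiny_cohort", function() {
    dir <- file.path(tempdir(), "wsisurv_tiny")
    spec <- cohort_spec(n_patients = 12, slide_px = 256, tile_px = 64,
                        beta_risk = 1.0, seed = 21)
    g <- generate_cohort(spec, dir)
    cfg <- tiling_config(tile_px = 64)
    manifest <- suppressMessages(
      build_manifest(g$slide_dir, g$clinical, cfg))
    store <- build_patch_store(g$slide_dir, manifest, 64)
    list(spec = spec, cohort = g, config = cfg, manifest = manifest,
         store = store, dir = dir)
  })
}

# Clinical-only cohorts (no images) are cheap; no memoization needed.
clinical_cohort <- function(n, seed = 1, ...) {
  generate_clinical(cohort_spec(n_patients = n, seed = seed, ...))
}

# Brute-force oracles, kept deliberately independent of the package's
# vectorized implementations.

brute_cox_loss <- function(scores, times, events) {
  n <- length(scores)
  total <- 0
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    risk <- which(times >= times[i])
    total <- total + scores[i] - log(sum(exp(scores[risk])))
  }
  -total / n
}

brute_c_index <- function(times, events, scores) {
  num <- 0; den <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (times[i] < times[j] && events[i] == 1) ||
      (times[i] == times[j] && events[i] == 1 && events[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / den
}

brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
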