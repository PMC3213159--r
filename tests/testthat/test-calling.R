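# deterministic background spread used to give columns a non-trivial sd
bg <- function(n) 0.25 * scale(seq_len(n) %% 7 - 3, scale = FALSE)[, 1]

test_that("stringent criteria call exactly the intended strains", {
  n <- 12
  strains <- sprintf("s%02d", 1:n)
  f4 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f3 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f2 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f4[1, ] <- -2                 # s01: textbook defect, all criteria pass
  f2[1, ] <- -0.1
  f4[2, ] <- -2                 # s02: fails criterion 2 in both replicates
  f3[2, ] <- -2
  f4[3, ] <- -2                 # s03: equal low/severe defect, crit 3 tie
  f2[3, ] <- -2
  f4[4, 1] <- -2                # s04: passes in 1 of 2 replicates only
  f2[4, 1] <- -0.1
  ft <- make_test_ft(list(S4vS3 = f4, S3vS1 = f3, S2vS1 = f2))
  cs <- call_stringent(ft, "NaCl")
  expect_setequal(cs$called, "s01")
  aud <- cs$audit
  expect_equal(aud$n_replicates_passing[aud$strain == "s04"], 1L)
  expect_equal(aud$route[aud$strain == "s01"], "stringent")
  # the caller agrees with the literal per-strain re-evaluation
  expect_setequal(cs$called, oracle_calls(ft, "NaCl"))
  expect_error(call_stringent(ft, "DTT"), "missing required")
})

test_that("correlation expansion adds correlated, guarded strains only", {
  n <- 12
  strains <- sprintf("s%02d", 1:n)
  f4 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f3 <- matrix(0.05 * rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f2 <- matrix(0.05 * rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f4[1, ] <- -2; f2[1, ] <- -0.1          # called stringently
  f4[2, ] <- c(-2, NA); f2[2, ] <- -0.1   # 1 replicate: correlated twin
  f3[2, 1] <- f3[1, 1]; f2[2, 1] <- f2[1, 1]
  f4[2, 1] <- f4[1, 1]
  # s03: profile proportional to s01's (high uncentered r) but the severe
  # defect is far too weak to satisfy the criterion-1 guard
  f4[3, ] <- -0.45; f3[3, ] <- f3[1, ]; f2[3, ] <- f2[1, ]
  ft <- make_test_ft(list(S4vS3 = f4, S3vS1 = f3, S2vS1 = f2))
  cs <- call_stringent(ft, "NaCl")
  expect_setequal(cs$called, "s01")
  ex <- expand_by_correlation(cs, ft, r_min = 0.95)
  expect_true("s02" %in% ex$called)       # identical profile, crit-1 guard ok
  expect_false("s03" %in% ex$called)      # guard: z(S4vS3) > -1 everywhere
  expect_true(ex$audit$added_by_correlation[ex$audit$strain == "s02"])
  # empty stringent set: expansion is a no-op
  none <- cs; none$called <- character()
  expect_equal(expand_by_correlation(none, ft)$called, character())
  expect_error(expand_by_correlation(cs, ft, r_min = 1.5), "r_min")
})

test_that("single-replicate libraries need both doses or multiple libraries", {
  n <- 12
  strains <- sprintf("s%02d", 1:n)
  one <- function(x) matrix(x, n, 1, dimnames = list(strains, NULL))
  f4 <- one(bg(n)); f4a <- one(bg(n)); f3 <- one(bg(n)); f2 <- one(bg(n))
  f3[1:4, ] <- 0                 # the strains under test are mild-neutral
  f4[1, ] <- -2; f4a[1, ] <- -2; f2[1, ] <- -0.1   # passes both doses
  f4[2, ] <- -2; f2[2, ] <- -0.1                   # 1.0 mM only
  f4[3, ] <- -2; f2[3, ] <- -0.1                   # het mutant of gene G
  f4[4, ] <- -2; f2[4, ] <- -0.1                   # damp mutant of gene G
  ft <- make_test_ft(list(S4vS3 = f4, S4AvS3 = f4a, S3vS1 = f3, S2vS1 = f2))
  ft$gene[c("s03", "s04")] <- "G"
  library_of <- setNames(rep("heterozygous", n), strains)
  library_of[c("s04")] <- "damp"
  cs <- call_single_replicate(ft, "NaCl", library = library_of)
  expect_true("s01" %in% cs$called)
  expect_false("s02" %in% cs$called)
  expect_true(all(c("s03", "s04") %in% cs$called))
  aud <- cs$audit
  expect_true(aud$added_by_two_dose_rule[aud$strain == "s01"])
  expect_equal(aud$route[aud$strain == "s03"], "multi_library")
  # without library info the multi-library route is off
  cs2 <- call_single_replicate(ft, "NaCl")
  expect_setequal(cs2$called, "s01")
  # refuses multi-replicate input
  ft2 <- make_test_ft(list(S4vS3 = cbind(f4, f4), S4AvS3 = cbind(f4a, f4a),
                           S3vS1 = cbind(f3, f3), S2vS1 = cbind(f2, f2)))
  expect_error(call_single_replicate(ft2, "NaCl"), "single-replicate")
})

test_that("low-dose sensitivity uses a BH ladder over replicate tests", {
  n <- 20
  strains <- sprintf("s%02d", 1:n)
  set.seed(5)
  m <- matrix(rnorm(n * 6, 0, 0.1), n, dimnames = list(strains, NULL))
  m[1, ] <- -3                       # unambiguous hit
  m[2, ] <- rnorm(6, -0.4, 0.05)     # moderate hit
  cols <- lapply(1:6, function(j) {
    f2 <- m[, j, drop = FALSE]
    list(S2vS1 = f2)
  })
  # assemble a 3-pretreatment x 2-replicate table holding only S2vS1
  info <- data.frame(pretreatment = rep(c("NaCl", "HS", "DTT"), each = 2),
                     replicate = rep(1:2, 3), comparison = "S2vS1",
                     platform = "UP")
  ft <- fitness_table(m, info)
  ld <- call_lowdose_sensitive(ft, q_max = 0.05)
  expect_true(all(c("s01", "s02") %in% ld$called))
  # hand-computed BH ladder on the same one-sided t-test p-values
  p <- apply(m, 1, function(x) {
    if (sd(x) == 0) (if (mean(x) < 0) 0 else 1)
    else t.test(x, alternative = "less")$p.value
  })
  o <- order(p)
  q_hand <- rep(NA_real_, n)
  q_hand[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(ld$table$q, pmin(1, q_hand), tolerance = 1e-12)
  # degenerate thresholds and inputs
  expect_length(call_lowdose_sensitive(ft, q_max = 0)$called, 0)
  ft0 <- fitness_table(matrix(0, n, 6, dimnames = list(strains, NULL)), info)
  expect_length(call_lowdose_sensitive(ft0)$called, 0)
  expect_error(call_lowdose_sensitive(
    fitness_table(m[, 1:2], info[1:2, ])), "3 low-dose replicates")
})

test_that("exclusions remove uniformly-sensitive and mild-sensitive strains", {
  n <- 12
  strains <- sprintf("s%02d", 1:n)
  f4 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f3 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f2 <- matrix(rep(bg(n), 2), n, dimnames = list(strains, NULL))
  f4[1, ] <- -2; f2[1, ] <- -0.1      # genuine acquisition defect
  f4[2, ] <- -2; f2[2, ] <- -2        # equal defect at both doses
  f4[3, ] <- -2; f2[3, ] <- -0.1; f3[3, ] <- -2  # mild-stress sensitive
  ft <- make_test_ft(list(S4vS3 = f4, S3vS1 = f3, S2vS1 = f2))
  calls <- structure(list(pretreatment = "NaCl",
                          called = c("s01", "s02", "s03"),
                          audit = data.frame(strain = strains,
                                             route = "stringent",
                                             stringsAsFactors = FALSE)),
                     class = "call_set")
  out <- apply_exclusions(calls, lowdose = c("s02"), ft)
  expect_setequal(out$called, "s01")
  expect_match(out$audit$route[out$audit$strain == "s02"], "uniform")
  expect_match(out$audit$route[out$audit$strain == "s03"], "mild")
  # idempotent; disjoint sets unchanged
  expect_equal(apply_exclusions(out, "s02", ft)$called, out$called)
  calls2 <- calls; calls2$called <- "s01"
  expect_equal(apply_exclusions(calls2, character(), ft)$called, "s01")
})

test_that("caller equals the brute-force filter on simulated screens", {
  for (seed in 1:3) {
    cs <- synth_catalog(n = 120, n_acquired = 12, n_pretreat = 6,
                        n_uniform = 6, seed = seed)
    sim <- simulate_screen(cs, replicates = 2, depth = 2e5, seed = seed)
    for (p in c("NaCl", "HS", "DTT")) {
      expect_setequal(call_stringent(sim$fitness, p)$called,
                      oracle_calls(sim$fitness, p))
    }
  }
})

test_that("strengthening a planted defect never removes a called strain", {
  cs <- synth_catalog(n = 200, n_acquired = 20, seed = 4)
  sim <- simulate_screen(cs, replicates = 2, depth = 2e5, seed = 4)
  called <- call_stringent(sim$fitness, "NaCl")$called
  planted <- intersect(sim$truth$strain_id[sim$truth$class == "acquired"],
                       called)
  expect_gt(length(planted), 0)
  cs2 <- cs
  sev <- grep("^survival\\.H2O2_1\\.[02]mM", names(cs2), value = TRUE)
  for (col in sev)
    cs2[[col]][cs2$strain_id %in% planted] <-
      cs2[[col]][cs2$strain_id %in% planted] / 2
  attr(cs2, "truth") <- attr(cs, "truth")
  sim2 <- simulate_screen(cs2, replicates = 2, depth = 2e5, seed = 4)
  called2 <- call_stringent(sim2$fitness, "NaCl")$called
  expect_true(all(planted %in% called2))
})

test_that("gene-level reconciliation prefers homozygous evidence", {
  cat_g <- strain_catalog(c("h1", "d1", "e1"), gene = c("G", "G", "G"),
                          library = c("homozygous", "damp", "heterozygous"),
                          survival = data.frame(NaCl = 1), seed = 8)
  calls <- structure(list(pretreatment = "NaCl",
                          called = c("d1", "h1", "e1"),
                          audit = data.frame(strain = c("h1", "d1", "e1"),
                                             route = "stringent")),
                     class = "call_set")
  rec <- reconcile_genes(calls, cat_g)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$strain, "h1")
})
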