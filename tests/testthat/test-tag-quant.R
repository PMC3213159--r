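test_that("demultiplexing applies the 1-mismatch uniqueness rule", {
  idx <- c(AAAAAA = "S1", CCCCCC = "S2", AACCGG = "S3")
  expect_equal(demultiplex("AAAAAAGGGG", idx), "S1")        # exact
  expect_equal(demultiplex("AAAAACGGGG", idx), "S1")        # 1 mismatch
  expect_equal(demultiplex("AAGGAAGGGG", idx), "UNASSIGNED")# 2 mismatches
  expect_equal(demultiplex("AAAA", idx), "MALFORMED")       # too short
  # ambiguous: equidistant (distance 1) from two catalog indexes
  idx2 <- c(AAAAAA = "S1", AAAAAT = "S2")
  expect_equal(demultiplex("AAAAAG", idx2), "UNASSIGNED")
  # exhaustive check over every 1-mismatch neighbourhood of a toy catalog
  for (i in seq_along(idx)) {
    seqs <- names(idx)[i]
    chars <- strsplit(seqs, "")[[1]]
    for (pos in 1:6) for (b in c("A", "C", "G", "T")) {
      mut <- chars; mut[pos] <- b
      read <- paste0(paste(mut, collapse = ""), "XXXXXXXXXX")
      d <- sapply(names(idx), function(s) sum(strsplit(s, "")[[1]] !=
                                                mut))
      expected <- if (sum(d <= 1) == 1) unname(idx[d <= 1]) else "UNASSIGNED"
      expect_equal(demultiplex(read, idx), expected)
    }
  }
})

test_that("tag mapping matches a brute-force Hamming scan", {
  cat50 <- strain_catalog(sprintf("t%02d", 1:50), seed = 33)
  expect_equal(map_tag(cat50$up_tag[7], cat50, "up"), "t07")  # exact
  mut3 <- cat50$up_tag[7]
  substr(mut3, 1, 3) <- chartr("ACGT", "CATG", substr(mut3, 1, 3))
  expect_equal(map_tag(mut3, cat50, "up"), "UNMAPPED")        # 3 mismatches
  expect_equal(map_tag("ACGT", cat50, "up"), "MALFORMED")
  # fuzz: random mutations of random catalog tags + random 20-mers
  set.seed(99)
  n <- 3000
  pick <- sample(50, n, replace = TRUE)
  tags <- cat50$up_tag[pick]
  nmut <- sample(0:4, n, replace = TRUE)
  for (i in which(nmut > 0)) {
    pos <- sample(20, nmut[i])
    ch <- strsplit(tags[i], "")[[1]]
    ch[pos] <- sample(c("A", "C", "G", "T"), nmut[i], replace = TRUE)
    tags[i] <- paste(ch, collapse = "")
  }
  rand <- replicate(500, paste(sample(c("A", "C", "G", "T"), 20,
                                      replace = TRUE), collapse = ""))
  tags <- c(tags, rand)
  expect_equal(map_tag(tags, cat50, "up"),
               oracle_map(tags, cat50$up_tag, cat50$strain_id))
})

test_that("an engineered equidistant tag is discarded as ambiguous", {
  # two reference tags at distance 4; midpoint is 2 from both
  base <- strsplit(paste(rep("A", 20), collapse = ""), "")[[1]]
  t1 <- base; t2 <- base
  t2[1:4] <- "C"
  obs <- base; obs[1:2] <- "C"
  cat2 <- strain_catalog(c("x", "y"),
                         up_tag = c(paste(t1, collapse = ""),
                                    paste(t2, collapse = "")),
                         down_tag = generate_tags(2, seed = 5))
  expect_equal(map_tag(paste(obs, collapse = ""), cat2, "up"), "AMBIGUOUS")
})

test_that("count_tags conserves reads and round-trips error-free input", {
  cat6 <- toy_catalog()
  st <- simulate_selection(cat6, selection_design("NaCl"))
  idx <- c(AAAAAA = "S3", CCCCCC = "S4")
  r3 <- generate_reads(st$S3, cat6, 5000, error_rate = 0,
                       multiplex_index = "AAAAAA", seed = 4)
  r4 <- generate_reads(st$S4, cat6, 5000, error_rate = 0.02,
                       multiplex_index = "CCCCCC", seed = 8)
  junk <- c("ACGT", paste(rep("G", 44), collapse = ""))
  tc <- count_tags(c(r3, r4, junk), cat6, idx)
  expect_equal(unname(tc$stats["n_assigned"] + tc$stats["n_discarded_index"] +
                        tc$stats["n_discarded_unmapped"] +
                        tc$stats["n_discarded_ambiguous"] +
                        tc$stats["n_malformed"]), length(c(r3, r4, junk)))
  expect_equal(sum(tc$counts), unname(tc$stats["n_assigned"]))
  # error-free sample equals the simulator's multinomial draw exactly
  expect_equal(tc$counts[, "S3"], sample_counts(st$S3, 5000, seed = 4))
  # empty input: all counters zero
  tc0 <- count_tags(character(), cat6, idx)
  expect_true(all(tc0$stats == 0) && sum(tc0$counts) == 0)
})

test_that("1% sequencing error yields the binomial unmapped fraction", {
  cat50 <- strain_catalog(sprintf("t%02d", 1:50), seed = 21)
  st <- structure(list(sample = "S0",
                       abundance = setNames(rep(1 / 50, 50),
                                            cat50$strain_id)),
                  class = "pool_state")
  depth <- 4e4
  reads <- generate_reads(st, cat50, depth, error_rate = 0.01,
                          multiplex_index = "ACACAC", seed = 13)
  tc <- count_tags(reads, cat50, c(ACACAC = "S0"))
  considered <- sum(tc$stats[c("n_assigned", "n_discarded_unmapped",
                               "n_discarded_ambiguous")])
  p_ge3 <- 1 - pbinom(2, 20, 0.01)  # >=3 tag errors cannot map
  obs <- tc$stats[["n_discarded_unmapped"]] / considered
  expect_lt(abs(obs - p_ge3), 4 * sqrt(p_ge3 * (1 - p_ge3) / considered))
  expect_equal(tc$stats[["n_discarded_ambiguous"]], 0L)  # tags >= 5 apart
})

test_that("feature summarisation excludes clear outliers by the MAD rule", {
  arr <- data.frame(tag_id = "t_up", strain_id = "t", tag_class = "up",
                    intensity = c(100, 100, 100, 100, 10000))
  s <- summarize_features(arr)
  expect_equal(s$mean_intensity, 100)
  expect_equal(s$n_used, 4L)
  # five identical features: mean v, none excluded
  arr2 <- arr; arr2$intensity <- rep(7, 5)
  expect_equal(summarize_features(arr2)$mean_intensity, 7)
  expect_equal(summarize_features(arr2)$n_used, 5L)
  # single feature: kept but low-quality at min_features = 3
  arr1 <- arr[1, ]
  s1 <- summarize_features(arr1, min_features = 3)
  expect_equal(s1$mean_intensity, 100)
  expect_true(s1$low_quality)
  # dispersed features: the stated rule evaluated literally
  x <- c(90, 100, 110, 105, 600)
  keep <- abs(x - median(x)) <= 5 * mad(x, center = median(x))
  s2 <- summarize_features(data.frame(tag_id = "a", strain_id = "a",
                                      tag_class = "up", intensity = x))
  expect_equal(s2$mean_intensity, mean(x[keep]))
})

test_that("quantile normalization matches the sort-average oracle", {
  m <- cbind(a = c(2, 4, 6), b = c(3, 1, 2))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(qn[, "b"]), c(4.5, 1.5, 3))
  # identical columns and single columns are unchanged
  two <- cbind(c(5, 1, 9), c(5, 1, 9))
  expect_equal(quantile_normalize(two), two)
  expect_equal(quantile_normalize(two[, 1, drop = FALSE]),
               two[, 1, drop = FALSE])
  # random matrices: sorted columns identical, ranks preserved, idempotent
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(2:10, 1); nc <- sample(2:10, 1)
    m <- matrix(rnorm(nr * nc), nr, nc)
    qn <- quantile_normalize(m)
    target <- rowMeans(apply(m, 2, sort))
    for (j in seq_len(nc)) {
      expect_equal(sort(qn[, j]), target)
      expect_equal(rank(qn[, j]), rank(m[, j]))
    }
    expect_equal(quantile_normalize(qn), qn)
  }
})

test_that("quantile normalization agrees with limma on tie-free input", {
  skip_if_not_installed("limma")
  set.seed(42)
  m <- matrix(rexp(60), 12, 5)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)))
})

test_that("missing cells are imputed for normalization then restored", {
  m <- cbind(c(1, 2, NA, 8), c(2, 4, 6, 8))
  qn <- quantile_normalize(m)
  expect_true(is.na(qn[3, 1]))
  expect_false(anyNA(qn[-3, ]))
})

test_that("desaturation inverts the configured response", {
  expect_equal(desaturate(3e4, imax = 6e4, K = 5e3), 5e3)  # I = Imax/2 -> K
  expect_equal(desaturate(0, imax = 6e4, K = 5e3), 0)
  s <- c(1e-4, 0.5, 3, 10, 250, 1e4)
  expect_equal(desaturate(saturate(s, 6e4, 5e3), 6e4, 5e3), s)
  expect_equal(desaturate(s, 6e4, Inf), s)  # linear array: identity
  expect_warning(out <- desaturate(c(100, 7e4), imax = 6e4, K = 5e3),
                 "clipped")
  expect_true(is.finite(out[2]))
  # monotone increasing
  I <- seq(0, 5.9e4, length.out = 50)
  expect_true(all(diff(desaturate(I, 6e4, 5e3)) > 0))
})

test_that("abundance normalisation and up/down combination", {
  cnt <- matrix(c(10, 30, 60), ncol = 1,
                dimnames = list(c("a", "b", "c"), "S0"))
  ab <- to_abundance(up = cnt)
  expect_equal(unname(ab$combined[, 1]), c(0.1, 0.3, 0.6))
  # equal counts -> 1/n each
  eq <- matrix(5, 4, 1, dimnames = list(letters[1:4], "S0"))
  expect_equal(unname(to_abundance(up = eq)$combined[, 1]), rep(0.25, 4))
  # up usable only for one strain: combined falls back to the usable class
  up <- matrix(c(2, 2), ncol = 1, dimnames = list(c("a", "b"), "S0"))
  dn <- matrix(c(1, NA), ncol = 1, dimnames = list(c("a", "b"), "S0"))
  ab2 <- to_abundance(up = up, down = dn)
  expect_equal(ab2$combined["b", 1], ab2$up["b", 1])
  expect_equal(ab2$combined["a", 1], (0.5 + 1) / 2)
  expect_error(to_abundance(up = matrix(0, 2, 1)), "zero column total")
})
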