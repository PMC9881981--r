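model_fixture <- system.file("extdata", "model_q2_synthetic.tsv",
                             package = "hqalign")

test_that("pore model tables load completely and reject malformed input", {
  qm <- load_qmer_map(model_fixture, Q = 2)
  expect_s3_class(qm, "qmer_map")
  expect_equal(nrow(qm), 16L)
  expect_equal(qm$current[qm$kmer == "AA"], 80)
  expect_equal(qm$current[qm$kmer == "TT"], 95)
  expect_equal(qmer_order(qm), 2L)

  df <- utils::read.delim(model_fixture)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[-3, ], tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_qmer_map(tmp, Q = 2), "missing Q-mer: AG",
               class = "hqalign_missing_qmer")

  utils::write.table(rbind(df, df[1, ]), tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_qmer_map(tmp, Q = 2), class = "hqalign_duplicate_qmer")

  bad <- df; bad$level_mean[2] <- "oops"
  utils::write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_qmer_map(tmp, Q = 2), class = "hqalign_bad_current")

  expect_error(load_qmer_map(model_fixture, Q = 3), class = "hqalign_bad_kmer")

  # header line is optional
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  expect_equal(load_qmer_map(tmp, Q = 2)$current[1], 80)
})

test_that("synthesized maps are deterministic, ranged and confusable", {
  a <- synthesize_qmer_map(2, seed = 7)
  b <- synthesize_qmer_map(2, seed = 7)
  expect_identical(a$current, b$current)

  m6 <- synthesize_qmer_map(6, seed = 1, current_range = c(60, 120))
  expect_equal(nrow(m6), 4096L)
  expect_true(all(m6$current >= 60 & m6$current <= 120))
  # at least one pair of distinct Q-mers within 1 pA
  expect_true(min(diff(sort(m6$current))) < 1)

  m3 <- synthesize_qmer_map(3, seed = 3)
  cfg <- compute_thresholds(m3, 3)
  lv <- findInterval(m3$current, cfg$thresholds, left.open = TRUE)
  expect_true(any(table(lv) > 1)) # shared tertile bins exist

  expect_error(synthesize_qmer_map(0, seed = 1), class = "hqalign_bad_q")
})

test_that("thresholds are equal-occupancy quantiles with documented ties", {
  # toy multiset {1..6}: thresholds split occupancies 2/2/2
  toy <- structure(tibble::tibble(kmer = letters[1:6], current = 1:6),
                   Q = 1L, class = c("qmer_map", "tbl_df", "tbl", "data.frame"))
  cfg <- compute_thresholds(toy, 3)
  lv <- findInterval(1:6, cfg$thresholds, left.open = TRUE)
  expect_equal(unname(table(lv)), array(c(2L, 2L, 2L)), ignore_attr = TRUE)
  # L = 2: the single threshold is the median of the currents
  expect_equal(compute_thresholds(toy, 2)$thresholds, stats::median(1:6))
  expect_error(compute_thresholds(toy, 1), class = "hqalign_bad_levels")
  expect_error(compute_thresholds(toy, 7), class = "hqalign_bad_levels")

  # occupancy balance over a full synthetic map with distinct currents
  qm <- synthesize_qmer_map(4, seed = 11)
  cfg3 <- compute_thresholds(qm, 3)
  occ <- table(findInterval(qm$current, cfg3$thresholds, left.open = TRUE))
  expect_lte(max(occ) - min(occ), 1)
})

test_that("current translation follows the sliding Q-mer window", {
  qm <- load_qmer_map(model_fixture, Q = 2)
  expect_equal(to_current_levels("AAC", qm), c(80, 81))
  expect_equal(to_current_levels("AC", qm), 81)   # length exactly Q
  expect_equal(to_current_levels("A", qm), numeric(0)) # shorter than Q
  expect_true(is.na(to_current_levels("ANA", qm)[1]))
})

test_that("quantization obeys the length law and bin consistency", {
  qm <- synthesize_qmer_map(3, seed = 5)
  cfg <- compute_thresholds(qm, 3)
  withr::local_seed(42)
  for (n in c(0, 2, 3, 10, 100, 357)) {
    s <- random_dna(max(n, 1))
    if (n == 0) s <- ""
    q <- quantize(s, qm, cfg)
    expect_equal(length(q), max(nchar(s) - 3 + 1, 0))
    if (length(q) > 0) {
      cur <- to_current_levels(s, qm)
      # level = number of thresholds strictly below the window current
      expect_equal(unclass(q),
                   vapply(cur, function(x) sum(cfg$thresholds < x), 0L),
                   ignore_attr = TRUE)
      expect_true(all(unclass(q) >= 0 & unclass(q) < cfg$L))
    }
  }
  # all currents below the first threshold quantize to level 0
  low <- qm$kmer[qm$current < cfg$thresholds[1]]
  s0 <- low[1]
  expect_equal(unclass(quantize(s0, qm, cfg)), 0L, ignore_attr = TRUE)
})

test_that("distinct sequences with shared bins are confusable", {
  qm <- synthesize_qmer_map(2, seed = 9)
  cfg <- compute_thresholds(qm, 3)
  lv <- stats::setNames(findInterval(qm$current, cfg$thresholds,
                                     left.open = TRUE), qm$kmer)
  # search 8-mers whose 2-mer windows land in identical bins
  withr::local_seed(1)
  found <- FALSE
  for (i in 1:2000) {
    a <- random_dna(8); b <- random_dna(8)
    if (a == b) next
    wa <- substring(a, 1:7, 2:8); wb <- substring(b, 1:7, 2:8)
    if (all(lv[wa] == lv[wb])) {
      expect_identical(unclass(quantize(a, qm, cfg)),
                       unclass(quantize(b, qm, cfg)))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("the quantized reverse complement is its own transform", {
  qm <- synthesize_qmer_map(3, seed = 2)
  cfg <- compute_thresholds(qm, 3)
  withr::local_seed(7)
  diff_found <- FALSE
  for (i in 1:200) {
    s <- random_dna(sample(10:40, 1))
    qrc <- quantize_revcomp(s, qm, cfg)
    expect_identical(unclass(qrc), unclass(quantize(revcomp(s), qm, cfg)))
    expect_equal(length(qrc), length(quantize(s, qm, cfg)))
    if (!identical(unclass(qrc), rev(unclass(quantize(s, qm, cfg))))) {
      diff_found <- TRUE
    }
  }
  # not derivable from the forward quantized sequence by reversal
  expect_true(diff_found)
  # involution: s = revcomp(s2) implies quantize_revcomp(s) = quantize(s2)
  s2 <- random_dna(25)
  expect_identical(unclass(quantize_revcomp(revcomp(s2), qm, cfg)),
                   unclass(quantize(s2, qm, cfg)))
})

test_that("model tables round-trip through the writer", {
  qm <- synthesize_qmer_map(2, seed = 4)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_qmer_map(qm, tmp)
  back <- load_qmer_map(tmp, Q = 2)
  expect_equal(back$current, qm$current, tolerance = 1e-12)
})
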