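sv <- function(start, end, type, length, chrom = "chr1",
               id = paste0("x", start)) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), type = type,
                 length = as.integer(length), id = id)
}

test_that("breakpoint score is the mean absolute breakpoint offset", {
  a <- sv(1000, 2000, "DEL", 1000)
  expect_equal(breakpoint_score(a, a), 0)
  b <- sv(1010, 2020, "DEL", 1010)
  expect_equal(breakpoint_score(a, b), 15)
  expect_equal(breakpoint_score(b, a), breakpoint_score(a, b))
  c2 <- sv(1000, 2000, "DEL", 1000, chrom = "chr2")
  expect_error(breakpoint_score(a, c2), class = "hqalign_chrom_mismatch")
})

test_that("length similarity is the min/max ratio", {
  a <- sv(1, 100, "DEL", 100)
  expect_equal(length_similarity(a, a), 1)
  b <- sv(1, 50, "DEL", 50)
  expect_equal(length_similarity(a, b), 0.5)
  expect_equal(length_similarity(b, a), 0.5)
  z <- sv(1, 1, "INS", 0)
  expect_error(length_similarity(a, z), class = "hqalign_bad_param")
})

test_that("matching gates on type, distance and similarity, one-to-one", {
  truth <- dplyr::bind_rows(sv(1000, 2000, "DEL", 1000, id = "t1"),
                            sv(5000, 5000, "INS", 300, id = "t2"))
  perfect <- match_calls(truth, truth)
  expect_equal(glance(perfect)$precision, 1)
  expect_equal(glance(perfect)$recall, 1)
  expect_equal(glance(perfect)$f1, 1)

  one <- match_calls(truth, truth[1, ])
  expect_equal(one$tp, 1L)
  expect_equal(one$fn, 1L)
  expect_equal(one$recall, 0.5)

  # type gate: a DEL call cannot match an INS truth entry at the same locus
  wrong <- sv(5000, 5300, "DEL", 300)
  m <- match_calls(truth[2, ], wrong)
  expect_equal(m$tp, 0L)
  expect_equal(m$fp, 1L)

  # similarity gate at the 0.7 default
  short <- sv(1000, 1600, "DEL", 600)
  expect_equal(match_calls(truth[1, ], short)$tp, 0L)
  ok <- sv(1050, 2070, "DEL", 1020)
  expect_equal(match_calls(truth[1, ], ok)$tp, 1L)
})

test_that("matching is one-to-one and F1 is the harmonic mean", {
  withr::local_seed(81)
  for (rep in 1:10) {
    nt <- sample(3:10, 1); nc <- sample(3:10, 1)
    truth <- sv(cumsum(sample(3000:6000, nt)), 0, "DEL",
                sample(100:2000, nt, replace = TRUE),
                id = sprintf("t%d", 1:nt))
    truth$end <- truth$start + truth$length
    calls <- truth[sample.int(nt, min(nc, nt)), ]
    calls$start <- calls$start + sample(-300:300, nrow(calls), replace = TRUE)
    calls$end <- calls$start + calls$length
    m <- match_calls(truth, calls)
    expect_lte(length(unique(m$matches$truth_row)), nrow(m$matches) + 0)
    expect_equal(anyDuplicated(m$matches$truth_row), 0L)
    expect_equal(anyDuplicated(m$matches$call_row), 0L)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
    }
    expect_equal(m$tp + m$fn, nt)
    expect_equal(m$tp + m$fp, nrow(calls))
  }
})

test_that("excluded intervals are masked out before matching", {
  truth <- dplyr::bind_rows(sv(1000, 2000, "DEL", 1000, id = "t1"),
                            sv(50000, 51000, "DEL", 1000, id = "t2"))
  m <- match_calls(truth, truth,
                   exclude = tibble::tibble(chrom = "chr1",
                                            start = 40000L, end = 60000L))
  expect_equal(m$tp, 1L)
  expect_equal(m$fn, 0L) # the masked truth entry does not count as missed
})

test_that("the union model is idempotent, additive on disjoint sets and
          never loses recall", {
  a <- dplyr::bind_rows(sv(1000, 2000, "DEL", 1000, id = "a1"),
                        sv(9000, 9000, "INS", 400, id = "a2"))
  expect_equal(nrow(union_model(a, a)), 2L)
  b <- sv(20000, 21000, "INV", 1000, id = "b1")
  expect_equal(nrow(union_model(a, b)), 3L)

  withr::local_seed(91)
  for (rep in 1:10) {
    nt <- 12L
    truth <- sv(cumsum(sample(4000:8000, nt)), 0,
                sample(c("DEL", "INS", "INV"), nt, replace = TRUE),
                sample(100:3000, nt, replace = TRUE),
                id = sprintf("t%d", 1:nt))
    truth$end <- ifelse(truth$type == "INS", truth$start,
                        truth$start + truth$length)
    pick <- function() {
      idx <- sample.int(nt, sample(4:10, 1))
      cc <- truth[idx, ]
      cc$start <- cc$start + sample(-200:200, length(idx), replace = TRUE)
      cc$end <- ifelse(cc$type == "INS", cc$start, cc$start + cc$length)
      cc
    }
    ca <- pick(); cb <- pick()
    u <- union_model(ca, cb)
    ra <- match_calls(truth, ca)$recall
    rb <- match_calls(truth, cb)$recall
    ru <- match_calls(truth, u)$recall
    expect_gte(ru, max(ra, rb))
  }
})

test_that("complementary calls partition into captured and unique", {
  only_a <- dplyr::bind_rows(sv(1000, 2000, "DEL", 1000, id = "a1"),
                             sv(9000, 10000, "DEL", 1000, id = "a2"))
  expect_true(all(classify_complementary(only_a, only_a[0, ])$status == "unique"))
  # a same-locus call at similarity 0.5 is captured once the gate is relaxed
  b <- sv(1000, 1500, "DEL", 500)
  cls <- classify_complementary(only_a, b)
  expect_equal(cls$status, c("captured_at_lower_similarity", "unique"))
  expect_equal(nrow(cls), nrow(only_a))
})
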