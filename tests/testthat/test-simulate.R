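test_that("genome generation is deterministic with controlled repeat content", {
  g1 <- generate_genome(50000, 0.2, seed = 5)
  g2 <- generate_genome(50000, 0.2, seed = 5)
  expect_identical(g1[[1]], g2[[1]])
  expect_false(identical(g1[[1]], generate_genome(50000, 0.2, seed = 6)[[1]]))

  g0 <- generate_genome(20000, 0, seed = 5)
  expect_equal(nrow(attr(g0, "repeats")), 0L)

  gg <- generate_genome(1e6, 0.2, seed = 7)
  rp <- attr(gg, "repeats")
  frac <- sum(rp$end - rp$start + 1) / nchar(gg[[1]])
  expect_lte(abs(frac - 0.2), 0.05)
  expect_error(generate_genome(500, 0.2), class = "hqalign_bad_param")
  expect_error(generate_genome(50000, 0.95), class = "hqalign_bad_param")
})

test_that("planted SVs honor counts, bounds and reconstruct the mutation", {
  g <- generate_genome(120000, 0.1, seed = 8)
  pl <- plant_svs(g, n_indel = 8, n_inv = 3, len_low = 50, len_high = 3000,
                  seed = 9)
  tr <- pl$truth
  expect_equal(nrow(tr), 11L)
  expect_equal(sum(tr$type == "INV"), 3L)
  expect_equal(sum(tr$type == "INS"), 4L) # even INS/DEL split
  expect_true(all(tr$length >= 50 & tr$length <= 3000))
  expect_true(all(tr$end[tr$type == "INS"] == tr$start[tr$type == "INS"]))

  # independent reconstruction oracle: apply the truth records to the
  # original genome with plain string operations
  src <- g[[1]]
  ev <- tr[order(-tr$start), ]
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; l <- ev$length[i]
    if (ev$type[i] == "DEL") {
      src <- paste0(substr(src, 1, s - 1), substr(src, s + l, nchar(src)))
    } else if (ev$type[i] == "INV") {
      src <- paste0(substr(src, 1, s - 1), revcomp(substr(src, s, s + l - 1)),
                    substr(src, s + l, nchar(src)))
    } else {
      ins <- substr(pl$genome[[1]],
                    s + local({ # locate the inserted block in the mutated genome
                      before <- tr[tr$start < s, ]
                      sum(ifelse(before$type == "INS", before$length,
                                 ifelse(before$type == "DEL", -before$length, 0)))
                    }),
                    s - 1 + l + local({
                      before <- tr[tr$start < s, ]
                      sum(ifelse(before$type == "INS", before$length,
                                 ifelse(before$type == "DEL", -before$length, 0)))
                    }))
      src <- paste0(substr(src, 1, s - 1), ins, substr(src, s, nchar(src)))
    }
  }
  expect_identical(src, pl$genome[[1]])
})

test_that("planted lengths are uniform on the requested range", {
  g <- generate_genome(2e6, 0, seed = 10)
  pl <- plant_svs(g, n_indel = 450, n_inv = 50, len_low = 50, len_high = 400,
                  seed = 11, margin = 200)
  m <- mean(pl$truth$length)
  expect_lte(abs(m - (50 + 400) / 2) / ((50 + 400) / 2), 0.05)
})

test_that("read simulation is deterministic and respects coverage", {
  g <- generate_genome(200000, 0.1, seed = 12)
  r1 <- simulate_reads(g, coverage = 5, mean_len = 3000, median_len = 1000,
                       error_rate = 0.1, seed = 13)
  r2 <- simulate_reads(g, coverage = 5, mean_len = 3000, median_len = 1000,
                       error_rate = 0.1, seed = 13)
  expect_identical(r1$seq, r2$seq)
  total <- sum(nchar(r1$seq))
  expect_lte(abs(total - 5 * 200000) / (5 * 200000), 0.1)

  # the no-noise limit: every read is an exact (possibly reverse-complement)
  # substring of the genome
  r0 <- simulate_reads(g, coverage = 0.3, mean_len = 2000, median_len = 1000,
                       error_rate = 0, seed = 14)
  for (i in seq_len(nrow(r0))) {
    src <- substr(g[[r0$chrom[i]]], r0$start[i], r0$end[i])
    if (r0$strand[i] == "-") src <- revcomp(src)
    expect_identical(r0$seq[i], src)
  }
  expect_error(simulate_reads(g, error_rate = 0.5), class = "hqalign_bad_param")
})

test_that("confusion-weighted errors are quieter in quantized space", {
  qm <- synthesize_qmer_map(6, seed = 15)
  cfg <- compute_thresholds(qm, 3)
  g <- generate_genome(150000, 0.1, seed = 16)
  r_w1 <- simulate_reads(g, coverage = 5, mean_len = 1500, median_len = 1200,
                         error_rate = 0.1, qmap = qm, confusion_weight = 1,
                         seed = 17, min_len = 800)
  r_w0 <- simulate_reads(g, coverage = 5, mean_len = 1500, median_len = 1200,
                         error_rate = 0.1, qmap = qm, confusion_weight = 0,
                         seed = 17, min_len = 800)
  expect_gte(nrow(r_w1), 200)
  qdist <- function(rr) {
    vapply(seq_len(nrow(rr)), function(i) {
      src <- substr(g[[rr$chrom[i]]], rr$start[i], rr$end[i])
      if (rr$strand[i] == "-") src <- revcomp(src)
      edit_distance(quantize(rr$seq[i], qm, cfg), quantize(src, qm, cfg))
    }, numeric(1))
  }
  n <- min(nrow(r_w1), nrow(r_w0), 250)
  d1 <- qdist(r_w1[1:n, ])
  d0 <- qdist(r_w0[1:n, ])
  # identical seeds give paired reads; bin-preserving errors must leave a
  # strictly smaller quantized-domain footprint
  expect_lt(mean(d1), mean(d0))
  expect_lt(t.test(d1, d0, paired = TRUE)$estimate, 0)
})
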