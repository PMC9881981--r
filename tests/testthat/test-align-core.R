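test_that("minimizer selection matches the brute-force window rule", {
  withr::local_seed(11)
  for (asize in c(4L, 3L)) {
    s <- sample.int(asize, 200, replace = TRUE) - 1L
    k <- if (asize == 4) 15L else 18L
    all_hashes <- minimizers(s, k = k, w = 1L, alphabet_size = asize)
    expect_equal(nrow(all_hashes), 200 - k + 1)
    for (w in c(5L, 10L)) {
      got <- minimizers(s, k = k, w = w, alphabet_size = asize)$pos
      expect_equal(got, r_minimizer_positions(all_hashes$hash, w))
    }
  }
  # degenerate single k-mer target: every position of "AA" indexed
  m <- minimizers("AAAA", k = 2L, w = 1L, alphabet_size = 4L)
  expect_equal(m$pos, 0:2)
  expect_equal(length(unique(m$hash)), 1L)
})

test_that("index construction is deterministic and validated", {
  g <- c(chrA = random_dna(400), chrB = random_dna(400))
  ix1 <- build_minimizer_index(g, k = 15, w = 10)
  ix2 <- build_minimizer_index(g, k = 15, w = 10)
  expect_identical(ix1$hash, ix2$hash)
  expect_identical(ix1$pos, ix2$pos)
  expect_true(all(ix1$pos < ix1$target_lengths[ix1$tid + 1L]))
  # two identical targets index identical per-target position lists
  g2 <- c(a = g[[1]], b = g[[1]])
  ix3 <- build_minimizer_index(g2, k = 15, w = 10)
  expect_identical(ix3$pos[ix3$tid == 0L], ix3$pos[ix3$tid == 1L])
  expect_error(build_minimizer_index(g, k = 0), class = "hqalign_bad_param")
  expect_error(build_minimizer_index(list(a = c(0L, 5L)), alphabet_size = 4L),
               class = "hqalign_bad_alphabet")
})

test_that("chaining matches exhaustive search on small instances", {
  withr::local_seed(21)
  # perfectly colinear anchors form a single chain with all members
  colinear <- tibble::tibble(query_pos = seq(0, 90, 10),
                             target_pos = seq(100, 190, 10))
  ch <- chain_anchors(colinear)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$n_anchors, 10L)
  # two colinear blocks split by a gap beyond max_gap give two chains
  blocks <- tibble::tibble(
    query_pos = c(0, 10, 20, 5000, 5010, 5020),
    target_pos = c(0, 10, 20, 9000, 9010, 9020))
  ch2 <- chain_anchors(blocks, max_gap = 1000)
  expect_equal(nrow(ch2), 2L)
  # random instances: best chain score equals exhaustive enumeration
  for (rep in 1:8) {
    n <- 12L
    a <- tibble::tibble(query_pos = sample.int(300, n),
                        target_pos = sample.int(300, n))
    got <- chain_anchors(a, max_gap = 12000)$score[1]
    expect_equal(got, r_best_chain_score(a$query_pos, a$target_pos),
                 tolerance = 1e-9)
  }
})

test_that("banded extension reproduces unbanded affine DP scores", {
  withr::local_seed(31)
  scoring <- aln_params()
  k <- 8L
  for (asize in c(4L, 3L)) {
    for (rep in 1:15) {
      # gap-fill case: two exact anchors with a noisy interior, flush ends
      mid_t <- sample.int(asize, sample(5:20, 1), replace = TRUE) - 1L
      mid_q <- mid_t
      flip <- runif(length(mid_q)) < 0.3
      mid_q[flip] <- (mid_q[flip] + sample.int(asize - 1, sum(flip),
                                               replace = TRUE)) %% asize
      a1 <- sample.int(asize, k, replace = TRUE) - 1L
      a2 <- sample.int(asize, k, replace = TRUE) - 1L
      q <- c(a1, mid_q, a2)
      t <- c(a1, mid_t, a2)
      chain <- tibble::tibble(query_pos = c(0L, k + length(mid_q)),
                              target_pos = c(0L, k + length(mid_t)))
      rec <- banded_extend(q, t, chain, band_width = 64, scoring = scoring,
                           k = k, alphabet_size = asize)
      oracle <- 4 * k + r_affine_global(mid_q, mid_t)
      expect_equal(rec$score, oracle, tolerance = 1e-9)
      # CIGAR consistency with coordinates
      ops <- regmatches(rec$cigar, gregexpr("\\d+[MID]", rec$cigar))[[1]]
      lens <- as.integer(sub("[MID]", "", ops))
      kinds <- sub("\\d+", "", ops)
      expect_equal(sum(lens[kinds != "D"]), rec$qend - rec$qstart)
      expect_equal(sum(lens[kinds != "I"]), rec$tend - rec$tstart)
    }
    for (rep in 1:15) {
      # extension case: single left anchor, noisy tail to the right
      tail_t <- sample.int(asize, sample(10:32, 1), replace = TRUE) - 1L
      tail_q <- tail_t
      flip <- runif(length(tail_q)) < 0.25
      tail_q[flip] <- (tail_q[flip] + sample.int(asize - 1, sum(flip),
                                                 replace = TRUE)) %% asize
      a1 <- sample.int(asize, k, replace = TRUE) - 1L
      q <- c(a1, tail_q)
      t <- c(a1, tail_t)
      chain <- tibble::tibble(query_pos = 0L, target_pos = 0L)
      big <- aln_params(zdrop = 1e9, ext_slack = 0)
      rec <- banded_extend(q, t, chain, band_width = 64, scoring = big,
                           k = k, alphabet_size = asize)
      expect_equal(rec$score, 2 * k + r_affine_extend(tail_q, tail_t),
                   tolerance = 1e-9)
    }
  }
})

test_that("banded extension degenerate and error cases behave", {
  q <- encode_dna("ACGTACGTACGTACGTACGT")
  chain <- tibble::tibble(query_pos = 0L, target_pos = 0L)
  rec <- banded_extend(q, q, chain, k = 8L)
  expect_equal(rec$cigar, "20M") # identity alignment
  expect_equal(rec$nm, 0L)
  # a single substitution keeps the CIGAR length and costs one edit
  t2 <- q; t2[10] <- (t2[10] + 1L) %% 4L
  rec2 <- banded_extend(q, t2, tibble::tibble(query_pos = c(0L, 12L),
                                              target_pos = c(0L, 12L)),
                        k = 8L)
  expect_equal(rec2$cigar, "20M")
  expect_equal(rec2$nm, 1L)
  # anchors whose diagonals differ more than the band can hold
  far <- tibble::tibble(query_pos = c(0L, 10L), target_pos = c(0L, 9000L))
  expect_error(
    banded_extend(sample(0:3, 40, TRUE), sample(0:3, 9500, TRUE), far,
                  band_width = 16, band_cap = 64, k = 8L),
    class = "hqalign_band_exceeded")
  expect_error(banded_extend(q, q, chain[0, ], k = 8L),
               class = "hqalign_bad_param")
})

test_that("edit distance is exact, symmetric and oracle-consistent", {
  expect_equal(edit_distance("", "ACGT"), 4L)
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  withr::local_seed(41)
  for (rep in 1:50) {
    a <- random_dna(sample(0:20, 1))
    b <- random_dna(sample(0:20, 1))
    d <- edit_distance(a, b)
    expect_equal(d, r_levenshtein(utf8ToInt(a), utf8ToInt(b)))
    expect_equal(d, edit_distance(b, a))
  }
  # cross-check the band-doubling path against base R on longer strings
  a <- random_dna(600)
  b <- paste0(substr(a, 1, 200), random_dna(80), substr(a, 280, 600))
  expect_equal(edit_distance(a, b), drop(utils::adist(a, b)))
})

test_that("mapping quality follows the score-separation formula", {
  expect_equal(compute_mapq(100, 0, 50), 60L)   # unique
  expect_equal(compute_mapq(100, 100, 50), 0L)  # fully ambiguous
  expect_equal(compute_mapq(100, 50, 20), 20L)
  expect_equal(compute_mapq(100, 50, 5), 10L)   # thin chain halves it
  q <- compute_mapq(rep(100, 11), seq(0, 100, 10), rep(50, 11))
  expect_true(all(diff(q) <= 0)) # monotone non-increasing in second best
  expect_true(all(q >= 0 & q <= 60))
  expect_error(compute_mapq(0, 0, 5), class = "hqalign_bad_param")
})

test_that("self-alignment is perfect for ternary and quaternary alphabets", {
  withr::local_seed(51)
  for (asize in c(3L, 4L)) {
    s <- sample.int(asize, 500, replace = TRUE) - 1L
    ix <- build_minimizer_index(list(t1 = s), k = 12L, w = 5L,
                                alphabet_size = asize)
    res <- hqalign:::map_query(s, NULL, ix, aln_params(), query_name = "q")
    prim <- res$records[res$records$is_primary, ]
    expect_equal(nrow(prim), 1L)
    expect_equal(prim$nm, 0L)
    expect_equal(prim$qstart, 0L)
    expect_equal(prim$qend, 500L)
    expect_equal(prim$mapq, 60L)
  }
})
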