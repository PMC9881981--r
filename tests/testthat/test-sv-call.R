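fake_rec <- function(name, strand, qstart, qend, tstart, tend, cigar,
                     chrom = "chr1") {
  tibble::tibble(
    query_name = name, target_name = chrom, strand = strand,
    qstart = qstart, qend = qend, tstart = tstart, tend = tend,
    cigar = cigar, score = 100, nm = 0L, mapq = 60L, is_primary = TRUE,
    is_supplementary = FALSE, chain_rank = 0L, chain_score = 50,
    n_anchors = 20L, query_length = qend, domain = "nucleotide",
    read_length = qend)
}

test_that("CIGAR indel runs become signatures above the length floor", {
  r <- fake_rec("r1", "+", 0L, 320L, 1000L, 1200L, "100M120I100M")
  sig <- extract_signatures(r)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$type, "INS")
  expect_equal(sig$length, 120L)
  expect_equal(sig$pos, 1101L)

  r2 <- fake_rec("r1", "+", 0L, 200L, 1000L, 1230L, "100M30D100M")
  expect_equal(nrow(extract_signatures(r2, min_sv_len = 50)), 0L)

  r3 <- fake_rec("r1", "+", 0L, 260L, 1000L, 1330L, "100M60I10M130D100M")
  sig3 <- extract_signatures(r3)
  # one net event: 130 deleted minus 60 inserted within one locality
  expect_equal(sig3$type, "DEL")
  expect_equal(sig3$length, 70L)
})

test_that("balanced nearby indel pieces cancel instead of calling", {
  r <- fake_rec("r1", "+", 0L, 260L, 1000L, 1260L, "100M60I10M60D90M")
  expect_equal(nrow(extract_signatures(r)), 0L)
})

test_that("shattered deletions merge across aligned islands", {
  cig <- "100M300D20M300D20M300D100M"
  r <- fake_rec("r1", "+", 0L, 240L, 1000L, 1940L, cig)
  sig <- extract_signatures(r)
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$type, "DEL")
  expect_equal(sig$length, 900L)
  expect_equal(sig$pos, 1101L)
})

test_that("split records expose the inversion and large-indel signatures", {
  recs <- dplyr::bind_rows(
    fake_rec("r1", "+", 0L, 1000L, 0L, 1000L, "1000M"),
    fake_rec("r1", "-", 1000L, 1400L, 1000L, 1400L, "400M"),
    fake_rec("r1", "+", 1400L, 2400L, 1400L, 2400L, "1000M"))
  sig <- extract_signatures(recs)
  inv <- dplyr::filter(sig, .data$type == "INV")
  # a fully spanning read contributes the interval once per breakpoint pair
  expect_gte(nrow(inv), 1L)
  expect_true(all(inv$pos == 1001L))
  expect_true(all(inv$length == 400L))

  # same-strand split pair with a large unbalanced query gap = insertion
  ins_pair <- dplyr::bind_rows(
    fake_rec("r2", "+", 0L, 1000L, 5000L, 6000L, "1000M"),
    fake_rec("r2", "+", 1800L, 2800L, 6010L, 7010L, "1000M"))
  si <- extract_signatures(ins_pair)
  expect_equal(si$type, "INS")
  expect_equal(si$length, 790L)

  # and a large target gap = deletion
  del_pair <- dplyr::bind_rows(
    fake_rec("r3", "+", 0L, 1000L, 5000L, 6000L, "1000M"),
    fake_rec("r3", "+", 1010L, 2010L, 8000L, 9000L, "1000M"))
  sd <- extract_signatures(del_pair)
  expect_equal(sd$type, "DEL")
  expect_equal(sd$length, 1990L)
})

test_that("clustering needs support and takes medians", {
  one <- tibble::tibble(read_name = sprintf("r%d", 1:5), chrom = "chr1",
                        pos = 5000L, type = "DEL", length = 120L,
                        source = "cigar")
  calls <- cluster_and_call(one)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 5000L)
  expect_equal(calls$support, 5L)

  two <- one[1:2, ]
  expect_equal(nrow(cluster_and_call(two, min_support = 3)), 0L)

  spread <- tibble::tibble(read_name = c("a", "b", "c"), chrom = "chr1",
                           pos = c(1000L, 1004L, 1008L), type = "INS",
                           length = c(98L, 100L, 102L), source = "cigar")
  got <- cluster_and_call(spread)
  expect_equal(got$start, 1004L)
  expect_equal(got$length, 100L)

  # reproducible under permutation of input rows
  perm <- spread[c(3, 1, 2), ]
  expect_equal(cluster_and_call(perm), got)

  # support counts distinct reads, not signatures
  dup <- dplyr::bind_rows(two, two)
  expect_equal(nrow(cluster_and_call(dup, min_support = 3)), 0L)
})

test_that("overlapping duplicate estimates of one event are deduplicated", {
  sig <- dplyr::bind_rows(
    tibble::tibble(read_name = sprintf("a%d", 1:6), chrom = "chr1",
                   pos = 10000L, type = "DEL", length = 5000L, source = "cigar"),
    tibble::tibble(read_name = sprintf("b%d", 1:3), chrom = "chr1",
                   pos = 12500L, type = "DEL", length = 5000L, source = "split"))
  calls <- cluster_and_call(sig)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 6L)
})

test_that("VCF output round-trips and parses with an independent reader", {
  calls <- tibble::tibble(
    chrom = "chr1", start = c(100L, 900L, 5000L),
    end = c(100L, 1400L, 5200L), type = c("INS", "DEL", "INV"),
    length = c(300L, 500L, 200L), id = c("sv1", "sv2", "sv3"),
    support = c(7L, 9L, 4L))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls, tmp, contigs = c(chr1 = 10000L))
  back <- read_sv_vcf(tmp)
  expect_equal(back$start, calls$start)
  expect_equal(back$type, calls$type)
  expect_equal(back$length, calls$length)
  expect_equal(back$end, calls$end)
  v <- vcfR::read.vcfR(tmp, verbose = FALSE)
  expect_equal(nrow(v@fix), 3L)
  expect_equal(unname(v@fix[, "ALT"]), c("<INS>", "<DEL>", "<INV>"))
})
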