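# The two-stage hybrid procedure: nucleotide alignment locates regions of
# interest; the quantized read (and its separately quantized reverse
# complement) is then re-aligned to the quantized genome restricted to the
# extended regions.

#' Hybrid pipeline parameters
#'
#' @param k_nucleotide,w_nucleotide minimizer length / window for the
#'   nucleotide stage (minimap2 map-ont-like defaults).
#' @param k_quantized,w_quantized minimizer length / window for the quantized
#'   stage; the ternary alphabet uses k = 18 so seed entropy roughly matches
#'   a nucleotide 11-12-mer while staying specific at genome scale.
#' @param levels quantization levels `L` (3 = the ternary "HQ3" mode).
#' @param nucleotide,quantized [aln_params()] for the two stages.
#' @param roi_extension_min minimum extension fraction of read length added
#'   on each side of a region of interest (the `0.25 n` floor).
#' @return list of class `hq_params`.
#' @export
hq_params <- function(k_nucleotide = 15L, w_nucleotide = 6L,
                      k_quantized = 18L, w_quantized = 6L, levels = 3L,
                      nucleotide = aln_params(), quantized = aln_params(),
                      roi_extension_min = 0.25) {
  structure(list(
    k_nt = as.integer(k_nucleotide), w_nt = as.integer(w_nucleotide),
    k_q = as.integer(k_quantized), w_q = as.integer(w_quantized),
    levels = as.integer(levels), nt = nucleotide, q = quantized,
    ext_min = roi_extension_min
  ), class = "hq_params")
}

#' Precompute the hybrid aligner's indexes
#'
#' Builds the nucleotide minimizer index, the quantized translation of every
#' chromosome and the quantized minimizer index once, so that many reads can
#' be mapped against the same reference cheaply.
#'
#' @param genome named character vector of chromosome sequences.
#' @param qmap a [qmer_map()].
#' @param cfg a [quantizer_config()]; defaults to ternary equal-occupancy
#'   thresholds of `qmap`.
#' @param params [hq_params()].
#' @return an `hq_index` holding both indexes and the quantized genome.
#' @export
hq_index <- function(genome, qmap, cfg = NULL, params = hq_params()) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  if (is.null(cfg)) cfg <- compute_thresholds(qmap, params$levels)
  nt_index <- build_minimizer_index(genome, params$k_nt, params$w_nt, 4L)
  qgen <- lapply(genome, quantize, map = qmap, cfg = cfg)
  q_index <- build_minimizer_index(qgen, params$k_q, params$w_q, cfg$L)
  structure(list(
    nt = nt_index, q = q_index, genome = genome, qmap = qmap, cfg = cfg,
    Q = qmer_order(qmap), params = params,
    ltab = level_table(qmap, cfg),
    target_lengths = nchar(genome)
  ), class = "hq_index")
}

#' @export
print.hq_index <- function(x, ...) {
  cat(sprintf("<hq_index> %d chromosome(s), %s bases, Q=%d, L=%d\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
              x$Q, x$cfg$L))
  invisible(x)
}

as_hq_index <- function(genome, qmap, cfg, params) {
  if (inherits(genome, "hq_index")) genome else hq_index(genome, qmap, cfg, params)
}

#' Stage 1: locate regions of interest by nucleotide alignment
#'
#' Maps the read (both orientations) against the nucleotide minimizer index
#' and reports one region of interest per retained chain: the target interval
#' `[start, end)` it spans, and the aligned fraction `frac = (end - start)/n`
#' clamped to `[0, 1]`.
#'
#' @param read a single nucleotide string, or a one-row tibble with `name`
#'   and `seq`.
#' @param genome named character vector, or a prebuilt [hq_index()].
#' @param qmap,cfg,params see [hq_index()]; ignored when `genome` is already
#'   an index.
#' @return tibble of regions of interest (possibly empty): `roi_id`,
#'   `target_name`, `start`, `end`, `frac`, plus the stage-1 alignment
#'   records as the `records` attribute.
#' @export
stage1_align <- function(read, genome, qmap = NULL, cfg = NULL,
                         params = hq_params()) {
  rd <- normalize_read(read)
  ix <- if (inherits(genome, "hq_index")) genome$nt else
    build_minimizer_index(genome, params$k_nt, params$w_nt, 4L)
  if (inherits(genome, "hq_index")) params <- genome$params
  qf <- encode_dna(rd$seq)
  qr <- encode_dna(revcomp(rd$seq))
  res <- map_query(qf, qr, ix, params$nt, windows = NULL,
                   query_name = rd$name, domain = "nucleotide")
  rois <- rois_from_chains(res$chains, nchar(rd$seq))
  attr(rois, "records") <- res$records
  rois
}

rois_from_chains <- function(chains, n) {
  if (nrow(chains) == 0) {
    return(tibble::tibble(roi_id = integer(), target_name = character(),
                          start = integer(), end = integer(), frac = numeric()))
  }
  tibble::tibble(
    roi_id = seq_len(nrow(chains)),
    target_name = chains$target_name,
    start = chains$tlo, end = chains$thi,
    frac = pmin(pmax((chains$thi - chains$tlo) / n, 0), 1)
  )
}

#' Extend a region of interest
#'
#' The extension is `b = round(max(1 - frac, 0.25) * n)` bases on each side:
#' a quarter read length for well-aligned reads, growing as the stage-1
#' aligned fraction drops, so that poorly anchored reads get a wider region
#' for quantized re-alignment. Bounds are clamped to the chromosome.
#'
#' @param roi tibble from [stage1_align()] (columns `start`, `end`, `frac`).
#' @param n read length in bases.
#' @param target_length chromosome length(s), recycled along rows.
#' @param ext_min the extension floor fraction (default 0.25).
#' @return `roi` with added columns `extension`, `ext_start`, `ext_end`.
#' @export
extend_roi <- function(roi, n, target_length, ext_min = 0.25) {
  f <- pmin(pmax(roi$frac, 0), 1)
  b <- as.integer(round(pmax(1 - f, ext_min) * n))
  dplyr::mutate(roi,
    extension = b,
    ext_start = pmax(roi$start - b, 0L),
    ext_end = as.integer(pmin(roi$end + b, target_length)))
}

# merge overlapping extended ROIs per target -> disjoint stage-2 windows
merge_rois <- function(roi) {
  roi |>
    dplyr::group_by(.data$target_name) |>
    dplyr::arrange(.data$ext_start, .by_group = TRUE) |>
    dplyr::mutate(new_block = cumsum(
      dplyr::lag(cummax(.data$ext_end), default = -1L) < .data$ext_start)) |>
    dplyr::group_by(.data$target_name, .data$new_block) |>
    dplyr::summarise(ext_start = min(.data$ext_start),
                     ext_end = max(.data$ext_end), .groups = "drop") |>
    dplyr::select("target_name", "ext_start", "ext_end")
}

#' Map quantized coordinates back to nucleotide coordinates
#'
#' A quantized symbol at position `p` summarizes the `Q` nucleotide bases
#' `p .. p+Q-1`, so a half-open quantized interval `[qstart, qend)` covers
#' nucleotides `[offset + qstart, offset + qend + Q - 1)` where `offset` is
#' the extended region's start (0 when coordinates are already genomic).
#'
#' @param qstart,qend 0-based half-open quantized coordinates.
#' @param roi optional one-row tibble with `ext_start` (the region offset).
#' @param Q k-mer order of the quantizer.
#' @param target_length optional clamp.
#' @return tibble with `nstart`, `nend` (0-based half-open, nucleotide).
#' @export
map_quantized_to_nucleotide <- function(qstart, qend, roi = NULL, Q = 6L,
                                        target_length = NULL) {
  stopifnot(all(qstart >= 0), all(qstart < qend))
  off <- if (is.null(roi)) 0L else as.integer(roi$ext_start)
  ns <- off + as.integer(qstart)
  ne <- off + as.integer(qend) + Q - 1L
  if (!is.null(target_length)) {
    ns <- pmin(ns, target_length)
    ne <- pmin(ne, target_length)
  }
  tibble::tibble(nstart = ns, nend = ne)
}

#' Stage 2: quantized re-alignment within extended regions
#'
#' Quantizes the read and, separately, its reverse complement (the quantized
#' reverse complement is not derivable from the forward quantized sequence),
#' and aligns both against the quantized genome restricted to the extended
#' regions of interest. The best-scoring orientation yields the primary
#' record; leftover query intervals are re-chained into supplementary
#' records, so a read spanning an inversion splits into +/-/+ segments.
#'
#' @inheritParams stage1_align
#' @param rois extended regions from [stage1_align()] + [extend_roi()].
#' @param genome an [hq_index()] (preferred) or named character vector.
#' @return tibble of quantized-domain alignment records; `tstart`/`tend` are
#'   genomic window-start coordinates, `nt_tstart`/`nt_tend` the
#'   back-translated nucleotide span.
#' @export
stage2_align <- function(read, genome, rois, qmap = NULL, cfg = NULL,
                         params = hq_params()) {
  rd <- normalize_read(read)
  ix <- as_hq_index(genome, qmap, cfg, params)
  wins <- stage2_windows(rois, ix)
  stage2_map(rd, ix, wins)
}

stage2_windows <- function(rois, ix) {
  Q <- ix$Q
  merged <- merge_rois(rois)
  tid <- match(merged$target_name, ix$q$target_names) - 1L
  lo <- merged$ext_start
  hi <- pmax(merged$ext_start, merged$ext_end - Q + 1L)
  keep <- !is.na(tid) & hi - lo >= Q
  if (!any(keep)) return(NULL)
  list(tid = as.integer(tid[keep]), lo = as.integer(lo[keep]),
       hi = as.integer(hi[keep]))
}

stage2_map <- function(rd, ix, wins) {
  if (is.null(wins)) return(empty_records())
  qf <- quantize(rd$seq, ix$qmap, ix$cfg)
  qr <- quantize_revcomp(rd$seq, ix$qmap, ix$cfg)
  res <- map_query(as.integer(unclass(qf)), as.integer(unclass(qr)),
                   ix$q, ix$params$q, windows = wins,
                   query_name = rd$name, domain = "quantized")
  rec <- res$records
  if (nrow(rec) > 0) {
    nt <- map_quantized_to_nucleotide(rec$tstart, rec$tend, Q = ix$Q)
    len <- ix$target_lengths[match(rec$target_name, names(ix$genome))]
    rec$nt_tstart <- pmin(nt$nstart, len)
    rec$nt_tend <- pmin(nt$nend, len)
  } else {
    rec$nt_tstart <- integer()
    rec$nt_tend <- integer()
  }
  rec
}

normalize_read <- function(read) {
  if (is.character(read)) {
    nm <- names(read)
    if (is.null(nm)) nm <- "read"
    return(list(name = nm[1], seq = unname(read[1])))
  }
  list(name = read$name[1], seq = read$seq[1])
}

#' Run the full hybrid alignment pipeline
#'
#' For every read: stage-1 nucleotide alignment finds regions of interest,
#' each region is extended, and the quantized read plus its quantized reverse
#' complement are re-aligned within the extended regions. Reads with no
#' stage-1 region are left unmapped. Deterministic for fixed inputs.
#'
#' @param reads tibble with columns `name` and `seq`, or a named character
#'   vector of read sequences.
#' @param genome named character vector of chromosomes, or a prebuilt
#'   [hq_index()].
#' @param qmap a [qmer_map()] (ignored if `genome` is an index).
#' @param cfg optional [quantizer_config()].
#' @param params [hq_params()].
#' @param keep_stage1 also return the stage-1 nucleotide records (needed for
#'   nucleotide-vs-quantized comparisons); default `TRUE`.
#' @return tibble of alignment records for all reads, quantized-domain rows
#'   flagged `domain == "quantized"` and stage-1 rows `domain ==
#'   "nucleotide"`. The `read_length` column is always in bases;
#'   `query_length` is in the record's own domain units.
#' @export
run_hqalign <- function(reads, genome, qmap = NULL, cfg = NULL,
                        params = hq_params(), keep_stage1 = TRUE) {
  ix <- as_hq_index(genome, qmap, cfg, params)
  params <- ix$params
  reads <- normalize_reads(reads)
  n_reads <- nrow(reads)
  Q <- ix$Q
  q_tlen <- ix$q$target_lengths
  par_nt <- unclass(params$nt)
  par_q <- unclass(params$q)
  acc <- vector("list", 2L * n_reads)
  ai <- 0L
  for (i in seq_len(n_reads)) {
    seq_i <- reads$seq[i]
    n <- nchar(seq_i)
    qf <- encode_dna(seq_i)
    qr <- rev(ifelse(qf < 0L, -1L, 3L - qf)) # reverse complement in code space
    s1 <- cpp_map_query(qf, qr, ix$nt$hash, ix$nt$pos, ix$nt$tid,
                        ix$nt$targets, ix$nt$k, ix$nt$w, 4L, NULL, par_nt)
    if (keep_stage1 && length(s1$records$orient) > 0) {
      ai <- ai + 1L
      acc[[ai]] <- c(s1$records, list(read = i, domain = 1L, qlen = length(qf)))
    }
    ch <- s1$chains
    if (length(ch$tid) == 0) next
    # extend + merge regions of interest, then translate to quantized windows
    f <- pmin(pmax((ch$thi - ch$tlo) / n, 0), 1)
    b <- as.integer(round(pmax(1 - f, params$ext_min) * n))
    lo <- pmax(ch$tlo - b, 0L)
    hi <- pmin(ch$thi + b, q_tlen[ch$tid + 1L] + Q - 1L)
    o <- order(ch$tid, lo)
    tid <- ch$tid[o]; lo <- lo[o]; hi <- hi[o]
    keep <- rep(TRUE, length(lo))
    if (length(lo) > 1) {
      for (j in 2:length(lo)) {
        if (tid[j] == tid[j - 1L] && lo[j] <= hi[j - 1L]) {
          hi[j] <- max(hi[j], hi[j - 1L]); lo[j] <- lo[j - 1L]
          keep[j - 1L] <- FALSE
        }
      }
    }
    tid <- tid[keep]; lo <- lo[keep]
    hi <- pmax(lo, pmin(hi[keep] - Q + 1L, q_tlen[tid + 1L]))
    ok <- hi - lo >= Q
    if (!any(ok)) next
    wins <- list(tid = tid[ok], lo = lo[ok], hi = hi[ok])
    qlev <- quantize_codes(qf, ix$ltab, ix$cfg$L, Q)
    rlev <- quantize_codes(qr, ix$ltab, ix$cfg$L, Q)
    s2 <- cpp_map_query(qlev, rlev, ix$q$hash, ix$q$pos, ix$q$tid,
                        ix$q$targets, ix$q$k, ix$q$w, ix$cfg$L, wins, par_q)
    if (length(s2$records$orient) > 0) {
      ai <- ai + 1L
      acc[[ai]] <- c(s2$records, list(read = i, domain = 2L, qlen = length(qlev)))
    }
  }
  if (ai == 0L) return(dplyr::mutate(empty_records(), read_length = integer(),
                                     nt_tstart = integer(), nt_tend = integer()))
  acc <- acc[seq_len(ai)]
  take <- function(fld) do.call(c, lapply(acc, function(x) x[[fld]]))
  nrec <- vapply(acc, function(x) length(x$orient), integer(1))
  read_i <- rep(vapply(acc, `[[`, integer(1), "read"), nrec)
  dom_i <- rep(vapply(acc, `[[`, integer(1), "domain"), nrec)
  qlen <- rep(vapply(acc, `[[`, integer(1), "qlen"), nrec)
  orient <- take("orient")
  qs0 <- take("qstart"); qe0 <- take("qend")
  res <- tibble::tibble(
    query_name = reads$name[read_i],
    target_name = ix$nt$target_names[take("tid") + 1L],
    strand = ifelse(orient == 1L, "-", "+"),
    qstart = ifelse(orient == 1L, qlen - qe0, qs0),
    qend = ifelse(orient == 1L, qlen - qs0, qe0),
    tstart = take("tstart"), tend = take("tend"),
    cigar = take("cigar"),
    score = take("score"), nm = take("nm"),
    mapq = 0L,
    is_primary = FALSE, is_supplementary = FALSE,
    chain_rank = take("chain_rank"), chain_score = take("chain_score"),
    n_anchors = take("n_anchors"),
    query_length = qlen,
    domain = c("nucleotide", "quantized")[dom_i],
    read_length = nchar(reads$seq)[read_i]
  )
  best_other <- take("best_other")
  res$mapq <- compute_mapq(res$chain_score, pmin(best_other, res$chain_score),
                           res$n_anchors)
  key <- paste0(read_i, "/", dom_i)
  score_adj <- res$score + ifelse(res$chain_rank == 0L, 1e9, 0)
  o <- order(key, -score_adj)
  res$is_primary[o] <- !duplicated(key[o])
  res$is_supplementary <- !res$is_primary
  qdom <- res$domain == "quantized"
  len_of <- nchar(ix$genome)[match(res$target_name, names(ix$genome))]
  res$nt_tstart <- ifelse(qdom, pmin(res$tstart, len_of), NA_integer_)
  res$nt_tend <- ifelse(qdom, pmin(res$tend + Q - 1L, len_of), NA_integer_)
  res
}

# quantize an already-encoded nucleotide code vector via the index level table
quantize_codes <- function(codes, ltab, L, Q) {
  w <- kmer_window_codes(codes, Q)
  lv <- rep(L %/% 2L, length(w))
  ok <- w >= 0L
  lv[ok] <- ltab[w[ok] + 1L]
  lv
}

normalize_reads <- function(reads) {
  if (is.character(reads)) {
    nm <- names(reads)
    if (is.null(nm)) nm <- sprintf("read%06d", seq_along(reads))
    return(tibble::tibble(name = nm, seq = unname(reads)))
  }
  stopifnot(all(c("name", "seq") %in% names(reads)))
  tibble::as_tibble(reads[, c("name", "seq")])
}
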