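# Generic minimizer seed--chain--banded-extend aligner over a configurable
# finite alphabet (4-letter nucleotide or L-letter quantized).

#' Alignment parameters
#'
#' Scoring and heuristics of the seed-chain-extend aligner. Defaults are
#' minimap2-like and apply to both the nucleotide and the quantized alphabet.
#'
#' @param match,mismatch,gap_open,gap_extend affine-gap scoring. A gap of
#'   length `L` costs `gap_open + gap_extend * L`.
#' @param max_gap maximum query/target gap (in symbols) bridged by one chain;
#'   must exceed the largest deletion/insertion to be represented inside a
#'   single alignment record.
#' @param gap_cap cap on the per-link chaining penalty, so a chain can jump a
#'   large structural-variant gap at bounded cost.
#' @param lookback how many previous anchors the chaining DP inspects.
#' @param max_occ seeds occurring more often than this in the index are
#'   skipped (repeat masking).
#' @param min_chain_anchors,min_chain_score minimum anchors / score for a
#'   chain to be retained.
#' @param max_chains number of chains kept per query.
#' @param band_pad half-width padding of the banded gap-filling DP.
#' @param zdrop x-drop threshold terminating end extensions.
#' @param split_min,split_frac an inter-anchor gap with both sides at least
#'   `split_min` symbols whose alignment scores below
#'   `-split_frac * (gap_q + gap_t)` splits the record (the mechanism that
#'   exposes inverted segments as split alignments).
#' @param min_new a non-primary segment must cover at least this many query
#'   symbols not already covered to be emitted (supplementary threshold).
#' @param min_seg minimum emitted segment length, in query symbols.
#' @param ext_slack end extensions keep the furthest point scoring within
#'   `ext_slack` of the best, trading a little score for contiguity on
#'   noisy tails (0 = strictly score-maximal extension).
#' @param extend_ends whether to extend past the outermost anchors.
#' @return a named list of class `aln_params`.
#' @export
aln_params <- function(match = 2, mismatch = -4, gap_open = -4, gap_extend = -2,
                       max_gap = 16000L, gap_cap = 15, lookback = 64L,
                       max_occ = 10L, min_chain_anchors = 3L,
                       min_chain_score = 3, max_chains = 8L,
                       band_pad = 48L, zdrop = 400, split_min = 100L,
                       split_frac = 0.1, min_new = 100L, min_seg = 30L,
                       ext_slack = 50, extend_ends = TRUE) {
  structure(list(
    match = match, mismatch = mismatch, gap_open = gap_open, gap_ext = gap_extend,
    max_gap = as.integer(max_gap), gap_cap = gap_cap, lookback = as.integer(lookback),
    max_occ = as.integer(max_occ), min_chain_anchors = as.integer(min_chain_anchors),
    min_chain_score = min_chain_score, max_chains = as.integer(max_chains),
    band_pad = as.integer(band_pad), zdrop = zdrop, split_min = as.integer(split_min),
    split_frac = split_frac, min_new = as.integer(min_new),
    min_seg = as.integer(min_seg), ext_slack = ext_slack,
    extend_ends = isTRUE(extend_ends), band = 0L
  ), class = "aln_params")
}

# coerce a sequence to integer symbol codes
as_symbols <- function(x, alphabet_size) {
  if (inherits(x, "hq_seq")) return(as.integer(unclass(x)))
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    return(encode_dna(x))
  }
  as.integer(x)
}

check_alphabet <- function(codes, alphabet_size, what = "sequence") {
  bad <- codes[!is.na(codes) & (codes < -1L | codes >= alphabet_size)]
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("%s contains symbol %d outside alphabet of size %d",
              what, bad[1], alphabet_size),
      class = "hqalign_bad_alphabet")
  }
  codes[is.na(codes)] <- -1L
  codes
}

#' Build a minimizer index
#'
#' Indexes every k-mer position that attains the minimum hash of at least one
#' window of `w` consecutive k-mers (ties index all positions). Hashing is an
#' invertible 64-bit mix of the packed k-mer, so indexing is deterministic.
#'
#' @param targets named character vector of nucleotide sequences, or a named
#'   list of integer symbol vectors / `hq_seq` objects.
#' @param k minimizer k-mer length (15 is the nucleotide default; quantized
#'   ternary alignment uses 18 to keep seed entropy comparable).
#' @param w window size in k-mers.
#' @param alphabet_size number of symbols (4 nucleotide, `L` quantized).
#' @return a `minimizer_index`: the hash-sorted position table plus the
#'   encoded targets it was built from.
#' @export
build_minimizer_index <- function(targets, k = 15L, w = 10L, alphabet_size = 4L) {
  k <- as.integer(k); w <- as.integer(w); alphabet_size <- as.integer(alphabet_size)
  if (k < 1 || w < 1) rlang::abort("k and w must be >= 1", class = "hqalign_bad_param")
  if (is.character(targets)) {
    nm <- names(targets)
    enc <- lapply(targets, encode_dna)
  } else {
    nm <- names(targets)
    enc <- lapply(targets, as_symbols, alphabet_size = alphabet_size)
  }
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm) > 0) {
    rlang::abort("targets must have unique non-empty names", class = "hqalign_bad_param")
  }
  enc <- lapply(seq_along(enc), function(i) {
    check_alphabet(enc[[i]], alphabet_size, what = paste0("target ", nm[i]))
  })
  idx <- cpp_build_index(enc, k, w, alphabet_size)
  structure(list(
    hash = idx$hash, pos = idx$pos, tid = idx$tid,
    k = k, w = w, alphabet_size = alphabet_size,
    targets = enc, target_names = nm,
    target_lengths = vapply(enc, length, integer(1))
  ), class = "minimizer_index")
}

#' @export
print.minimizer_index <- function(x, ...) {
  cat(sprintf("<minimizer_index> k=%d w=%d |alphabet|=%d: %d minimizers over %d target(s), %s symbols\n",
              x$k, x$w, x$alphabet_size, length(x$pos), length(x$targets),
              format(sum(x$target_lengths), big.mark = ",")))
  invisible(x)
}

#' Minimizers of a single sequence
#'
#' Mostly a testing/inspection surface for the indexing rule.
#'
#' @param seq sequence (string or symbol vector).
#' @inheritParams build_minimizer_index
#' @return tibble with `pos` (0-based) and `hash`.
#' @export
minimizers <- function(seq, k = 15L, w = 10L, alphabet_size = 4L) {
  s <- check_alphabet(as_symbols(seq, alphabet_size), alphabet_size)
  m <- cpp_minimizers(s, as.integer(k), as.integer(w), as.integer(alphabet_size))
  tibble::tibble(pos = m$pos, hash = m$hash)
}

#' Chain anchors into colinear runs
#'
#' Scores a chain as its anchor count minus, per link, a gap penalty
#' `min(0.01 * g + 0.5 * log2(g + 1), gap_cap)` where `g` is the difference
#' between the query and target gaps. Capping the penalty lets a chain jump a
#' large insertion or deletion at bounded cost. Chains are strictly increasing
#' in both coordinates; the best chain is extracted, its anchors removed, and
#' the process repeats.
#'
#' @param anchors tibble with `query_pos`, `target_pos` and optionally
#'   `target_id` (default one target), sorted by target then query position.
#' @param max_gap maximum per-link gap in either coordinate.
#' @param min_chain_anchors minimum anchors per emitted chain.
#' @param gap_cap,lookback,max_chains,min_chain_score see [aln_params()].
#' @return tibble with one row per chain: `chain_id`, `score`, `n_anchors`
#'   and an `anchors` list-column (row indices into the input), sorted by
#'   score descending.
#' @export
chain_anchors <- function(anchors, max_gap = 12000L, min_chain_anchors = 1L,
                          gap_cap = 15, lookback = 64L, max_chains = 6L,
                          min_chain_score = 0.5) {
  if (nrow(anchors) == 0) {
    return(tibble::tibble(chain_id = integer(), score = numeric(),
                          n_anchors = integer(), anchors = list()))
  }
  grp <- if ("target_id" %in% names(anchors)) as.integer(anchors$target_id) else
    rep(0L, nrow(anchors))
  ord <- order(grp, anchors$target_pos, anchors$query_pos)
  res <- cpp_chain(as.integer(anchors$query_pos[ord]),
                   as.integer(anchors$target_pos[ord]), grp[ord],
                   as.integer(max_gap), gap_cap, as.integer(lookback),
                   as.integer(min_chain_anchors), min_chain_score,
                   as.integer(max_chains))
  tibble::tibble(
    chain_id = seq_along(res),
    score = vapply(res, function(ch) ch$score, numeric(1)),
    n_anchors = vapply(res, function(ch) length(ch$idx), integer(1)),
    anchors = lapply(res, function(ch) ord[ch$idx])
  )
}

#' Banded extension of a chain into a CIGAR alignment
#'
#' Fills the gaps between consecutive anchors with banded affine-gap dynamic
#' programming and extends past the outermost anchors with x-drop extension,
#' producing one alignment record whose CIGAR is consistent with its
#' coordinates. If the band cannot connect consecutive anchors it is doubled
#' up to a cap, then the call fails with a `band_exceeded` error.
#'
#' @param query,target sequences (strings or symbol vectors on a common
#'   alphabet).
#' @param chain tibble with `query_pos`, `target_pos` of the chained anchors
#'   (ascending), e.g. `anchors[chain_anchors(anchors)$anchors[[1]], ]`.
#' @param band_width initial DP band half-width.
#' @param scoring an [aln_params()] (only the scoring fields are used).
#' @param k anchor (seed) length in symbols.
#' @param alphabet_size symbols in the alphabet; inferred for strings/hq_seq.
#' @param band_cap band width at which widening gives up.
#' @return one-row alignment record tibble (`qstart`, `qend`, `tstart`,
#'   `tend` 0-based half-open, `cigar`, `score`, `nm`).
#' @export
banded_extend <- function(query, target, chain, band_width = 100L,
                          scoring = aln_params(), k = 15L,
                          alphabet_size = NULL, band_cap = 4096L) {
  if (nrow(chain) == 0) rlang::abort("chain must be nonempty", class = "hqalign_bad_param")
  if (is.null(alphabet_size)) {
    alphabet_size <- if (inherits(query, "hq_seq")) attr(query, "L") else 4L
  }
  q <- check_alphabet(as_symbols(query, alphabet_size), alphabet_size)
  t <- check_alphabet(as_symbols(target, alphabet_size), alphabet_size)
  par <- unclass(scoring)
  par$split_min <- .Machine$integer.max # no record splitting in the single-record op
  band <- as.integer(band_width)
  repeat {
    par$band <- band
    res <- cpp_align_chain(q, t, as.integer(chain$query_pos),
                           as.integer(chain$target_pos), as.integer(k), par)
    if (isTRUE(res$band_ok)) break
    if (band >= band_cap) {
      rlang::abort("band_exceeded", class = "hqalign_band_exceeded")
    }
    band <- min(band * 2L, as.integer(band_cap))
  }
  tibble::tibble(
    qstart = res$qstart[1], qend = res$qend[1],
    tstart = res$tstart[1], tend = res$tend[1],
    strand = "+", cigar = as.character(res$cigar[1]),
    score = res$score[1], nm = res$nm[1]
  )
}

#' Levenshtein edit distance
#'
#' Exact unit-cost edit distance, computed by banded dynamic programming with
#' band doubling (fast for similar kilobase-scale sequences).
#'
#' @param a,b strings or integer symbol vectors.
#' @return integer edit distance.
#' @export
edit_distance <- function(a, b) {
  enc <- function(x) if (is.character(x)) utf8ToInt(x) else as.integer(unclass(x))
  cpp_edit_distance(enc(a), enc(b))
}

#' Mapping quality from chain-score separation
#'
#' A unique hit gets MAPQ 60; otherwise
#' `clamp(round(40 * (1 - second/best) * min(1, anchors/10)), 0, 60)`, so
#' quality decays as the second-best candidate approaches the best and for
#' thinly-anchored chains.
#'
#' @param best_score,second_best_score chain scores, `best >= second >= 0`
#'   (`second = 0` when the hit is unique).
#' @param chain_anchor_count anchors in the best chain.
#' @return integer MAPQ in `[0, 60]`; vectorized.
#' @export
compute_mapq <- function(best_score, second_best_score, chain_anchor_count) {
  if (any(best_score <= 0)) {
    rlang::abort("best_score must be > 0", class = "hqalign_bad_param")
  }
  second <- pmin(second_best_score, best_score)
  q <- ifelse(second <= 0, 60,
              pmax(0, pmin(60, round(40 * (1 - second / best_score) *
                                       pmin(1, chain_anchor_count / 10)))))
  as.integer(q)
}

# internal: map one query (and optionally its other-orientation twin) against
# an index, returning tidy records and chain summaries
map_query <- function(qf, qr, index, params, windows = NULL,
                      query_name = "query", domain = "nucleotide") {
  res <- cpp_map_query(qf, qr, index$hash, index$pos, index$tid,
                       index$targets, index$k, index$w, index$alphabet_size,
                       windows, unclass(params))
  r <- res$records
  n <- length(r$orient)
  Lq <- length(qf)
  if (n == 0) {
    rec <- empty_records()
  } else {
    strand <- ifelse(r$orient == 1L, "-", "+")
    qs <- ifelse(r$orient == 1L, Lq - r$qend, r$qstart)
    qe <- ifelse(r$orient == 1L, Lq - r$qstart, r$qend)
    mapq <- compute_mapq(r$chain_score, pmin(r$best_other, r$chain_score), r$n_anchors)
    primary <- rep(FALSE, n)
    primary[which(r$chain_rank == 0L)[which.max(r$score[r$chain_rank == 0L])]] <- TRUE
    rec <- tibble::tibble(
      query_name = query_name,
      target_name = index$target_names[r$tid + 1L],
      strand = strand,
      qstart = as.integer(qs), qend = as.integer(qe),
      tstart = r$tstart, tend = r$tend,
      cigar = as.character(r$cigar),
      score = r$score, nm = r$nm, mapq = mapq,
      is_primary = primary, is_supplementary = !primary,
      chain_rank = r$chain_rank, chain_score = r$chain_score,
      n_anchors = r$n_anchors,
      query_length = Lq, domain = domain
    )
  }
  ch <- res$chains
  chains <- tibble::tibble(
    orient = ch$orient, target_name = index$target_names[ch$tid + 1L],
    qlo = ch$qlo, qhi = ch$qhi, tlo = ch$tlo, thi = ch$thi,
    score = ch$score, n_anchors = ch$n_anchors
  )
  list(records = rec, chains = chains)
}

empty_records <- function() {
  tibble::tibble(
    query_name = character(), target_name = character(), strand = character(),
    qstart = integer(), qend = integer(), tstart = integer(), tend = integer(),
    cigar = character(), score = numeric(), nm = integer(), mapq = integer(),
    is_primary = logical(), is_supplementary = logical(),
    chain_rank = integer(), chain_score = numeric(), n_anchors = integer(),
    query_length = integer(), domain = character()
  )
}
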