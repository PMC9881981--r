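# SV benchmarking: breakpoint score, length similarity, Truvari-style
# one-to-one matching with precision/recall/F1, the union model, and
# complementary-call classification.

#' Breakpoint score of a call against its truth entry
#'
#' Mean absolute offset of the start and end breakpoints,
#' `(|start' - start| + |end' - end|) / 2`; lower means more accurate
#' breakpoints. Symmetric in its arguments. Vectorized over paired rows.
#'
#' @param truth,call SV call tibbles (equal height, paired rows) with
#'   `chrom`, `start`, `end`.
#' @return numeric vector of scores, in bases.
#' @export
breakpoint_score <- function(truth, call) {
  if (!all(truth$chrom == call$chrom)) {
    rlang::abort("breakpoint score requires matching chromosomes",
                 class = "hqalign_chrom_mismatch")
  }
  (abs(call$start - truth$start) + abs(call$end - truth$end)) / 2
}

#' SV length similarity
#'
#' `min(length_truth, length_call) / max(length_truth, length_call)`, a
#' ratio in (0, 1]; 1 means identical lengths. Symmetric. Vectorized.
#'
#' @param truth,call SV call tibbles (paired rows) with `length`.
#' @return numeric vector in (0, 1].
#' @export
length_similarity <- function(truth, call) {
  if (any(truth$length < 1) || any(call$length < 1)) {
    rlang::abort("SV lengths must be >= 1", class = "hqalign_bad_param")
  }
  pmin(truth$length, call$length) / pmax(truth$length, call$length)
}

#' Match a call set against a truth set
#'
#' Candidate pairs must share chromosome and type, lie within `refdist`
#' breakpoint score of each other and have length similarity at least
#' `min_len_sim` (the Truvari default gate of 0.7). Pairs are assigned
#' greedily one-to-one by ascending breakpoint score (ties broken by truth
#' start); unmatched calls count as false positives, unmatched truth entries
#' as false negatives.
#'
#' @param truth_set,call_set SV call tibbles.
#' @param refdist maximum breakpoint score for a candidate pair (bases).
#' @param min_len_sim minimum length similarity.
#' @param exclude optional tibble of intervals (`chrom`, `start`, `end`,
#'   1-based inclusive; e.g. read from a BED file) — truth entries and calls
#'   whose start lies inside an excluded interval are dropped before
#'   matching.
#' @return an `hq_bench` object: `$matches` (one row per matched pair with
#'   `bp_score` and `len_sim`), `$tp`, `$fp`, `$fn`, `$precision`,
#'   `$recall`, `$f1`, plus the unmatched call/truth ids.
#' @export
match_calls <- function(truth_set, call_set, refdist = 500, min_len_sim = 0.7,
                        exclude = NULL) {
  if (!is.null(exclude) && nrow(exclude) > 0) {
    drop_in <- function(x) {
      keep <- vapply(seq_len(nrow(x)), function(i) {
        !any(exclude$chrom == x$chrom[i] & exclude$start <= x$start[i] &
               x$start[i] <= exclude$end)
      }, logical(1))
      x[keep, , drop = FALSE]
    }
    truth_set <- drop_in(tibble::as_tibble(truth_set))
    call_set <- drop_in(tibble::as_tibble(call_set))
  }
  tr <- dplyr::mutate(tibble::as_tibble(truth_set),
                      .t = dplyr::row_number())
  ca <- dplyr::mutate(tibble::as_tibble(call_set),
                      .c = dplyr::row_number())
  cand <- dplyr::inner_join(
    dplyr::select(tr, ".t", chrom = "chrom", type = "type",
                  t_start = "start", t_end = "end", t_len = "length"),
    dplyr::select(ca, ".c", chrom = "chrom", type = "type",
                  c_start = "start", c_end = "end", c_len = "length"),
    by = c("chrom", "type"), relationship = "many-to-many")
  if (nrow(cand) > 0) {
    cand$bp_score <- (abs(cand$c_start - cand$t_start) +
                        abs(cand$c_end - cand$t_end)) / 2
    cand$len_sim <- pmin(cand$t_len, cand$c_len) / pmax(cand$t_len, cand$c_len)
    cand <- dplyr::filter(cand, .data$bp_score <= refdist,
                          .data$len_sim >= min_len_sim)
    cand <- dplyr::arrange(cand, .data$bp_score, .data$t_start)
  }
  used_t <- logical(nrow(tr)); used_c <- logical(nrow(ca))
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ti <- cand$.t[i]; ci <- cand$.c[i]
    if (used_t[ti] || used_c[ci]) next
    used_t[ti] <- TRUE; used_c[ci] <- TRUE
    keep <- c(keep, i)
  }
  matches <- cand[keep, , drop = FALSE]
  if (!"bp_score" %in% names(matches)) { # no candidate pairs at all
    matches$bp_score <- numeric(0)
    matches$len_sim <- numeric(0)
  }
  tp <- nrow(matches)
  fp <- sum(!used_c)
  fn <- sum(!used_t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(
    matches = tibble::tibble(
      truth_id = if ("id" %in% names(tr)) tr$id[matches$.t] else as.character(matches$.t),
      call_id = if ("id" %in% names(ca)) ca$id[matches$.c] else as.character(matches$.c),
      truth_row = matches$.t, call_row = matches$.c,
      chrom = matches$chrom, type = matches$type,
      bp_score = matches$bp_score, len_sim = matches$len_sim),
    tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1,
    unmatched_truth = which(!used_t), unmatched_calls = which(!used_c),
    refdist = refdist, min_len_sim = min_len_sim
  ), class = "hq_bench")
}

#' @export
print.hq_bench <- function(x, ...) {
  cat(sprintf("<hq_bench> TP %d, FP %d, FN %d | precision %.3f recall %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
tidy.hq_bench <- function(x, ...) x$matches

#' @export
glance.hq_bench <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
                 recall = x$recall, f1 = x$f1)
}

#' Union model of two call sets
#'
#' Every call of A, plus each call of B that has no match in A under the
#' [match_calls()] gate (same `refdist` and `min_len_sim`); for deduplicated
#' pairs A's record is kept. Exploits the complementary detections of two
#' aligners: the union's recall is at least each constituent's.
#'
#' @param calls_a,calls_b SV call tibbles.
#' @param refdist,min_len_sim the matching gate.
#' @return merged SV call tibble with an `origin` column.
#' @export
union_model <- function(calls_a, calls_b, refdist = 500, min_len_sim = 0.7) {
  a <- dplyr::mutate(tibble::as_tibble(calls_a), origin = "A")
  b <- dplyr::mutate(tibble::as_tibble(calls_b), origin = "B")
  if (nrow(b) == 0) return(a)
  if (nrow(a) == 0) return(b)
  m <- match_calls(a, b, refdist = refdist, min_len_sim = min_len_sim)
  extra <- b[m$unmatched_calls, , drop = FALSE]
  out <- dplyr::bind_rows(a, extra)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Classify one method's exclusive true positives against the other method
#'
#' Calls made only by method A (at the default gate) are re-matched against
#' B's calls with the length-similarity requirement relaxed: calls that now
#' match were captured by B at a lower similarity; the rest are unique to A.
#'
#' @param only_in_a SV call tibble of A-only calls.
#' @param calls_b method B's call set.
#' @param relaxed_min_len_sim relaxed similarity gate (default 0).
#' @param refdist breakpoint gate (unchanged).
#' @return `only_in_a` with a `status` column:
#'   `"captured_at_lower_similarity"` or `"unique"`.
#' @export
classify_complementary <- function(only_in_a, calls_b,
                                   relaxed_min_len_sim = 0, refdist = 500) {
  a <- tibble::as_tibble(only_in_a)
  if (nrow(a) == 0) return(dplyr::mutate(a, status = character(0)))
  if (nrow(calls_b) == 0) return(dplyr::mutate(a, status = "unique"))
  m <- match_calls(a, calls_b, refdist = refdist,
                   min_len_sim = relaxed_min_len_sim)
  status <- rep("unique", nrow(a))
  status[m$matches$truth_row] <- "captured_at_lower_similarity"
  dplyr::mutate(a, status = status)
}
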