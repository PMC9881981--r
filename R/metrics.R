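# Alignment-quality metrics: well-aligned classification, normalized edit
# distance, normalized alignment length, and paired cohort comparison.

#' Is a read well-aligned?
#'
#' A read is well-aligned when its primary alignment covers at least 90% of
#' the read (target span vs read length, both in the record's domain) with
#' mapping quality strictly greater than 20. The span test is inclusive
#' (exactly 0.9 passes); MAPQ 20 itself fails.
#'
#' @param record alignment record tibble (vectorized over rows).
#' @param read_length_in_domain read length in the record's domain (`n` for
#'   nucleotide records, `n - Q + 1` for quantized records); defaults to the
#'   records' own `query_length` column.
#' @return logical vector.
#' @export
is_well_aligned <- function(record, read_length_in_domain = record$query_length) {
  (record$tend - record$tstart) >= 0.9 * read_length_in_domain & record$mapq > 20
}

#' Normalized edit distance of an alignment
#'
#' The edit distance between the entire nucleotide read and the nucleotide
#' genome slice under the alignment, divided by read length. Only the
#' *coordinates* come from the alignment's domain: a quantized interval is
#' first translated back to nucleotides (a symbol at `p` covers bases
#' `p..p+Q-1`), and the distance itself is always computed on nucleotide
#' sequences.
#'
#' @param read nucleotide read string.
#' @param genome named character vector of chromosomes.
#' @param target_name chromosome of the alignment.
#' @param start,end 0-based half-open alignment interval on the target, in
#'   `domain` coordinates (genomic window-start positions for quantized).
#' @param domain `"nucleotide"` or `"quantized"`.
#' @param Q quantizer order (used only for `domain = "quantized"`).
#' @return normalized edit distance (>= 0).
#' @export
normalized_edit_distance <- function(read, genome, target_name, start, end,
                                     domain = c("nucleotide", "quantized"),
                                     Q = 6L) {
  domain <- match.arg(domain)
  n <- nchar(read)
  if (n == 0) rlang::abort("empty read", class = "hqalign_bad_param")
  if (start >= end) rlang::abort("start must be < end", class = "hqalign_bad_param")
  tseq <- genome[[target_name]]
  if (domain == "quantized") {
    nt <- map_quantized_to_nucleotide(start, end, Q = Q,
                                      target_length = nchar(tseq))
    start <- nt$nstart; end <- nt$nend
  }
  slice <- substr(tseq, start + 1L, end)
  edit_distance(read, slice) / n
}

#' Normalized alignment length
#'
#' Ratio of the aligned target span to the read length, each in the
#' alignment's own domain (the quantized variant divides by the quantized
#' read length `n - Q + 1`). A contiguous full-length alignment scores 1.
#'
#' @param start,end alignment interval on the target (same domain units as
#'   `read_length_in_domain`); `start <= end`.
#' @param read_length_in_domain read length in domain units (> 0).
#' @return numeric ratio >= 0; vectorized.
#' @export
normalized_alignment_length <- function(start, end, read_length_in_domain) {
  stopifnot(all(start <= end))
  if (any(read_length_in_domain <= 0)) {
    rlang::abort("read length must be > 0", class = "hqalign_bad_param")
  }
  (end - start) / read_length_in_domain
}

# pick one representative (primary, highest mapq) record per read
representative_records <- function(records) {
  records |>
    dplyr::filter(.data$is_primary) |>
    dplyr::group_by(.data$query_name) |>
    dplyr::slice_max(.data$mapq, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Compare two alignment methods over a read cohort
#'
#' Classifies each read as well-aligned or not under both methods, computes
#' per-read normalized edit distances (always on nucleotide sequences, at
#' each method's own coordinates), and fits an ordinary-least-squares
#' regression of method B's normalized edit distance on method A's over the
#' reads aligned by both. A slope below 1 means method B's alignments sit at
#' systematically lower edit distance than method A's on the same reads.
#'
#' @param records_a,records_b alignment tibbles for the two methods.
#' @param reads reads tibble (`name`, `seq`); the well-aligned percentage is
#'   over all reads, aligned or not.
#' @param genome named character vector of chromosomes.
#' @param Q quantizer order for back-translating quantized coordinates.
#' @param label_a,label_b method labels used in summaries.
#' @return an `hq_cohort` object: `$summary` (per-method counts and
#'   well-aligned percentage), `$pairs` (per-read metric pairs over common
#'   reads), `$slope`, `$intercept`.
#' @export
summarize_cohort <- function(records_a, records_b, reads, genome, Q = 6L,
                             label_a = "A", label_b = "B") {
  reads <- normalize_reads(reads)
  rep_a <- representative_records(records_a)
  rep_b <- representative_records(records_b)
  one_method <- function(rep, label) {
    wa <- is_well_aligned(rep)
    tibble::tibble(method = label, n_reads = nrow(reads),
                   n_aligned = nrow(rep),
                   pct_well_aligned = 100 * sum(wa) / nrow(reads))
  }
  summary <- dplyr::bind_rows(one_method(rep_a, label_a), one_method(rep_b, label_b))
  common <- intersect(rep_a$query_name, rep_b$query_name)
  # nucleotide-domain slice intervals of each representative record; when
  # both methods place a read identically the (expensive) edit distance is
  # computed once
  nt_interval <- function(rep, nm) {
    i <- match(nm, rep$query_name)
    s <- rep$tstart[i]; e <- rep$tend[i]
    qd <- rep$domain[i] == "quantized"
    e[qd] <- e[qd] + Q - 1L
    list(target = rep$target_name[i], s = s, e = e)
  }
  ia <- nt_interval(rep_a, common)
  ib <- nt_interval(rep_b, common)
  rd <- reads$seq[match(common, reads$name)]
  ned_at <- function(j, iv) {
    tseq <- genome[[iv$target[j]]]
    slice <- substr(tseq, iv$s[j] + 1L, min(iv$e[j], nchar(tseq)))
    edit_distance(rd[j], slice) / nchar(rd[j])
  }
  ned_a <- vapply(seq_along(common), ned_at, numeric(1), iv = ia)
  same <- ia$target == ib$target & ia$s == ib$s & ia$e == ib$e
  ned_b <- ned_a
  if (any(!same)) {
    ned_b[!same] <- vapply(which(!same), ned_at, numeric(1), iv = ib)
  }
  nal_of <- function(rep, nm) {
    i <- match(nm, rep$query_name)
    normalized_alignment_length(rep$tstart[i], rep$tend[i], rep$query_length[i])
  }
  pairs <- tibble::tibble(
    query_name = common,
    ned_a = ned_a, ned_b = ned_b,
    nal_a = nal_of(rep_a, common), nal_b = nal_of(rep_b, common),
    well_a = is_well_aligned(rep_a[match(common, rep_a$query_name), ]),
    well_b = is_well_aligned(rep_b[match(common, rep_b$query_name), ])
  )
  if (nrow(pairs) < 2) {
    rlang::abort("need at least 2 common reads for the regression",
                 class = "hqalign_bad_param")
  }
  fit <- stats::lm(ned_b ~ ned_a, data = pairs)
  structure(list(summary = summary, pairs = pairs,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 labels = c(label_a, label_b)),
            class = "hq_cohort")
}

#' @export
print.hq_cohort <- function(x, ...) {
  cat("<hq_cohort>\n")
  print(x$summary)
  cat(sprintf("OLS %s ~ %s: slope %.4f, intercept %.4f over %d common reads\n",
              x$labels[2], x$labels[1], x$slope, x$intercept, nrow(x$pairs)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.hq_cohort <- function(x, ...) x$pairs

#' @export
glance.hq_cohort <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, n_pairs = nrow(x$pairs),
    pct_well_a = x$summary$pct_well_aligned[1],
    pct_well_b = x$summary$pct_well_aligned[2]
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter of per-read normalized edit distance for two methods
#'
#' @param object an `hq_cohort` from [summarize_cohort()].
#' @param ... unused.
#' @return a ggplot: method B vs method A with the identity line and the
#'   fitted regression.
#' @export
autoplot.hq_cohort <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$ned_a, y = .data$ned_b)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(x = paste("normalized edit distance,", object$labels[1]),
                  y = paste("normalized edit distance,", object$labels[2]),
                  subtitle = sprintf("slope %.3f, intercept %.3f",
                                     object$slope, object$intercept)) +
    ggplot2::theme_minimal()
}

#' Plot a Q-mer map with its quantization thresholds
#'
#' @param map a [qmer_map()].
#' @param cfg optional [quantizer_config()] whose cutoffs are drawn.
#' @return a ggplot of sorted median currents.
#' @export
plot_qmer_map <- function(map, cfg = NULL) {
  df <- tibble::tibble(rank = rank(map$current, ties.method = "first"),
                       current = map$current)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$current)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::labs(x = "Q-mer (sorted by median current)", y = "current (pA)") +
    ggplot2::theme_minimal()
  if (!is.null(cfg)) {
    p <- p + ggplot2::geom_hline(yintercept = cfg$thresholds,
                                 colour = "firebrick", linetype = "dashed")
  }
  p
}
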