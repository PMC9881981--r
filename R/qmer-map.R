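#' The Q-mer current map
#'
#' A Q-mer map is the physics model of a nanopore flow cell: every Q-length
#' nucleotide word is assigned the median ionic current (in pA) it produces
#' while traversing the pore, optionally with a standard deviation. Words with
#' near-identical currents are the source of systematic basecalling confusions,
#' and the quantizer built on top of this map (see [compute_thresholds()] and
#' [quantize()]) collapses such words onto a common symbol.
#'
#' @param currents named numeric vector mapping every one of the `4^Q` Q-mers
#'   (alphabet `A`, `C`, `G`, `T`) to a median current in pA. All values must
#'   be finite and positive and the mapping must be total.
#' @param Q k-mer order of the pore model (default 6, the R9.4-style hexamer).
#' @param sds optional named numeric vector of per-Q-mer standard deviations.
#'
#' @return A tibble of class `qmer_map` with columns `kmer`, `current` and
#'   (optionally) `sd`, sorted lexicographically, carrying `Q` as an attribute.
#' @seealso [load_qmer_map()], [synthesize_qmer_map()], [compute_thresholds()]
#' @export
qmer_map <- function(currents, Q = 6L, sds = NULL) {
  Q <- as.integer(Q)
  expected <- all_qmers(Q)
  nm <- names(currents)
  if (is.null(nm)) {
    rlang::abort("`currents` must be a named vector.", class = "hqalign_bad_map")
  }
  bad_len <- nm[nchar(nm) != Q]
  if (length(bad_len) > 0) {
    rlang::abort(
      paste0("k-mer of wrong length for Q=", Q, ": ", bad_len[1]),
      class = "hqalign_bad_kmer"
    )
  }
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate Q-mer: ", dup[1]), class = "hqalign_duplicate_qmer")
  }
  missing <- setdiff(expected, nm)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing Q-mer: ", missing[1]), class = "hqalign_missing_qmer")
  }
  extra <- setdiff(nm, expected)
  if (length(extra) > 0) {
    rlang::abort(paste0("invalid Q-mer: ", extra[1]), class = "hqalign_bad_kmer")
  }
  cur <- unname(currents[expected])
  if (anyNA(cur) || !all(is.finite(cur)) || any(cur <= 0)) {
    rlang::abort("all currents must be finite and > 0", class = "hqalign_bad_current")
  }
  out <- tibble::tibble(kmer = expected, current = as.numeric(cur))
  if (!is.null(sds)) out$sd <- as.numeric(unname(sds[expected]))
  structure(out, Q = Q, class = c("qmer_map", class(out)))
}

#' All Q-mers in lexicographic order
#'
#' @param Q word length.
#' @return character vector of length `4^Q` over `A < C < G < T`.
#' @export
all_qmers <- function(Q) {
  Q <- as.integer(Q)
  if (Q < 1) rlang::abort("Q must be >= 1", class = "hqalign_bad_q")
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), Q), KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic order
  do.call(paste0, rev(grid))
}

#' @export
print.qmer_map <- function(x, ...) {
  cat(sprintf("<qmer_map> Q=%d, %d Q-mers, currents %.2f-%.2f pA\n",
              attr(x, "Q"), nrow(x), min(x$current), max(x$current)))
  NextMethod()
}

#' Q of a map
#' @param map a [qmer_map()].
#' @return integer k-mer order.
#' @export
qmer_order <- function(map) attr(map, "Q")

#' Read a pore model table
#'
#' Reads the tab-separated pore-model dialect: columns `kmer`, `level_mean`
#' and optionally `level_stdv`, with an optional header line. The table must
#' contain every `4^Q` Q-mer exactly once; violations raise classed errors
#' (`hqalign_missing_qmer`, `hqalign_duplicate_qmer`, `hqalign_bad_current`,
#' `hqalign_bad_kmer`).
#'
#' @param path path to the TSV model file.
#' @param Q expected k-mer order.
#' @return a [qmer_map()].
#' @export
load_qmer_map <- function(path, Q = 6L) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 2) {
    rlang::abort("model table needs at least columns kmer and level_mean",
                 class = "hqalign_bad_map")
  }
  # header line is optional: drop it when the first field is not a Q-mer word
  if (!grepl("^[ACGTacgt]+$", raw[1, 1])) raw <- raw[-1, , drop = FALSE]
  kmer <- toupper(raw[[1]])
  cur <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(cur)) {
    rlang::abort(paste0("non-numeric current for k-mer ", kmer[which(is.na(cur))[1]]),
                 class = "hqalign_bad_current")
  }
  sds <- NULL
  if (ncol(raw) >= 3) {
    sds_num <- suppressWarnings(as.numeric(raw[[3]]))
    if (!anyNA(sds_num)) sds <- stats::setNames(sds_num, kmer)
  }
  qmer_map(stats::setNames(cur, kmer), Q = Q, sds = sds)
}

#' Write a pore model table
#'
#' Inverse of [load_qmer_map()]: tab-separated `kmer`, `level_mean`
#' (`level_stdv` when present), with a header line.
#'
#' @param map a [qmer_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qmer_map <- function(map, path) {
  df <- as.data.frame(map)
  names(df)[1:2] <- c("kmer", "level_mean")
  if (ncol(df) >= 3) names(df)[3] <- "level_stdv"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthesize a Q-mer map
#'
#' Draws a deterministic synthetic pore model: every Q-mer receives a uniform
#' current within `current_range`, and one extra pair of distinct Q-mers is
#' forced to lie within 1 pA of each other so that current-level confusability
#' (the phenomenon the quantizer exploits) is guaranteed to be present.
#'
#' @param Q k-mer order (>= 1).
#' @param seed integer seed; the map is a pure function of `(Q, seed,
#'   current_range)`.
#' @param current_range numeric length-2, the pA range of drawn currents.
#' @return a [qmer_map()] with `sd` column.
#' @export
synthesize_qmer_map <- function(Q = 6L, seed = 1L, current_range = c(60, 120)) {
  Q <- as.integer(Q)
  if (Q < 1) rlang::abort("Q must be >= 1", class = "hqalign_bad_q")
  stopifnot(length(current_range) == 2, current_range[1] < current_range[2])
  withr::local_seed(as.integer(seed))
  n <- 4L^Q
  cur <- stats::runif(n, current_range[1], current_range[2])
  if (n >= 2) {
    pair <- sample.int(n, 2L)
    delta <- stats::runif(1, -0.5, 0.5)
    cur[pair[2]] <- min(max(cur[pair[1]] + delta, current_range[1]), current_range[2])
  }
  sds <- stats::runif(n, 0.5, 2.5)
  kmers <- all_qmers(Q)
  qmer_map(stats::setNames(cur, kmers), Q = Q, sds = stats::setNames(sds, kmers))
}
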