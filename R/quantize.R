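#' @useDynLib hqalign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- encoding helpers -------------------------------------------------------

.dna_code <- local({
  tab <- rep(-1L, 256L)
  tab[utf8ToInt("A") + 1L] <- 0L; tab[utf8ToInt("a") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L; tab[utf8ToInt("c") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L; tab[utf8ToInt("g") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L; tab[utf8ToInt("t") + 1L] <- 3L
  tab
})

#' Encode a nucleotide string as integers
#'
#' `A,C,G,T -> 0..3`; anything else (including `N`) becomes `-1`.
#'
#' @param seq a single nucleotide string.
#' @return integer vector of per-base codes.
#' @export
encode_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  .dna_code[utf8ToInt(seq) + 1L]
}

#' Reverse complement
#'
#' `A<->T`, `C<->G`, `N -> N` (case preserved for upper-case input).
#'
#' @param seq nucleotide string(s).
#' @return reverse-complemented string(s).
#' @export
revcomp <- function(seq) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", seq))
}

# rolling base-4 window codes; -1 where the window touches a non-ACGT base
kmer_window_codes <- function(ints, Q) {
  n <- length(ints)
  nw <- n - Q + 1L
  if (nw <= 0L) return(integer(0))
  code <- integer(nw)
  bad <- logical(nw)
  for (j in seq_len(Q)) {
    b <- ints[j:(j + nw - 1L)]
    bad <- bad | b < 0L
    code <- code * 4L + pmax(b, 0L)
  }
  code[bad] <- -1L
  code
}

# ---- quantizer --------------------------------------------------------------

#' Quantizer configuration
#'
#' Holds the number of levels `L` and the `L - 1` strictly ascending current
#' cutoffs (pA) of the hard-thresholding quantizer. `L = 3` is the ternary
#' "HQ3" mode.
#'
#' @param thresholds strictly increasing numeric vector of length `L - 1`.
#' @param L number of levels (>= 2); defaults to `length(thresholds) + 1`.
#' @return an object of class `quantizer_config`.
#' @export
quantizer_config <- function(thresholds, L = length(thresholds) + 1L) {
  L <- as.integer(L)
  if (L < 2) rlang::abort("L must be >= 2", class = "hqalign_bad_levels")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != L - 1L || is.unsorted(thresholds, strictly = TRUE)) {
    rlang::abort("thresholds must be strictly increasing, length L - 1",
                 class = "hqalign_bad_levels")
  }
  structure(list(L = L, thresholds = thresholds), class = "quantizer_config")
}

#' @export
print.quantizer_config <- function(x, ...) {
  cat(sprintf("<quantizer_config> L=%d, thresholds: %s pA\n",
              x$L, paste(sprintf("%.2f", x$thresholds), collapse = ", ")))
  invisible(x)
}

#' Place quantization thresholds from a pore model
#'
#' Cutoffs are the empirical quantiles of the `4^Q` model currents at
#' cumulative fractions `j/L`, so the levels receive (up to tie mass) equal
#' numbers of Q-mers — the maximum-entropy choice for the quantized alphabet.
#' A current exactly equal to a cutoff is assigned to the lower level.
#'
#' @param map a [qmer_map()].
#' @param L number of levels, `2 <= L <= 4^Q`.
#' @return a [quantizer_config()].
#' @export
compute_thresholds <- function(map, L = 3L) {
  L <- as.integer(L)
  if (L < 2) rlang::abort("L must be >= 2", class = "hqalign_bad_levels")
  if (L > nrow(map)) rlang::abort("L exceeds number of Q-mers", class = "hqalign_bad_levels")
  th <- unname(stats::quantile(map$current, probs = seq_len(L - 1L) / L, type = 7))
  if (is.unsorted(th, strictly = TRUE)) {
    # duplicated currents can collapse quantiles; nudge apart deterministically
    th <- th + seq_along(th) * 1e-9
  }
  quantizer_config(th, L)
}

# per-code level table in lexicographic Q-mer order (0-based code + 1 -> level)
level_table <- function(map, cfg) {
  lvl <- findInterval(map$current, cfg$thresholds, left.open = TRUE)
  as.integer(lvl)
}

new_hq_seq <- function(levels, n, Q, L) {
  structure(as.integer(levels), n = as.integer(n), Q = as.integer(Q),
            L = as.integer(L), class = "hq_seq")
}

#' @export
print.hq_seq <- function(x, ...) {
  cat(sprintf("<hq_seq> %d symbols (source %d nt, Q=%d, L=%d)\n",
              length(x), attr(x, "n"), attr(x, "Q"), attr(x, "L")))
  if (length(x) > 0) {
    shown <- paste(utils::head(unclass(x), 60), collapse = "")
    cat(" ", shown, if (length(x) > 60) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Translate a nucleotide sequence to current levels
#'
#' Slides a Q-wide window over `seq` and looks each word up in the pore
#' model. Windows touching a non-ACGT base give `NA`.
#'
#' @param seq nucleotide string.
#' @param map a [qmer_map()].
#' @return numeric vector of length `max(nchar(seq) - Q + 1, 0)`, in pA.
#' @export
to_current_levels <- function(seq, map) {
  Q <- qmer_order(map)
  codes <- kmer_window_codes(encode_dna(seq), Q)
  out <- rep(NA_real_, length(codes))
  ok <- codes >= 0L
  out[ok] <- map$current[codes[ok] + 1L]
  out
}

#' Quantize a nucleotide sequence
#'
#' The current-level translation of `seq` under the pore model is hard
#' thresholded into `L` levels: symbol `p` is the number of cutoffs strictly
#' below the current of window `p` (a current equal to a cutoff falls to the
#' lower level). Windows containing a non-ACGT base get the middle level
#' `floor(L/2)` rather than an invented current.
#'
#' @param seq nucleotide string.
#' @param map a [qmer_map()].
#' @param cfg a [quantizer_config()]; defaults to the ternary
#'   equal-occupancy thresholds of `map`.
#' @return an `hq_seq`: integer levels in `[0, L)` with attributes `n`
#'   (source length), `Q` and `L`.
#' @export
quantize <- function(seq, map, cfg = compute_thresholds(map, 3L)) {
  Q <- qmer_order(map)
  codes <- kmer_window_codes(encode_dna(seq), Q)
  lt <- level_table(map, cfg)
  lvl <- rep(cfg$L %/% 2L, length(codes))
  ok <- codes >= 0L
  lvl[ok] <- lt[codes[ok] + 1L]
  new_hq_seq(lvl, nchar(seq), Q, cfg$L)
}

#' Quantize the reverse complement
#'
#' Equal to `quantize(revcomp(seq), ...)`. The quantized reverse complement
#' is *not* a function of the forward quantized sequence — windows read in
#' opposite orientations are different Q-mers with unrelated currents — so an
#' aligner over the quantized alphabet must receive it as a second query.
#'
#' @inheritParams quantize
#' @return an `hq_seq` of the same length as `quantize(seq, map, cfg)`.
#' @export
quantize_revcomp <- function(seq, map, cfg = compute_thresholds(map, 3L)) {
  quantize(revcomp(seq), map, cfg)
}
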