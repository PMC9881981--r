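# Generators emulating the benchmark inputs: repeat-containing genomes,
# planted structural variants, and nanopore-like reads whose substitution
# errors can be biased toward Q-mer current-level confusability.

resample <- function(x, ...) x[sample.int(length(x), ...)]

#' Generate a random genome with tandem-repeat arrays
#'
#' A uniform-GC random background interleaved with VNTR-style tandem arrays
#' (random unit of length drawn from `vntr_unit_range`, repeated to an array
#' of 200-2000 bases) until approximately `repeat_fraction` of the genome
#' lies in annotated repeats. Repeats are where alignment is ambiguous and
#' most structural variation concentrates, so the generator plants them
#' deliberately.
#'
#' @param length genome length in bases (>= 1000).
#' @param repeat_fraction target fraction of repeat bases, in `[0, 0.9]`.
#' @param vntr_unit_range integer range of tandem unit lengths.
#' @param seed integer seed; output is deterministic given all arguments.
#' @param divergence per-base substitution rate between successive copies of
#'   a tandem unit (real VNTR copies are a few percent diverged; identical
#'   copies would make every coordinate inside an array ambiguous).
#' @param name chromosome name.
#' @return named character vector of length 1 with a `repeats` attribute
#'   (tibble of 1-based repeat intervals).
#' @export
generate_genome <- function(length, repeat_fraction = 0.2,
                            vntr_unit_range = c(10L, 100L), seed = 1L,
                            name = "chr1", divergence = 0.05) {
  if (length < 1000) rlang::abort("genome length must be >= 1000",
                                  class = "hqalign_bad_param")
  if (repeat_fraction < 0 || repeat_fraction > 0.9) {
    rlang::abort("repeat_fraction must be in [0, 0.9]", class = "hqalign_bad_param")
  }
  withr::local_seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  target <- round(repeat_fraction * length)
  arrays <- character(0)
  rep_total <- 0L
  while (rep_total < target) {
    unit_len <- sample(vntr_unit_range[1]:vntr_unit_range[2], 1L)
    alen <- min(round(stats::runif(1, 200, 2000)), target - rep_total + 200L)
    if (alen < 2L * unit_len) alen <- 2L * unit_len
    unit <- sample(bases, unit_len, replace = TRUE)
    # copies diverge by ~5% substitutions, as real VNTR units do; exact
    # copies would make coordinates inside an array globally ambiguous
    ncopy <- ceiling(alen / unit_len)
    copies <- vapply(seq_len(ncopy), function(i) {
      u <- unit
      mut <- which(stats::runif(unit_len) < divergence)
      if (length(mut) > 0) {
        u[mut] <- bases[(match(u[mut], bases) - 1L +
                           sample.int(3L, length(mut), replace = TRUE)) %% 4L + 1L]
      }
      paste(u, collapse = "")
    }, character(1))
    arr <- substr(paste(copies, collapse = ""), 1L, alen)
    arrays <- c(arrays, arr)
    rep_total <- rep_total + alen
  }
  bg_total <- max(length - rep_total, length(arrays) + 1L)
  n_chunks <- base::length(arrays) + 1L
  cuts <- sort(sample.int(bg_total - 1L, n_chunks - 1L))
  bg_lens <- diff(c(0L, cuts, bg_total))
  bg <- vapply(bg_lens, function(l) {
    paste(sample(bases, l, replace = TRUE), collapse = "")
  }, character(1))
  pieces <- character(2L * n_chunks - 1L)
  pieces[seq(1, by = 2, length.out = n_chunks)] <- bg
  if (base::length(arrays) > 0) {
    pieces[seq(2, by = 2, length.out = base::length(arrays))] <- arrays
  }
  seq <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  is_arr <- seq_along(pieces) %% 2 == 0
  repeats <- tibble::tibble(start = starts[is_arr], end = ends[is_arr])
  out <- stats::setNames(seq, name)
  attr(out, "repeats") <- repeats
  out
}

#' Plant structural variants into a genome
#'
#' Places `n_indel` insertions/deletions (split evenly) and `n_inv`
#' inversions with lengths uniform on `[len_low, len_high]`, footprints
#' non-overlapping with a separation margin. The truth set's coordinates
#' refer to the *original* genome: reads are simulated from the mutated
#' genome and aligned back to the original, the discovery direction of an
#' SV-calling benchmark.
#'
#' @param genome named character vector (the original reference).
#' @param n_indel number of INS+DEL events (even split).
#' @param n_inv number of inversions.
#' @param len_low,len_high SV length bounds (uniform).
#' @param seed integer seed.
#' @param margin minimum bases between SV footprints (and to the ends).
#' @return list with `genome` (mutated named character vector) and `truth`
#'   (SV call tibble on original coordinates; for INS, `start` is the base
#'   before which the sequence is inserted and `end = start`).
#' @export
plant_svs <- function(genome, n_indel, n_inv, len_low = 50L, len_high = 10000L,
                      seed = 1L, margin = 2000L) {
  withr::local_seed(as.integer(seed))
  chrom_len <- nchar(genome)
  n <- n_indel + n_inv
  type <- c(sample(rep(c("INS", "DEL"), length.out = n_indel)),
            rep("INV", n_inv))
  len <- sample(len_low:len_high, n, replace = TRUE)
  foot <- ifelse(type == "INS", 1L, len)
  if (sum(foot[type != "INS"]) >= sum(chrom_len) / 2) {
    rlang::abort("total SV footprint exceeds half the genome",
                 class = "hqalign_bad_param")
  }
  chrom <- sample(names(genome), n, replace = TRUE, prob = chrom_len)
  placed <- vector("list", base::length(genome))
  names(placed) <- names(genome)
  start <- integer(n)
  # place the largest footprints first: rejection sampling at high packing
  # density fails for big events placed late
  ord <- order(-foot, seq_len(n))
  for (i in ord) {
    G <- chrom_len[[chrom[i]]]
    ok <- FALSE
    for (try in 1:20000) {
      s <- sample.int(G - foot[i] - 2L * margin, 1L) + margin
      iv <- c(s - margin, s + foot[i] - 1L + margin)
      clash <- FALSE
      for (p in placed[[chrom[i]]]) {
        if (iv[1] <= p[2] && p[1] <= iv[2]) { clash <- TRUE; break }
      }
      if (!clash) {
        placed[[chrom[i]]] <- c(placed[[chrom[i]]], list(c(s, s + foot[i] - 1L)))
        start[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      rlang::abort("could not place all SVs without overlap",
                   class = "hqalign_placement_failed")
    }
  }
  truth <- tibble::tibble(chrom = chrom, start = start, type = type,
                          length = len) |>
    dplyr::mutate(end = ifelse(type == "INS", start, start + len)) |>
    dplyr::arrange(.data$chrom, .data$start)
  truth$id <- sprintf("truth%04d", seq_len(nrow(truth)))
  bases <- c("A", "C", "G", "T")
  mutated <- genome
  for (nm in names(genome)) {
    ev <- dplyr::filter(truth, .data$chrom == nm)
    if (nrow(ev) == 0) next
    src <- genome[[nm]]
    pieces <- character(0)
    cursor <- 1L
    for (i in seq_len(nrow(ev))) {
      s <- ev$start[i]; l <- ev$length[i]
      pieces <- c(pieces, substr(src, cursor, s - 1L))
      if (ev$type[i] == "INS") {
        pieces <- c(pieces, paste(sample(bases, l, replace = TRUE), collapse = ""))
        cursor <- s
      } else if (ev$type[i] == "DEL") {
        cursor <- s + l
      } else { # INV
        pieces <- c(pieces, revcomp(substr(src, s, s + l - 1L)))
        cursor <- s + l
      }
    }
    pieces <- c(pieces, substr(src, cursor, nchar(src)))
    mutated[[nm]] <- paste(pieces, collapse = "")
  }
  list(genome = mutated,
       truth = dplyr::select(truth, "chrom", "start", "end", "type",
                             "length", "id"))
}

# substitution/insertion/deletion noise on one read; substitutions optionally
# biased so the altered Q-mer stays in the same quantization bin
apply_read_errors <- function(src, error_rate, mix, ltab, Q, confusion_weight) {
  len <- nchar(src)
  k <- stats::rbinom(1L, len, error_rate)
  if (k == 0L) return(src)
  pos <- sort(sample.int(len, k))
  etype <- sample(c("S", "I", "D"), k, replace = TRUE, prob = mix)
  chars <- strsplit(src, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  subs <- pos[etype == "S"]
  if (base::length(subs) > 0) {
    ints <- .dna_code[utf8ToInt(src) + 1L]
    b0 <- ints[subs]
    new <- (b0 + sample.int(3L, base::length(subs), replace = TRUE)) %% 4L
    if (!is.null(ltab) && confusion_weight > 0 && len >= Q) {
      codes <- kmer_window_codes(ints, Q)
      s <- pmin(pmax(subs - Q + 1L, 1L), len - Q + 1L)
      off <- subs - s
      code0 <- codes[s]
      mult <- 4L^(Q - 1L - off)
      lvl0 <- ifelse(code0 >= 0L, ltab[code0 + 1L], NA_integer_)
      u <- stats::runif(base::length(subs))
      for (j in seq_along(subs)) {
        if (is.na(lvl0[j]) || u[j] >= confusion_weight) next
        alts <- setdiff(0:3, b0[j])
        alt_lvl <- ltab[code0[j] + (alts - b0[j]) * mult[j] + 1L]
        elig <- alts[alt_lvl == lvl0[j]]
        if (base::length(elig) > 0) new[j] <- resample(elig, 1L)
      }
    }
    chars[subs] <- bases[new + 1L]
  }
  ins <- pos[etype == "I"]
  if (base::length(ins) > 0) {
    chars[ins] <- paste0(chars[ins],
                         sample(bases, base::length(ins), replace = TRUE))
  }
  del <- pos[etype == "D"]
  if (base::length(del) > 0) chars[del] <- ""
  paste(chars, collapse = "")
}

#' Simulate nanopore-like long reads
#'
#' Read lengths follow a log-normal fit to `(mean_len, median_len)` (the
#' heavy tail is what lets long reads span large variants), truncated to
#' `[min_len, max_len]`. Reads are drawn from either strand with probability
#' 0.5. Per-base errors at `error_rate` split ~40/30/30 into substitutions,
#' insertions and deletions; with probability `confusion_weight` a
#' substitution is chosen, where possible, so that the altered Q-mer's
#' current falls in the same quantization bin as the original — errors that
#' are invisible in the quantized space, the bias a current-level-aware
#' aligner exploits.
#'
#' @param genome named character vector to sample reads from (typically the
#'   mutated genome of [plant_svs()]).
#' @param coverage mean sequencing depth.
#' @param mean_len,median_len read-length distribution parameters (bases);
#'   `mean_len >= median_len`.
#' @param error_rate total per-base error rate, in `[0, 0.3]`.
#' @param qmap optional [qmer_map()] enabling the confusion bias.
#' @param confusion_weight probability a substitution is drawn
#'   bin-preservingly (0 = unbiased).
#' @param seed integer seed.
#' @param max_len,min_len truncation bounds for read lengths.
#' @param error_mix sub/ins/del proportions.
#' @param levels quantization levels for the confusion bias.
#' @return tibble with `name`, `seq` and the truth source interval: `chrom`,
#'   `start`, `end` (1-based inclusive on the input genome), `strand`.
#' @export
simulate_reads <- function(genome, coverage = 40, mean_len = 14000,
                           median_len = 4500, error_rate = 0.10, qmap = NULL,
                           confusion_weight = 0, seed = 1L, max_len = 50000L,
                           min_len = 300L, error_mix = c(sub = 0.4, ins = 0.3,
                                                         del = 0.3),
                           levels = 3L) {
  if (error_rate < 0 || error_rate > 0.3) {
    rlang::abort("error_rate must be in [0, 0.3]", class = "hqalign_bad_param")
  }
  if (mean_len < median_len) {
    rlang::abort("mean_len must be >= median_len", class = "hqalign_bad_param")
  }
  withr::local_seed(as.integer(seed))
  chrom_len <- nchar(genome)
  total_target <- coverage * sum(chrom_len)
  sigma <- sqrt(2 * log(max(mean_len / median_len, 1 + 1e-9)))
  mu <- log(median_len)
  lens <- integer(0)
  while (sum(lens) < total_target) {
    batch <- pmin(pmax(round(stats::rlnorm(1000L, mu, sigma)), min_len),
                  min(max_len, max(chrom_len)))
    lens <- c(lens, as.integer(batch))
  }
  lens <- lens[seq_len(which(cumsum(lens) >= total_target)[1])]
  n <- base::length(lens)
  chrom <- sample(names(genome), n, replace = TRUE, prob = chrom_len)
  lens <- pmin(lens, chrom_len[chrom])
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_len[[chrom[i]]] - lens[i] + 1L, 1L)
  }, integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ltab <- NULL
  Q <- 6L
  if (!is.null(qmap)) {
    Q <- qmer_order(qmap)
    ltab <- level_table(qmap, compute_thresholds(qmap, levels))
  }
  mix <- error_mix / sum(error_mix)
  seqs <- character(n)
  for (i in seq_len(n)) {
    src <- substr(genome[[chrom[i]]], start[i], start[i] + lens[i] - 1L)
    if (strand[i] == "-") src <- revcomp(src)
    seqs[i] <- if (error_rate > 0) {
      apply_read_errors(src, error_rate, mix, ltab, Q, confusion_weight)
    } else src
  }
  tibble::tibble(
    name = sprintf("read%06d", seq_len(n)),
    seq = seqs, chrom = chrom, start = start,
    end = start + lens - 1L, strand = strand
  )
}
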