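# Minimal structural-variant caller from alignment records: CIGAR indel runs
# and split-read inversion signatures, clustered into calls. Deliberately the
# simplest caller sufficient for simulated benchmarking, not a re-creation of
# a production SV caller.

parse_cigar <- function(cigar) {
  m <- stringi::stri_match_all_regex(cigar, "(\\d+)([MIDSH])")[[1]]
  list(len = as.integer(m[, 2]), op = m[, 3])
}

# genomic (nucleotide) target coordinates of a record, regardless of domain
rec_coords <- function(records) {
  if ("nt_tstart" %in% names(records)) {
    q <- records$domain == "quantized"
    ts <- ifelse(q, records$nt_tstart, records$tstart)
    te <- ifelse(q, records$nt_tend, records$tend)
  } else {
    ts <- records$tstart; te <- records$tend
  }
  list(tstart = ts, tend = te)
}

#' Extract per-read SV signatures from alignment records
#'
#' CIGAR insertion/deletion runs of at least `min_sv_len` symbols become
#' INS/DEL signatures. A minus-strand record bracketed by two plus-strand
#' records of the same read over (near-)adjacent target intervals becomes an
#' INV signature spanning the minus segment — the split-alignment inversion
#' signature.
#'
#' @param records alignment record tibble (one domain; quantized records are
#'   placed at their back-translated nucleotide coordinates).
#' @param min_sv_len minimum indel length, in symbols (default 50).
#' @param min_piece minimum length of a CIGAR indel run considered part of an
#'   SV; runs of at least this size separated by short aligned islands are
#'   merged into one signature (a large indel is often shattered by spurious
#'   short matches, especially over the small quantized alphabet).
#' @param intra_read_gap maximum island (bases) bridged when merging indel
#'   runs within one record.
#' @param inv_adjacency_tol maximum gap/overlap (bases) between consecutive
#'   segments still considered adjacent for the inversion signature.
#' @return tibble of signatures: `read_name`, `chrom`, `pos` (1-based),
#'   `type`, `length`, `source`.
#' @export
extract_signatures <- function(records, min_sv_len = 50L, min_piece = 10L,
                               intra_read_gap = 1000L,
                               inv_adjacency_tol = 500L) {
  empty <- tibble::tibble(read_name = character(), chrom = character(),
                          pos = integer(), type = character(),
                          length = integer(), source = character())
  if (nrow(records) == 0) return(empty)
  co <- rec_coords(records)
  acc_read <- list(); acc_chrom <- list(); acc_pos <- list()
  acc_type <- list(); acc_len <- list(); acc_src <- list()
  si <- 0L
  emit <- function(read, chrom, pos, type, len, src) {
    si <<- si + 1L
    acc_read[[si]] <<- rep(read, length(pos))
    acc_chrom[[si]] <<- rep(chrom, length(pos))
    acc_pos[[si]] <<- pos
    acc_type[[si]] <<- type
    acc_len[[si]] <<- len
    acc_src[[si]] <<- rep(src, length(pos))
  }
  # CIGAR indel runs, merged across small aligned islands within the record
  for (i in seq_len(nrow(records))) {
    cg <- parse_cigar(records$cigar[i])
    piece <- which(cg$len >= min_piece & cg$op %in% c("I", "D"))
    if (length(piece) == 0) next
    tadv <- ifelse(cg$op %in% c("M", "D"), cg$len, 0L)
    qadv <- ifelse(cg$op %in% c("M", "I"), cg$len, 0L)
    tpos <- co$tstart[i] + c(0L, cumsum(tadv))[seq_along(tadv)]
    qpos <- c(0L, cumsum(qadv))[seq_along(qadv)]
    pc <- tibble::tibble(
      op = cg$op[piece], len = cg$len[piece],
      ts = tpos[piece], te = tpos[piece] + tadv[piece],
      qs = qpos[piece], qe = qpos[piece] + qadv[piece])
    out_pos <- integer(0); out_type <- character(0); out_len <- integer(0)
    # group indel pieces (both types together) by proximity; the group's net
    # query/target imbalance gives the event type and size, so balanced
    # slip artifacts cancel and an insertion partly absorbed as mismatch
    # runs (cheap over a small alphabet) still reports its full length
    j <- 1L
    while (j <= nrow(pc)) {
      k2 <- j
      while (k2 < nrow(pc) &&
             pc$ts[k2 + 1L] - pc$te[k2] <= intra_read_gap &&
             pc$qs[k2 + 1L] - pc$qe[k2] <= intra_read_gap) {
        k2 <- k2 + 1L
      }
      qspan <- pc$qe[k2] - pc$qs[j]
      tspan <- pc$te[k2] - pc$ts[j]
      net <- qspan - tspan
      if (abs(net) >= min_sv_len) {
        out_pos <- c(out_pos, pc$ts[j] + 1L)
        out_type <- c(out_type, if (net > 0) "INS" else "DEL")
        out_len <- c(out_len, as.integer(abs(net)))
      }
      j <- k2 + 1L
    }
    if (length(out_pos) == 0) next
    emit(records$query_name[i], records$target_name[i], out_pos, out_type,
         out_len, "cigar")
  }
  # split-pair indel signatures: consecutive same-strand segments of one read
  # whose query and target gaps are imbalanced by >= min_sv_len indicate an
  # insertion (query >> target) or deletion (target >> query) that the
  # aligner represented as a record break rather than a CIGAR run
  by_read <- split(seq_len(nrow(records)), records$query_name)
  for (idx in by_read) {
    if (length(idx) < 2) next
    idx <- idx[order(records$qstart[idx])]
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b2 <- idx[j + 1L]
      if (records$strand[a] != records$strand[b2]) next
      if (records$target_name[a] != records$target_name[b2]) next
      fwd <- records$strand[a] == "+"
      # target order follows query order on +, reverses on -
      ta <- if (fwd) a else b2
      tb <- if (fwd) b2 else a
      if (co$tstart[tb] < co$tend[ta]) next
      qgap <- records$qstart[b2] - records$qend[a]
      tgap <- co$tstart[tb] - co$tend[ta]
      if (qgap < 0) next
      diffgap <- qgap - tgap
      if (diffgap >= min_sv_len && tgap <= 2L * qgap) {
        emit(records$query_name[a], records$target_name[a], co$tend[ta] + 1L,
             "INS", as.integer(diffgap), "split")
      } else if (-diffgap >= min_sv_len) {
        # the unaligned query gap presumably belongs to the flank just after
        # the left record, so the deleted interval starts that far in
        emit(records$query_name[a], records$target_name[a],
             co$tend[ta] + qgap + 1L, "DEL",
             as.integer(tgap - max(qgap, 0L)), "split")
      }
    }
  }
  # nested opposite-strand signature: a minus-strand segment whose target
  # interval lies inside a plus-strand segment of the same read (the aligner
  # absorbed the inverted region in the forward record but the reverse
  # orientation also aligned it)
  for (idx in by_read) {
    if (length(idx) < 2) next
    minus <- idx[records$strand[idx] == "-"]
    plus <- idx[records$strand[idx] == "+"]
    for (m in minus) {
      for (p in plus) {
        if (records$target_name[m] != records$target_name[p]) next
        if (co$tstart[m] >= co$tstart[p] + 50L &&
            co$tend[m] <= co$tend[p] - 50L) {
          len <- co$tend[m] - co$tstart[m]
          if (len < min_sv_len) next
          emit(records$query_name[m], records$target_name[m],
               co$tstart[m] + 1L, "INV", as.integer(len), "split")
          break
        }
      }
    }
  }
  # strand-flip breakpoint pairs: a query-adjacent +/- (or -/+) pair marks an
  # inversion breakpoint, and because the inverted segment maps in reverse,
  # the far end of the minus segment reveals the opposite breakpoint -- one
  # breakpoint-spanning read determines the whole inverted interval (a read
  # spanning the entire inversion contributes the +/-/+ pattern as two such
  # pairs at the same interval)
  for (idx in by_read) {
    if (length(idx) < 2) next
    idx <- idx[order(records$qstart[idx])]
    for (j in seq_len(length(idx) - 1L)) {
      a <- idx[j]; b2 <- idx[j + 1L]
      if (records$strand[a] == records$strand[b2]) next
      if (records$target_name[a] != records$target_name[b2]) next
      if (records$strand[a] == "+") {
        S <- co$tend[a]; E <- co$tend[b2]
        inside_ok <- co$tstart[b2] >= S - inv_adjacency_tol
      } else {
        S <- co$tstart[a]; E <- co$tstart[b2]
        inside_ok <- co$tend[a] <= E + inv_adjacency_tol
      }
      len <- E - S
      if (!inside_ok || len < min_sv_len) next
      emit(records$query_name[a], records$target_name[a], S + 1L, "INV",
           as.integer(len), "split")
    }
  }
  if (si == 0L) return(empty)
  tibble::tibble(
    read_name = unlist(acc_read), chrom = unlist(acc_chrom),
    pos = as.integer(unlist(acc_pos)), type = unlist(acc_type),
    length = as.integer(unlist(acc_len)), source = unlist(acc_src))
}

#' Cluster signatures and emit SV calls
#'
#' Signatures of the same type on the same chromosome within `merge_window`
#' of each other (single linkage on position) form a cluster; clusters
#' supported by at least `min_support` distinct reads emit one call at the
#' median position with the median length. Output is independent of input
#' row order.
#'
#' @param signatures tibble from [extract_signatures()].
#' @param min_support minimum distinct supporting reads (default 3).
#' @param merge_window clustering window in bases (default 500).
#' @return SV call tibble: `chrom`, `start`, `end`, `type`, `length`, `id`,
#'   `support`. `start` is the 1-based first affected base; `end = start +
#'   length` for DEL/INV and `end = start` for INS.
#' @export
cluster_and_call <- function(signatures, min_support = 3L, merge_window = 500L) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), type = character(),
                          length = integer(), id = character(),
                          support = integer())
  if (nrow(signatures) == 0) return(empty)
  sig <- dplyr::arrange(signatures, .data$chrom, .data$type, .data$pos,
                        .data$read_name)
  # single linkage on position; for span events (DEL/INV) whose position
  # estimates scatter with event size, the link window grows with the
  # smaller involved length, capped below the planting separation scale
  link <- function(pos, len, type) {
    n <- length(pos)
    if (n == 1) return(1L)
    win <- pmax(merge_window,
                ifelse(type[-n] == "INS", 0,
                       pmin(0.4 * pmin(len[-n], len[-1]), 1900)))
    cumsum(c(1L, as.integer(diff(pos) > win)))
  }
  calls <- sig |>
    dplyr::group_by(.data$chrom, .data$type) |>
    dplyr::mutate(cluster = link(.data$pos, .data$length, .data$type)) |>
    dplyr::group_by(.data$chrom, .data$type, .data$cluster) |>
    dplyr::summarise(
      start = as.integer(round(stats::median(.data$pos))),
      length = as.integer(round(stats::median(.data$length))),
      support = dplyr::n_distinct(.data$read_name),
      .groups = "drop") |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::mutate(end = ifelse(.data$type == "INS", .data$start,
                               .data$start + .data$length)) |>
    dplyr::arrange(.data$chrom, .data$start)
  # overlapping same-type calls of similar length are duplicate estimates of
  # one event (true same-type variants cannot overlap); keep the best
  keep <- rep(TRUE, nrow(calls))
  if (nrow(calls) > 1) {
    o <- order(-calls$support, -calls$length)
    for (a in seq_along(o)) {
      i <- o[a]
      if (!keep[i]) next
      for (b in seq_along(o)) {
        j <- o[b]
        if (i == j || !keep[j]) next
        if (calls$chrom[i] != calls$chrom[j] || calls$type[i] != calls$type[j]) next
        ls <- min(calls$length[i], calls$length[j]) /
          max(calls$length[i], calls$length[j])
        if (ls < 0.7) next
        near <- if (calls$type[i] == "INS") {
          abs(calls$start[j] - calls$start[i]) <= 1000
        } else {
          calls$start[j] < calls$end[i] && calls$start[i] < calls$end[j]
        }
        if (near && calls$support[j] <= calls$support[i]) keep[j] <- FALSE
      }
    }
  }
  calls <- calls[keep, , drop = FALSE]
  calls$id <- sprintf("sv%04d", seq_len(nrow(calls)))
  dplyr::select(calls, "chrom", "start", "end", "type", "length", "id", "support")
}

#' Call SVs from a set of alignment records
#'
#' Convenience wrapper: [extract_signatures()], [cluster_and_call()], then an
#' allele-fraction filter: a call must be supported by at least `min_af` of
#' the primary records overlapping its position, which removes recurrent
#' low-level alignment artifacts (e.g. tandem-repeat slips) that a raw
#' support count passes at high coverage.
#'
#' @inheritParams extract_signatures
#' @inheritParams cluster_and_call
#' @param min_af minimum supporting-read fraction of local coverage; 0
#'   disables the filter.
#' @return SV call tibble (see [cluster_and_call()]).
#' @export
call_svs <- function(records, min_sv_len = 50L, min_support = 3L,
                     merge_window = 500L, min_af = 0.25) {
  calls <- cluster_and_call(extract_signatures(records, min_sv_len = min_sv_len),
                            min_support = min_support,
                            merge_window = merge_window)
  if (min_af > 0 && nrow(calls) > 0) {
    prim <- records[records$is_primary, , drop = FALSE]
    co <- rec_coords(prim)
    covered <- vapply(seq_len(nrow(calls)), function(i) {
      sum(prim$target_name == calls$chrom[i] &
            co$tstart < calls$start[i] & co$tend > calls$start[i])
    }, numeric(1))
    # long events are only visible to the long spanning reads, so raw local
    # coverage overstates their eligible support; artifact slips are short
    keep <- calls$length > 1000 | calls$support >= min_af * pmax(covered, 1)
    calls <- calls[keep, , drop = FALSE]
    calls$id <- sprintf("sv%04d", seq_len(nrow(calls)))
  }
  calls
}

#' Write SV calls as minimal VCF 4.2
#'
#' Symbolic ALT records (`<INS>`, `<DEL>`, `<INV>`) with `SVTYPE`, `SVLEN`
#' and `END` INFO keys. `SVLEN` is stored positive for all types; `END`
#' equals `start + length` for DEL/INV and `start` for INS.
#'
#' @param calls SV call tibble.
#' @param path output path.
#' @param contigs named lengths (or named character genome) for `##contig`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">"),
             con)
  if (!is.null(contigs)) {
    if (is.character(contigs) && !is.numeric(contigs)) {
      contigs <- stats::setNames(nchar(contigs), names(contigs))
    }
    for (nm in names(contigs)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>", nm,
                         as.integer(contigs[[nm]])), con)
    }
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(calls) > 0) {
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", calls$type, calls$length,
                    calls$end)
    writeLines(paste(calls$chrom, calls$start, calls$id, "N",
                     paste0("<", calls$type, ">"), ".", "PASS", info,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read SV calls from a VCF
#'
#' Understands the symbolic-ALT dialect written by [write_sv_vcf()] (and any
#' VCF carrying `SVTYPE` plus `SVLEN` and/or `END`).
#'
#' @param path VCF path.
#' @return SV call tibble.
#' @export
read_sv_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), type = character(),
                          length = integer(), id = character()))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- stringi::stri_match_first_regex(info, paste0("(?:^|;)", key, "=([^;]+)"))
    m[, 2]
  }
  info <- vapply(f, `[`, character(1), 8)
  type <- info_get(info, "SVTYPE")
  len <- suppressWarnings(abs(as.integer(info_get(info, "SVLEN"))))
  start <- as.integer(vapply(f, `[`, character(1), 2))
  end <- suppressWarnings(as.integer(info_get(info, "END")))
  end[is.na(end)] <- ifelse(type[is.na(end)] == "INS", start[is.na(end)],
                            start[is.na(end)] + len[is.na(end)])
  len[is.na(len)] <- pmax(end[is.na(len)] - start[is.na(len)], 1L)
  tibble::tibble(
    chrom = vapply(f, `[`, character(1), 1), start = start, end = end,
    type = type, length = len, id = vapply(f, `[`, character(1), 3))
}
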