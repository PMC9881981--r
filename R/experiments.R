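# End-to-end simulation studies: the SV-detection benchmark (hybrid pipeline
# vs nucleotide-only alignment vs their union) and the paired alignment-
# quality comparison, both on fully synthetic inputs.

experiment_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2^30, n))
}

#' Simulated SV-detection benchmark
#'
#' One full replicate of the simulation study: generate a repeat-containing
#' genome, plant insertions/deletions/inversions with lengths uniform on
#' `len_range`, simulate noisy reads from the mutated genome at the given
#' coverage, align them back to the original genome with the hybrid
#' quantized pipeline (stage-1 nucleotide records are kept as the
#' nucleotide-only comparator), call SVs from each record set, and benchmark
#' both call sets plus their union against the planted truth.
#'
#' Defaults are the desk-scale study conditions: a 1 Mb genome with 20%
#' repeats, 100 INDELs + 20 inversions of 50-10000 bases, 40x coverage of
#' ~3 kb-mean log-normal reads at 10% error with half the substitutions
#' drawn bin-preservingly.
#'
#' @param seed integer seed driving every random component.
#' @param genome_length,repeat_fraction genome generator settings.
#' @param n_indel,n_inv,len_range planted-SV settings.
#' @param coverage,mean_len,median_len,error_rate,confusion_weight read
#'   simulator settings.
#' @param Q,levels quantizer settings.
#' @param min_sv_len,min_support,merge_window SV caller settings.
#' @param refdist,min_len_sim benchmarking gate.
#' @param params [hq_params()].
#' @param keep_alignments retain the full alignment tibble in the result.
#' @return an `hq_sv_experiment`: truth and call sets, `bench_hq`,
#'   `bench_nt`, `bench_union` ([match_calls()] results) and inputs.
#' @export
hq_sv_experiment <- function(seed = 1L, genome_length = 1e6,
                             repeat_fraction = 0.2, n_indel = 100L,
                             n_inv = 20L, len_range = c(50L, 10000L),
                             coverage = 40, mean_len = 3000,
                             median_len = round(3000 * 4500 / 14000),
                             error_rate = 0.10, confusion_weight = 0.5,
                             Q = 6L, levels = 3L, min_sv_len = 50L,
                             min_support = 3L, merge_window = 500L,
                             refdist = 500, min_len_sim = 0.7,
                             params = hq_params(), keep_alignments = FALSE) {
  ss <- experiment_seeds(seed, 4L)
  qmap <- synthesize_qmer_map(Q, ss[1])
  genome <- generate_genome(genome_length, repeat_fraction, seed = ss[2])
  planted <- plant_svs(genome, n_indel = n_indel, n_inv = n_inv,
                       len_low = len_range[1], len_high = len_range[2],
                       seed = ss[3])
  reads <- simulate_reads(planted$genome, coverage = coverage,
                          mean_len = mean_len, median_len = median_len,
                          error_rate = error_rate, qmap = qmap,
                          confusion_weight = confusion_weight, seed = ss[4],
                          levels = levels)
  ix <- hq_index(genome, qmap, params = params)
  aln <- run_hqalign(reads, ix, keep_stage1 = TRUE)
  calls_hq <- call_svs(dplyr::filter(aln, .data$domain == "quantized"),
                       min_sv_len = min_sv_len, min_support = min_support,
                       merge_window = merge_window)
  calls_nt <- call_svs(dplyr::filter(aln, .data$domain == "nucleotide"),
                       min_sv_len = min_sv_len, min_support = min_support,
                       merge_window = merge_window)
  union_calls <- union_model(calls_hq, calls_nt, refdist = refdist,
                             min_len_sim = min_len_sim)
  out <- list(
    truth = planted$truth,
    calls_hq = calls_hq, calls_nt = calls_nt, union_calls = union_calls,
    bench_hq = match_calls(planted$truth, calls_hq, refdist, min_len_sim),
    bench_nt = match_calls(planted$truth, calls_nt, refdist, min_len_sim),
    bench_union = match_calls(planted$truth, union_calls, refdist, min_len_sim),
    n_reads = nrow(reads), genome_length = sum(nchar(genome)), seed = seed
  )
  if (keep_alignments) {
    out$alignments <- aln
    out$reads <- reads
    out$genome <- genome
    out$qmap <- qmap
  }
  structure(out, class = "hq_sv_experiment")
}

#' @export
print.hq_sv_experiment <- function(x, ...) {
  cat(sprintf("<hq_sv_experiment> seed %s: %d truth SVs, %d reads, %.2f Mb genome\n",
              format(x$seed), nrow(x$truth), x$n_reads, x$genome_length / 1e6))
  print(glance(x))
  invisible(x)
}

#' @export
glance.hq_sv_experiment <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$bench_hq), method = "hq3", .before = 1),
    dplyr::mutate(glance(x$bench_nt), method = "nucleotide", .before = 1),
    dplyr::mutate(glance(x$bench_union), method = "union", .before = 1)
  )
}

#' Paired alignment-quality comparison on simulated reads
#'
#' Simulates reads from a synthetic genome without structural variants,
#' aligns each read in nucleotide mode (stage 1) and in the hybrid quantized
#' mode, and compares the per-read normalized edit distances of the two
#' modes by ordinary least squares over the reads aligned by both (see
#' [summarize_cohort()]).
#'
#' @param seed integer seed.
#' @param genome_length synthetic genome length.
#' @param repeat_fraction repeat content of the genome.
#' @param n_reads number of reads entering the comparison.
#' @param mean_len,median_len,error_rate,confusion_weight read simulator
#'   settings.
#' @param Q,levels quantizer settings.
#' @param max_len read-length cap for this cohort (the per-read edit
#'   distance computation is quadratic in read length, and the comparison
#'   does not need the extreme tail).
#' @param params [hq_params()].
#' @return an `hq_alignment_experiment` with the `hq_cohort` in `$cohort`
#'   and its regression slope in `$slope`.
#' @export
hq_alignment_experiment <- function(seed = 1L, genome_length = 1e6,
                                    repeat_fraction = 0.2, n_reads = 2000L,
                                    mean_len = 3000,
                                    median_len = round(3000 * 4500 / 14000),
                                    error_rate = 0.10,
                                    confusion_weight = 0.5, Q = 6L,
                                    levels = 3L, max_len = 10000L,
                                    params = hq_params()) {
  ss <- experiment_seeds(seed, 3L)
  qmap <- synthesize_qmer_map(Q, ss[1])
  genome <- generate_genome(genome_length, repeat_fraction, seed = ss[2])
  coverage <- 1.15 * n_reads * mean_len / genome_length
  reads <- simulate_reads(genome, coverage = coverage, mean_len = mean_len,
                          median_len = median_len, error_rate = error_rate,
                          qmap = qmap, confusion_weight = confusion_weight,
                          seed = ss[3], levels = levels, max_len = max_len)
  reads <- utils::head(reads, n_reads)
  ix <- hq_index(genome, qmap, params = params)
  aln <- run_hqalign(reads, ix, keep_stage1 = TRUE)
  cohort <- summarize_cohort(
    dplyr::filter(aln, .data$domain == "nucleotide"),
    dplyr::filter(aln, .data$domain == "quantized"),
    reads, genome, Q = Q, label_a = "nucleotide", label_b = "hq3")
  structure(list(cohort = cohort, slope = cohort$slope,
                 intercept = cohort$intercept, n_reads = nrow(reads),
                 seed = seed),
            class = "hq_alignment_experiment")
}

#' @export
print.hq_alignment_experiment <- function(x, ...) {
  cat(sprintf("<hq_alignment_experiment> seed %s, %d reads\n",
              format(x$seed), x$n_reads))
  print(x$cohort)
  invisible(x)
}

#' @export
glance.hq_alignment_experiment <- function(x, ...) glance(x$cohort)
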