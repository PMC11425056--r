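#' Run the scaled simulation benchmark end to end
#'
#' Generates a seeded synthetic reference, plants TD length classes,
#' simulates paired-end reads, aligns them (with `bwa mem`, or with the
#' aligner-free emulator), runs the caller at the supplied parameters and
#' scores the calls per length class. The default configuration mirrors
#' the method's simulation protocol at desk scale: a 5-Mb reference,
#' length classes from 10 bp to 9 kb with 25 TDs each, 15x 2x100 bp
#' pairs, a 400-bp insert and 0.5% substitution error, scored by 50%
#' reciprocal overlap.
#'
#' @param seed Integer master seed; all stages derive their seeds from
#'   it.
#' @param ref_length Reference length (bp).
#' @param gc Reference GC fraction.
#' @param class_lengths TD unit lengths (bp), one class per value.
#' @param tds_per_class Number of TDs per class.
#' @param coverage Fold coverage of the donor genome.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param aligner `"bwa"` (requires `bwa` on the PATH) or `"emulate"`.
#' @param params [td_params()] used for calling.
#' @param reciprocal_overlap Matching threshold for evaluation.
#' @param workdir Scratch directory for FASTA/FASTQ/BAM intermediates.
#' @param keep Keep the intermediates instead of deleting them.
#' @return List with `truth`, `calls`, `eval` (see [evaluate_by_class()])
#'   and `bam` (path, if `keep`).
#' @export
run_td_benchmark <- function(seed = 1L,
                             ref_length = 5e6,
                             gc = 0.41,
                             class_lengths = c(10L, 15L, 20L, 25L, 50L, 75L,
                                               100L, 150L, 250L, 500L, 1000L,
                                               2000L, 5000L, 9000L),
                             tds_per_class = 25L,
                             coverage = 15,
                             read_len = 100L,
                             insert_mean = 400L,
                             insert_sd = 50L,
                             error_rate = 0.005,
                             aligner = c("bwa", "emulate"),
                             params = td_params(),
                             reciprocal_overlap = 0.5,
                             workdir = tempfile("td_bench_"),
                             keep = FALSE) {
  aligner <- match.arg(aligner)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  if (!keep) on.exit(unlink(workdir, recursive = TRUE), add = TRUE)

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  genome <- simulate_genome(ref_length, gc = gc, seed = seeds[1L])
  truth <- plant_tds(genome, lengths = class_lengths,
                     count_per_length = tds_per_class, seed = seeds[2L],
                     insert_size = insert_mean)
  reads <- simulate_reads(truth$donor, coverage = coverage,
                          read_len = read_len, insert_mean = insert_mean,
                          insert_sd = insert_sd, error_rate = error_rate,
                          seed = seeds[3L])

  bam <- if (aligner == "bwa") {
    .align_bwa(reads, genome, truth$contig, workdir)
  } else {
    emulate_alignment(reads, truth, bam_prefix = file.path(workdir, "emul"))
  }

  ref <- reference_index(stats::setNames(genome, truth$contig))
  calls <- call_tandem_duplications(bam, ref, params = params)
  eval <- evaluate_by_class(calls, truth,
                            reciprocal_overlap = reciprocal_overlap)
  list(truth = truth, calls = calls, eval = eval,
       bam = if (keep) bam else NULL)
}

.align_bwa <- function(reads, genome, contig, workdir) {
  bwa <- Sys.which("bwa")
  if (bwa == "") {
    stop("bwa not found on the PATH; use aligner = \"emulate\" or install bwa")
  }
  fa <- file.path(workdir, "ref.fa")
  write_reference(reference_index(stats::setNames(genome, contig)), fa)
  fq <- write_fastq_pairs(reads, file.path(workdir, "reads"))

  status <- system2(bwa, c("index", fa), stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("bwa index failed with status ", status)
  sam <- file.path(workdir, "aln.sam")
  status <- system2(bwa, c("mem", "-t", "1", shQuote(fa), shQuote(fq[1L]),
                           shQuote(fq[2L])),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("bwa mem failed with status ", status)
  bam <- Rsamtools::asBam(sam, destination = file.path(workdir, "aln"),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}
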