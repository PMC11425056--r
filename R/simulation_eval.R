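#' Simulate a random reference genome
#'
#' Pseudo-random nucleotide sequence with a given GC fraction,
#' reproducible from a seed. Homopolymer runs are capped at 8 bp so that
#' unique-substring searches stay well posed near planted junctions.
#'
#' @param length Sequence length (bp); must be at least `min_length`.
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @param min_length Smallest admissible genome (guards degenerate
#'   simulations).
#' @return Character scalar sequence.
#' @export
simulate_genome <- function(length, gc = 0.41, seed = 1L, min_length = 100L) {
  stopifnot(gc >= 0, gc <= 1)
  if (length < min_length) {
    stop("genome length ", length, " is below the minimum of ", min_length)
  }
  set.seed(seed)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  x <- sample(names(prob), length, replace = TRUE, prob = prob)
  # cap homopolymer runs at 8 by resampling every ninth base of a run
  r <- rle(x)
  long <- which(r$lengths > 8L)
  if (length(long) > 0L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in long) {
      at <- seq(starts[i] + 8L, ends[i], by = 9L)
      others <- setdiff(names(prob), r$values[i])
      x[at] <- sample(others, length(at), replace = TRUE,
                      prob = prob[others] / sum(prob[others]))
    }
  }
  paste(x, collapse = "")
}

#' Plant tandem duplications into a reference sequence
#'
#' Chooses non-overlapping unit intervals (uniformly at random unless
#' `intervals` is supplied), spaced at least `2 * insert_size` apart and
#' at least `insert_size` from the contig ends, and builds the donor
#' genome in which each unit is duplicated immediately after itself. The
#' donor carries exactly one novel junction per TD; the returned segment
#' map records the piecewise-linear donor-to-reference coordinate
#' correspondence used by [emulate_alignment()].
#'
#' @param reference Reference sequence (character scalar).
#' @param lengths TD unit lengths (bp) to plant.
#' @param count_per_length Number of TDs per length.
#' @param seed Integer seed for placement.
#' @param insert_size Library insert size (bp) controlling spacing.
#' @param contig Contig name used in truth records.
#' @param intervals Optional `data.frame` with `td_start`, `td_end`
#'   (0-based half-open, sorted, non-overlapping) overriding random
#'   placement.
#' @return A `td_truth` object: list with `table` (contig, td_start,
#'   td_end, td_len in reference coordinates), `donor`, `segments`
#'   (donor_start, ref_start), `junctions` (donor coordinates), `contig`,
#'   `ref_length`, `reference` and `params`.
#' @export
plant_tds <- function(reference, lengths = NULL, count_per_length = 1L,
                      seed = 1L, insert_size = 400L, contig = "chr1",
                      intervals = NULL) {
  L <- nchar(reference)
  if (is.null(intervals)) {
    stopifnot(length(lengths) > 0L, all(lengths >= 1L))
    set.seed(seed)
    lens <- rep(as.integer(lengths), each = as.integer(count_per_length))
    lens <- sample(lens)           # interleave length classes along the contig
    n <- length(lens)
    margin <- as.integer(insert_size)
    gap <- 2L * as.integer(insert_size)
    free <- L - 2 * margin - sum(as.numeric(lens)) - (n - 1) * gap
    if (free < 0) {
      stop("cannot place ", n, " TDs totalling ", sum(lens),
           " bp on a ", L, " bp reference; use a longer reference")
    }
    u <- sort(floor(stats::runif(n, 0, free + 1)))
    starts <- as.integer(margin + u + c(0, cumsum(lens))[seq_len(n)] +
                         (seq_len(n) - 1L) * gap)
    tab <- data.frame(
      contig = contig,
      td_start = starts,
      td_end = starts + lens,
      td_len = lens,
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.frame(
      contig = contig,
      td_start = as.integer(intervals$td_start),
      td_end = as.integer(intervals$td_end),
      stringsAsFactors = FALSE
    )
    tab$td_len <- tab$td_end - tab$td_start
    stopifnot(all(tab$td_len >= 1L), all(diff(tab$td_start) > 0L),
              all(tab$td_end <= L), all(tab$td_start >= 0L))
    if (nrow(tab) > 1L &&
        any(tab$td_start[-1L] < tab$td_end[-nrow(tab)])) {
      stop("explicit TD intervals must be non-overlapping")
    }
  }

  n <- nrow(tab)
  # donor pieces: ref[0, e1), ref[s1, e2), ..., ref[sn, L)
  piece_from <- c(0L, tab$td_start)
  piece_to <- c(tab$td_end, L)
  pieces <- substring(reference, piece_from + 1L, piece_to)
  donor <- paste(pieces, collapse = "")
  shift <- c(0L, cumsum(tab$td_len))
  junctions <- tab$td_end + shift[seq_len(n)]
  segments <- data.frame(
    donor_start = c(0L, junctions),
    ref_start = c(0L, tab$td_start),
    stringsAsFactors = FALSE
  )

  structure(
    list(table = tab, donor = donor, segments = segments,
         junctions = junctions, contig = contig, ref_length = L,
         reference = reference,
         params = list(seed = seed, lengths = lengths,
                       count_per_length = count_per_length,
                       insert_size = insert_size)),
    class = "td_truth"
  )
}

.mutate_reads <- function(reads, error_rate, read_len) {
  if (error_rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), read_len, error_rate)
  idx <- which(n_err > 0L)
  if (length(idx) == 0L) return(reads)
  bases <- c("A", "C", "G", "T")
  split <- strsplit(reads[idx], "", fixed = TRUE)
  for (i in seq_along(idx)) {
    at <- sample.int(read_len, n_err[idx[i]])
    for (p in at) {
      cur <- split[[i]][p]
      split[[i]][p] <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads[idx] <- vapply(split, paste, character(1L), collapse = "")
  reads
}

#' Simulate paired-end reads from a donor genome
#'
#' wgsim-style simulator: fragment starts are uniform over the donor,
#' fragment lengths Normal(`insert_mean`, `insert_sd`) rounded and
#' floored at twice the read length, read 1 runs forward from the
#' fragment start and read 2 is the reverse complement of the fragment
#' end; per-base substitution errors occur at `error_rate`. The number of
#' pairs is `ceiling(coverage * donor_length / (2 * read_len))`.
#'
#' @param donor Donor sequence (character scalar).
#' @param coverage Fold coverage.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `td_reads` object: list with `qname`, `frag_start` (0-based),
#'   `frag_len`, `r1`, `r2` (sequenced orientation) and `read_len`.
#' @export
simulate_reads <- function(donor, coverage = 15, read_len = 100L,
                           insert_mean = 400L, insert_sd = 50L,
                           error_rate = 0.005, seed = 1L) {
  dlen <- nchar(donor)
  stopifnot(dlen > insert_mean + 4 * insert_sd)
  set.seed(seed)
  n <- as.integer(ceiling(coverage * dlen / (2 * read_len)))
  frag <- pmin(dlen,
               pmax(2L * read_len,
                    as.integer(round(stats::rnorm(n, insert_mean, insert_sd)))))
  start <- as.integer(floor(stats::runif(n, 0, dlen - frag + 1)))
  r1 <- substring(donor, start + 1L, start + read_len)
  r2 <- reverse_complement(substring(donor, start + frag - read_len + 1L,
                                     start + frag))
  r1 <- .mutate_reads(r1, error_rate, read_len)
  r2 <- .mutate_reads(r2, error_rate, read_len)
  structure(
    list(qname = sprintf("sim_%07d", seq_len(n)),
         frag_start = start, frag_len = frag,
         r1 = r1, r2 = r2, read_len = as.integer(read_len)),
    class = "td_reads"
  )
}

#' Write simulated read pairs to FASTQ
#'
#' @param reads A `td_reads` object.
#' @param prefix Output prefix; files `<prefix>_1.fq` and `<prefix>_2.fq`
#'   are written.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, prefix) {
  qual <- strrep("I", reads$read_len)
  f1 <- paste0(prefix, "_1.fq")
  f2 <- paste0(prefix, "_2.fq")
  writeLines(paste0("@", reads$qname, "/1\n", reads$r1, "\n+\n", qual), f1)
  writeLines(paste0("@", reads$qname, "/2\n", reads$r2, "\n+\n", qual), f2)
  invisible(c(f1, f2))
}

#' Tile deterministic read pairs over a donor genome
#'
#' Places one fragment every `step` bases along the donor, with no
#' sequencing error. Unlike [simulate_reads()] this guarantees junction
#' coverage at every read offset residue class, which exact-recovery
#' tests need: a small TD is only verifiable from reads whose junction
#' offset leaves a complete copy on each side, a window of
#' `read_len - 2 * td_len + 3` positions that random sampling can miss
#' at moderate coverage.
#'
#' The default fragment length is not a multiple of `step`, so read 1
#' and read 2 tiles never repeat a donor window (duplicate read
#' sequences would let a single chance match validate itself) and
#' junction offsets sample two residue classes instead of one.
#'
#' @param donor Donor sequence.
#' @param read_len Read length (bp).
#' @param frag_len Fragment length (bp); keep coprime to `step`.
#' @param step Distance between consecutive fragment starts (bp).
#' @return A `td_reads` object (see [simulate_reads()]).
#' @export
tile_reads <- function(donor, read_len = 100L, frag_len = 401L, step = 3L) {
  dlen <- nchar(donor)
  stopifnot(dlen > frag_len)
  start <- as.integer(seq(0L, dlen - frag_len, by = step))
  r1 <- substring(donor, start + 1L, start + read_len)
  r2 <- reverse_complement(substring(donor, start + frag_len - read_len + 1L,
                                     start + frag_len))
  structure(
    list(qname = sprintf("tile_%07d", seq_along(start)),
         frag_start = start, frag_len = rep(as.integer(frag_len),
                                            length(start)),
         r1 = r1, r2 = r2, read_len = as.integer(read_len)),
    class = "td_reads"
  )
}

.donor_to_ref <- function(pos, segments) {
  idx <- findInterval(pos, segments$donor_start)
  segments$ref_start[idx] + (pos - segments$donor_start[idx])
}

#' Emulate a short-read aligner on simulated reads
#'
#' Places every read on the reference at the position implied by the
#' donor-to-reference coordinate map of the truth set. Reads contained in
#' one map segment become single-M records; reads spanning a planted
#' junction are written with the longer reference-consistent flank
#' aligned and the remainder soft-clipped, mimicking a primary alignment
#' from a BWA-style aligner. All records get mapping quality 60 and
#' proper-pair flags; the output BAM is coordinate-sorted and indexed.
#'
#' @param reads A `td_reads` object generated from `truth$donor`.
#' @param truth The `td_truth` object the reads were simulated from.
#' @param bam_prefix Output BAM path without the `.bam` extension.
#' @return Path to the sorted, indexed BAM file.
#' @export
emulate_alignment <- function(reads, truth, bam_prefix = tempfile("emul")) {
  seg <- truth$segments
  rl <- reads$read_len
  dlen <- nchar(truth$donor)

  place <- function(a) {
    b <- a + rl
    if (any(a < 0L) || any(b > dlen)) {
      stop("read coordinates outside the donor; inconsistent simulation")
    }
    si <- findInterval(a, seg$donor_start)
    sj <- findInterval(b - 1L, seg$donor_start)
    if (any(sj > si + 1L)) {
      stop("read spans more than one junction; inconsistent simulation")
    }
    junc <- sj > si
    J <- seg$donor_start[sj]
    left <- ifelse(junc, J - a, rl)
    right <- rl - left
    left_major <- left >= right
    pos <- ifelse(!junc, .donor_to_ref(a, seg),
                  ifelse(left_major, .donor_to_ref(a, seg), seg$ref_start[sj]))
    cigar <- ifelse(!junc, paste0(rl, "M"),
                    ifelse(left_major, paste0(left, "M", right, "S"),
                           paste0(left, "S", right, "M")))
    list(pos = as.integer(pos), cigar = cigar)
  }

  a1 <- reads$frag_start
  a2 <- reads$frag_start + reads$frag_len - rl
  p1 <- place(a1)
  p2 <- place(a2)
  qual <- strrep("I", rl)
  seq2 <- reverse_complement(reads$r2)   # stored reference-forward

  sam <- tempfile(fileext = ".sam")
  con <- file(sam, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", truth$contig, truth$ref_length)),
             con)
  lines1 <- sprintf(
    "%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
    reads$qname, truth$contig, p1$pos + 1L, p1$cigar, p2$pos + 1L,
    reads$frag_len, reads$r1, qual
  )
  lines2 <- sprintf(
    "%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
    reads$qname, truth$contig, p2$pos + 1L, p2$cigar, p1$pos + 1L,
    -reads$frag_len, seq2, qual
  )
  writeLines(lines1, con)
  writeLines(lines2, con)
  close(con)
  on.exit(NULL)

  bam <- Rsamtools::asBam(sam, destination = bam_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Match TD calls against a planted truth set
#'
#' Greedy one-to-one matching. In `"reciprocal"` mode a call can match a
#' truth interval when their reciprocal overlap (minimum of
#' overlap/length over both intervals) reaches `reciprocal_overlap`; in
#' `"truvari"` mode when both breakpoints lie within
#' `max_breakpoint_dist` and the size ratio reaches `size_similarity`.
#' Candidate pairs are processed in decreasing reciprocal-overlap order
#' and each call and truth interval is consumed at most once.
#'
#' @param calls Call `data.frame` (`contig`, `td_start`, `td_end`,
#'   `td_len`).
#' @param truth A `td_truth` object or a truth `data.frame` of the same
#'   shape.
#' @param reciprocal_overlap Reciprocal-overlap threshold.
#' @param mode `"reciprocal"` or `"truvari"`.
#' @param max_breakpoint_dist Breakpoint distance bound (truvari mode).
#' @param size_similarity Minimum size ratio (truvari mode).
#' @return A `td_eval` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `fdr`, `no_calls` flag and the matched index pairs
#'   (`matches`: data.frame with `call`, `truth`).
#' @export
match_calls <- function(calls, truth, reciprocal_overlap = 0.5,
                        mode = c("reciprocal", "truvari"),
                        max_breakpoint_dist = 1000L, size_similarity = 0.5) {
  mode <- match.arg(mode)
  tt <- if (inherits(truth, "td_truth")) truth$table else truth
  n_call <- nrow(calls)
  n_truth <- nrow(tt)
  matches <- data.frame(call = integer(0), truth = integer(0))

  if (n_call > 0L && n_truth > 0L) {
    pairs <- NULL
    maxgap <- if (mode == "truvari") as.integer(max_breakpoint_dist) else -1L
    for (ctg in intersect(unique(calls$contig), unique(tt$contig))) {
      ci <- which(calls$contig == ctg)
      ti <- which(tt$contig == ctg)
      ir_c <- IRanges::IRanges(calls$td_start[ci] + 1L, calls$td_end[ci])
      ir_t <- IRanges::IRanges(tt$td_start[ti] + 1L, tt$td_end[ti])
      hits <- IRanges::findOverlaps(ir_c, ir_t, maxgap = maxgap)
      if (length(hits) == 0L) next
      pairs <- rbind(pairs, data.frame(
        call = ci[S4Vectors::queryHits(hits)],
        truth = ti[S4Vectors::subjectHits(hits)]
      ))
    }
    if (!is.null(pairs) && nrow(pairs) > 0L) {
      ov <- pmin(calls$td_end[pairs$call], tt$td_end[pairs$truth]) -
            pmax(calls$td_start[pairs$call], tt$td_start[pairs$truth])
      ov <- pmax(ov, 0L)
      len_c <- calls$td_end[pairs$call] - calls$td_start[pairs$call]
      len_t <- tt$td_end[pairs$truth] - tt$td_start[pairs$truth]
      ro <- pmin(ov / len_c, ov / len_t)
      keep <- if (mode == "reciprocal") {
        ro >= reciprocal_overlap
      } else {
        abs(calls$td_start[pairs$call] - tt$td_start[pairs$truth]) <=
          max_breakpoint_dist &
        abs(calls$td_end[pairs$call] - tt$td_end[pairs$truth]) <=
          max_breakpoint_dist &
        pmin(len_c, len_t) / pmax(len_c, len_t) >= size_similarity
      }
      pairs <- pairs[keep, , drop = FALSE]
      ro <- ro[keep]
      if (nrow(pairs) > 0L) {
        ord <- order(-ro)
        used_c <- logical(n_call)
        used_t <- logical(n_truth)
        sel <- integer(0)
        for (h in ord) {
          ic <- pairs$call[h]; it <- pairs$truth[h]
          if (!used_c[ic] && !used_t[it]) {
            used_c[ic] <- TRUE; used_t[it] <- TRUE
            sel <- c(sel, h)
          }
        }
        matches <- pairs[sel, , drop = FALSE]
      }
    }
  }

  tp <- nrow(matches)
  fp <- n_call - tp
  fn <- n_truth - tp
  no_calls <- (tp + fp) == 0L
  precision <- if (no_calls) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, fdr = 1 - precision, no_calls = no_calls,
         matches = matches),
    class = "td_eval"
  )
}

#' Per-length-class evaluation with macro averages
#'
#' Matches calls to truth once (globally, one-to-one) and stratifies the
#' result by planted unit length. True positives are attributed to the
#' class of the matched truth interval; unmatched calls (false
#' positives) are attributed to the class whose length is nearest the
#' call length on the log scale.
#'
#' @param calls Call `data.frame`.
#' @param truth `td_truth` or truth `data.frame`.
#' @param ... Passed to [match_calls()].
#' @return List with `per_class` (data.frame of class_len, n_truth, tp,
#'   fp, fn, precision, recall, f1, fdr) and `macro` (named vector of
#'   macro-averaged precision, recall, f1, fdr as fractions).
#' @export
evaluate_by_class <- function(calls, truth, ...) {
  tt <- if (inherits(truth, "td_truth")) truth$table else truth
  ev <- match_calls(calls, tt, ...)
  classes <- sort(unique(tt$td_len))
  truth_class <- tt$td_len
  call_class <- rep(NA_integer_, nrow(calls))
  if (nrow(calls) > 0L) {
    call_class <- classes[max.col(-abs(outer(log(calls$td_len),
                                             log(classes), "-")))]
  }
  matched_call <- logical(nrow(calls))
  matched_call[ev$matches$call] <- TRUE

  per <- lapply(classes, function(cl) {
    t_idx <- which(truth_class == cl)
    tp <- sum(truth_class[ev$matches$truth] == cl)
    fn <- length(t_idx) - tp
    fp <- sum(!matched_call & call_class == cl)
    precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    recall <- if (length(t_idx) == 0L) 0 else tp / length(t_idx)
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    data.frame(class_len = cl, n_truth = length(t_idx), tp = tp, fp = fp,
               fn = fn, precision = precision, recall = recall, f1 = f1,
               fdr = 1 - precision)
  })
  per <- do.call(rbind, per)
  macro <- c(precision = mean(per$precision), recall = mean(per$recall),
             f1 = mean(per$f1), fdr = mean(per$fdr))
  list(per_class = per, macro = macro, overall = ev)
}
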