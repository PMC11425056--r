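#' Classify a TD length relative to the read length
#'
#' Size classes drive the choice of step-3 search region and calling
#' strategy: `large` when `td_len` exceeds the read length, `medium` when
#' it lies between half the read length and the read length, `small`
#' below half the read length. The two boundary points are assigned to
#' the adjacent wider class (`td_len == read_len` is large,
#' `td_len == read_len / 2` is medium), keeping every length covered.
#'
#' @param td_len TD length (bp), >= 1.
#' @param read_len Read length (bp), >= 2.
#' @return `"large"`, `"medium"` or `"small"`.
#' @export
classify_size <- function(td_len, read_len) {
  stopifnot(td_len >= 1L, read_len >= 2L)
  if (td_len >= read_len) return("large")
  if (2L * td_len >= read_len) return("medium")
  "small"
}

#' Levenshtein edit distance
#'
#' Unit-cost global edit distance (substitutions, insertions, deletions).
#'
#' @param a,b Sequences to compare.
#' @return Non-negative integer distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Step 2: unique-substring search from the mate's 3' end
#'
#' Grows suffixes of the (reference-forward) mate sequence within a window
#' of `search_span_multiplier * insert_size` bp anchored at the anchor's
#' 3'-end coordinate: downstream of the anchor point for forward-strand
#' anchors, upstream for reverse-strand anchors (where the mate lies
#' before the anchor on the reference). The window is clamped to the
#' contig.
#'
#' @param signal One row of [extract_informative_pairs()] output (list or
#'   single-row data.frame).
#' @param ref A `ReferenceIndex`.
#' @param params A [td_params()] with `insert_size` set.
#' @return `grow_unique()` result (minimum/maximum matches) or `NULL`.
#' @export
step2_search_3prime <- function(signal, ref, params) {
  span <- params$search_span_multiplier * params$insert_size
  ap <- signal$anchor_point
  if (identical(signal$anchor_strand, "+")) {
    lo <- ap; hi <- ap + span
  } else {
    lo <- ap - span; hi <- ap
  }
  lo <- max(0L, lo)
  region <- fetch_region(ref, signal$contig, lo, hi)
  if (nchar(region) == 0L) return(NULL)
  grow_unique(signal$mate_seq, "from_3prime", region,
              region_offset = lo, min_len = params$min_distance_to_the_end)
}

#' Step 3: unique-substring search from the mate's 5' end
#'
#' The search region depends on the size class being attempted, with
#' `p = m3$ref_start` the mapped 5' end of the step-2 maximum match:
#' `[p, p + max_td_size)` for the large attempt and
#' `[p - max_span_size, p + max_span_size)` for the medium and small
#' attempts. The small attempt additionally restricts match start
#' positions to coordinates strictly below `p` (the search terminates at
#' the step-2 coordinate), which preserves uniqueness when the two copies
#' of a short duplication straddle `p`.
#'
#' @param signal Signal record (see [step2_search_3prime()]).
#' @param m3 Maximum match from step 2.
#' @param size_class_attempt `"large"`, `"medium"` or `"small"`.
#' @param ref A `ReferenceIndex`.
#' @param params A [td_params()] with `max_span_size` resolved.
#' @return `grow_unique()` result or `NULL`.
#' @export
step3_search_5prime <- function(signal, m3, size_class_attempt, ref, params) {
  p <- m3$ref_start
  max_start <- NULL
  if (size_class_attempt == "large") {
    lo <- p; hi <- p + params$max_td_size
  } else {
    lo <- p - params$max_span_size; hi <- p + params$max_span_size
    if (size_class_attempt == "small") max_start <- p
  }
  lo <- max(0L, lo)
  region <- fetch_region(ref, signal$contig, lo, hi)
  if (nchar(region) == 0L) return(NULL)
  grow_unique(signal$mate_seq, "from_5prime", region,
              region_offset = lo, min_len = params$min_distance_to_the_end,
              max_ref_start = max_start)
}

#' Combine 5' and 3' matches into a candidate TD
#'
#' The 3' match `m3` (read suffix, mapped at the duplication unit start)
#' and the 5' match `m5` (read prefix, mapped at the unit end) must
#' together explain the complete read: the read span of `m5` must reach
#' the read span of `m3` (`m3$read_start <= m5$read_end`). Because the two
#' matches are grown independently they can both extend through junction
#' micro-homology; the homologous run appears as an overlap of their read
#' spans, and the TD length is the reference span minus that overlap:
#' `td_len = (m5$ref_end - m3$ref_start) - max(0, m5$read_end -
#' m3$read_start)`. Placing the junction at the leftmost consistent read
#' position makes the reported interval the left-shifted canonical form.
#'
#' For large and medium classes the candidate is accepted as a
#' reconstruction call. For the small class the two inferred copies are
#' cut at the junction parse: with the junction placed at read offset
#' `j = m3$read_start`, `td_str` is the `td_len` bases before it (the
#' first copy, inside the 5'-match segment) and `td_str_dup` the
#' `td_len` bases after it (the second copy, the head of the 3'-match
#' segment). Cutting both copies at the same parse keeps them in frame
#' through junction micro-homology. The candidate is accepted when their
#' edit distance is strictly below `params$edit_distance_max`.
#'
#' @param signal Signal record providing `contig`, `mate_seq`,
#'   `read_name`.
#' @param m5 Maximum 5'-end match (read prefix).
#' @param m3 Maximum 3'-end match (read suffix).
#' @param params A [td_params()] with `read_len` resolved.
#' @return A single-row candidate `data.frame`, or `NULL` when no gate
#'   passes.
#' @export
call_from_matches <- function(signal, m5, m3, params) {
  j <- m3$read_start          # leftmost read offset explained by the suffix
  k <- m5$read_end            # rightmost read offset explained by the prefix
  if (j > k) return(NULL)     # gap: the read is not fully reconstructed
  overlap <- k - j            # micro-homology (or degenerate full overlap)
  td_len <- (m5$ref_end - m3$ref_start) - overlap
  if (td_len < 1L) return(NULL)
  td_start <- m3$ref_start
  td_end <- td_start + td_len
  cls <- classify_size(td_len, params$read_len)

  td_str <- ""
  td_str_dup <- ""
  if (cls == "small") {
    # cut both copies at one consistent junction parse: with the junction
    # at read offset t, the first copy is the td_len bases before t and
    # the second the td_len bases after it. Any t in [j, k] (the
    # micro-homology window) is equivalent; take the leftmost t for which
    # both copies fit inside the read, and shift the breakpoints to match
    n <- nchar(signal$mate_seq)
    t_lo <- max(j, td_len)
    t_hi <- min(k, n - td_len)
    if (t_lo > t_hi) return(NULL)
    t <- t_lo
    td_start <- td_start + (t - j)
    td_end <- td_start + td_len
    td_str <- substr(signal$mate_seq, t - td_len + 1L, t)
    td_str_dup <- substr(signal$mate_seq, t + 1L, t + td_len)
    if (edit_distance(td_str, td_str_dup) >= params$edit_distance_max) {
      return(NULL)
    }
    strategy <- "overlap_edit"
  } else {
    strategy <- "reconstruction"
  }

  data.frame(
    contig = signal$contig,
    td_start = as.integer(td_start),
    td_end = as.integer(td_end),
    td_len = as.integer(td_len),
    size_class = cls,
    strategy = strategy,
    read_name = signal$read_name,
    td_str = td_str,
    td_str_dup = td_str_dup,
    stringsAsFactors = FALSE
  )
}

#' Left-shift a TD interval through boundary homology
#'
#' A duplication whose unit boundaries sit in a homologous run admits
#' several equivalent placements; the canonical form used throughout is
#' the smallest `td_start` producing an identical duplicated sequence:
#' while the base before the interval equals the base before its end, the
#' interval slides one position left.
#'
#' @param ref A `ReferenceIndex`.
#' @param contig Contig name.
#' @param td_start,td_end 0-based half-open interval.
#' @return Integer vector `c(td_start, td_end)` after normalisation.
#' @export
normalize_breakpoints <- function(ref, contig, td_start, td_end) {
  s <- as.integer(td_start); e <- as.integer(td_end)
  repeat {
    if (s <= 0L) break
    chunk <- 64L
    lo <- max(0L, s - chunk)
    n <- s - lo
    left <- fetch_region(ref, contig, lo, s)                 # bases before start
    right <- fetch_region(ref, contig, e - n, e)             # bases before end
    shifted <- 0L
    while (shifted < n &&
           substr(left, n - shifted, n - shifted) ==
           substr(right, n - shifted, n - shifted)) {
      shifted <- shifted + 1L
    }
    s <- s - shifted; e <- e - shifted
    if (shifted < n) break
  }
  c(s, e)
}

#' Detect candidate TDs from one informative read pair
#'
#' Runs the step-2 suffix search and then attempts the three
#' size-stratified step-3 schemes in order large, medium, small,
#' returning the first accepted candidate (at most one per read pair),
#' with breakpoints left-shift normalised.
#'
#' @param signal Signal record (list or single-row data.frame).
#' @param ref A `ReferenceIndex`.
#' @param params A [td_params()] with `insert_size`, `read_len` and
#'   `max_span_size` resolved.
#' @return A candidate `data.frame` with zero or one row.
#' @export
detect_from_pair <- function(signal, ref, params) {
  empty <- data.frame(
    contig = character(0), td_start = integer(0), td_end = integer(0),
    td_len = integer(0), size_class = character(0), strategy = character(0),
    read_name = character(0), td_str = character(0), td_str_dup = character(0),
    stringsAsFactors = FALSE
  )
  g3 <- step2_search_3prime(signal, ref, params)
  if (is.null(g3)) return(empty)
  m3 <- g3$maximum
  for (attempt in c("large", "medium", "small")) {
    g5 <- step3_search_5prime(signal, m3, attempt, ref, params)
    if (is.null(g5)) next
    cand <- call_from_matches(signal, g5$maximum, m3, params)
    if (!is.null(cand)) {
      bp <- normalize_breakpoints(ref, cand$contig, cand$td_start, cand$td_end)
      cand$td_start <- bp[1L]
      cand$td_end <- bp[2L]
      return(cand)
    }
  }
  empty
}

.resolve_params <- function(params, bam = NULL) {
  if (is.null(params$read_len)) {
    if (is.null(bam)) stop("read_len not set and no BAM to observe it from")
    params$read_len <- observe_read_length(bam)
  }
  if (is.null(params$insert_size)) {
    if (is.null(bam)) stop("insert_size not set and no BAM to estimate it from")
    params$insert_size <- estimate_insert_size(bam, params = params)
  }
  if (is.null(params$max_span_size)) params$max_span_size <- params$read_len
  params
}

#' Detect candidate TDs for a set of signals
#'
#' @param signals Output of [extract_informative_pairs()].
#' @param ref A `ReferenceIndex`.
#' @param params Resolved [td_params()].
#' @return Candidate `data.frame` (one row per accepted read pair).
#' @export
detect_candidates <- function(signals, ref, params) {
  empty <- data.frame(
    contig = character(0), td_start = integer(0), td_end = integer(0),
    td_len = integer(0), size_class = character(0), strategy = character(0),
    read_name = character(0), td_str = character(0), td_str_dup = character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(signals) == 0L) return(empty)
  sig <- list()
  out <- vector("list", nrow(signals))
  for (i in seq_len(nrow(signals))) {
    sig <- list(
      contig = signals$contig[i],
      anchor_point = signals$anchor_point[i],
      anchor_strand = signals$anchor_strand[i],
      mate_seq = signals$mate_seq[i],
      read_name = signals$read_name[i]
    )
    out[[i]] <- detect_from_pair(sig, ref, params)
  }
  out <- out[vapply(out, nrow, integer(1L)) > 0L]
  if (length(out) == 0L) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setDF(res)
  res
}

#' Call tandem duplications from a BAM file
#'
#' End-to-end driver: resolves data-dependent parameters (read length,
#' insert size), extracts informative read-pair signals, detects
#' candidates, applies the support filter and merges redundant calls.
#'
#' @param bam Path to a coordinate-sorted BAM file.
#' @param ref A `ReferenceIndex` or path to the reference FASTA.
#' @param params A [td_params()] object.
#' @param which Optional region restriction (see
#'   [extract_informative_pairs()]).
#' @return A `data.frame` of merged TD calls (see [merge_overlapping()]).
#' @export
call_tandem_duplications <- function(bam, ref, params = td_params(),
                                     which = NULL) {
  if (is.character(ref)) ref <- load_reference(ref)
  params <- .resolve_params(params, bam)
  signals <- extract_informative_pairs(bam, params, which = which)
  candidates <- detect_candidates(signals, ref, params)
  calls <- collect_and_filter(candidates, params)
  merge_overlapping(calls)
}
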