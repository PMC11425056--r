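#' Detection parameters
#'
#' Bundles the tunable thresholds of the caller. Defaults follow the
#' method's standard settings: anchors must exceed mapping quality 30,
#' unique substrings must reach at least 8 bp from the read end, small-TD
#' candidates are accepted when the edit distance between the two inferred
#' copies is strictly smaller than 4, and a call needs at least 2 distinct
#' supporting reads. `max_td_size` bounds the downstream search for
#' large-TD breakpoints; `max_span_size` (half-width of the centred
#' medium/small search window) defaults to the read length once observed.
#' `insert_size` and `read_len` are normally estimated from the alignment
#' data and `search_span_multiplier` fixes the step-2 window at twice the
#' insert size.
#'
#' @param anchor_quality Mapping-quality threshold; anchors must be
#'   strictly greater.
#' @param min_distance_to_the_end Minimum unique-substring length (bp).
#' @param max_td_size Largest detectable TD (bp); sets the large-TD search
#'   range.
#' @param max_span_size Half-width (bp) of the medium/small step-3 window;
#'   `NULL` means "use the read length".
#' @param min_support Minimum distinct supporting reads per call.
#' @param edit_distance_max Small-TD candidates require edit distance
#'   strictly below this value.
#' @param insert_size Library insert size (bp); `NULL` means "estimate
#'   from proper pairs".
#' @param read_len Read length (bp); `NULL` means "observe from the data".
#' @param search_span_multiplier Step-2 window size in insert-size units.
#' @return A `td_params` list.
#' @export
td_params <- function(anchor_quality = 30L,
                      min_distance_to_the_end = 8L,
                      max_td_size = 10000L,
                      max_span_size = NULL,
                      min_support = 2L,
                      edit_distance_max = 4L,
                      insert_size = NULL,
                      read_len = NULL,
                      search_span_multiplier = 2L) {
  p <- list(
    anchor_quality = as.integer(anchor_quality),
    min_distance_to_the_end = as.integer(min_distance_to_the_end),
    max_td_size = as.integer(max_td_size),
    max_span_size = if (is.null(max_span_size)) NULL else as.integer(max_span_size),
    min_support = as.integer(min_support),
    edit_distance_max = as.integer(edit_distance_max),
    insert_size = if (is.null(insert_size)) NULL else as.integer(insert_size),
    read_len = if (is.null(read_len)) NULL else as.integer(read_len),
    search_span_multiplier = as.integer(search_span_multiplier)
  )
  stopifnot(
    p$anchor_quality >= 0L, p$min_distance_to_the_end > 0L,
    p$max_td_size > 0L, p$min_support >= 1L,
    p$edit_distance_max >= 1L, p$search_span_multiplier >= 1L
  )
  if (!is.null(p$insert_size) && !is.null(p$read_len) &&
      p$insert_size < p$read_len) {
    stop("insert_size must be at least the read length")
  }
  class(p) <- "td_params"
  p
}

.bam_core_flags <- function(...) {
  Rsamtools::scanBamFlag(
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE,
    ...
  )
}

#' Estimate the library insert size from a BAM file
#'
#' Median absolute template length over (up to) the first `n_pairs`
#' properly paired first-of-pair records. An explicit
#' `params$insert_size` overrides estimation.
#'
#' @param bam Path to a BAM file.
#' @param n_pairs Number of proper pairs to sample.
#' @param params Optional [td_params()]; a non-`NULL` `insert_size`
#'   short-circuits the estimate.
#' @return Integer insert size (bp).
#' @export
estimate_insert_size <- function(bam, n_pairs = 100000L, params = NULL) {
  if (!is.null(params) && !is.null(params$insert_size)) {
    return(params$insert_size)
  }
  bf <- Rsamtools::BamFile(bam, yieldSize = NA_integer_)
  sp <- Rsamtools::ScanBamParam(
    flag = .bam_core_flags(isProperPair = TRUE, isFirstMateRead = TRUE),
    what = "isize"
  )
  isize <- abs(Rsamtools::scanBam(bf, param = sp)[[1L]]$isize)
  isize <- isize[!is.na(isize) & isize > 0L]
  if (length(isize) == 0L) {
    stop("no properly paired reads found in '", bam,
         "'; supply the insert size explicitly (td_params(insert_size = ...))")
  }
  if (length(isize) > n_pairs) isize <- isize[seq_len(n_pairs)]
  as.integer(round(stats::median(isize)))
}

.cigar_m_run <- function(cigar) {
  # length of the aligned run for single-M CIGARs, NA otherwise
  out <- rep(NA_integer_, length(cigar))
  ok <- !is.na(cigar) & grepl("^[0-9]+M$", cigar)
  out[ok] <- as.integer(sub("M$", "", cigar[ok]))
  out
}

#' Extract TD-informative read-pair signals from a BAM file
#'
#' Scans primary alignments and keeps pairs where exactly one read
#' qualifies as the anchor (mapped, CIGAR a single aligned-match run,
#' mapping quality strictly above `anchor_quality`) and its mate carries a
#' soft-clip or is unmapped. Hard-clipped mates are skipped (their stored
#' sequence is incomplete), as are pairs whose reads map to different
#' contigs. The mate sequence is normalised to read reference-forward:
#' mapped mates are already stored that way in the BAM; unmapped mates of
#' forward-strand anchors are reverse-complemented (FR library geometry).
#'
#' @param bam Path to a coordinate-sorted BAM file.
#' @param params A [td_params()] object.
#' @param which Optional [IRanges::IRangesList]/`GRanges`-style region
#'   restriction passed to [Rsamtools::ScanBamParam()].
#' @return A `data.frame` of signals: `contig`, `anchor_start`,
#'   `anchor_end`, `anchor_strand`, `anchor_point`, `mate_seq`,
#'   `read_name` (coordinates 0-based half-open; `anchor_point` is the
#'   3'-end reference coordinate of the anchor).
#' @export
extract_informative_pairs <- function(bam, params = td_params(), which = NULL) {
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar", "seq")
  sp <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = .bam_core_flags(), what = what)
  } else {
    Rsamtools::ScanBamParam(flag = .bam_core_flags(), what = what, which = which)
  }
  chunks <- Rsamtools::scanBam(bam, param = sp)

  empty <- data.frame(
    contig = character(0), anchor_start = integer(0), anchor_end = integer(0),
    anchor_strand = character(0), anchor_point = integer(0),
    mate_seq = character(0), read_name = character(0),
    stringsAsFactors = FALSE
  )

  res <- lapply(chunks, function(ch) {
    if (length(ch$qname) == 0L) return(NULL)
    dt <- data.table::data.table(
      qname = ch$qname,
      flag = ch$flag,
      rname = as.character(ch$rname),
      pos = ch$pos,
      mapq = ch$mapq,
      cigar = ch$cigar,
      seq = as.character(ch$seq)
    )
    dt[, `:=`(
      mapped = bitwAnd(flag, 4L) == 0L,
      reverse = bitwAnd(flag, 16L) == 16L
    )]
    dt[, m_len := .cigar_m_run(cigar)]
    dt[, anchor_ok := mapped & !is.na(m_len) & !is.na(mapq) &
                      mapq > params$anchor_quality]
    dt[, mate_ok := (!mapped | grepl("S", cigar, fixed = TRUE)) &
                    !grepl("H", cigar, fixed = TRUE) &
                    !is.na(seq) & nchar(seq) > 0L]
    dt[, `:=`(n_rec = .N, n_anchor = sum(anchor_ok), n_mate = sum(mate_ok)),
       by = qname]
    # exactly one read qualifies as anchor; the other must qualify as mate
    dt <- dt[n_rec == 2L & n_anchor == 1L]
    if (nrow(dt) == 0L) return(NULL)
    data.table::setorder(dt, qname, -anchor_ok)
    a <- dt[seq(1L, .N, by = 2L)]
    m <- dt[seq(2L, .N, by = 2L)]
    keep <- m$mate_ok & (!m$mapped | m$rname == a$rname)
    a <- a[keep]; m <- m[keep]
    if (nrow(a) == 0L) return(NULL)
    anchor_start <- a$pos - 1L
    anchor_end <- anchor_start + a$m_len
    mate_seq <- m$seq
    flip <- !m$mapped & !m$reverse & !a$reverse
    if (any(flip)) mate_seq[flip] <- reverse_complement(mate_seq[flip])
    data.frame(
      contig = a$rname,
      anchor_start = anchor_start,
      anchor_end = anchor_end,
      anchor_strand = ifelse(a$reverse, "-", "+"),
      anchor_point = ifelse(a$reverse, anchor_start, anchor_end),
      mate_seq = mate_seq,
      read_name = a$qname,
      stringsAsFactors = FALSE
    )
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Observe the read length from a BAM file
#'
#' Modal read length over the first records of the file.
#'
#' @param bam Path to a BAM file.
#' @param n Number of records to inspect.
#' @return Integer read length (bp).
#' @export
observe_read_length <- function(bam, n = 10000L) {
  bf <- Rsamtools::BamFile(bam, yieldSize = as.integer(n))
  on.exit(try(Rsamtools::close.BamFile(bf), silent = TRUE), add = TRUE)
  open(bf)
  sp <- Rsamtools::ScanBamParam(flag = .bam_core_flags(), what = "seq")
  w <- Biostrings::width(Rsamtools::scanBam(bf, param = sp)[[1L]]$seq)
  if (length(w) == 0L) stop("no reads found in '", bam, "'")
  tab <- table(w)
  as.integer(names(tab)[which.max(tab)])
}
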