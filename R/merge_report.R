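#' Group candidates into supported TD calls
#'
#' Candidates are grouped by exact breakpoint identity
#' (`contig`, `td_start`, `td_end`); support is the number of distinct
#' read names in a group (one fragment never counts twice), and groups
#' reaching `params$min_support` become calls, sorted by
#' (`contig`, `td_start`).
#'
#' @param candidates Candidate `data.frame` from [detect_candidates()].
#' @param params A [td_params()].
#' @return A `data.frame` of calls: `contig`, `td_start`, `td_end`,
#'   `td_len`, `size_class`, `support`.
#' @export
collect_and_filter <- function(candidates, params = td_params()) {
  empty <- data.frame(
    contig = character(0), td_start = integer(0), td_end = integer(0),
    td_len = integer(0), size_class = character(0), support = integer(0),
    stringsAsFactors = FALSE
  )
  if (nrow(candidates) == 0L) return(empty)
  dt <- data.table::as.data.table(candidates)
  calls <- dt[, .(
    td_len = td_len[1L],
    size_class = size_class[1L],
    support = data.table::uniqueN(read_name)
  ), by = .(contig, td_start, td_end)]
  calls <- calls[support >= params$min_support]
  data.table::setorder(calls, contig, td_start, td_end)
  data.table::setDF(calls)
  calls <- calls[, c("contig", "td_start", "td_end", "td_len",
                     "size_class", "support")]
  rownames(calls) <- NULL
  calls
}

.merge_once <- function(calls) {
  n <- nrow(calls)
  if (n < 2L) return(calls)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ctg in unique(calls$contig)) {
    idx <- which(calls$contig == ctg)
    if (length(idx) < 2L) next
    ir <- IRanges::IRanges(start = calls$td_start[idx] + 1L,
                           end = calls$td_end[idx])
    hits <- IRanges::findOverlaps(ir, ir, minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh) == 0L) next
    li <- calls$td_len[idx[qh]]
    lj <- calls$td_len[idx[sh]]
    ok <- abs(li - lj) < 2L * pmin(li, lj)   # strict inequality
    for (h in which(ok)) {
      a <- find(idx[qh[h]]); b <- find(idx[sh[h]])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, integer(1L))
  # representative per cluster: highest support, then smallest td_start,
  # then largest td_len
  ord <- order(root, -calls$support, calls$td_start, -calls$td_len)
  keep <- ord[!duplicated(root[ord])]
  out <- calls[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge redundant TD calls
#'
#' Calls whose intervals overlap by at least one base and whose lengths
#' satisfy `|len_i - len_j| < 2 * min(len_i, len_j)` (strict) are
#' clustered transitively; each cluster is replaced by its most frequent
#' member (highest support, ties broken by smallest `td_start`, then
#' largest `td_len`), keeping that member's own support. Clustering is
#' iterated to a fixed point, so the operation is idempotent.
#'
#' @param calls Call `data.frame` from [collect_and_filter()], sorted by
#'   (`contig`, `td_start`).
#' @return Merged call `data.frame`, sorted.
#' @export
merge_overlapping <- function(calls) {
  if (nrow(calls) < 2L) return(calls)
  repeat {
    merged <- .merge_once(calls)
    if (nrow(merged) == nrow(calls)) break
    calls <- merged
  }
  ord <- order(merged$contig, merged$td_start, merged$td_end)
  out <- merged[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write TD calls to VCF 4.2
#'
#' One `<DUP:TANDEM>` record per call with 1-based `POS`
#' (`td_start + 1`), the reference base at the start breakpoint as `REF`,
#' and `SVTYPE`, `END` (1-based inclusive = `td_end`), `SVLEN` and
#' `SUPPORT` in `INFO`.
#'
#' @param calls Call `data.frame`.
#' @param ref A `ReferenceIndex` covering all call contigs.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_td_vcf <- function(calls, ref, path) {
  stopifnot(inherits(ref, "ReferenceIndex"))
  if (nrow(calls) > 0L) {
    missing <- setdiff(unique(calls$contig), names(ref$lengths))
    if (length(missing) > 0L) {
      stop("call contig(s) absent from the reference: ",
           paste(missing, collapse = ", "))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tandemdup",
    sprintf("##contig=<ID=%s,length=%d>", names(ref$lengths), ref$lengths),
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the duplicated unit\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Number of distinct supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(0)
  if (nrow(calls) > 0L) {
    refbase <- vapply(seq_len(nrow(calls)), function(i) {
      fetch_region(ref, calls$contig[i], calls$td_start[i],
                   calls$td_start[i] + 1L)
    }, character(1L))
    lines <- sprintf(
      "%s\t%d\tTD_%d\t%s\t<DUP:TANDEM>\t.\tPASS\tSVTYPE=DUP;END=%d;SVLEN=%d;SUPPORT=%d",
      calls$contig, calls$td_start + 1L, seq_len(nrow(calls)), refbase,
      calls$td_end, calls$td_len, calls$support
    )
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write TD calls to BED4
#'
#' Intervals are 0-based half-open; the name field encodes index, length
#' and support as `TD_<n>_len<td_len>_sup<support>`.
#'
#' @param calls Call `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_td_bed <- function(calls, path) {
  if (nrow(calls) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(calls$contig, calls$td_start, calls$td_end)
  calls <- calls[ord, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\tTD_%d_len%d_sup%d",
                   calls$contig, calls$td_start, calls$td_end,
                   seq_len(nrow(calls)), calls$td_len, calls$support)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Minimal BED3+ reader used for truth sets and round-trips; returns
#' 0-based half-open intervals.
#'
#' @param path BED file path.
#' @return A `data.frame` with `contig`, `td_start`, `td_end`, `td_len`
#'   and, when a name column is present, `name`.
#' @export
read_td_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(0), td_start = integer(0),
                      td_end = integer(0), td_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(
    contig = as.character(tab[[1L]]),
    td_start = as.integer(tab[[2L]]),
    td_end = as.integer(tab[[3L]]),
    stringsAsFactors = FALSE
  )
  out$td_len <- out$td_end - out$td_start
  if (ncol(tab) >= 4L) out$name <- as.character(tab[[4L]])
  out
}
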