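#' Count exact occurrences of a pattern in a region
#'
#' Overlapping occurrences are counted; matching is exact (no mismatches).
#'
#' @param pattern Non-empty nucleotide string.
#' @param region Nucleotide string to scan.
#' @return Non-negative integer occurrence count.
#' @export
occurrence_count <- function(pattern, region) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    stop("pattern must be a single non-empty string")
  }
  cpp_occurrence_count(pattern, region)
}

#' Grow minimum and maximum unique substrings from one read end
#'
#' Starting from the chosen end of `read`, substrings of increasing length
#' L = 1, 2, ... (suffixes for `from_3prime`, prefixes for `from_5prime`)
#' are matched exactly against `region`. Growth stops at the first length
#' with zero occurrences or when the read is exhausted. The minimum unique
#' substring is the shortest grown substring with exactly one occurrence
#' and length >= `min_len`; the maximum is the longest grown substring
#' still occurring exactly once. If no substring of length >= `min_len` is
#' unique, both are `NULL`.
#'
#' @param read Read sequence (oriented so that it reads reference-forward).
#' @param direction `"from_3prime"` (grow suffixes) or `"from_5prime"`
#'   (grow prefixes).
#' @param region Reference window sequence.
#' @param region_offset 0-based contig coordinate of the first base of
#'   `region`; reported matches carry contig coordinates.
#' @param min_len Minimum length for the reported minimum match
#'   (`min_distance_to_the_end`).
#' @param max_ref_start Optional exclusive upper bound (contig coordinate)
#'   on the match start position; used by the small-TD termination rule.
#' @return List with elements `minimum` and `maximum` (each a list with
#'   `read_start`, `read_end`, `ref_start`, `ref_end`, `direction`; 0-based
#'   half-open), or `NULL` if no qualifying unique substring exists.
#' @export
grow_unique <- function(read, direction = c("from_3prime", "from_5prime"),
                        region, region_offset = 0L, min_len = 8L,
                        max_ref_start = NULL) {
  direction <- match.arg(direction)
  if (nchar(region) == 0L || nchar(read) == 0L) return(NULL)
  limit <- -1L
  if (!is.null(max_ref_start)) {
    limit <- as.integer(max_ref_start) - as.integer(region_offset)
    if (limit <= 0L) return(NULL)   # no admissible start position
    limit <- min(limit, nchar(region))
  }
  hit <- cpp_grow_unique(read, region, direction == "from_3prime",
                         as.integer(min_len), limit)
  if (hit[1L] < 0L) return(NULL)
  off <- as.integer(region_offset)
  mk <- function(i) {
    list(read_start = hit[i], read_end = hit[i + 1L],
         ref_start = hit[i + 2L] + off, ref_end = hit[i + 3L] + off,
         direction = direction)
  }
  list(minimum = mk(1L), maximum = mk(5L))
}
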