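# Independent brute-force oracles and fixture builders used across tests.
# The oracles deliberately share no code with the package internals.

# count overlapping occurrences by testing every start position
oracle_occurrences <- function(pattern, region) {
  L <- nchar(pattern)
  m <- nchar(region)
  if (L == 0L || L > m) return(0L)
  starts <- seq_len(m - L + 1L)
  sum(substring(region, starts, starts + L - 1L) == pattern)
}

# enumerate every suffix/prefix length and report the shortest unique
# length >= min_len and the longest unique length seen before the first
# zero-occurrence length, with their 0-based local match positions
oracle_grow <- function(read, direction, region, min_len) {
  n <- nchar(read)
  uniq <- list()
  for (L in seq_len(n)) {
    sub <- if (direction == "from_3prime") {
      substring(read, n - L + 1L, n)
    } else {
      substring(read, 1L, L)
    }
    cnt <- oracle_occurrences(sub, region)
    if (cnt == 0L) break
    if (cnt == 1L) uniq[[length(uniq) + 1L]] <- c(L = L, pos = oracle_pos(sub, region))
  }
  if (length(uniq) == 0L) return(NULL)
  lens <- vapply(uniq, `[[`, integer(1L), "L")
  if (max(lens) < min_len) return(NULL)
  min_i <- which(lens >= min_len)[1L]
  max_i <- length(lens)
  list(min_len = lens[min_i], min_pos = uniq[[min_i]][["pos"]],
       max_len = lens[max_i], max_pos = uniq[[max_i]][["pos"]])
}

oracle_pos <- function(pattern, region) {
  L <- nchar(pattern)
  starts <- seq_len(nchar(region) - L + 1L)
  which(substring(region, starts, starts + L - 1L) == pattern)[1L] - 1L
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a BAM from explicit SAM records (list of character lines)
make_bam <- function(records, contig = "chr1", contig_len = 10000L,
                     prefix = tempfile("fix")) {
  sam <- paste0(prefix, ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len),
               records), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

sam_line <- function(qname, flag, pos, mapq, cigar, seq, mpos = pos,
                     tlen = 0L, contig = "chr1") {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
          qname, flag, contig, pos, mapq, cigar, mpos, tlen, seq,
          strrep("I", nchar(seq)))
}

# independent donor reconstruction: insert duplicate copies right-to-left
oracle_donor <- function(reference, table) {
  donor <- reference
  for (i in rev(seq_len(nrow(table)))) {
    s <- table$td_start[i]; e <- table$td_end[i]
    donor <- paste0(substr(donor, 1L, e),
                    substr(reference, s + 1L, e),
                    substr(donor, e + 1L, nchar(donor)))
  }
  donor
}
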