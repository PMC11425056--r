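test_that("size classes follow the length inequalities with wider-class ties", {
  expect_equal(classify_size(150, 100), "large")
  expect_equal(classify_size(75, 100), "medium")
  expect_equal(classify_size(49, 100), "small")
  expect_equal(classify_size(100, 100), "large")   # boundary -> large
  expect_equal(classify_size(50, 100), "medium")   # boundary -> medium
  expect_equal(classify_size(1, 100), "small")
  expect_error(classify_size(0, 100))
})

test_that("edit distance is unit-cost Levenshtein", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "AGGT"), 1L)
  expect_equal(edit_distance("AAAA", ""), 4L)
  expect_equal(edit_distance("ACGT", "CGT"), 1L)
})

# deterministic fixture: TD duplicating ref [400, 600) on a 1000 bp contig,
# junction-spanning mate with 50 bp on each side of the junction
.large_fixture <- function() {
  set.seed(1234)
  genome <- random_seq(1000)
  # keep unit boundaries homology-free so planted == canonical coordinates
  substr(genome, 396, 405) <- "ACACACGTGT"
  substr(genome, 596, 605) <- "TGTGTGACAC"
  ref <- reference_index(c(chr1 = genome))
  read <- paste0(fetch_region(ref, "chr1", 550, 600),
                 fetch_region(ref, "chr1", 400, 450))
  params <- td_params(insert_size = 400L, read_len = 100L,
                      max_span_size = 100L)
  signal <- list(contig = "chr1", anchor_point = 350L, anchor_strand = "+",
                 mate_seq = read, read_name = "frag1")
  list(ref = ref, signal = signal, params = params, read = read)
}

test_that("reconstruction combines the two matches into exact breakpoints", {
  fx <- .large_fixture()
  m5 <- list(read_start = 0L, read_end = 50L, ref_start = 550L,
             ref_end = 600L, direction = "from_5prime")
  m3 <- list(read_start = 50L, read_end = 100L, ref_start = 400L,
             ref_end = 450L, direction = "from_3prime")
  cand <- call_from_matches(fx$signal, m5, m3, fx$params)
  expect_equal(cand$td_start, 400L)
  expect_equal(cand$td_end, 600L)
  expect_equal(cand$td_len, 200L)
  expect_equal(cand$size_class, "large")
  expect_equal(cand$strategy, "reconstruction")
})

test_that("overlapping read spans are subtracted from the TD length", {
  fx <- .large_fixture()
  # both maxima over-extend 3 bases through simulated junction homology:
  # read spans overlap by 3 and the reference span inflates by 3
  m5 <- list(read_start = 0L, read_end = 53L, ref_start = 550L,
             ref_end = 603L, direction = "from_5prime")
  m3 <- list(read_start = 50L, read_end = 100L, ref_start = 400L,
             ref_end = 450L, direction = "from_3prime")
  cand <- call_from_matches(fx$signal, m5, m3, fx$params)
  expect_equal(cand$td_len, 200L)
  expect_equal(cand$td_start, 400L)
})

test_that("a gap between the matches fails the reconstruction gate", {
  fx <- .large_fixture()
  m5 <- list(read_start = 0L, read_end = 45L, ref_start = 550L,
             ref_end = 595L, direction = "from_5prime")
  m3 <- list(read_start = 50L, read_end = 100L, ref_start = 400L,
             ref_end = 450L, direction = "from_3prime")
  expect_null(call_from_matches(fx$signal, m5, m3, fx$params))
})

test_that("a fully reference-consistent mate yields no candidate", {
  fx <- .large_fixture()
  # whole read matches at one locus: both maxima cover the entire read
  m5 <- list(read_start = 0L, read_end = 100L, ref_start = 700L,
             ref_end = 800L, direction = "from_5prime")
  m3 <- list(read_start = 0L, read_end = 100L, ref_start = 700L,
             ref_end = 800L, direction = "from_3prime")
  expect_null(call_from_matches(fx$signal, m5, m3, fx$params))
})

# small-TD fixture: read P(30) U(20) U'(20) S(30); the junction sits at
# read offset 50, copies U and U' compared by edit distance
.small_fixture <- function(n_subs = 0L) {
  set.seed(777)
  P <- random_seq(30); U <- random_seq(20); S <- random_seq(30)
  U2 <- U
  if (n_subs > 0L) {
    at <- seq_len(n_subs) * 4L
    for (p in at) {
      cur <- substr(U2, p, p)
      substr(U2, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1L]
    }
  }
  read <- paste0(P, U, U2, S)
  params <- td_params(insert_size = 400L, read_len = 100L,
                      max_span_size = 100L)
  # copy 1 at ref [480, 500): m5 covers P+U ending at 500, m3 covers
  # U'+S starting at the unit start 480
  m5 <- list(read_start = 0L, read_end = 50L, ref_start = 450L,
             ref_end = 500L, direction = "from_5prime")
  m3 <- list(read_start = 50L, read_end = 100L, ref_start = 480L,
             ref_end = 530L, direction = "from_3prime")
  signal <- list(contig = "chr1", anchor_point = 440L, anchor_strand = "+",
                 mate_seq = read, read_name = "small1")
  list(signal = signal, m5 = m5, m3 = m3, params = params, U = U, U2 = U2)
}

test_that("small TDs are accepted below the edit-distance threshold", {
  fx <- .small_fixture(0L)
  cand <- call_from_matches(fx$signal, fx$m5, fx$m3, fx$params)
  expect_equal(cand$td_start, 480L)
  expect_equal(cand$td_end, 500L)
  expect_equal(cand$td_len, 20L)
  expect_equal(cand$size_class, "small")
  expect_equal(cand$strategy, "overlap_edit")
  expect_equal(cand$td_str, fx$U)
  expect_equal(cand$td_str_dup, fx$U2)

  fx3 <- .small_fixture(3L)
  expect_equal(edit_distance(fx3$U, fx3$U2), 3L)
  cand3 <- call_from_matches(fx3$signal, fx3$m5, fx3$m3, fx3$params)
  expect_equal(cand3$td_len, 20L)
})

test_that("edit distance 4 is not smaller than 4: candidate rejected", {
  fx4 <- .small_fixture(4L)
  expect_equal(edit_distance(fx4$U, fx4$U2), 4L)
  expect_null(call_from_matches(fx4$signal, fx4$m5, fx4$m3, fx4$params))
})

test_that("detect_from_pair recovers a planted large TD end to end", {
  set.seed(99)
  genome <- random_seq(30000)
  ref <- reference_index(c(chr1 = genome))
  s <- 12000L; e <- 14000L       # 2 kb unit
  params <- td_params(insert_size = 400L, read_len = 100L,
                      max_span_size = 100L)
  # junction mate: 40 bp ending at the unit end + 60 bp from the unit start
  read <- paste0(fetch_region(ref, "chr1", e - 40L, e),
                 fetch_region(ref, "chr1", s, s + 60L))
  # reverse-strand anchor downstream of the junction, inside copy 2
  signal <- list(contig = "chr1", anchor_point = s + 250L,
                 anchor_strand = "-", mate_seq = read, read_name = "rev1")
  cand <- detect_from_pair(signal, ref, params)
  expect_equal(nrow(cand), 1L)
  bp <- normalize_breakpoints(ref, "chr1", s, e)
  expect_equal(cand$td_start, bp[1L])
  expect_equal(cand$td_end, bp[2L])
  expect_equal(cand$size_class, "large")
})

test_that("detect_from_pair recovers a planted small TD end to end", {
  set.seed(101)
  genome <- random_seq(20000)
  ref <- reference_index(c(chr1 = genome))
  s <- 9000L; e <- 9020L         # 20 bp unit
  params <- td_params(insert_size = 400L, read_len = 100L,
                      max_span_size = 100L)
  unit <- fetch_region(ref, "chr1", s, e)
  read <- paste0(fetch_region(ref, "chr1", s - 30L, e), unit,
                 fetch_region(ref, "chr1", e, e + 30L))
  signal <- list(contig = "chr1", anchor_point = s - 200L,
                 anchor_strand = "+", mate_seq = read, read_name = "fwd1")
  cand <- detect_from_pair(signal, ref, params)
  expect_equal(nrow(cand), 1L)
  bp <- normalize_breakpoints(ref, "chr1", s, e)
  expect_equal(cand$td_start, bp[1L])
  expect_equal(cand$td_end, bp[2L])
  expect_equal(cand$size_class, "small")
  expect_equal(cand$strategy, "overlap_edit")
})

test_that("a reference-consistent mate produces no call", {
  set.seed(103)
  genome <- random_seq(20000)
  ref <- reference_index(c(chr1 = genome))
  params <- td_params(insert_size = 400L, read_len = 100L,
                      max_span_size = 100L)
  signal <- list(contig = "chr1", anchor_point = 9800L, anchor_strand = "+",
                 mate_seq = fetch_region(ref, "chr1", 10000L, 10100L),
                 read_name = "clean")
  cand <- detect_from_pair(signal, ref, params)
  expect_equal(nrow(cand), 0L)
})

test_that("breakpoint normalisation slides through homologous runs", {
  #        0123456789012345678901
  ref <- reference_index(c(chr1 = "AAAACCTTGGCCTTGGCCTTAA"))
  # [10, 16) and [4, 10) duplicate the same 6-mer CCTTGG; the canonical
  # placement is the leftmost
  expect_equal(normalize_breakpoints(ref, "chr1", 10L, 16L), c(4L, 10L))
  # no homology: interval unchanged
  expect_equal(normalize_breakpoints(ref, "chr1", 4L, 6L), c(4L, 6L))
  # interval at the contig start cannot slide
  expect_equal(normalize_breakpoints(ref, "chr1", 0L, 4L), c(0L, 4L))
})
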