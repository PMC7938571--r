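# BSJ pseudo-reference construction and ribo-circRNA calling.

test_that("pseudo-reference is the 23+23 junction-centred sequence", {
  set.seed(41)
  s60 <- random_seq(60)
  jr <- build_pseudo_reference(list(circ_rna("a", s60)))
  expect_equal(nchar(jr$jseq), 46L)
  expect_equal(jr$junction_offset, 23L)
  expect_equal(jr$jseq, paste0(substr(s60, 38, 60), substr(s60, 1, 23)))

  # homopolymer
  jr2 <- build_pseudo_reference(list(circ_rna("b", strrep("A", 60))))
  expect_equal(jr2$jseq, strrep("A", 46))

  # circle shorter than 2*flank wraps; cross-check against rotation
  s30 <- random_seq(30)
  jr3 <- build_pseudo_reference(list(circ_rna("c", s30)))
  expect_equal(nchar(jr3$jseq), 46L)
  expect_equal(jr3$jseq, substr(strrep(rotate_seq(s30, 7), 3), 1, 46))
})

test_that("linear exclusion removes exact linear substrings only", {
  set.seed(42)
  linear <- random_seq(400)
  planted <- substr(linear, 101, 130)
  novel <- random_seq(30)
  expect_false(grepl(novel, linear, fixed = TRUE))
  reads <- data.frame(read_id = c("r1", "r2"), seq = c(planted, novel))
  kept <- exclude_linear_mappers(reads, linear)
  expect_equal(kept$read_id, "r2")
  # empty reference set is the identity
  expect_equal(exclude_linear_mappers(reads, character()), reads)
  # revcomp matching only when asked
  rc_read <- data.frame(read_id = "r3", seq = revcomp_dna(planted))
  expect_equal(nrow(exclude_linear_mappers(rc_read, linear)), 1L)
  expect_equal(nrow(exclude_linear_mappers(
    rc_read, linear, detection_params(allow_revcomp = TRUE))), 0L)
})

test_that("junction matching enforces length and overlap boundaries", {
  set.seed(43)
  circ <- circ_rna("c", random_seq(100))
  jrefs <- build_pseudo_reference(list(circ))
  jseq <- jrefs$jseq
  mk <- function(id, s) data.frame(read_id = id, seq = s)

  # offset 18, 27 nt: overlaps 5 / 22
  h <- match_junction_reads(mk("r", substr(jseq, 19, 45)), jrefs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$offset, 18L)
  expect_equal(h$left_overlap, 5L)
  expect_equal(h$right_overlap, 22L)

  # left overlap 2 < 3: rejected
  expect_equal(nrow(match_junction_reads(mk("r", substr(jseq, 22, 46)), jrefs)), 0L)
  # right overlap boundary: offset 20, 25 nt has overlaps 3/22 -> accepted
  expect_equal(nrow(match_junction_reads(mk("r", substr(jseq, 21, 45)), jrefs)), 1L)
  # read length 24 / 36: rejected despite perfect match
  expect_equal(nrow(match_junction_reads(mk("r", substr(jseq, 10, 33)), jrefs)), 0L)
  long_circ <- circ_rna("d", random_seq(100))
  jl <- build_pseudo_reference(list(long_circ))
  expect_equal(nrow(match_junction_reads(mk("r", substr(jl$jseq, 6, 41)), jl)), 0L)
  # lengths 25 and 35 pass
  expect_equal(nrow(match_junction_reads(mk("r", substr(jl$jseq, 8, 32)), jl)), 1L)
  expect_equal(nrow(match_junction_reads(mk("r", substr(jl$jseq, 6, 40)), jl)), 1L)
})

test_that("windows or reads containing N never match", {
  circ <- circ_rna("c", paste0("ACGTN", strrep("ACGT", 20)))
  jrefs <- build_pseudo_reference(list(circ))
  # a read equal to an N-containing window is rejected
  win <- substr(jrefs$jseq, 16, 45)
  if (grepl("N", win, fixed = TRUE)) {
    expect_equal(nrow(match_junction_reads(
      data.frame(read_id = "r", seq = win), jrefs)), 0L)
  }
  expect_equal(nrow(match_junction_reads(
    data.frame(read_id = "r", seq = paste0("N", substr(jrefs$jseq, 11, 39))),
    jrefs)), 0L)
})

test_that("calling requires two unique read sequences, not two hits", {
  set.seed(44)
  circ <- circ_rna("c", random_seq(90))
  jrefs <- build_pseudo_reference(list(circ))
  s1 <- substr(jrefs$jseq, 11, 40)
  s2 <- substr(jrefs$jseq, 13, 42)
  # 3 hits from 2 distinct sequences -> positive
  reads <- data.frame(read_id = c("a", "b", "dup"), seq = c(s1, s2, s1))
  calls <- call_ribo_circs(match_junction_reads(reads, jrefs), list(circ))
  expect_equal(calls$total_junction_reads, 3L)
  expect_equal(calls$unique_junction_reads, 2L)
  expect_true(calls$is_ribo_circ)
  # 5 hits all of one sequence -> negative
  reads5 <- data.frame(read_id = paste0("r", 1:5), seq = rep(s1, 5))
  calls5 <- call_ribo_circs(match_junction_reads(reads5, jrefs), list(circ))
  expect_equal(calls5$unique_junction_reads, 1L)
  expect_false(calls5$is_ribo_circ)
  # zero hits -> zero counts, negative, but the circRNA is still reported
  calls0 <- call_ribo_circs(match_junction_reads(
    data.frame(read_id = character(), seq = character()), jrefs), list(circ))
  expect_equal(calls0$total_junction_reads, 0L)
  expect_false(calls0$is_ribo_circ)
})

test_that("matcher agrees with the naive all-offset oracle on random instances", {
  set.seed(45)
  params <- detection_params()
  for (rep in 1:40) {
    jrefs <- build_pseudo_reference(
      lapply(1:4, function(i) circ_rna(paste0("c", i), random_seq(sample(50:120, 1)))))
    # mixture of planted windows and random reads, some with N
    seqs <- c(
      vapply(1:6, function(k) {
        j <- sample(nrow(jrefs), 1)
        rl <- sample(23:37, 1)
        off <- sample(0:(46 - rl), 1)
        substr(jrefs$jseq[j], off + 1, off + rl)
      }, character(1)),
      vapply(1:4, function(k)
        random_seq(sample(23:37, 1), c("A", "C", "G", "T", "N")),
        character(1)))
    reads <- data.frame(read_id = sprintf("r%02d", seq_along(seqs)), seq = seqs)
    expect_identical(hit_key(match_junction_reads(reads, jrefs, params)),
                     hit_key(naive_match_oracle(reads, jrefs, params)))
  }
})

test_that("calls are monotone in thresholds", {
  set.seed(46)
  circs <- lapply(1:6, function(i) circ_rna(paste0("c", i), random_seq(80)))
  jrefs <- build_pseudo_reference(circs)
  reads <- do.call(rbind, lapply(1:6, function(i) {
    n <- sample(0:3, 1)
    if (n == 0) return(NULL)
    data.frame(read_id = sprintf("c%d_%d", i, 1:n),
               seq = vapply(1:n, function(k) {
                 rl <- sample(25:35, 1)
                 off <- sample(max(0, 23 - rl + 3):(23 - 3), 1)
                 substr(jrefs$jseq[i], off + 1, off + rl)
               }, character(1)))
  }))
  hits <- match_junction_reads(reads, jrefs)
  # raising min_unique_reads never adds a positive call
  for (mu in 1:4) {
    lo <- call_ribo_circs(hits, circs, detection_params(min_unique_reads = mu))
    hi <- call_ribo_circs(hits, circs, detection_params(min_unique_reads = mu + 1))
    expect_true(all(lo$is_ribo_circ | !hi$is_ribo_circ))
  }
  # widening the length window never removes a hit
  narrow <- match_junction_reads(reads, jrefs,
                                 detection_params(min_len = 28, max_len = 32))
  wide <- match_junction_reads(reads, jrefs,
                               detection_params(min_len = 25, max_len = 35))
  expect_true(all(hit_key(narrow) %in% hit_key(wide)))
})
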