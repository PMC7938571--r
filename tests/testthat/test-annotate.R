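# IRES hits, m6A RAC sites, and cORF conservation scoring.

test_that("IRES hits respect identity and alignment-length cutoffs", {
  set.seed(51)
  circ <- circ_rna("c", random_seq(200))
  sub30 <- substr(circ$seq, 61, 90)
  sub29 <- substr(circ$seq, 61, 89)

  hit <- find_ires(circ, c(q = sub30))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$aln_len, 30L)
  expect_equal(hit$circ_start, 60L)
  expect_equal(hit$circ_end, 90L)

  # 29-nt exact substring: alignment too short
  expect_equal(nrow(find_ires(circ, c(q = sub29))), 0L)

  # interior mismatches: 24/30 identical columns passes, 23/30 fails.
  # mismatches are spread so trimming cannot improve the local score
  mutate_at <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- c(A = "C", C = "G", G = "T", T = "A")[[v[p]]]
    paste(v, collapse = "")
  }
  q24 <- mutate_at(sub30, c(5, 9, 13, 17, 21, 25))
  h24 <- find_ires(circ, c(q = q24))
  expect_equal(nrow(h24), 1L)
  expect_equal(h24$identity, 24 / 30)
  q23 <- mutate_at(sub30, c(5, 9, 13, 17, 21, 25, 29))
  h23 <- find_ires(circ, c(q = q23))
  expect_true(nrow(h23) == 0L ||
                h23$identity < 0.8 || h23$aln_len < 30)
  expect_equal(nrow(h23), 0L)

  expect_equal(nrow(find_ires(circ, character())), 0L)
})

test_that("junction-straddling IRES elements are found on the doubled circle", {
  set.seed(52)
  circ <- circ_rna("c", random_seq(150))
  straddle <- circular_substring(circ, 150 - 12, 35)  # 12 nt before + 23 after
  hits <- find_ires(circ, c(bsj = straddle))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$circ_start, 138L)
  expect_equal(hits$circ_end, 173L)  # end past L marks the wrap
  expect_equal(hits$identity, 1.0)
  # no duplicated placement modulo L
  expect_false(any(duplicated(paste(hits$ires_id, hits$circ_start %% 150))))
})

test_that("m6A sites require a purine-A-C motif inside peak overlap", {
  # circle carrying all four NAC contexts plus junction-adjacent motif
  #          0123456789012345678
  seqv <- "GACTAACTCACTTTGGGTT"
  circ <- circ_rna("m", seqv, chrom = "chr1", strand = "+",
                   blocks = cbind(0L, nchar(seqv)))
  peak_all <- data.frame(chrom = "chr1", start = 0L, end = nchar(seqv),
                         name = "p1", source = "toolA")
  sites <- find_m6a_sites(circ, peak_all)
  # GAC at 1, AAC at 5 qualify; CAC at 9 (C is not a purine) must not
  expect_setequal(sites$circ_pos, c(1L, 5L))
  expect_setequal(sites$motif, c("GAC", "AAC"))
  # every emitted motif re-validates on the circle sequence
  for (i in seq_len(nrow(sites))) {
    p <- sites$circ_pos[i]
    L <- nchar(seqv)
    expect_equal(sites$motif[i], paste0(
      substr(seqv, (p - 1) %% L + 1, (p - 1) %% L + 1),
      substr(seqv, p + 1, p + 1),
      substr(seqv, (p + 1) %% L + 1, (p + 1) %% L + 1)))
  }

  # peak covering nothing: no sites; no blocks: error
  off_peak <- data.frame(chrom = "chr1", start = 1000L, end = 1100L,
                         name = "p2", source = "toolA")
  expect_equal(nrow(find_m6a_sites(circ, off_peak)), 0L)
  expect_error(find_m6a_sites(circ_rna("x", "AACA"), peak_all), "blocks")

  # n_tools counts distinct sources covering the A
  multi <- rbind(peak_all,
                 data.frame(chrom = "chr1", start = 0L, end = 3L,
                            name = "p3", source = "toolB"))
  s2 <- find_m6a_sites(circ, multi)
  expect_equal(s2$n_tools[s2$circ_pos == 1], 2L)
  expect_equal(s2$n_tools[s2$circ_pos == 5], 1L)
})

test_that("motif detection wraps across the junction", {
  # A at position 0, C at 1, purine at L-1: RAC straddles the junction
  seqv <- paste0("AC", strrep("T", 10), "G")
  circ <- circ_rna("w", seqv, chrom = "chr1", strand = "+",
                   blocks = cbind(0L, nchar(seqv)))
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 2L,
                      name = "p", source = "t")
  sites <- find_m6a_sites(circ, peaks)
  expect_equal(sites$circ_pos, 0L)
  expect_equal(sites$motif, "GAC")
})

test_that("conservation mean uses covered bases only and can be missing", {
  circ <- circ_rna("c", strrep("A", 9), chrom = "chr1", strand = "+",
                   blocks = cbind(100L, 109L))
  corf <- data.frame(corf_id = "c:f0:s0", start = 0L, nt_len = 3L)
  track <- data.frame(chrom = "chr1", start = 100:102, end = 101:103,
                      score = c(0.2, 0.4, 0.6))
  sc <- score_peptide_conservation(corf, circ, track)
  expect_equal(sc$mean_score, 0.4)
  expect_equal(sc$n_bases_scored, 3L)

  # empty track: missing mean, not zero
  sc0 <- score_peptide_conservation(corf, circ, track[0, ])
  expect_true(is.na(sc0$mean_score))
  expect_equal(sc0$n_bases_scored, 0L)

  # partially covered footprint excludes uncovered bases from both sides
  sc1 <- score_peptide_conservation(corf, circ, track[1:2, ])
  expect_equal(sc1$mean_score, 0.3)
  expect_equal(sc1$n_bases_scored, 2L)
})

test_that("wrapping cORFs and fragmented blocks score identically", {
  set.seed(53)
  seqv <- random_seq(30)
  one_block <- circ_rna("a", seqv, chrom = "chr1", strand = "+",
                        blocks = cbind(500L, 530L))
  two_block <- circ_rna("b", seqv, chrom = "chr1", strand = "+",
                        blocks = cbind(c(500L, 512L), c(512L, 530L)))
  track <- data.frame(chrom = "chr1", start = 500L, end = 530L, score = 1.0)
  corf <- data.frame(corf_id = "x", start = 24L, nt_len = 18L)  # wraps
  sa <- score_peptide_conservation(corf, one_block, track)
  sb <- score_peptide_conservation(corf, two_block, track)
  expect_equal(sa$mean_score, 1.0)
  expect_equal(sa$mean_score, sb$mean_score)
  expect_equal(sa$n_bases_scored, sb$n_bases_scored)

  # rolling-circle ORF longer than the circle: each base counted once
  inf_corf <- data.frame(corf_id = "y", start = 3L, nt_len = 120L)
  si <- score_peptide_conservation(inf_corf, one_block, track)
  expect_equal(si$n_bases_scored, 30L)
})

test_that("local aligner agrees with a brute-force dynamic program", {
  set.seed(54)
  for (rep in 1:30) {
    q <- random_seq(sample(8:40, 1))
    s <- random_seq(sample(8:40, 1))
    a <- local_align(q, s)
    expect_equal(a$score, sw_score_oracle(q, s), info = paste(q, s))
  }
  # and under the conservation scoring scheme (+1/-2)
  for (rep in 1:15) {
    q <- random_seq(sample(8:40, 1))
    s <- random_seq(sample(8:40, 1))
    a <- local_align(q, s, match = 1, mismatch = -2)
    expect_equal(a$score,
                 sw_score_oracle(q, s, match = 1, mismatch = -2),
                 info = paste(q, s))
  }
})
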