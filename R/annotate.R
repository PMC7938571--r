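# Annotation of translation-supporting cis-elements on circRNAs:
# IRES hits (local alignment against the doubled circle so junction-crossing
# placements are found), m6A RAC sites within peak overlap, and per-base
# conservation averaged over a cORF's genomic footprint.

#' IRES search parameters
#'
#' Defaults: at least 80% identity over at least 30 alignment columns,
#' with megablast-like local-alignment scoring (+2 match, -3 mismatch,
#' gap of length k costs 5 + 2k). Identity is counted over alignment
#' columns, gap columns included.
#'
#' @param min_identity minimum fraction of identical columns.
#' @param min_aln_len minimum alignment length in columns.
#' @param match,mismatch,gap_open,gap_extend local-alignment scores.
#' @return list of class `ires_params`.
#' @export
ires_params <- function(min_identity = 0.80, min_aln_len = 30L,
                        match = 2, mismatch = -3, gap_open = -5,
                        gap_extend = -2) {
  stopifnot(min_identity > 0, min_identity <= 1, min_aln_len >= 1L)
  structure(list(min_identity = min_identity,
                 min_aln_len = as.integer(min_aln_len),
                 match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "ires_params")
}

#' Find IRES elements on a circRNA
#'
#' Each library sequence is locally aligned against the doubled circle
#' sequence (`seq` followed by its first L-1 bases) so that every
#' junction-crossing placement is visible; the best local alignment per
#' library entry is kept when it reaches both the identity and the
#' alignment-length cutoffs. Reported coordinates are circle coordinates:
#' `circ_start` in `[0, L)` and `circ_end = circ_start + alignment span`
#' (values `>= L` indicate a junction-crossing hit; positions are taken
#' modulo L).
#'
#' @param circ a [circ_rna()].
#' @param ires_library named character vector of IRES sequences (DNA or
#'   RNA; U is normalised to T).
#' @param params an [ires_params()].
#' @return data.frame with `circ_id`, `ires_id`, `circ_start`, `circ_end`,
#'   `aln_len`, `identity`, `score`.
#' @export
find_ires <- function(circ, ires_library, params = ires_params()) {
  empty <- data.frame(circ_id = character(), ires_id = character(),
                      circ_start = integer(), circ_end = integer(),
                      aln_len = integer(), identity = numeric(),
                      score = numeric())
  if (length(ires_library) == 0L) return(empty)
  L <- nchar(circ$seq)
  doubled <- paste0(circ$seq, substr(circ$seq, 1L, L - 1L))
  out <- list()
  for (i in seq_along(ires_library)) {
    q <- normalize_dna(ires_library[[i]], "IRES")
    a <- local_align(q, doubled, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
    if (a$aln_len >= params$min_aln_len &&
        !is.na(a$identity) && a$identity >= params$min_identity) {
      cs <- (a$s_start - 1L) %% L
      out[[length(out) + 1L]] <- data.frame(
        circ_id = circ$circ_id,
        ires_id = names(ires_library)[i],
        circ_start = cs,
        circ_end = cs + (a$s_end - a$s_start + 1L),
        aln_len = a$aln_len, identity = a$identity, score = a$score)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  # dedup modulo L: one hit per (ires, circle placement)
  res <- res[!duplicated(paste(res$ires_id, res$circ_start %% L)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find m6A consensus sites on a circRNA within modification peaks
#'
#' Intersects the peaks with the circRNA exon blocks, maps the covered
#' genomic positions to circle coordinates (strand-aware), and reports
#' every RAC motif occurrence (R = A or G; the central A is the putative
#' m6A site) whose A lies in the covered region. The motif is read
#' circularly, so sites next to the back-splice junction are found.
#'
#' @param circ a [circ_rna()] with genomic blocks.
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, and optionally `source` (peak-calling tool label).
#' @return data.frame with `circ_id`, `circ_pos` (circle coordinate of the
#'   A), `motif`, `peak_id` (comma-collapsed covering peaks), `n_tools`
#'   (distinct peak sources covering the site).
#' @export
find_m6a_sites <- function(circ, peaks) {
  if (is.null(circ$blocks)) {
    stop(sprintf("circRNA '%s' has no blocks; genomic mapping impossible",
                 circ$circ_id))
  }
  empty <- data.frame(circ_id = character(), circ_pos = integer(),
                      motif = character(), peak_id = character(),
                      n_tools = integer())
  if (is.null(peaks$source)) peaks$source <- "peak"
  peaks <- peaks[peaks$chrom == circ$chrom, , drop = FALSE]
  if (nrow(peaks) == 0L) return(empty)
  gmap <- circle_genome_map(circ)
  L <- nchar(circ$seq)
  ch <- strsplit(circ$seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (p in 0:(L - 1L)) {
    if (ch[p + 1L] != "A") next
    r <- ch[((p - 1L) %% L) + 1L]
    cc <- ch[((p + 1L) %% L) + 1L]
    if (!(r %in% c("A", "G")) || cc != "C") next
    g <- gmap[p + 1L]
    cover <- pos_in(g, peaks$start, peaks$end)
    if (!any(cover)) next
    out[[length(out) + 1L]] <- data.frame(
      circ_id = circ$circ_id, circ_pos = p,
      motif = paste0(r, "A", cc),
      peak_id = paste(sort(unique(peaks$name[cover])), collapse = ","),
      n_tools = length(unique(peaks$source[cover])))
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean conservation over a cORF's genomic footprint
#'
#' Maps the circle positions covered by the cORF (wrapping; each circle
#' base counted once even when a rolling-circle ORF traverses it several
#' times) to genomic positions via the exon blocks and averages the
#' per-base conservation scores found in the track. Positions absent from
#' the track are excluded from both numerator and denominator; when no
#' position is scored the mean is `NA` (missing, not 0).
#'
#' @param corf one row of a cORF table (needs `corf_id`, `start`, `nt_len`).
#' @param circ the matching [circ_rna()] with blocks.
#' @param track data.frame with `chrom`, `start`, `end`, `score` (0-based
#'   half-open, non-overlapping intervals, e.g. from [read_bedgraph()]).
#' @return data.frame with `corf_id`, `mean_score`, `n_bases_scored`.
#' @export
score_peptide_conservation <- function(corf, circ, track) {
  if (is.null(circ$blocks)) {
    stop(sprintf("circRNA '%s' has no blocks; genomic mapping impossible",
                 circ$circ_id))
  }
  L <- nchar(circ$seq)
  span <- min(corf$nt_len, L)
  cpos <- unique((corf$start + 0:(span - 1L)) %% L)
  gmap <- circle_genome_map(circ)
  gpos <- gmap[cpos + 1L]
  tr <- track[track$chrom == circ$chrom, , drop = FALSE]
  scores <- numeric(0)
  if (nrow(tr) > 0L) {
    tr <- tr[order(tr$start), , drop = FALSE]
    idx <- findInterval(gpos, tr$start)
    ok <- idx > 0L
    ok[ok] <- gpos[ok] < tr$end[idx[ok]]
    scores <- tr$score[idx[ok]]
  }
  data.frame(corf_id = corf$corf_id,
             mean_score = if (length(scores) == 0L) NA_real_ else mean(scores),
             n_bases_scored = length(scores))
}
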