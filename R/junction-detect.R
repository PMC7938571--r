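# Back-splice junction (BSJ) pseudo-reference construction and
# ribosome-associated circRNA calling.
#
# A circRNA is called ribosome-associated when, after excluding footprints
# that map to the linear transcriptome, it carries (1) at least
# `min_unique_reads` distinct junction-spanning footprint sequences, each
# (2) overlapping the junction by at least `min_overlap` nt on either side
# and (3) falling in the typical footprint length range
# [`min_len`, `max_len`]. Matching is exact (zero mismatches) by default.

#' Detection parameters for ribo-circRNA calling
#'
#' Defaults encode the standard footprint-based criteria: 23-nt flanks on
#' each side of the junction (46-nt pseudo-reference), footprint lengths of
#' 25-35 nt, a minimum 3-nt read-junction overlap on either side, at least
#' 2 unique junction-spanning reads, and exact matching (0 mismatches).
#'
#' @param flank flank length on each side of the BSJ (nt).
#' @param min_len,max_len accepted footprint length range (nt).
#' @param min_overlap minimum overlap with either junction side (nt).
#' @param min_unique_reads minimum distinct junction-spanning read sequences
#'   for a positive call.
#' @param allow_revcomp also match reverse-complemented reads (for
#'   unstranded protocols).
#' @param max_mismatches maximum mismatches allowed in a read-reference
#'   match; 0 means exact.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(flank = 23L, min_len = 25L, max_len = 35L,
                             min_overlap = 3L, min_unique_reads = 2L,
                             allow_revcomp = FALSE, max_mismatches = 0L) {
  stopifnot(flank >= 1L, min_len <= max_len, min_overlap >= 1L,
            min_unique_reads >= 1L, max_mismatches >= 0L)
  structure(list(flank = as.integer(flank), min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_overlap = as.integer(min_overlap),
                 min_unique_reads = as.integer(min_unique_reads),
                 allow_revcomp = isTRUE(allow_revcomp),
                 max_mismatches = as.integer(max_mismatches)),
            class = "detection_params")
}

#' Build the BSJ pseudo-reference
#'
#' For each circRNA, extracts the last `flank` nt of the circle followed by
#' the first `flank` nt, i.e. the 2x`flank` sequence centred on the
#' back-splice junction. Extraction is circular, so circles shorter than
#' 2x`flank` still yield a full-length junction sequence by wrap-around.
#'
#' @param circs list of [circ_rna()] objects.
#' @param params a [detection_params()] object.
#' @return data.frame with `circ_id`, `jseq` (length 2x`flank`) and
#'   `junction_offset` (= `flank`, the index of the first post-junction
#'   base within `jseq`).
#' @export
build_pseudo_reference <- function(circs, params = detection_params()) {
  jseq <- vapply(circs, function(circ) {
    L <- nchar(circ$seq)
    circular_substring(circ, (L - params$flank) %% L, 2L * params$flank)
  }, character(1))
  data.frame(circ_id = vapply(circs, `[[`, character(1), "circ_id"),
             jseq = jseq,
             junction_offset = params$flank)
}

#' Exclude footprints that map to the linear transcriptome
#'
#' Removes every read occurring as an exact substring of any linear
#' reference sequence (or of its reverse complement when
#' `params$allow_revcomp`). Mirrors the map-to-linear-first, remap-the-rest
#' order of the footprint pipeline: a read explainable by a linear template
#' never reaches junction matching.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param linear_refs character vector of linear reference sequences; when
#'   empty the step is the identity.
#' @param params a [detection_params()].
#' @return `reads` with linear mappers removed, original order preserved.
#' @export
exclude_linear_mappers <- function(reads, linear_refs,
                                   params = detection_params()) {
  if (length(linear_refs) == 0L || nrow(reads) == 0L) return(reads)
  refs <- normalize_dna(unname(unlist(linear_refs)), "linear reference")
  uniq <- unique(reads$seq)
  hits_linear <- vapply(uniq, function(s) {
    any(grepl(s, refs, fixed = TRUE)) ||
      (params$allow_revcomp && any(grepl(revcomp_dna(s), refs, fixed = TRUE)))
  }, logical(1))
  drop <- uniq[hits_linear]
  reads[!(reads$seq %in% drop), , drop = FALSE]
}

# Hash all junction-spanning windows of every jseq:
# an environment mapping window sequence -> data.frame(jref index, offset).
index_junction_windows <- function(jrefs, params) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  f <- params$flank
  for (i in seq_len(nrow(jrefs))) {
    jseq <- jrefs$jseq[i]
    for (rl in params$min_len:params$max_len) {
      lo <- max(0L, f - rl + params$min_overlap)
      hi <- min(2L * f - rl, f - params$min_overlap)
      if (hi < lo) next
      offs <- lo:hi
      wins <- substring(jseq, offs + 1L, offs + rl)
      keep <- !grepl("N", wins, fixed = TRUE)  # ambiguous windows never match
      for (k in which(keep)) {
        key <- wins[k]
        env[[key]] <- rbind(env[[key]], c(i, offs[k]))
      }
    }
  }
  env
}

count_mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Match footprint reads against the BSJ pseudo-reference
#'
#' Emits one hit per (read, junction reference, offset) at which the read
#' matches the 46-nt junction sequence with at most `max_mismatches`
#' mismatches (exact by default), has a length within
#' [`min_len`, `max_len`], and overlaps both junction sides by at least
#' `min_overlap` nt. A read may hit several references and several offsets
#' within one reference. Windows or reads containing N never match.
#'
#' @param reads data.frame with `read_id`, `seq` (post-exclusion).
#' @param jrefs pseudo-reference from [build_pseudo_reference()].
#' @param params a [detection_params()].
#' @return data.frame with `circ_id`, `read_id`, `read_seq`, `offset`
#'   (0-based match start within `jseq`), `left_overlap`, `right_overlap`,
#'   `revcomp`.
#' @export
match_junction_reads <- function(reads, jrefs, params = detection_params()) {
  empty <- data.frame(circ_id = character(), read_id = character(),
                      read_seq = character(), offset = integer(),
                      left_overlap = integer(), right_overlap = integer(),
                      revcomp = logical())
  if (nrow(reads) == 0L || nrow(jrefs) == 0L) return(empty)
  f <- params$flank
  ok_len <- nchar(reads$seq) >= params$min_len &
    nchar(reads$seq) <= params$max_len
  reads <- reads[ok_len, , drop = FALSE]
  if (nrow(reads) == 0L) return(empty)

  collect <- list()
  if (params$max_mismatches == 0L) {
    env <- index_junction_windows(jrefs, params)
    uniq <- unique(reads$seq)
    for (s in uniq) {
      variants <- list(c(s, FALSE))
      if (params$allow_revcomp) variants <- c(variants, list(c(revcomp_dna(s), TRUE)))
      for (v in variants) {
        m <- env[[v[1L]]]
        if (is.null(m)) next
        rows <- reads[reads$seq == s, , drop = FALSE]
        for (j in seq_len(nrow(m))) {
          rl <- nchar(s)
          collect[[length(collect) + 1L]] <- data.frame(
            circ_id = jrefs$circ_id[m[j, 1L]],
            read_id = rows$read_id,
            read_seq = rows$seq,
            offset = m[j, 2L],
            left_overlap = f - m[j, 2L],
            right_overlap = rl - (f - m[j, 2L]),
            revcomp = as.logical(v[2L]))
        }
      }
    }
  } else {
    # mismatch-tolerant path: direct scan (desk-scale inputs)
    for (i in seq_len(nrow(jrefs))) {
      jseq <- jrefs$jseq[i]
      for (r in seq_len(nrow(reads))) {
        s <- reads$seq[r]
        rl <- nchar(s)
        variants <- list(c(s, FALSE))
        if (params$allow_revcomp) variants <- c(variants, list(c(revcomp_dna(s), TRUE)))
        for (v in variants) {
          q <- v[1L]
          lo <- max(0L, f - rl + params$min_overlap)
          hi <- min(2L * f - rl, f - params$min_overlap)
          if (hi < lo) next
          for (off in lo:hi) {
            win <- substr(jseq, off + 1L, off + rl)
            if (grepl("N", win, fixed = TRUE) || grepl("N", q, fixed = TRUE)) next
            if (count_mismatches(q, win) <= params$max_mismatches) {
              collect[[length(collect) + 1L]] <- data.frame(
                circ_id = jrefs$circ_id[i], read_id = reads$read_id[r],
                read_seq = s, offset = off, left_overlap = f - off,
                right_overlap = rl - (f - off), revcomp = as.logical(v[2L]))
            }
          }
        }
      }
    }
  }
  if (length(collect) == 0L) return(empty)
  hits <- do.call(rbind, collect)
  hits <- hits[order(hits$circ_id, hits$read_id, hits$offset), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Call ribosome-associated circRNAs from junction hits
#'
#' Per circRNA counts all junction-spanning hits and the number of distinct
#' read sequences among them ("unique" reads: PCR duplicates share a
#' sequence and count once); a circRNA is called ribosome-associated when
#' the unique count reaches `min_unique_reads`. circRNAs without hits are
#' reported with zero counts.
#'
#' @param hits data.frame from [match_junction_reads()].
#' @param circs list of `circ_rna` objects (defines the output rows).
#' @param params a [detection_params()].
#' @return data.frame with `circ_id`, `total_junction_reads`,
#'   `unique_junction_reads`, `is_ribo_circ`.
#' @export
call_ribo_circs <- function(hits, circs, params = detection_params()) {
  ids <- vapply(circs, `[[`, character(1), "circ_id")
  total <- integer(length(ids))
  uniq <- integer(length(ids))
  if (nrow(hits) > 0L) {
    tot_tab <- table(hits$circ_id)
    uni_tab <- tapply(hits$read_seq, hits$circ_id,
                      function(s) length(unique(s)))
    total <- as.integer(ifelse(ids %in% names(tot_tab), tot_tab[ids], 0L))
    uniq <- as.integer(ifelse(ids %in% names(uni_tab), uni_tab[ids], 0L))
    uniq[is.na(uniq)] <- 0L
    total[is.na(total)] <- 0L
  }
  data.frame(circ_id = ids,
             total_junction_reads = total,
             unique_junction_reads = uniq,
             is_ribo_circ = uniq >= params$min_unique_reads)
}

#' Detect ribosome-associated circRNAs end to end
#'
#' Convenience wrapper: linear exclusion, pseudo-reference construction,
#' junction matching, and calling.
#'
#' @param circs list of `circ_rna` objects.
#' @param reads footprint data.frame (`read_id`, `seq`).
#' @param linear_refs character vector of linear reference sequences
#'   (possibly empty).
#' @param params a [detection_params()].
#' @return list with elements `calls` (per-circRNA table), `hits`
#'   (per-match table), and `jrefs` (the pseudo-reference).
#' @export
detect_ribo_circs <- function(circs, reads, linear_refs = character(),
                              params = detection_params()) {
  kept <- exclude_linear_mappers(reads, linear_refs, params)
  jrefs <- build_pseudo_reference(circs, params)
  hits <- match_junction_reads(kept, jrefs, params)
  list(calls = call_ribo_circs(hits, circs, params), hits = hits,
       jrefs = jrefs)
}
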