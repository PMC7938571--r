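# Independent oracles used by the property tests. These deliberately share
# no code with the package implementation: the junction matcher oracle is a
# naive all-offsets substring scan, the alignment oracle is a hand-rolled
# Gotoh dynamic program, and the rotation helpers are plain string ops.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rotate_seq <- function(s, r) {
  L <- nchar(s)
  r <- r %% L
  if (r == 0) return(s)
  paste0(substr(s, r + 1, L), substr(s, 1, r))
}

# Naive junction matcher: scan every (read, jref, offset) triple.
naive_match_oracle <- function(reads, jrefs, params) {
  f <- params$flank
  rows <- list()
  for (r in seq_len(nrow(reads))) {
    s <- reads$seq[r]
    rl <- nchar(s)
    if (rl < params$min_len || rl > params$max_len) next
    if (grepl("N", s, fixed = TRUE)) next
    for (j in seq_len(nrow(jrefs))) {
      jseq <- jrefs$jseq[j]
      for (off in 0:(2 * f - rl)) {
        win <- substr(jseq, off + 1, off + rl)
        if (grepl("N", win, fixed = TRUE)) next
        left <- f - off
        right <- rl - left
        if (left < params$min_overlap || right < params$min_overlap) next
        if (win == s) {
          rows[[length(rows) + 1]] <- data.frame(
            circ_id = jrefs$circ_id[j], read_id = reads$read_id[r],
            read_seq = s, offset = off, left_overlap = left,
            right_overlap = right, revcomp = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(circ_id = character(), read_id = character(),
                      read_seq = character(), offset = integer(),
                      left_overlap = integer(), right_overlap = integer(),
                      revcomp = logical()))
  }
  out <- do.call(rbind, rows)
  out[order(out$circ_id, out$read_id, out$offset), , drop = FALSE]
}

hit_key <- function(h) {
  if (nrow(h) == 0) return(character())
  sort(paste(h$circ_id, h$read_id, h$offset, h$revcomp, sep = "/"))
}

# Gotoh local alignment (affine gaps, gap of length k costs open + k*extend
# with positive penalties); returns only the optimal score.
sw_score_oracle <- function(q, s, match = 2, mismatch = -3,
                            open = 5, extend = 2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (consume subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (consume query)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qv[i - 1] == sv[j - 1] && qv[i - 1] != "N") match else mismatch
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Canonical representation of a cORF set for rotation-invariance checks.
# Finite cORFs compare exactly; INF-cORF peptides are truncated to L
# residues (the template-end truncation point depends on where the start
# sits within the 4x template, so only the first L residues are
# rotation-stable; 4L - p >= 3L + 1 guarantees they exist).
corf_canonical <- function(corfs, L) {
  if (nrow(corfs) == 0) return(character())
  pep <- ifelse(corfs$is_infinite, substr(corfs$peptide, 1, L), corfs$peptide)
  len <- ifelse(corfs$is_infinite, NA_integer_, corfs$nt_len)
  sort(paste(corfs$start, corfs$frame, corfs$is_infinite, len, pep, sep = "/"))
}

# Map cORFs called on a rotated circle back to original coordinates.
unrotate_corfs <- function(corfs, r, L) {
  if (nrow(corfs) == 0) return(corfs)
  corfs$start <- (corfs$start + r) %% L
  corfs$frame <- corfs$start %% 3
  corfs$corf_id <- sprintf("%s:f%d:s%d", corfs$circ_id, corfs$frame,
                           corfs$start)
  corfs
}

fixture_bundle_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixture_bundle(fixture_spec(seed = 1))
    cache
  }
})
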