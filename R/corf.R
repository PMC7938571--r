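# circRNA-derived ORF (cORF) prediction under rolling-circle translation.
#
# The circular sequence is concatenated `copies` times (default 4) and read
# as a linear template. Start codons are restricted to the first copy so
# each circular ORF is reported once; reading proceeds in steps of 3 to the
# first in-frame stop codon (finite cORF) or to the template end (INF-cORF,
# the rolling-circle signature: no in-frame stop exists on the circle in
# that frame). ORFs must reach `min_aa` residues and, by default, span the
# back-splice junction (template position L, the first junction image).

#' cORF prediction parameters
#'
#' @param copies number of template copies of the circle (rolling-circle
#'   reading depth).
#' @param min_aa minimum peptide length in amino acids, initiator Met
#'   included, stop excluded.
#' @param start_codons accepted initiation codons.
#' @param codon_table NCBI genetic-code identifier passed to
#'   [Biostrings::getGeneticCode()] (default `"1"`, the standard code).
#' @param require_junction keep only ORFs whose codon run crosses the
#'   back-splice junction.
#' @return list of class `corf_params`.
#' @export
corf_params <- function(copies = 4L, min_aa = 20L, start_codons = "ATG",
                        codon_table = "1", require_junction = TRUE) {
  stopifnot(copies >= 1L, min_aa >= 1L, length(start_codons) >= 1L)
  structure(list(copies = as.integer(copies), min_aa = as.integer(min_aa),
                 start_codons = toupper(start_codons),
                 codon_table = as.character(codon_table),
                 require_junction = isTRUE(require_junction)),
            class = "corf_params")
}

.code_cache <- new.env(parent = emptyenv())

get_code <- function(codon_table) {
  hit <- .code_cache[[codon_table]]
  if (!is.null(hit)) return(hit)
  code <- Biostrings::getGeneticCode(codon_table)
  names(code) <- chartr("U", "T", names(code))
  .code_cache[[codon_table]] <- code
  code
}

#' Translate a nucleotide sequence with the standard (or chosen) code
#'
#' Translation proceeds codon by codon and stops at the first stop codon
#' (excluded from the peptide) or at the first codon containing an
#' ambiguous base (N), which is treated as the end of the template.
#' Trailing bases short of a full codon are ignored.
#'
#' @param seq nucleotide string (DNA alphabet; U normalised to T).
#' @param codon_table genetic-code identifier (default standard table 1).
#' @return peptide string (possibly empty).
#' @export
#' @examples
#' translate_nt("ATGGCATAA")  # "MA"
translate_nt <- function(seq, codon_table = "1") {
  seq <- normalize_dna(seq, "template")
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  code <- get_code(codon_table)
  aa <- code[codons]
  aa[grepl("N", codons, fixed = TRUE)] <- NA_character_
  stop_at <- which(is.na(aa) | aa == "*")
  if (length(stop_at) > 0L) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Enumerate circRNA-derived ORFs on the rolling-circle template
#'
#' All ORFs beginning with an accepted start codon in the first copy of the
#' `copies`-fold concatenated circle, extended to the first in-frame stop
#' (finite) or to the template end (infinite, `is_infinite = TRUE`). A
#' codon containing N terminates extension as if the template ended there.
#' ORFs shorter than `min_aa` residues and, when `require_junction`, ORFs
#' not crossing the back-splice junction are dropped.
#'
#' @param circ a [circ_rna()] (sequence length at least 3).
#' @param params a [corf_params()].
#' @return data.frame with `circ_id`, `corf_id`, `frame` (start mod 3),
#'   `start` (0-based circle coordinate of the start codon), `nt_len`
#'   (template nucleotides, multiple of 3, stop excluded), `aa_len`,
#'   `peptide`, `is_infinite`, `spans_junction`; sorted by frame then start.
#' @export
enumerate_corfs <- function(circ, params = corf_params()) {
  seq <- if (inherits(circ, "circ_rna")) circ$seq else normalize_dna(circ)
  circ_id <- if (inherits(circ, "circ_rna")) circ$circ_id else "circ"
  L <- nchar(seq)
  stopifnot(L >= 3L)
  template <- strrep(seq, params$copies)
  TL <- nchar(template)
  code <- get_code(params$codon_table)

  start0 <- integer(0); n_aa <- integer(0); infinite <- logical(0)
  peptide <- character(0)
  for (f in 0:2) {
    if (f + 1L > TL - 2L) next
    s <- seq.int(f + 1L, TL - 2L, by = 3L)  # 1-based codon starts
    codons <- substring(template, s, s + 2L)
    has_n <- grepl("N", codons, fixed = TRUE)
    is_stop <- codons %in% STOP_CODONS & !has_n
    starts <- which(codons %in% params$start_codons & s <= L & !has_n)
    if (length(starts) == 0L) next
    terminators <- which(is_stop | has_n)  # reading cannot pass these
    n_codons <- length(codons)
    # first terminator at or after each start (0 = none: runs off template)
    nxt <- terminators[findInterval(starts, terminators) + 1L]
    end_codon <- ifelse(is.na(nxt), n_codons, nxt - 1L)  # stop/N excluded
    inf_here <- is.na(nxt) | !is_stop[ifelse(is.na(nxt), 1L, nxt)]
    len_aa <- end_codon - starts + 1L
    keep <- len_aa >= params$min_aa
    if (params$require_junction) {
      keep <- keep & (s[starts] - 1L + 3L * len_aa) > L
    }
    if (!any(keep)) next
    aa <- unname(code[codons])
    pep <- vapply(which(keep), function(k) {
      paste(aa[starts[k]:end_codon[k]], collapse = "")
    }, character(1))
    start0 <- c(start0, s[starts[keep]] - 1L)
    n_aa <- c(n_aa, len_aa[keep])
    infinite <- c(infinite, inf_here[keep])
    peptide <- c(peptide, pep)
  }
  res <- data.frame(
    circ_id = rep(circ_id, length(start0)),
    corf_id = sprintf("%s:f%d:s%d", circ_id, start0 %% 3L, start0),
    frame = start0 %% 3L, start = start0, nt_len = 3L * n_aa,
    aa_len = n_aa, peptide = peptide, is_infinite = infinite,
    spans_junction = (start0 + 3L * n_aa) > L)
  res <- res[order(res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep the longest cORF per reading frame
#'
#' For each circRNA and each of the three frames, retains the cORF with the
#' greatest template length; ties are broken by smaller start coordinate,
#' then finite before infinite. At most three cORFs survive per circRNA.
#'
#' @param corfs data.frame from [enumerate_corfs()] (may mix circRNAs).
#' @return data.frame with at most one row per (circ_id, frame), sorted by
#'   circ_id, frame, start.
#' @export
select_longest_per_frame <- function(corfs) {
  if (nrow(corfs) == 0L) return(corfs)
  ord <- order(corfs$circ_id, corfs$frame, -corfs$nt_len, corfs$start,
               corfs$is_infinite)
  sorted <- corfs[ord, , drop = FALSE]
  keep <- !duplicated(paste(sorted$circ_id, sorted$frame, sep = "\r"))
  res <- sorted[keep, , drop = FALSE]
  res <- res[order(res$circ_id, res$frame, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Predict cORFs for a set of circRNAs
#'
#' Enumerates rolling-circle ORFs for every circRNA and applies the
#' longest-per-frame selection.
#'
#' @param circs list of `circ_rna` objects.
#' @param params a [corf_params()].
#' @return data.frame of selected cORFs (at most 3 per circRNA).
#' @export
predict_corfs <- function(circs, params = corf_params()) {
  all <- do.call(rbind, lapply(circs, enumerate_corfs, params = params))
  if (is.null(all)) all <- enumerate_corfs(circ_rna("empty", "AAA"), params)[0, ]
  select_longest_per_frame(all)
}
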