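# Proteogenomic support: custom search databases combining the linear
# proteome with cORF peptides, and classification of identified peptides
# as unique junction-spanning translation evidence.

#' Peptide-evidence parameters
#'
#' Defaults: minimum identified-peptide length 7 residues; junction
#' spanning required; isoleucine and leucine treated as distinct for the
#' uniqueness test (set `collapse_il` for I=L-insensitive search engines).
#'
#' @param min_pep_len minimum peptide length (aa).
#' @param require_junction_span require the peptide to cover the
#'   junction-crossing codon.
#' @param collapse_il treat I and L as indistinguishable when testing
#'   presence in the linear proteome.
#' @return list of class `peptide_params`.
#' @export
peptide_params <- function(min_pep_len = 7L, require_junction_span = TRUE,
                           collapse_il = FALSE) {
  stopifnot(min_pep_len >= 1L)
  structure(list(min_pep_len = as.integer(min_pep_len),
                 require_junction_span = isTRUE(require_junction_span),
                 collapse_il = isTRUE(collapse_il)),
            class = "peptide_params")
}

#' Build a combined proteomic search database
#'
#' Concatenates the linear proteome with cORF-derived peptide sequences.
#' cORF entries are namespaced with a `cORF|` prefix; duplicate
#' identifiers are rejected. cORF peptides identical to a proteome entry
#' are kept (the search engine handles redundancy) but flagged.
#'
#' @param proteome data.frame with `id`, `seq` (amino-acid sequences).
#' @param corfs cORF data.frame (needs `corf_id`, `peptide`).
#' @return data.frame with `id`, `seq`, `source` (`"proteome"`/`"corf"`),
#'   `dup_of_proteome` (logical).
#' @export
build_search_database <- function(proteome, corfs) {
  corf_ids <- if (nrow(corfs) > 0L) paste0("cORF|", corfs$corf_id) else character()
  ids <- c(proteome$id, corf_ids)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate database id '%s'", ids[anyDuplicated(ids)[1L]][1L]))
  }
  data.frame(
    id = ids,
    seq = c(toupper(proteome$seq),
            if (nrow(corfs) > 0L) toupper(corfs$peptide) else character()),
    source = c(rep("proteome", nrow(proteome)), rep("corf", length(corf_ids))),
    dup_of_proteome = c(rep(FALSE, nrow(proteome)),
                        if (nrow(corfs) > 0L)
                          toupper(corfs$peptide) %in% toupper(proteome$seq)
                        else logical()))
}

# Residue index sets whose coverage demonstrates junction crossing, for
# every junction image k*L reached by the cORF. When the junction falls
# inside a codon the split codon's single residue suffices; when it falls
# between codons the peptide must include one residue on each side.
junction_residue_sets <- function(start, nt_len, L) {
  sets <- list()
  k <- 1L
  while (k * L < start + nt_len) {
    d <- k * L - start
    if (d > 0L) {
      if (d %% 3L != 0L) {
        sets[[length(sets) + 1L]] <- d %/% 3L
      } else {
        sets[[length(sets) + 1L]] <- c(d %/% 3L - 1L, d %/% 3L)
      }
    }
    k <- k + 1L
  }
  sets
}

#' Classify identified peptides as circRNA translation evidence
#'
#' A peptide is evidence for circRNA translation when it (1) spans the
#' back-splice junction — some occurrence of the peptide within its cORF
#' covers the junction-crossing codon (any junction image reached by a
#' rolling-circle ORF qualifies; when the junction falls between codons a
#' residue on each side is required), (2) is unique — not a substring of
#' any linear-proteome entry (case-insensitive) — and (3) reaches the
#' minimum peptide length.
#'
#' @param identified data.frame with `peptide`, `corf_id`.
#' @param corfs cORF data.frame (needs `corf_id`, `circ_id`, `start`,
#'   `nt_len`, `peptide`).
#' @param circs list of [circ_rna()] objects covering the cORFs' circRNAs.
#' @param proteome data.frame with `id`, `seq`.
#' @param params a [peptide_params()].
#' @return data.frame with `peptide`, `corf_id`, `circ_id`,
#'   `spans_junction`, `is_unique`, `is_evidence`.
#' @export
classify_peptides <- function(identified, corfs, circs, proteome,
                              params = peptide_params()) {
  circ_len <- vapply(circs, function(c) nchar(c$seq), integer(1))
  names(circ_len) <- vapply(circs, `[[`, character(1), "circ_id")
  prot <- toupper(proteome$seq)
  if (params$collapse_il) prot <- chartr("I", "L", prot)
  out <- lapply(seq_len(nrow(identified)), function(r) {
    pep <- toupper(identified$peptide[r])
    cid <- identified$corf_id[r]
    row <- corfs[corfs$corf_id == cid, , drop = FALSE]
    if (nrow(row) == 0L) stop(sprintf("unknown cORF id '%s'", cid))
    row <- row[1L, ]
    cpep <- toupper(row$peptide)
    occ <- gregexpr(pep, cpep, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L) {
      stop(sprintf("peptide '%s' not found in cORF '%s'", pep, cid))
    }
    L <- circ_len[[row$circ_id]]
    jsets <- junction_residue_sets(row$start, row$nt_len, L)
    plen <- nchar(pep)
    spans <- any(vapply(occ, function(o) {
      lo <- o - 1L                    # 0-based residue interval [lo, hi]
      hi <- o + plen - 2L
      any(vapply(jsets, function(s) all(s >= lo & s <= hi), logical(1)))
    }, logical(1)))
    qpep <- if (params$collapse_il) chartr("I", "L", pep) else pep
    unique_pep <- !any(grepl(qpep, prot, fixed = TRUE))
    evid <- unique_pep && plen >= params$min_pep_len &&
      (spans || !params$require_junction_span)
    data.frame(peptide = pep, corf_id = cid, circ_id = row$circ_id,
               spans_junction = spans, is_unique = unique_pep,
               is_evidence = evid)
  })
  if (length(out) == 0L) {
    return(data.frame(peptide = character(), corf_id = character(),
                      circ_id = character(), spans_junction = logical(),
                      is_unique = logical(), is_evidence = logical()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise peptide evidence per circRNA
#'
#' @param evidences data.frame from [classify_peptides()].
#' @return data.frame with `circ_id`, `n_evidence_peptides` (distinct
#'   evidence peptide sequences) and `evidenced` (at least one).
#' @export
summarize_evidence <- function(evidences) {
  if (nrow(evidences) == 0L) {
    return(data.frame(circ_id = character(), n_evidence_peptides = integer(),
                      evidenced = logical()))
  }
  ids <- sort(unique(evidences$circ_id))
  n <- vapply(ids, function(c) {
    length(unique(evidences$peptide[evidences$circ_id == c &
                                      evidences$is_evidence]))
  }, integer(1))
  data.frame(circ_id = ids, n_evidence_peptides = unname(n),
             evidenced = unname(n) >= 1L)
}
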