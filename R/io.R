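# Readers and writers for the plain-text formats the pipeline touches:
# FASTA / FASTQ, BED6 / BED12, bedGraph, and tab-separated tables.
# BED-family and bedGraph parsing is delegated to rtracklayer; coordinates
# are converted to the package-internal 0-based half-open convention.

#' Read a FASTA file into a named character vector
#'
#' Headers are truncated at the first whitespace. Sequences are returned
#' verbatim (no alphabet normalisation); see [read_circ_annotations()] for
#' the normalising circRNA reader.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read ribosome-footprint reads from FASTQ or FASTA
#'
#' A small validating FASTQ reader: malformed records (missing `+` line,
#' sequence/quality length mismatch, truncated final record) are reported
#' with their line number. Files whose first non-empty character is `>` are
#' parsed as FASTA instead.
#'
#' @param path FASTQ or FASTA file of post-preprocessing footprint reads.
#' @return data.frame with columns `read_id`, `seq` (upper-case, U normalised
#'   to T).
#' @export
read_footprints <- function(path) {
  lines <- readLines(path)
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(), seq = character()))
  }
  first <- substr(lines[1L], 1L, 1L)
  if (first == ">") {
    seqs <- read_fasta(path)
    return(data.frame(read_id = names(seqs),
                      seq = normalize_dna(unname(seqs), "read")))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ record starting at line %d",
                 path, 4L * (length(lines) %/% 4L) + 1L))
  }
  idx <- seq(1L, length(lines), by = 4L)
  for (i in idx) {
    if (substr(lines[i], 1L, 1L) != "@") {
      stop(sprintf("%s: line %d: expected '@' header", path, i))
    }
    if (substr(lines[i + 2L], 1L, 1L) != "+") {
      stop(sprintf("%s: line %d: expected '+' separator", path, i + 2L))
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      stop(sprintf("%s: line %d: sequence and quality lengths differ (%d vs %d)",
                   path, i + 3L, nchar(lines[i + 1L]), nchar(lines[i + 3L])))
    }
  }
  data.frame(
    read_id = sub("\\s.*$", "", sub("^@", "", lines[idx])),
    seq = normalize_dna(lines[idx + 1L], "read"))
}

#' Write footprint reads as FASTQ
#'
#' Quality is a constant placeholder (`I`); the pipeline never consumes
#' base qualities.
#'
#' @param reads data.frame with `read_id`, `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  out <- as.vector(rbind(paste0("@", reads$read_id),
                         reads$seq,
                         "+",
                         strrep("I", nchar(reads$seq))))
  writeLines(out, path)
  invisible(path)
}

#' Read circRNA annotations (FASTA + optional BED12 blocks)
#'
#' One `circ_rna` per FASTA record; when a BED12 file is given, exon blocks
#' (and chrom/strand) are attached to the matching records by name.
#'
#' @param fasta_path FASTA of full-length circRNA sequences, headers carrying
#'   the circRNA identifiers.
#' @param bed12_path optional BED12 whose `name` fields match the FASTA ids.
#' @param species optional species label stamped on every record.
#' @return list of [circ_rna()] objects, in FASTA order.
#' @export
read_circ_annotations <- function(fasta_path, bed12_path = NULL,
                                  species = NA_character_) {
  seqs <- read_fasta(fasta_path)
  if (anyDuplicated(names(seqs))) {
    stop(sprintf("%s: duplicate circRNA id '%s'", fasta_path,
                 names(seqs)[anyDuplicated(names(seqs))[1L]][1L]))
  }
  blocks <- list()
  meta <- list()
  if (!is.null(bed12_path)) {
    gr <- rtracklayer::import(bed12_path, format = "bed")
    nm <- as.character(gr$name)
    missing <- setdiff(nm, names(seqs))
    if (length(missing) > 0L) {
      stop(sprintf("%s: BED12 name '%s' has no FASTA record",
                   bed12_path, missing[1L]))
    }
    for (i in seq_along(gr)) {
      feat_start0 <- GenomicRanges::start(gr)[i] - 1L
      if (!is.null(gr$blocks) && length(gr$blocks[[i]]) > 0L) {
        b <- gr$blocks[[i]]  # 1-based, relative to feature start
        bs <- feat_start0 + IRanges::start(b) - 1L
        be <- bs + IRanges::width(b)
      } else {
        bs <- feat_start0
        be <- GenomicRanges::end(gr)[i]
      }
      blocks[[nm[i]]] <- cbind(start = bs, end = be)
      meta[[nm[i]]] <- list(
        chrom = as.character(GenomicRanges::seqnames(gr))[i],
        strand = as.character(GenomicRanges::strand(gr))[i])
    }
  }
  lapply(names(seqs), function(id) {
    m <- meta[[id]]
    circ_rna(id, seqs[[id]],
             chrom = if (is.null(m)) NA_character_ else m$chrom,
             strand = if (is.null(m) || !m$strand %in% c("+", "-")) "+" else m$strand,
             blocks = blocks[[id]],
             species = species)
  })
}

#' Write circRNA exon blocks as BED12
#'
#' @param circs list of `circ_rna` objects with blocks.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(circs, path) {
  rows <- vapply(circs, function(circ) {
    if (is.null(circ$blocks)) {
      stop(sprintf("circRNA '%s' has no blocks; cannot write BED12", circ$circ_id))
    }
    b <- circ$blocks
    span <- c(min(b[, "start"]), max(b[, "end"]))
    paste(circ$chrom, span[1], span[2], circ$circ_id, 0L, circ$strand,
          span[1], span[1], "0", nrow(b),
          paste0(paste(b[, "end"] - b[, "start"], collapse = ","), ","),
          paste0(paste(b[, "start"] - span[1], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read BED6 intervals (e.g. m6A peaks)
#'
#' Peak source labels may be encoded in the name field as `source|peak_id`;
#' otherwise the source defaults to `"peak"`.
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `strand`, `source`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (is.null(gr$name)) paste0("peak", seq_along(gr)) else as.character(gr$name)
  src <- ifelse(grepl("|", nm, fixed = TRUE), sub("\\|.*$", "", nm), "peak")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    strand = as.character(GenomicRanges::strand(gr)),
    source = src)
}

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file (`chrom start end score`, 0-based half-open).
#' @return data.frame with `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(gr$score))
}

#' Write a conservation track as bedGraph
#'
#' @param track data.frame with `chrom`, `start`, `end`, `score` (0-based).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start,
                     track$end, track$score), path)
  invisible(path)
}

#' Read a pairwise ortholog gene table
#'
#' A two-column tab-separated table of orthologous gene symbols between two
#' species; lookup is symmetric (either column may be queried).
#'
#' @param path TSV with a header row naming the two columns.
#' @return data.frame of class `ortholog_table` with columns `gene_a`,
#'   `gene_b`.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2L) {
    stop(sprintf("%s: ortholog table needs two columns, found %d", path, ncol(df)))
  }
  ortholog_table(df[[1L]], df[[2L]])
}

#' Construct an ortholog table
#'
#' @param gene_a,gene_b character vectors of paired gene symbols.
#' @return data.frame of class `ortholog_table`.
#' @export
ortholog_table <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  structure(data.frame(gene_a = as.character(gene_a),
                       gene_b = as.character(gene_b)),
            class = c("ortholog_table", "data.frame"))
}

#' Test whether two genes are orthologous
#'
#' Symmetric: `(a, b)` matches rows stored as `(a, b)` or `(b, a)`.
#'
#' @param table an `ortholog_table`.
#' @param a,b gene symbols (vectorised, recycled).
#' @return logical vector.
#' @export
is_orthologous <- function(table, a, b) {
  key <- paste(table$gene_a, table$gene_b, sep = "\r")
  rkey <- paste(table$gene_b, table$gene_a, sep = "\r")
  paste(a, b, sep = "\r") %in% c(key, rkey)
}

#' Write a result table as TSV with a version header
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# circribo %s", circribo_version()), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_result_tsv()]
#'
#' @param path TSV file; `#`-prefixed lines are ignored.
#' @return data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
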