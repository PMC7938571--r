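# Deterministic synthetic-data generator. Every pipeline stage is testable
# without downloads: the bundle carries a small genome, circRNA annotations
# whose sequences are embedded in that genome, footprint reads planted as
# exact windows of the BSJ pseudo-reference, an IRES library with one
# junction-straddling element, m6A peaks around a planted RAC site, a
# conservation track, a diverged-ortholog flank series, and a proteome plus
# identified-peptide table with known junction-spanning evidence. All
# planted signals are recorded in machine-readable truth tables.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
random_aa <- function(n) paste(sample(AA_ALPHABET, n, TRUE), collapse = "")

#' Fixture specification
#'
#' Defaults emulate a small noiseless study: 25 circRNAs of 120-300 nt, 5
#' of them planted as ribosome-associated with 3 distinct junction-spanning
#' footprints each (the remaining 20 are decoys, 5 of which carry a single
#' junction read and must not be called), 20 decoy footprints drawn from
#' linear transcripts, one designed 30-aa junction-spanning cORF, one
#' junction-straddling IRES, one planted m6A RAC site supported by three
#' peak sources, and an ortholog flank series diverged in 5% steps from 0
#' to 50%.
#'
#' @param seed integer seed; the whole bundle is a pure function of it.
#' @param n_circs number of circRNAs.
#' @param circ_len_range length range (nt) for undesigned circRNAs.
#' @param n_planted_ribo circRNAs planted with enough junction reads to be
#'   called ribosome-associated.
#' @param reads_per_planted distinct junction-spanning reads per planted
#'   circRNA.
#' @param n_decoy_reads footprints drawn from linear transcripts.
#' @param planted_orf_aa peptide length (aa) of the designed cORF (>= 6).
#' @param plant_ires,plant_m6a whether to plant those signals.
#' @param divergence_grid per-pair divergence fractions for the ortholog
#'   flank series (nested mutation sets, so raw alignment score is
#'   non-increasing along the grid).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_circs = 25L,
                         circ_len_range = c(120L, 300L),
                         n_planted_ribo = 5L, reads_per_planted = 3L,
                         n_decoy_reads = 20L, planted_orf_aa = 30L,
                         plant_ires = TRUE, plant_m6a = TRUE,
                         divergence_grid = seq(0, 0.5, by = 0.05)) {
  stopifnot(n_circs >= 3L, n_planted_ribo >= 0L, n_planted_ribo <= n_circs,
            reads_per_planted >= 0L, n_decoy_reads >= 0L,
            length(circ_len_range) == 2L, circ_len_range[1] >= 100L,
            all(divergence_grid >= 0), all(divergence_grid <= 1),
            length(divergence_grid) <= n_circs)
  if (planted_orf_aa < 6L) {
    stop("planted_orf_aa must be at least 6 (circle too short for the requested ORF design)")
  }
  structure(list(seed = as.integer(seed), n_circs = as.integer(n_circs),
                 circ_len_range = as.integer(circ_len_range),
                 n_planted_ribo = as.integer(n_planted_ribo),
                 reads_per_planted = as.integer(reads_per_planted),
                 n_decoy_reads = as.integer(n_decoy_reads),
                 planted_orf_aa = as.integer(planted_orf_aa),
                 plant_ires = isTRUE(plant_ires),
                 plant_m6a = isTRUE(plant_m6a),
                 divergence_grid = divergence_grid),
            class = "fixture_spec")
}

# Designed circle carrying exactly one cORF: a single ATG placed u codons
# before the junction, safe (A-free, stop-free) codons elsewhere in the
# reading path, and a stop-rich ATG-free filler killing all other frames.
# Returns the sequence plus the truth record of the planted ORF.
design_orf_circle <- function(aa_len) {
  safe_pool <- c("GCC", "GCT", "CTC", "CCT", "GTC", "TCC")
  u <- min(5L, aa_len - 1L)
  K <- aa_len + 8L
  n_fill <- K - aa_len - 1L
  fill <- rep(c("TAG", "TAA"), length.out = n_fill)
  pre <- sample(safe_pool, u - 1L, replace = TRUE)    # after ATG, before BSJ
  post <- sample(safe_pool, aa_len - u, replace = TRUE)  # after BSJ
  codons <- c(post, "TAA", fill, "ATG", pre)
  seq <- paste(codons, collapse = "")
  stopifnot(nchar(seq) == 3L * K,
            length(gregexpr("ATG", seq, fixed = TRUE)[[1]]) == 1L)
  code <- get_code("1")
  peptide <- paste(c("M", code[pre], code[post]), collapse = "")
  list(seq = seq, start = 3L * (K - u), frame = 0L, aa_len = aa_len,
       nt_len = 3L * aa_len, peptide = peptide, u = u, L = 3L * K)
}

# Place circRNA sequences on a synthetic chromosome; even-numbered circles
# get two exon blocks (20-nt intron), and the second circle is put on the
# minus strand to exercise strand-aware mapping.
assemble_genome <- function(seqs, chrom = "chrA") {
  pieces <- character(0)
  cursor <- 0L
  add <- function(piece) {
    pieces[[length(pieces) + 1L]] <<- piece
    cursor <<- cursor + nchar(piece)
  }
  add(random_dna(100L))
  circs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    seq <- seqs[[i]]
    strand <- if (i == 2L) "-" else "+"
    gseq <- if (strand == "-") revcomp_dna(seq) else seq
    if (i %% 2L == 0L) {
      w1 <- nchar(gseq) %/% 2L
      b1s <- cursor; add(substr(gseq, 1L, w1))
      add(random_dna(20L))  # intron
      b2s <- cursor; add(substr(gseq, w1 + 1L, nchar(gseq)))
      blocks <- cbind(start = c(b1s, b2s),
                      end = c(b1s + w1, b2s + nchar(gseq) - w1))
    } else {
      b1s <- cursor; add(gseq)
      blocks <- cbind(start = b1s, end = b1s + nchar(gseq))
    }
    circs[[i]] <- circ_rna(sprintf("circ%02d", i), seq, chrom = chrom,
                           strand = strand, blocks = blocks,
                           host_gene = sprintf("geneA%02d", i),
                           species = "speciesA")
    add(random_dna(100L))
  }
  list(genome = stats::setNames(paste(pieces, collapse = ""), chrom),
       circs = circs)
}

#' Generate the synthetic fixture bundle
#'
#' @param spec a [fixture_spec()].
#' @return list with elements `circs` (list of [circ_rna()]), `genome`
#'   (named chromosome vector), `reads` (footprints), `linear` (linear
#'   transcript sequences), `ires_library`, `peaks`, `track`, `orthologs`,
#'   `flanks_a`, `flanks_b`, `proteome`, `identified`, and `truth` (a list
#'   of truth tables: `ribo`, `orf`, `ires`, `m6a`, `conserved`,
#'   `evidence`, `conservation_score`).
#' @export
generate_fixture_bundle <- function(spec = fixture_spec()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  orf <- design_orf_circle(spec$planted_orf_aa)
  lens <- sample(seq(spec$circ_len_range[1], spec$circ_len_range[2]),
                 spec$n_circs, replace = TRUE)
  seqs <- lapply(lens, random_dna)
  seqs[[1L]] <- orf$seq
  if (spec$plant_m6a) {
    s2 <- seqs[[2L]]
    substr(s2, 10L, 12L) <- "GAC"  # circle positions 9-11 (0-based); A at 10
    seqs[[2L]] <- s2
  }
  asm <- assemble_genome(seqs)
  circs <- asm$circs
  genome <- asm$genome

  # --- footprints -----------------------------------------------------
  dp <- detection_params()
  jrefs <- build_pseudo_reference(circs, dp)
  planted_reads <- list()
  mk_reads <- function(jseq, n) {
    out <- character(0)
    k <- 0L
    while (length(out) < n && k < 200L) {
      rl <- 25L + (k %% 11L)
      off <- (3L + k) %% (min(2L * dp$flank - rl, dp$flank - dp$min_overlap) -
                            max(0L, dp$flank - rl + dp$min_overlap) + 1L) +
        max(0L, dp$flank - rl + dp$min_overlap)
      cand <- substr(jseq, off + 1L, off + rl)
      if (!cand %in% out) out <- c(out, cand)
      k <- k + 1L
    }
    out
  }
  for (i in seq_len(spec$n_planted_ribo)) {
    planted_reads[[i]] <- mk_reads(jrefs$jseq[i], spec$reads_per_planted)
  }
  # five single-read decoy circles (below the 2-unique-read threshold)
  single_ids <- seq(spec$n_planted_ribo + 1L,
                    length.out = min(5L, spec$n_circs - spec$n_planted_ribo))
  single_reads <- lapply(single_ids, function(i) mk_reads(jrefs$jseq[i], 1L))

  all_planted <- unlist(c(planted_reads, single_reads))
  linear <- NULL
  for (try in 1:50) {
    linear <- vapply(1:5, function(i) random_dna(500L), character(1))
    if (!any(vapply(all_planted, function(s)
      any(grepl(s, linear, fixed = TRUE)), logical(1)))) break
  }
  names(linear) <- sprintf("linear%02d", seq_along(linear))
  decoys <- vapply(seq_len(spec$n_decoy_reads), function(k) {
    src <- linear[[sample(length(linear), 1L)]]
    rl <- sample(25:35, 1L)
    st <- sample(nchar(src) - rl, 1L)
    substr(src, st + 1L, st + rl)
  }, character(1))
  read_seqs <- c(all_planted, decoys)
  reads <- data.frame(read_id = sprintf("fp%04d", seq_along(read_seqs)),
                      seq = read_seqs)
  reads <- reads[sample(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL

  # --- IRES library ---------------------------------------------------
  ires_library <- character(0)
  ires_truth <- data.frame(ires_id = character(), circ_id = character(),
                           circ_start = integer(), length = integer())
  if (spec$plant_ires) {
    L2 <- nchar(circs[[2L]]$seq)
    straddle <- circular_substring(circs[[2L]], L2 - 15L, 40L)
    interior <- substr(circs[[3L]]$seq, 41L, 70L)
    ires_library <- c(ires_bsj = straddle, ires_lin = interior,
                      ires_decoy1 = random_dna(60L),
                      ires_decoy2 = random_dna(60L))
    ires_truth <- data.frame(
      ires_id = c("ires_bsj", "ires_lin"),
      circ_id = c("circ02", "circ03"),
      circ_start = c(L2 - 15L, 40L),
      length = c(40L, 30L))
  }

  # --- m6A peaks ------------------------------------------------------
  peaks <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), source = character())
  m6a_truth <- data.frame(circ_id = character(), circ_pos = integer(),
                          motif = character(), n_tools = integer())
  if (spec$plant_m6a) {
    gA <- circle_genome_map(circs[[2L]])[11L]  # genomic pos of the planted A (circle pos 10)
    tools <- c("exomePeak", "MeTPeak", "MACS2")
    peaks <- data.frame(
      chrom = "chrA",
      start = c(rep(gA - 10L, 3L), 10L),
      end = c(rep(gA + 11L, 3L), 30L),
      name = c(sprintf("%s|pk1", tools), "exomePeak|pk_off"),
      strand = "+",
      source = c(tools, "exomePeak"))
    m6a_truth <- data.frame(circ_id = "circ02", circ_pos = 10L,
                            motif = "GAC", n_tools = 3L)
  }

  # --- conservation flank series -------------------------------------
  cp <- conservation_params()
  npair <- length(spec$divergence_grid)
  flanks_a <- do.call(rbind, lapply(seq_len(npair), function(i) {
    extract_bsj_flanks(circs[[i]], genome, cp)
  }))
  mut_order <- sample(2L * cp$flank)  # nested mutation sets along the grid
  flip <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  flanks_b <- do.call(rbind, lapply(seq_len(npair), function(i) {
    n_mut <- round(spec$divergence_grid[i] * 2L * cp$flank)
    s <- strsplit(flanks_a$seq[i], "", fixed = TRUE)[[1]]
    for (p in mut_order[seq_len(n_mut)]) s[p] <- flip[[s[p]]]
    data.frame(circ_id = sprintf("circB%02d", i), species = "speciesB",
               host_gene = sprintf("geneB%02d", i),
               seq = paste(s, collapse = ""))
  }))
  # control: identical flank whose host gene has no ortholog entry
  flanks_b <- rbind(flanks_b,
                    data.frame(circ_id = "circB_noorth", species = "speciesB",
                               host_gene = "geneB_orphan",
                               seq = flanks_a$seq[1L]))
  orthologs <- ortholog_table(sprintf("geneA%02d", seq_len(npair)),
                              sprintf("geneB%02d", seq_len(npair)))
  conserved_truth <- data.frame(
    circ_a = flanks_a$circ_id, circ_b = sprintf("circB%02d", seq_len(npair)),
    divergence = spec$divergence_grid,
    in_ortholog_table = TRUE)

  # --- conservation track over the designed cORF ---------------------
  b1 <- circs[[1L]]$blocks
  track <- data.frame(chrom = "chrA", start = b1[, "start"],
                      end = b1[, "end"], score = 0.8)
  corf_id <- sprintf("circ01:f%d:s%d", orf$frame, orf$start)
  cons_truth <- data.frame(corf_id = corf_id, expected_mean = 0.8)

  # --- proteome and identified peptides ------------------------------
  u <- orf$u
  P <- orf$peptide
  frag <- function(a, b) substr(P, a, min(b, nchar(P)))
  f_span <- frag(u - 2L, u + 6L)      # 9 aa, covers the junction residues
  f_nonspan <- frag(u + 2L, u + 13L)  # downstream of the junction codons
  f_short <- frag(u - 1L, u + 4L)     # 6 aa, junction-spanning
  f_inprot <- frag(u - 1L, u + 7L)    # 9 aa, also planted into the proteome
  proteome <- NULL
  for (try in 1:50) {
    proteome <- data.frame(id = sprintf("prot%02d", 1:10),
                           seq = vapply(1:10, function(i)
                             random_aa(sample(60:120, 1L)), character(1)))
    proteome$seq[1L] <- paste0(proteome$seq[1L], f_inprot)
    clean <- !any(vapply(c(f_span, f_nonspan), function(s)
      any(grepl(s, proteome$seq, fixed = TRUE)), logical(1)))
    if (clean && f_span != f_inprot) break
  }
  identified <- data.frame(
    peptide = c(f_span, f_nonspan, f_short, f_inprot),
    corf_id = corf_id)
  evidence_truth <- data.frame(
    peptide = identified$peptide,
    corf_id = corf_id,
    expected_spans = c(TRUE, FALSE, TRUE, TRUE),
    expected_unique = c(TRUE, TRUE, NA, FALSE),  # NA: may sit inside f_inprot
    expected_evidence = c(TRUE, FALSE, FALSE, FALSE))

  ribo_truth <- data.frame(
    circ_id = vapply(circs, `[[`, character(1), "circ_id"),
    planted_positive = seq_len(spec$n_circs) <= spec$n_planted_ribo,
    n_planted_reads = vapply(seq_len(spec$n_circs), function(i) {
      if (i <= spec$n_planted_ribo) spec$reads_per_planted
      else if (i %in% single_ids) 1L else 0L
    }, integer(1)))
  orf_truth <- data.frame(circ_id = "circ01", corf_id = corf_id,
                          frame = orf$frame, start = orf$start,
                          nt_len = orf$nt_len, aa_len = orf$aa_len,
                          peptide = orf$peptide, is_infinite = FALSE,
                          spans_junction = TRUE)

  list(spec = spec, circs = circs, genome = genome, reads = reads,
       linear = linear, ires_library = ires_library, peaks = peaks,
       track = track, orthologs = orthologs, flanks_a = flanks_a,
       flanks_b = flanks_b, proteome = proteome, identified = identified,
       truth = list(ribo = ribo_truth, orf = orf_truth, ires = ires_truth,
                    m6a = m6a_truth, conserved = conserved_truth,
                    evidence = evidence_truth,
                    conservation_score = cons_truth))
}

#' Write a fixture bundle to disk
#'
#' Emits every input the command-line pipeline consumes (FASTA, FASTQ,
#' BED12, BED6, bedGraph, TSV) plus the truth tables, all as plain text
#' with deterministic ordering.
#'
#' @param bundle from [generate_fixture_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$genome, p("genome.fa"))
  circ_seqs <- stats::setNames(
    vapply(bundle$circs, `[[`, character(1), "seq"),
    vapply(bundle$circs, `[[`, character(1), "circ_id"))
  write_fasta(circ_seqs, p("circs.fa"))
  write_bed12(bundle$circs, p("circs.bed12"))
  write_fastq(bundle$reads, p("reads.fastq"))
  write_fasta(bundle$linear, p("linear.fa"))
  if (length(bundle$ires_library) > 0L) {
    write_fasta(bundle$ires_library, p("ires.fa"))
  }
  if (nrow(bundle$peaks) > 0L) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", bundle$peaks$chrom,
                       bundle$peaks$start, bundle$peaks$end,
                       bundle$peaks$name, bundle$peaks$strand),
               p("m6a_peaks.bed"))
  }
  write_bedgraph(bundle$track, p("cons.bedGraph"))
  utils::write.table(bundle$orthologs, p("orthologs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_flanks_fasta(bundle$flanks_a, p("flanks_a.fa"))
  write_flanks_fasta(bundle$flanks_b, p("flanks_b.fa"))
  write_fasta(stats::setNames(bundle$proteome$seq, bundle$proteome$id),
              p("proteome.fa"))
  utils::write.table(bundle$identified, p("identified_peptides.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$truth)) {
    utils::write.table(bundle$truth[[nm]], p(sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Write / read BSJ flank records as FASTA
#'
#' Headers encode `circ_id|species|host_gene`.
#'
#' @param flanks data.frame from [extract_bsj_flanks()].
#' @param path FASTA file.
#' @return `path` invisibly (writer); flank data.frame (reader).
#' @export
write_flanks_fasta <- function(flanks, path) {
  write_fasta(stats::setNames(flanks$seq,
                              paste(flanks$circ_id, flanks$species,
                                    flanks$host_gene, sep = "|")), path)
}

#' @rdname write_flanks_fasta
#' @export
read_flanks_fasta <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  data.frame(circ_id = vapply(parts, `[`, character(1), 1L),
             species = vapply(parts, function(x) if (length(x) > 1L) x[2L] else NA_character_, character(1)),
             host_gene = vapply(parts, function(x) if (length(x) > 2L) x[3L] else NA_character_, character(1)),
             seq = unname(seqs))
}
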