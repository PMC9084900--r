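# Readers and writers for the plain-text formats the pipeline consumes:
# paired FASTA and AXT codon alignments, BED gene intervals, BLAST tabular
# hits, and abundance-matrix TSVs.

#' Read a pairwise codon alignment from a FASTA file
#'
#' The first two records form the pair.
#'
#' @param path FASTA file with at least two aligned records.
#' @param id alignment identifier; defaults to the first record's name.
#' @param remove_gap_codons see [pair_alignment()].
#' @return a [pair_alignment()].
#' @export
read_pair_fasta <- function(path, id = NULL, remove_gap_codons = TRUE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2L) {
    stop("need at least two FASTA records", call. = FALSE)
  }
  pair_alignment(if (is.null(id)) names(seqs)[1L] else id,
                 as.character(seqs[[1L]]), as.character(seqs[[2L]]),
                 remove_gap_codons = remove_gap_codons)
}

#' Write a pairwise alignment as FASTA
#'
#' @param alignment a [pair_alignment()].
#' @param path output path.
#' @param names record names; default `<id>_a`, `<id>_b`.
#' @return `path`, invisibly.
#' @export
write_pair_fasta <- function(alignment, path, names = NULL) {
  stopifnot(inherits(alignment, "pair_alignment"))
  if (is.null(names)) {
    names <- paste0(alignment$id, c("_a", "_b"))
  }
  seqs <- Biostrings::DNAStringSet(c(alignment$seq_a, alignment$seq_b))
  names(seqs) <- names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read pairwise alignments from an AXT file
#'
#' Each AXT block is a header line followed by the two aligned sequence lines;
#' blocks are separated by blank lines.
#'
#' @param path AXT file.
#' @param remove_gap_codons see [pair_alignment()].
#' @return list of [pair_alignment()]s named by the first header field.
#' @export
read_axt <- function(path, remove_gap_codons = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) %% 3L != 0L) {
    stop("malformed AXT: expected blocks of header + two sequence lines",
         call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 3L)
  alns <- lapply(idx, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1L]][1L]
    pair_alignment(id, lines[i + 1L], lines[i + 2L],
                   remove_gap_codons = remove_gap_codons)
  })
  names(alns) <- vapply(alns, function(a) a$id, character(1))
  alns
}

#' Write pairwise alignments to an AXT file
#'
#' @param alignments list of [pair_alignment()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_axt <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in alignments) {
    stopifnot(inherits(a, "pair_alignment"))
    writeLines(c(a$id, a$seq_a, a$seq_b, ""), con)
  }
  invisible(path)
}

#' Read gene intervals from a BED-like file
#'
#' Columns: chrom (alignment id), start, end (0-based half-open), name
#' (gene id); extra columns are ignored.
#'
#' @param path BED file, tab-separated, no header.
#' @return data frame with `alignment_id`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) {
    stop("BED file needs chrom, start, end, name columns", call. = FALSE)
  }
  data.frame(alignment_id = as.character(tab[[1L]]),
             start = as.integer(tab[[2L]]),
             end = as.integer(tab[[3L]]),
             gene_id = as.character(tab[[4L]]))
}

#' Read 12-column BLAST tabular hits with a subject-label sidecar
#'
#' Expects `-outfmt 6` columns (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore). Labels map subject ids to
#' taxon/category strings for [classify_best_hit()].
#'
#' @param path BLAST tabular TSV.
#' @param labels optional two-column TSV (subject id, label) or a named
#'   character vector.
#' @return data frame with `query_id`, `subject_id`, `subject_label`,
#'   `bitscore`, `evalue`.
#' @export
read_blast_hits <- function(path, labels = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 12L) {
    stop("expected 12 BLAST tabular columns, got ", ncol(tab), call. = FALSE)
  }
  out <- data.frame(query_id = as.character(tab[[1L]]),
                    subject_id = as.character(tab[[2L]]),
                    subject_label = NA_character_,
                    bitscore = as.numeric(tab[[12L]]),
                    evalue = as.numeric(tab[[11L]]))
  if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L && file.exists(labels)) {
      lab_tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                                   colClasses = "character")
      labels <- stats::setNames(lab_tab[[2L]], lab_tab[[1L]])
    }
    out$subject_label <- unname(labels[out$subject_id])
  }
  out
}

#' Read a sample-by-taxon abundance matrix from TSV
#'
#' Samples as rows with a header row of column ids; optional
#' `#read_total<TAB>sample<TAB>count` comment lines carry per-sample read
#' totals.
#'
#' @param path TSV path.
#' @return an [abundance_matrix()].
#' @export
read_community_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rt_lines <- grep("^#read_total\t", lines, value = TRUE)
  read_totals <- NULL
  if (length(rt_lines) > 0L) {
    parts <- strsplit(rt_lines, "\t")
    read_totals <- stats::setNames(
      as.numeric(vapply(parts, `[`, character(1), 3L)),
      vapply(parts, `[`, character(1), 2L))
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                           header = TRUE, row.names = 1L, check.names = FALSE)
  vals <- as.matrix(tab)
  if (!is.null(read_totals)) {
    read_totals <- read_totals[rownames(vals)]
  }
  abundance_matrix(vals, read_totals = read_totals)
}

#' Write an abundance matrix to TSV
#'
#' @param matrix an [abundance_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_community_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(matrix$read_totals)) {
    writeLines(paste("#read_total", rownames(matrix$values),
                     matrix$read_totals, sep = "\t"), con)
  }
  writeLines(paste(c("sample", colnames(matrix$values)), collapse = "\t"),
             con)
  utils::write.table(matrix$values, con, sep = "\t", col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}
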