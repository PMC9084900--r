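# Presence/absence gene-repertoire algebra: core sets, pangenomes, Venn
# regions, and shared-fraction statistics over strain groups.

.roary_meta_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Presence/absence matrix constructor
#'
#' @param present logical matrix, gene clusters as rows (unique rownames) and
#'   strains as columns (unique colnames).
#' @return an object of class `pa_matrix` with `genes`, `strains`, `present`.
#' @export
pa_matrix <- function(present) {
  stopifnot(is.matrix(present), is.logical(present))
  if (is.null(rownames(present)) || anyDuplicated(rownames(present))) {
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  }
  if (is.null(colnames(present)) || anyDuplicated(colnames(present)) ||
      ncol(present) < 1L) {
    stop("at least one strain with a unique name is required", call. = FALSE)
  }
  structure(list(genes = rownames(present), strains = colnames(present),
                 present = present),
            class = "pa_matrix")
}

#' Read a Roary-style gene_presence_absence.csv
#'
#' Presence means a nonempty cell in a strain column (Roary cells hold locus
#' tags; paralog multiplicity is ignored). Strain columns are taken from
#' `strain_columns` when given, otherwise auto-detected as every column after
#' the 14 standard Roary metadata columns.
#'
#' @param path path to the CSV (quoted fields, first column `Gene`).
#' @param strain_columns optional explicit character vector of strain column
#'   names.
#' @return a [pa_matrix()].
#' @export
read_presence_absence <- function(path, strain_columns = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(tab)[1L] != "Gene") {
    stop("first column must be 'Gene'", call. = FALSE)
  }
  if (anyDuplicated(tab$Gene)) {
    stop("duplicate gene ids in presence/absence table", call. = FALSE)
  }
  if (is.null(strain_columns)) {
    if (ncol(tab) <= length(.roary_meta_cols)) {
      stop("no strain columns found after the 14 metadata columns",
           call. = FALSE)
    }
    strain_columns <- names(tab)[-seq_along(.roary_meta_cols)]
  } else {
    missing <- setdiff(strain_columns, names(tab))
    if (length(missing) > 0L) {
      stop("strain column(s) not in file: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  present <- vapply(strain_columns,
                    function(cn) nzchar(trimws(tab[[cn]])) & !is.na(tab[[cn]]),
                    logical(nrow(tab)))
  present <- matrix(present, nrow = nrow(tab),
                    dimnames = list(tab$Gene, strain_columns))
  pa_matrix(present)
}

#' Write a Roary-style gene_presence_absence.csv
#'
#' Emits the 14 standard metadata columns (filled minimally) followed by one
#' column per strain, with a synthetic locus tag where a gene is present.
#'
#' @param pa a [pa_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(pa, path) {
  stopifnot(inherits(pa, "pa_matrix"))
  n <- length(pa$genes)
  meta <- data.frame(matrix("", nrow = n,
                            ncol = length(.roary_meta_cols)),
                     check.names = FALSE)
  names(meta) <- .roary_meta_cols
  meta$Gene <- pa$genes
  meta[["No. isolates"]] <- rowSums(pa$present)
  cells <- matrix("", nrow = n, ncol = length(pa$strains),
                  dimnames = list(NULL, pa$strains))
  for (s in seq_along(pa$strains)) {
    hit <- pa$present[, s]
    cells[hit, s] <- paste0(pa$strains[s], "_", which(hit))
  }
  out <- cbind(meta, as.data.frame(cells, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @noRd
.group_members <- function(pa, group) {
  members <- if (is.list(group)) group$members else group
  if (length(members) == 0L) stop("empty strain group", call. = FALSE)
  missing <- setdiff(members, pa$strains)
  if (length(missing) > 0L) {
    stop("unknown strain(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  members
}

#' Core gene set of a strain group
#'
#' Genes present in every member of the group.
#'
#' @param pa a [pa_matrix()].
#' @param group character vector of strain ids (or a list with a `members`
#'   element).
#' @return character vector of gene ids.
#' @export
core_set <- function(pa, group) {
  members <- .group_members(pa, group)
  sub <- pa$present[, members, drop = FALSE]
  pa$genes[rowSums(sub) == length(members)]
}

#' Pangenome gene set of a strain group
#'
#' Genes present in at least one member of the group.
#'
#' @inheritParams core_set
#' @return character vector of gene ids.
#' @export
pangenome_set <- function(pa, group) {
  members <- .group_members(pa, group)
  sub <- pa$present[, members, drop = FALSE]
  pa$genes[rowSums(sub) > 0L]
}

#' Venn region counts for labeled gene sets
#'
#' Assigns every gene in the union to exactly one region signature (a
#' membership bit-string in the order of the input sets) and counts genes per
#' region; the counts sum to the union size.
#'
#' @param sets named list of 2 to `max_sets` character vectors.
#' @param max_sets readability cap on the number of sets.
#' @return named integer vector, names are bit-string signatures like `"10"`.
#' @examples
#' venn_regions(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
venn_regions <- function(sets, max_sets = 6) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("at least 2 sets are required", call. = FALSE)
  }
  if (length(sets) > max_sets) {
    stop("more than ", max_sets, " sets; raise max_sets to override",
         call. = FALSE)
  }
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes))
  sig <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  counts <- table(sig)
  stats::setNames(as.integer(counts), names(counts))
}

#' Fraction of a reference gene set shared with another set
#'
#' `|set_a intersect reference| / |reference|`.
#'
#' @param set_a,reference character vectors of gene ids; `reference` nonempty.
#' @return fraction in \[0, 1\].
#' @export
shared_fraction <- function(set_a, reference) {
  if (length(reference) == 0L) {
    stop("reference set must be nonempty", call. = FALSE)
  }
  length(intersect(set_a, reference)) / length(unique(reference))
}
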