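# GO DAG loading, annotation propagation, and gene-set enrichment
# (classic Fisher and elim decorrelation).

#' @noRd
new_go_dag <- function(terms, parents, alt = character(0)) {
  # validate reachability/acyclicity by topological layering from the roots
  ids <- terms$id
  parents <- stats::setNames(
    lapply(ids, function(id) as.character(parents[[id]])), ids)
  roots <- ids[lengths(parents[ids]) == 0L]
  if (length(roots) == 0L) stop("DAG has no root term", call. = FALSE)
  depth <- .dag_depths(ids, parents)
  structure(list(terms = terms, parents = parents, alt = alt,
                 roots = roots, depth = depth),
            class = "go_dag")
}

#' @noRd
.dag_depths <- function(ids, parents) {
  # longest distance from a root; errors on cycles or unreachable terms
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  indeg <- stats::setNames(lengths(parents[ids]), ids)
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) {
      if (!p %in% ids) {
        stop("term ", id, " references unknown parent ", p, call. = FALSE)
      }
      children[[p]] <- c(children[[p]], id)
    }
  }
  queue <- ids[indeg == 0L]
  depth[queue] <- 0L
  done <- 0L
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    done <- done + 1L
    for (ch in children[[cur]]) {
      depth[ch] <- max(depth[ch], depth[cur] + 1L, na.rm = TRUE)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (done != length(ids)) {
    stop("cycle detected in is_a graph", call. = FALSE)
  }
  depth
}

#' Load a GO DAG from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a`, `alt_id`, and
#' `is_obsolete`; obsolete terms are skipped and alternate ids are mapped to
#' their primary term. Only `is_a` edges are used.
#'
#' @param path path to an OBO file.
#' @return an object of class `go_dag`: `terms` (data frame `id`, `name`,
#'   `namespace`), `parents` (named list of parent ids), `alt` (named vector
#'   alt id -> primary id), `roots`, and `depth` (longest distance from a
#'   root).
#' @export
load_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("no [Term] stanzas found", call. = FALSE)
  stanza_ends <- c(term_starts[-1L] - 1L, length(lines))
  # a non-Term stanza (e.g. [Typedef]) terminates the preceding term block
  other <- which(grepl("^\\[", lines) & lines != "[Term]")

  ids <- names <- namespaces <- character(0)
  parents <- list()
  alt <- character(0)
  for (i in seq_along(term_starts)) {
    end <- stanza_ends[i]
    cut <- other[other > term_starts[i] & other <= end]
    if (length(cut) > 0L) end <- min(cut) - 1L
    block <- lines[(term_starts[i] + 1L):end]
    block <- sub("\\s*!.*$", "", block)
    field <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", v))
    }
    if (any(tolower(field("is_obsolete")) == "true")) next
    id <- field("id")
    if (length(id) != 1L) stop("term stanza without a single id", call. = FALSE)
    ns <- field("namespace")
    if (length(ns) != 1L || !nzchar(ns)) {
      stop("term ", id, " has no namespace", call. = FALSE)
    }
    nm <- field("name")
    ids <- c(ids, id)
    names <- c(names, if (length(nm) > 0) nm[1L] else id)
    namespaces <- c(namespaces, ns)
    parents[[id]] <- field("is_a")
    for (a in field("alt_id")) alt[a] <- id
  }
  if (anyDuplicated(ids)) stop("duplicate term ids in OBO file", call. = FALSE)
  terms <- data.frame(id = ids, name = names, namespace = namespaces)
  new_go_dag(terms, parents, alt)
}

#' Write a GO DAG to an OBO 1.2 file
#'
#' @param dag a `go_dag` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (length(dag$parents[[id]]) > 0)
                   paste0("is_a: ", dag$parents[[id]])), con)
  }
  invisible(path)
}

#' @noRd
.term_ancestors <- function(dag) {
  # inclusive ancestor sets, memoized in topological (increasing depth) order
  anc <- stats::setNames(vector("list", nrow(dag$terms)), dag$terms$id)
  for (id in dag$terms$id[order(dag$depth[dag$terms$id])]) {
    anc[[id]] <- unique(c(id, unlist(anc[dag$parents[[id]]])))
  }
  anc
}

#' Propagate gene annotations up the DAG (true-path rule)
#'
#' Every gene annotated to a term is implicitly annotated to all of that
#' term's ancestors.
#'
#' @param direct named list: gene id -> character vector of term ids (alternate
#'   ids are mapped to their primary term).
#' @param dag a `go_dag` object.
#' @return an object of class `annotation_map` with `direct` and `propagated`
#'   named lists.
#' @export
propagate_annotations <- function(direct, dag) {
  stopifnot(inherits(dag, "go_dag"), is.list(direct))
  known <- dag$terms$id
  direct <- lapply(direct, function(tt) {
    mapped <- ifelse(tt %in% names(dag$alt), dag$alt[tt], tt)
    unique(unname(mapped))
  })
  offenders <- unique(unlist(lapply(direct, setdiff, y = known)))
  if (length(offenders) > 0L) {
    stop("unknown term id(s): ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }
  anc <- .term_ancestors(dag)
  propagated <- lapply(direct, function(tt) unique(unlist(anc[tt])))
  structure(list(direct = direct, propagated = propagated),
            class = "annotation_map")
}

#' Read a two-column gene-to-term annotation TSV
#'
#' @param path TSV with columns gene id and term id, one pair per line, no
#'   header.
#' @return named list gene -> term ids, suitable for
#'   [propagate_annotations()].
#' @export
read_annotation_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "term"),
                           colClasses = "character")
  split(tab$term, tab$gene)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing `study_count` or more annotated genes when drawing
#' `study_total` genes without replacement from a universe of `universe_total`
#' genes of which `universe_count` are annotated (Fisher's exact test,
#' enrichment tail).
#'
#' @param study_count,study_total,universe_count,universe_total 2x2 table
#'   counts.
#' @return p-value.
#' @examples
#' fisher_tail(4, 5, 5, 20) # 76/15504
#' @export
fisher_tail <- function(study_count, study_total, universe_count,
                        universe_total) {
  if (study_count > study_total || study_count > universe_count ||
      study_total > universe_total || universe_count > universe_total ||
      any(c(study_count, study_total, universe_count, universe_total) < 0)) {
    stop("impossible counts for the 2x2 enrichment table", call. = FALSE)
  }
  stats::phyper(study_count - 1, universe_count,
                universe_total - universe_count, study_total,
                lower.tail = FALSE)
}

#' GO term enrichment over a gene universe
#'
#' Classic enrichment tests every term with [fisher_tail()] on propagated
#' counts. The elim variant processes terms children-before-parents (by
#' decreasing DAG depth); whenever a term's current p-value falls below
#' `elim_alpha`, its study genes are removed from all ancestors' gene sets
#' before those are tested, decorrelating the hierarchy. Genes without any
#' propagated annotation are dropped from both study and universe totals.
#'
#' @param study,universe character vectors of gene ids, `study` a subset of
#'   `universe`.
#' @param annotations an `annotation_map` from [propagate_annotations()].
#' @param dag a `go_dag` object.
#' @param method `"elim"` (default; computes both p-values) or `"classic"`
#'   (leaves `p_elim` as `NA`).
#' @param elim_alpha significance cutoff that triggers gene elimination.
#' @return data frame with `term_id`, `name`, `study_count`, `study_total`,
#'   `universe_count`, `universe_total`, `p_classic`, `p_elim`, ordered by
#'   `p_classic`. Counts are the pre-elimination (classic) counts; terms with
#'   no annotated universe gene are skipped.
#' @export
run_enrichment <- function(study, universe, annotations, dag,
                           method = c("elim", "classic"), elim_alpha = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(annotations, "annotation_map"), inherits(dag, "go_dag"))
  if (length(study) == 0L) stop("study set is empty", call. = FALSE)
  if (!all(study %in% universe)) {
    stop("study genes must be a subset of the universe", call. = FALSE)
  }
  annotated <- names(annotations$propagated)[
    lengths(annotations$propagated) > 0L]
  universe <- intersect(unique(universe), annotated)
  study <- intersect(unique(study), universe)
  universe_total <- length(universe)
  study_total <- length(study)
  if (universe_total == 0L) {
    stop("no universe gene carries an annotation", call. = FALSE)
  }

  prop <- annotations$propagated[universe]
  term_genes <- split(rep(names(prop), lengths(prop)), unlist(prop))
  term_ids <- names(term_genes)

  p_classic <- vapply(term_ids, function(t) {
    g <- term_genes[[t]]
    fisher_tail(sum(g %in% study), study_total, length(g), universe_total)
  }, numeric(1))

  p_elim <- rep(NA_real_, length(term_ids))
  names(p_elim) <- term_ids
  if (method == "elim") {
    anc <- .term_ancestors(dag)
    removed <- stats::setNames(vector("list", length(term_ids)), term_ids)
    for (t in term_ids[order(-dag$depth[term_ids])]) {
      g <- setdiff(term_genes[[t]], removed[[t]])
      sc <- sum(g %in% study)
      p <- fisher_tail(sc, study_total, length(g), universe_total)
      p_elim[t] <- p
      if (p < elim_alpha && sc > 0L) {
        elim_genes <- g[g %in% study]
        for (a in setdiff(anc[[t]], t)) {
          if (a %in% term_ids) {
            removed[[a]] <- union(removed[[a]], elim_genes)
          }
        }
      }
    }
  }

  out <- data.frame(
    term_id = term_ids,
    name = dag$terms$name[match(term_ids, dag$terms$id)],
    study_count = vapply(term_genes, function(g) sum(g %in% study),
                         integer(1)),
    study_total = study_total,
    universe_count = lengths(term_genes),
    universe_total = universe_total,
    p_classic = p_classic,
    p_elim = unname(p_elim))
  out <- out[order(out$p_classic, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significant terms from an enrichment result
#'
#' @param records data frame from [run_enrichment()].
#' @param alpha significance threshold (strict: `p < alpha`).
#' @param field which p-value column to threshold.
#' @return character vector of term ids sorted by p ascending, ties by id.
#' @export
significant_terms <- function(records, alpha = 0.05,
                              field = c("p_elim", "p_classic")) {
  field <- match.arg(field)
  if (nrow(records) == 0L) return(character(0))
  p <- records[[field]]
  hit <- which(!is.na(p) & p < alpha)
  hit <- hit[order(p[hit], records$term_id[hit])]
  records$term_id[hit]
}
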