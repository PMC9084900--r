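# Branch-transition analysis: quantile enrichment for each adjacent strain
# pair along an ordered chain, then classification of enriched terms as
# unique, shared, or universally conserved.

#' Adjacent pairs of an ordered strain chain
#'
#' @param chain character vector of at least 2 ordered strain ids.
#' @return data frame with `pair` (label `"a-b"`), `from`, `to`.
#' @export
chain_pairs <- function(chain) {
  if (length(chain) < 2L) {
    stop("a chain needs at least 2 strains", call. = FALSE)
  }
  from <- chain[-length(chain)]
  to <- chain[-1L]
  data.frame(pair = paste(from, to, sep = "-"), from = from, to = to)
}

#' Bundle a concatenated pairwise alignment with its gene intervals
#'
#' @param alignment a [pair_alignment()] covering all genes of a strain pair.
#' @param genes data frame with `gene_id`, `start`, `end` (0-based half-open,
#'   alignment coordinates).
#' @param ks_cutoff optional per-pair Ks cutoff overriding the partition
#'   spec's.
#' @return an object of class `pair_bundle`.
#' @export
pair_bundle <- function(alignment, genes, ks_cutoff = NULL) {
  stopifnot(inherits(alignment, "pair_alignment"),
            all(c("gene_id", "start", "end") %in% names(genes)))
  if (any(genes$end > alignment$length)) {
    stop("gene intervals exceed the alignment length", call. = FALSE)
  }
  structure(list(alignment = alignment, genes = genes,
                 ks_cutoff = ks_cutoff),
            class = "pair_bundle")
}

#' Build a pair bundle from a simulated ortholog panel
#'
#' Concatenates the per-gene alignments of a `sim_panel` into one alignment
#' with gene intervals, so the window pipeline can run end to end.
#'
#' @param panel a `sim_panel` from [simulate_ortholog_panel()].
#' @param id alignment identifier.
#' @return a [pair_bundle()].
#' @export
panel_to_bundle <- function(panel, id = "panel") {
  stopifnot(inherits(panel, "sim_panel"))
  lens <- vapply(panel$alignments, function(a) a$length, integer(1))
  ends <- cumsum(lens)
  genes <- data.frame(gene_id = names(panel$alignments),
                      start = c(0L, ends[-length(ends)]),
                      end = ends)
  aln <- pair_alignment(
    id,
    paste(vapply(panel$alignments, function(a) a$seq_a, character(1)),
          collapse = ""),
    paste(vapply(panel$alignments, function(a) a$seq_b, character(1)),
          collapse = ""))
  pair_bundle(aln, genes)
}

#' Quantile-set GO enrichment for one strain pair
#'
#' Runs the divergence scan (windows, NG86, Ks filtering, gene assignment,
#' per-gene aggregation, quantile partitioning) and then tests each quantile
#' gene set for GO enrichment against the universe of all scored genes,
#' returning the significant terms per set.
#'
#' @param bundle a [pair_bundle()].
#' @param annotations an `annotation_map` from [propagate_annotations()].
#' @param dag a `go_dag`.
#' @param spec a [partition_spec()]; the bundle's `ks_cutoff`, when set,
#'   overrides the spec's.
#' @param alpha per-term significance threshold.
#' @param method enrichment p-value used, see [run_enrichment()].
#' @param ... window geometry passed to [scan_alignment()].
#' @return list of class `transition_result`: per-quantile-set character
#'   vectors of significant term ids, plus `scores` (gene scores) and
#'   `partitions`.
#' @export
transition_enrichment <- function(bundle, annotations, dag,
                                  spec = partition_spec(), alpha = 0.05,
                                  method = "elim", ...) {
  stopifnot(inherits(bundle, "pair_bundle"))
  if (!is.null(bundle$ks_cutoff)) {
    spec$ks_cutoff <- bundle$ks_cutoff
  }
  est <- scan_alignment(bundle$alignment, spec = spec, ...)
  asg <- assign_genes_to_windows(est[, c("start", "end")], bundle$genes)
  scores <- gene_level_dnds(asg, est)
  parts <- partition_quantiles(scores, spec)
  universe <- intersect(scores$gene_id, names(annotations$propagated))
  field <- if (method == "elim") "p_elim" else "p_classic"
  sets <- lapply(parts, function(study_genes) {
    study <- intersect(study_genes, universe)
    if (length(study) == 0L) return(character(0))
    rec <- run_enrichment(study, universe, annotations, dag, method = method)
    significant_terms(rec, alpha = alpha, field = field)
  })
  structure(c(sets, list(scores = scores, partitions = parts)),
            class = "transition_result")
}

#' Classify per-pair enriched term sets across a chain
#'
#' A term is `universal` when present in every pair's set, `unique:<pair>` when
#' present in exactly one, and `shared:<pairs>` otherwise. The labels reference
#' pairs by name, so the classification is invariant under pair reordering.
#'
#' @param term_sets named list (one element per strain pair) of term-id
#'   character vectors, all for the same quantile class.
#' @return data frame with `term_id`, `status`
#'   (`universal`/`unique`/`shared`), `label`, and `pairs` (comma-joined pair
#'   names).
#' @export
classify_transition_terms <- function(term_sets) {
  if (!is.list(term_sets) || length(term_sets) < 2L) {
    stop("term sets for at least 2 pairs are required", call. = FALSE)
  }
  if (is.null(names(term_sets)) || anyDuplicated(names(term_sets))) {
    stop("term_sets must be uniquely named by pair", call. = FALSE)
  }
  terms <- sort(unique(unlist(term_sets)))
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), status = character(0),
                      label = character(0), pairs = character(0)))
  }
  rows <- lapply(terms, function(t) {
    in_pairs <- names(term_sets)[vapply(term_sets, function(s) t %in% s,
                                        logical(1))]
    status <- if (length(in_pairs) == length(term_sets)) {
      "universal"
    } else if (length(in_pairs) == 1L) {
      "unique"
    } else {
      "shared"
    }
    label <- switch(status,
                    universal = "universal",
                    unique = paste0("unique:", in_pairs),
                    shared = paste0("shared:", paste(in_pairs,
                                                     collapse = ",")))
    data.frame(term_id = t, status = status, label = label,
               pairs = paste(in_pairs, collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the transition pipeline over an ordered chain of strain pairs
#'
#' @param bundles named list of [pair_bundle()]s, one per adjacent pair, in
#'   chain order.
#' @param annotations,dag,spec,alpha,method,... passed to
#'   [transition_enrichment()].
#' @param class which quantile set to classify across pairs (the conserved
#'   `bottom10` sets by default).
#' @return list with `per_pair` (list of `transition_result`) and `classified`
#'   (data frame from [classify_transition_terms()]).
#' @export
run_transition_chain <- function(bundles, annotations, dag,
                                 spec = partition_spec(), alpha = 0.05,
                                 method = "elim", class = "bottom10", ...) {
  if (length(bundles) < 2L || is.null(names(bundles))) {
    stop("at least 2 named pair bundles are required", call. = FALSE)
  }
  per_pair <- lapply(bundles, transition_enrichment, annotations = annotations,
                     dag = dag, spec = spec, alpha = alpha, method = method,
                     ...)
  sets <- lapply(per_pair, function(r) r[[class]])
  list(per_pair = per_pair,
       classified = classify_transition_terms(sets))
}
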