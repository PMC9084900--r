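# Symbiont contig triage: GC band filter, relative-coverage filter, two-step
# best-hit classification, and the iterative-enrichment stopping rule.

#' GC fraction of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; N bases are excluded from the
#' denominator.
#'
#' @param sequence nonempty string over A/C/G/T/N (either case).
#' @return GC fraction in \[0, 1\].
#' @examples
#' compute_gc("ATGNN")
#' @export
compute_gc <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (nchar(s) == 0L || grepl("[^ACGTN]", s)) {
    stop("sequence must be a nonempty string over A/C/G/T/N", call. = FALSE)
  }
  counts <- table(strsplit(s, "")[[1]])
  gc <- sum(counts[names(counts) %in% c("G", "C")])
  denom <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (denom == 0L) {
    stop("degenerate input: sequence contains only N", call. = FALSE)
  }
  gc / denom
}

#' GC band filter for long contigs
#'
#' Contigs longer than `min_len` are removed when their GC fraction falls
#' strictly below `min_gc` or strictly above `max_gc` (boundary values are
#' retained); shorter contigs are untouched by this rule.
#'
#' @param contigs data frame with `contig_id`, `length`, `gc`.
#' @param min_gc,max_gc GC band bounds in \[0, 1\].
#' @param min_len length gate in bp; the rule applies to contigs `> min_len`.
#' @return data frame of removals: `contig_id`, `reason` (`gc_low`/`gc_high`).
#' @export
filter_by_gc <- function(contigs, min_gc = 0.24, max_gc = 0.42,
                         min_len = 1000) {
  stopifnot(min_gc >= 0, max_gc <= 1, min_gc <= max_gc)
  long <- contigs$length > min_len
  low <- long & contigs$gc < min_gc
  high <- long & contigs$gc > max_gc
  data.frame(contig_id = c(contigs$contig_id[low], contigs$contig_id[high]),
             reason = rep(c("gc_low", "gc_high"), c(sum(low), sum(high))))
}

#' Reference coverage from the longest contigs
#'
#' Arithmetic mean of `mean_coverage` over the `n_longest` contigs by length
#' (length ties broken by contig id ascending); all contigs are used when fewer
#' are available.
#'
#' @param contigs data frame with `contig_id`, `length`, `mean_coverage`.
#' @param n_longest number of longest contigs to average over.
#' @return reference fold-coverage.
#' @export
reference_coverage <- function(contigs, n_longest = 10) {
  if (nrow(contigs) == 0L) stop("no contigs supplied", call. = FALSE)
  ord <- order(-contigs$length, contigs$contig_id)
  take <- ord[seq_len(min(n_longest, nrow(contigs)))]
  mean(contigs$mean_coverage[take])
}

#' Relative-coverage filter for long contigs
#'
#' Contigs longer than `min_len` are removed when their coverage strictly
#' exceeds `factor` times the reference coverage; shorter contigs are
#' untouched. High relative coverage on long contigs flags likely horizontally
#' transferred fragments residing in an abundant non-target genome.
#'
#' @param contigs data frame with `contig_id`, `length`, `mean_coverage`.
#' @param reference reference fold-coverage (> 0), see [reference_coverage()].
#' @param factor removal threshold multiplier.
#' @param min_len length gate in bp; the rule applies to contigs `> min_len`.
#' @return data frame of removals: `contig_id`, `reason` (`coverage_high`).
#' @export
filter_by_coverage <- function(contigs, reference, factor = 2.0,
                               min_len = 5000) {
  if (!is.numeric(reference) || reference <= 0) {
    stop("reference coverage must be positive", call. = FALSE)
  }
  hit <- contigs$length > min_len &
    contigs$mean_coverage > factor * reference
  data.frame(contig_id = contigs$contig_id[hit],
             reason = rep("coverage_high", sum(hit)))
}

#' Two-step best-hit classification of query contigs
#'
#' A query is a candidate iff it has at least one hit in the step-1 (custom
#' database) table. A candidate's final label is the `subject_label` of its
#' best step-2 hit (maximum bitscore, ties by minimum evalue, then subject id
#' ascending); its status is `"target"` when that label is in `target_labels`.
#' Candidates without any step-2 hit keep status `"target"` (the custom-db
#' evidence stands). Queries with no step-1 hit are `"unclassified"`.
#'
#' @param hits_step1,hits_step2 data frames with columns `query_id`,
#'   `subject_id`, `subject_label`, `bitscore`, `evalue`.
#' @param target_labels character vector of labels counted as target.
#' @return data frame with `query_id`, `label`, `status`.
#' @export
classify_best_hit <- function(hits_step1, hits_step2, target_labels) {
  check_hits <- function(h, what) {
    need <- c("query_id", "subject_id", "subject_label", "bitscore", "evalue")
    if (!all(need %in% names(h))) {
      stop(what, " is missing columns: ",
           paste(setdiff(need, names(h)), collapse = ", "), call. = FALSE)
    }
    bad <- which(is.na(h$query_id) | is.na(h$bitscore) | h$bitscore < 0 |
                   is.na(h$evalue) | h$evalue < 0)
    if (length(bad) > 0L) {
      stop("malformed hit row ", bad[1L], " in ", what, call. = FALSE)
    }
    h
  }
  hits_step1 <- check_hits(hits_step1, "hits_step1")
  hits_step2 <- check_hits(hits_step2, "hits_step2")

  candidates <- unique(hits_step1$query_id)
  if (length(candidates) == 0L) {
    return(data.frame(query_id = character(0), label = character(0),
                      status = character(0)))
  }
  label <- rep(NA_character_, length(candidates))
  status <- rep("target", length(candidates))
  h2 <- hits_step2[hits_step2$query_id %in% candidates, , drop = FALSE]
  if (nrow(h2) > 0L) {
    h2 <- h2[order(h2$query_id, -h2$bitscore, h2$evalue, h2$subject_id), ,
             drop = FALSE]
    best <- h2[!duplicated(h2$query_id), , drop = FALSE]
    m <- match(candidates, best$query_id)
    has2 <- !is.na(m)
    label[has2] <- best$subject_label[m[has2]]
    status[has2] <- ifelse(label[has2] %in% target_labels,
                           "target", "nontarget")
  }
  data.frame(query_id = candidates, label = label, status = status)
}

#' Stopping rule for iterative subtractive enrichment
#'
#' Returns `TRUE` (continue) iff the last retained-length total strictly
#' exceeds the previous one and fewer than `max_iterations` cycles have run; a
#' single entry always continues.
#'
#' @param retained_lengths numeric vector of retained bp totals, one per cycle.
#' @param max_iterations safety cap on the number of cycles.
#' @return logical scalar.
#' @examples
#' should_continue_enrichment(c(100000, 150000, 150000))
#' @export
should_continue_enrichment <- function(retained_lengths, max_iterations = 10) {
  if (length(retained_lengths) < 1L) {
    stop("at least one cycle total is required", call. = FALSE)
  }
  if (any(retained_lengths < 0)) {
    stop("retained lengths must be nonnegative", call. = FALSE)
  }
  n <- length(retained_lengths)
  if (n >= max_iterations) return(FALSE)
  if (n == 1L) return(TRUE)
  retained_lengths[n] > retained_lengths[n - 1L]
}

#' Full contig triage
#'
#' Applies, in fixed order, best-hit classification (removing contigs
#' classified as nontarget), the GC band filter, and the relative-coverage
#' filter. A removed contig gets the reason of the first rule it fails; the
#' kept and removed sets partition the input. The reference coverage is
#' computed once from the full input set, so the kept set is independent of
#' rule order.
#'
#' @param contigs data frame with `contig_id`, `length`, `gc`,
#'   `mean_coverage`.
#' @param classification optional output of [classify_best_hit()] matched by
#'   contig id; contigs with status `"nontarget"` are removed.
#' @param min_gc,max_gc,gc_min_len GC filter parameters, see [filter_by_gc()].
#' @param cov_factor,cov_min_len,n_longest coverage filter parameters, see
#'   [filter_by_coverage()] and [reference_coverage()].
#' @return list of class `triage_report`: `kept` (contig ids), `removed`
#'   (named character vector contig id -> reason), `reference_coverage`.
#' @export
triage_contigs <- function(contigs, classification = NULL,
                           min_gc = 0.24, max_gc = 0.42, gc_min_len = 1000,
                           cov_factor = 2.0, cov_min_len = 5000,
                           n_longest = 10) {
  stopifnot(all(c("contig_id", "length", "gc", "mean_coverage") %in%
                  names(contigs)))
  if (anyDuplicated(contigs$contig_id)) {
    stop("duplicate contig ids", call. = FALSE)
  }
  reason <- stats::setNames(rep(NA_character_, nrow(contigs)),
                            contigs$contig_id)
  if (!is.null(classification)) {
    non <- classification$query_id[classification$status == "nontarget"]
    non <- intersect(non, contigs$contig_id)
    reason[non] <- "classified_nontarget"
  }
  add <- function(reason, removals) {
    new <- setdiff(removals$contig_id, names(reason)[!is.na(reason)])
    reason[new] <- removals$reason[match(new, removals$contig_id)]
    reason
  }
  reason <- add(reason, filter_by_gc(contigs, min_gc, max_gc, gc_min_len))
  ref <- reference_coverage(contigs, n_longest)
  reason <- add(reason, filter_by_coverage(contigs, ref, cov_factor,
                                           cov_min_len))
  removed <- reason[!is.na(reason)]
  structure(list(kept = contigs$contig_id[is.na(reason)],
                 removed = removed,
                 reference_coverage = ref),
            class = "triage_report")
}
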