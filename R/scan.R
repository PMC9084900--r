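# Sliding-window dN/dS scanning, gene assignment, and quantile partitioning.

#' Partition specification for quantile gene sets
#'
#' Bundles the quantile fractions used to split gene-level dN/dS scores and the
#' maximum synonymous divergence (Ks) beyond which a window estimate is treated
#' as saturated and excluded.
#'
#' @param top10,top25,bottom10,bottom25 quantile fractions in (0, 1).
#' @param ks_cutoff maximum Ks retained; 2.0 for divergent strain pairs, 2.5
#'   for closely related within-clade pairs.
#' @return an object of class `partition_spec`.
#' @export
partition_spec <- function(top10 = 0.10, top25 = 0.25,
                           bottom10 = 0.10, bottom25 = 0.25,
                           ks_cutoff = 2.0) {
  fr <- c(top10 = top10, top25 = top25, bottom10 = bottom10,
          bottom25 = bottom25)
  if (any(fr <= 0) || any(fr >= 1)) {
    stop("quantile fractions must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(ks_cutoff) || ks_cutoff <= 0) {
    stop("ks_cutoff must be a positive number", call. = FALSE)
  }
  structure(list(fractions = fr, ks_cutoff = ks_cutoff),
            class = "partition_spec")
}

#' Codon-preserving sliding windows over an alignment
#'
#' Windows start at 0, `step`, `2 * step`, ... and span `window` bp (or the
#' remaining tail). The final window is the first one that reaches the end of
#' the alignment; a trailing window shorter than `window` is emitted only when
#' it covers at least `min_tail` bp.
#'
#' @param alignment_length alignment length in bp, divisible by 3.
#' @param window,step window length and offset between window starts, in bp,
#'   both divisible by 3.
#' @param min_tail minimum length for a trailing partial window, bp.
#' @return data frame with 0-based half-open `start`, `end` columns.
#' @examples
#' make_windows(3000)
#' @export
make_windows <- function(alignment_length, window = 1200, step = 600,
                         min_tail = 300) {
  if (alignment_length %% 3 != 0) {
    stop("alignment_length must be divisible by 3", call. = FALSE)
  }
  if (window %% 3 != 0 || step %% 3 != 0) {
    stop("window and step must be divisible by 3", call. = FALSE)
  }
  if (alignment_length < min_tail) {
    warning("alignment shorter than min_tail (", alignment_length, " < ",
            min_tail, "); no windows emitted")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- integer(0)
  ends <- integer(0)
  start <- 0L
  repeat {
    end <- min(start + window, alignment_length)
    if (end - start == window || end - start >= min_tail) {
      starts <- c(starts, start)
      ends <- c(ends, end)
    }
    if (end >= alignment_length) break
    start <- start + as.integer(step)
    if (start >= alignment_length) break
  }
  keep <- !duplicated(paste(starts, ends))
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Pairwise codon alignment container
#'
#' @param id alignment identifier.
#' @param seq_a,seq_b aligned nucleotide strings of equal length.
#' @param remove_gap_codons drop codon columns containing a gap in either
#'   sequence (codon-aware alignments gap in multiples of 3).
#' @return an object of class `pair_alignment` with fields `id`, `seq_a`,
#'   `seq_b`, `length`.
#' @export
pair_alignment <- function(id, seq_a, seq_b, remove_gap_codons = TRUE) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  if (nchar(seq_a) %% 3 != 0) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  if (remove_gap_codons && (grepl("-", seq_a, fixed = TRUE) ||
                            grepl("-", seq_b, fixed = TRUE))) {
    ca <- .split_codons(seq_a)
    cb <- .split_codons(seq_b)
    keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
    seq_a <- paste(ca[keep], collapse = "")
    seq_b <- paste(cb[keep], collapse = "")
  }
  structure(list(id = as.character(id), seq_a = seq_a, seq_b = seq_b,
                 length = nchar(seq_a)),
            class = "pair_alignment")
}

#' Sliding-window dN/dS scan of a pairwise codon alignment
#'
#' Applies [ng86_pair()] to every window from [make_windows()]. Windows whose
#' Ks exceeds `spec$ks_cutoff` are flagged as saturated (`pass = FALSE`) and
#' excluded from downstream partitioning while remaining in the raw report, as
#' are windows with an undefined ratio.
#'
#' @param alignment a [pair_alignment()].
#' @param spec a [partition_spec()] carrying the Ks cutoff.
#' @param window,step,min_tail window geometry, see [make_windows()].
#' @param code_table genetic code id, see [ng86_pair()].
#' @return data frame with columns `start`, `end`, `ka`, `ks`, `ratio`, `sd`,
#'   `nd`, `s_sites`, `n_sites`, and logical `pass`.
#' @export
scan_alignment <- function(alignment, spec = partition_spec(),
                           window = 1200, step = 600, min_tail = 300,
                           code_table = "11") {
  stopifnot(inherits(alignment, "pair_alignment"),
            inherits(spec, "partition_spec"))
  wins <- make_windows(alignment$length, window = window, step = step,
                       min_tail = min_tail)
  if (nrow(wins) == 0L) {
    return(cbind(wins, ka = numeric(0), ks = numeric(0), ratio = numeric(0),
                 sd = numeric(0), nd = numeric(0), s_sites = numeric(0),
                 n_sites = numeric(0), pass = logical(0)))
  }
  est <- lapply(seq_len(nrow(wins)), function(i) {
    a <- substr(alignment$seq_a, wins$start[i] + 1L, wins$end[i])
    b <- substr(alignment$seq_b, wins$start[i] + 1L, wins$end[i])
    ng86_pair(a, b, code_table = code_table)
  })
  out <- cbind(wins, do.call(rbind, lapply(est, function(e) {
    data.frame(ka = e$ka, ks = e$ks, ratio = e$ratio, sd = e$sd, nd = e$nd,
               s_sites = e$s_sites, n_sites = e$n_sites)
  })))
  out$pass <- !is.na(out$ratio) & !is.na(out$ks) & out$ks <= spec$ks_cutoff
  out
}

#' Assign annotated genes to windows by overlap
#'
#' A gene is matched to a window when their intervals overlap across at least
#' `min_overlap` bp.
#'
#' @param windows data frame with `start`, `end` (0-based half-open).
#' @param genes data frame with `gene_id`, `start`, `end` (0-based half-open)
#'   on alignment coordinates.
#' @param min_overlap minimum overlap in bp.
#' @return data frame with columns `gene_id`, `start`, `end` (one row per
#'   gene-window assignment).
#' @export
assign_genes_to_windows <- function(windows, genes, min_overlap = 300) {
  stopifnot(all(c("start", "end") %in% names(windows)),
            all(c("gene_id", "start", "end") %in% names(genes)))
  if (nrow(genes) > 0 && any(genes$start < 0 | genes$end <= genes$start)) {
    stop("gene intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    ov <- pmin(windows$end, genes$end[g]) - pmax(windows$start, genes$start[g])
    hit <- which(ov >= min_overlap)
    if (length(hit) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g],
        start = windows$start[hit], end = windows$end[hit])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, rows)
}

#' Gene-level dN/dS from window estimates
#'
#' Per-gene score is the unweighted mean of the ratios of its assigned windows
#' that survived the Ks cutoff. Genes whose every assigned window was filtered
#' are dropped and reported in the `dropped` attribute.
#'
#' @param assignments output of [assign_genes_to_windows()].
#' @param estimates output of [scan_alignment()].
#' @return data frame with `gene_id`, `dnds`, `n_windows`; dropped gene ids in
#'   `attr(, "dropped")`.
#' @export
gene_level_dnds <- function(assignments, estimates) {
  surv <- estimates[estimates$pass & !is.na(estimates$ratio), , drop = FALSE]
  key <- function(d) paste(d$start, d$end)
  assignments$ratio <- surv$ratio[match(key(assignments), key(surv))]
  ok <- !is.na(assignments$ratio)
  genes <- unique(assignments$gene_id)
  kept <- assignments[ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    res <- data.frame(gene_id = character(0), dnds = numeric(0),
                      n_windows = integer(0))
    attr(res, "dropped") <- genes
    return(res)
  }
  agg <- aggregate(kept$ratio, by = list(gene_id = kept$gene_id),
                   FUN = function(r) c(mean(r), length(r)))
  res <- data.frame(gene_id = agg$gene_id,
                    dnds = agg$x[, 1], n_windows = as.integer(agg$x[, 2]))
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  dropped <- setdiff(genes, res$gene_id)
  if (length(dropped) > 0L) {
    message(length(dropped), " gene(s) dropped: no window survived filtering")
  }
  attr(res, "dropped") <- dropped
  res
}

#' Partition gene scores into top/bottom quantile sets
#'
#' Genes are sorted by dN/dS descending (ties broken by gene id ascending);
#' each top set takes the first `ceiling(f * n)` genes and each bottom set the
#' last `ceiling(f * n)`, so `top10` is nested in `top25` and `bottom10` in
#' `bottom25`.
#'
#' @param scores data frame from [gene_level_dnds()].
#' @param spec a [partition_spec()].
#' @return named list of gene-id character vectors: `top10`, `top25`,
#'   `bottom10`, `bottom25`.
#' @export
partition_quantiles <- function(scores, spec = partition_spec()) {
  stopifnot(inherits(spec, "partition_spec"))
  n <- nrow(scores)
  if (n < 4L) {
    stop("at least 4 scored genes are required for quantile partitioning",
         call. = FALSE)
  }
  ord <- order(-scores$dnds, scores$gene_id)
  ids <- scores$gene_id[ord]
  take <- function(f, from_top) {
    k <- ceiling(f * n)
    if (from_top) ids[seq_len(k)] else ids[seq.int(n - k + 1L, n)]
  }
  fr <- spec$fractions
  list(top10 = take(fr[["top10"]], TRUE),
       top25 = take(fr[["top25"]], TRUE),
       bottom10 = take(fr[["bottom10"]], FALSE),
       bottom25 = take(fr[["bottom25"]], FALSE))
}

#' Linear molecular-clock calibration of divergence time
#'
#' Converts a percent sequence divergence into million years with a linear
#' calibration, by default 216 My per 2.8% 16S rRNA divergence.
#'
#' @param percent_divergence percent divergence (e.g. 3.934 for 3.934%).
#' @param my_per_unit million years accumulated per `pct_per_unit`.
#' @param pct_per_unit percent divergence per `my_per_unit`.
#' @return estimated divergence time in million years.
#' @examples
#' calibrate_divergence_time(3.934) # ~303 My
#' @export
calibrate_divergence_time <- function(percent_divergence, my_per_unit = 216,
                                      pct_per_unit = 2.8) {
  if (any(percent_divergence < 0)) {
    stop("percent_divergence must be nonnegative", call. = FALSE)
  }
  percent_divergence * my_per_unit / pct_per_unit
}

#' Score every gene of a simulated ortholog panel
#'
#' Runs the full window pipeline (scan, assign, aggregate) on each per-gene
#' alignment of a panel from [simulate_ortholog_panel()].
#'
#' @param panel a `sim_panel` object.
#' @param spec a [partition_spec()].
#' @param ... passed to [scan_alignment()].
#' @return data frame of gene scores as in [gene_level_dnds()].
#' @export
score_panel <- function(panel, spec = partition_spec(), ...) {
  stopifnot(inherits(panel, "sim_panel"))
  rows <- lapply(names(panel$alignments), function(gid) {
    aln <- panel$alignments[[gid]]
    est <- scan_alignment(aln, spec = spec, ...)
    asg <- assign_genes_to_windows(
      est[, c("start", "end")],
      data.frame(gene_id = gid, start = 0L, end = aln$length))
    suppressMessages(gene_level_dnds(asg, est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
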