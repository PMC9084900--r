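# Synthetic-data generators. Each generator is seeded explicitly and emulates
# the statistical structure one analysis stage assumes, so the downstream
# estimators can be tested for parameter recovery without sequencing data.

#' Simulate a pairwise codon alignment with planted dN/dS and Ks
#'
#' Draws a random gap-free ancestor of sense codons and plants substitution
#' events per codon position using the Nei-Gojobori site definitions: each
#' position carries a synonymous site fraction f, and a synonymous difference
#' is introduced with probability `ps * f` and a nonsynonymous one with
#' probability `pn * (1 - f)`, where `ps` and `pn` invert the Jukes-Cantor
#' correction at the target Ks and Ka = dN/dS * Ks. Events that would create a
#' stop codon are resampled. The expected NG86 estimates of the resulting pair
#' therefore recover the targets.
#'
#' @param codons number of codons (>= 1).
#' @param target_dnds planted nonsynonymous/synonymous rate ratio (>= 0).
#' @param target_ks planted synonymous divergence, substitutions per
#'   synonymous site (>= 0).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param id alignment identifier.
#' @param code_table genetic code id, see [ng86_pair()].
#' @return a [pair_alignment()].
#' @examples
#' aln <- simulate_codon_pair(200, target_dnds = 0.1, target_ks = 0.4, seed = 1)
#' ng86_pair(aln$seq_a, aln$seq_b)
#' @export
simulate_codon_pair <- function(codons, target_dnds, target_ks, seed,
                                id = "sim_pair", code_table = "11") {
  stopifnot(codons >= 1, target_dnds >= 0, target_ks >= 0)
  if (exp(-4 / 3 * target_ks) < .Machine$double.eps) {
    warning("target_ks = ", target_ks, " is beyond the resolvable range of ",
            "the Jukes-Cantor correction; generating a saturated alignment")
  }
  tabs <- .ng86_tables(code_table)
  sense <- tabs$codons[!tabs$is_stop]
  # invert the JC correction: expected proportion of differing sites per class
  ps <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  pn <- 0.75 * (1 - exp(-4 / 3 * target_dnds * target_ks))

  withr::with_seed(seed, {
    anc <- sample(sense, codons, replace = TRUE)
    cods_b <- anc
    f <- tabs$syn_frac[anc, , drop = FALSE]          # codons x 3
    has_non <- matrix(
      lengths(tabs$non_alts[anc, , drop = FALSE]) > 0L, nrow = codons)
    p_syn <- ps * f
    p_non <- pn * (1 - f) * has_non
    u <- matrix(stats::runif(3L * codons), nrow = codons)
    ev_syn <- u < p_syn
    ev_non <- !ev_syn & u < p_syn + p_non

    mutate_codon <- function(cod, syn_pos, non_pos) {
      # events are defined relative to the ancestor codon; retry the whole
      # codon if the combination lands on a stop
      for (attempt in 1:20) {
        out <- cod
        for (p in syn_pos) {
          alt <- tabs$syn_alts[[cod, p]]
          substr(out, p, p) <- alt[sample.int(length(alt), 1L)]
        }
        for (p in non_pos) {
          alt <- tabs$non_alts[[cod, p]]
          substr(out, p, p) <- alt[sample.int(length(alt), 1L)]
        }
        if (!tabs$is_stop[out]) return(out)
      }
      cod
    }
    touched <- which(rowSums(ev_syn | ev_non) > 0L)
    for (i in touched) {
      cods_b[i] <- mutate_codon(anc[i], which(ev_syn[i, ]), which(ev_non[i, ]))
    }
    pair_alignment(id, paste(anc, collapse = ""),
                   paste(cods_b, collapse = ""))
  })
}

#' Specification for a simulated ortholog panel
#'
#' @param n_genes,codons_per_gene panel size; every gene has the same length.
#' @param categories data frame with columns `label`, `go_terms` (list column
#'   of character vectors), `dnds`, `ks`, and `n_genes` (genes per category;
#'   must sum to `n_genes`).
#' @param seed integer seed.
#' @return an object of class `sim_panel_spec`.
#' @export
sim_panel_spec <- function(n_genes, codons_per_gene, categories, seed) {
  stopifnot(n_genes >= 1, codons_per_gene >= 1,
            is.data.frame(categories),
            all(c("label", "go_terms", "dnds", "ks", "n_genes") %in%
                  names(categories)))
  if (sum(categories$n_genes) != n_genes) {
    stop("category gene counts must sum to n_genes", call. = FALSE)
  }
  if (any(categories$dnds < 0) || any(categories$ks < 0)) {
    stop("target dnds and ks must be nonnegative", call. = FALSE)
  }
  structure(list(n_genes = n_genes, codons_per_gene = codons_per_gene,
                 categories = categories, seed = seed),
            class = "sim_panel_spec")
}

#' Simulate a panel of codon-aligned ortholog pairs
#'
#' One pairwise alignment per gene; every gene belongs to exactly one category
#' and carries that category's GO terms. The planted parameters are recorded in
#' a truth table.
#'
#' @param spec a [sim_panel_spec()].
#' @return an object of class `sim_panel`: list with `alignments` (named list
#'   of [pair_alignment()]), `annotations` (named list of GO term character
#'   vectors), and `truth` (data frame `gene_id`, `category`, `true_dnds`,
#'   `true_ks`).
#' @export
simulate_ortholog_panel <- function(spec) {
  stopifnot(inherits(spec, "sim_panel_spec"))
  cat_idx <- rep(seq_len(nrow(spec$categories)), spec$categories$n_genes)
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  gene_seeds <- withr::with_seed(spec$seed,
                                 sample.int(.Machine$integer.max - 1L,
                                            spec$n_genes))
  alignments <- vector("list", spec$n_genes)
  names(alignments) <- gene_ids
  annotations <- vector("list", spec$n_genes)
  names(annotations) <- gene_ids
  for (i in seq_len(spec$n_genes)) {
    ci <- cat_idx[i]
    alignments[[i]] <- simulate_codon_pair(
      spec$codons_per_gene,
      target_dnds = spec$categories$dnds[ci],
      target_ks = spec$categories$ks[ci],
      seed = gene_seeds[i], id = gene_ids[i])
    annotations[[i]] <- spec$categories$go_terms[[ci]]
  }
  truth <- data.frame(gene_id = gene_ids,
                      category = spec$categories$label[cat_idx],
                      true_dnds = spec$categories$dnds[cat_idx],
                      true_ks = spec$categories$ks[cat_idx])
  structure(list(alignments = alignments, annotations = annotations,
                 truth = truth),
            class = "sim_panel")
}

#' Simulate a rooted GO-style DAG
#'
#' Builds an acyclic is_a graph with a single root; every non-root term gets
#' one or two parents drawn from terms of smaller depth, capped at `max_depth`.
#'
#' @param n_terms number of terms (>= 1), including the root.
#' @param max_depth maximum distance from the root.
#' @param seed integer seed.
#' @return a `go_dag` object, see [load_obo()].
#' @export
simulate_go_universe <- function(n_terms, max_depth = 4, seed = 1) {
  stopifnot(n_terms >= 1, max_depth >= 1)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  depth <- integer(n_terms)
  withr::with_seed(seed, {
    for (i in seq_len(n_terms)[-1]) {
      cand <- which(depth[seq_len(i - 1L)] < max_depth)
      k <- min(length(cand), sample(1:2, 1L))
      par <- cand[sample.int(length(cand), k)]
      parents[[i]] <- ids[par]
      depth[i] <- max(depth[par]) + 1L
    }
  })
  terms <- data.frame(
    id = ids,
    name = c("biological_process",
             sprintf("simulated term %d", seq_len(n_terms))[-1]),
    namespace = "biological_process")
  new_go_dag(terms, parents, alt = character(0))
}

#' Simulate a sample-by-taxon abundance matrix with one planted association
#'
#' Taxon columns are independent lognormal abundances; a symbiont column is
#' appended as `corr_strength * host + (1 - corr_strength) * noise_sd *
#' sd(host) * e`, with standard-normal `e`, floored at zero. `corr_strength = 1`
#' with zero noise reproduces the host column exactly (Spearman rho = 1);
#' `corr_strength = 0` yields pure noise.
#'
#' @param n_samples number of samples (>= 3).
#' @param n_taxa number of taxon columns before the symbiont is appended.
#' @param host_index 1-based index of the planted host column.
#' @param corr_strength association strength in \[0, 1\].
#' @param noise_sd noise scale, relative to the host column's standard
#'   deviation.
#' @param seed integer seed.
#' @return an [abundance_matrix()] whose last column is `symbiont_16S`; the
#'   planted host column name is stored in `attr(, "host_column")`.
#' @export
simulate_community_matrix <- function(n_samples, n_taxa, host_index = 1,
                                      corr_strength = 0.8, noise_sd = 1,
                                      seed = 1) {
  stopifnot(n_samples >= 3, n_taxa >= 1,
            host_index >= 1, host_index <= n_taxa,
            corr_strength >= 0, corr_strength <= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    vals <- matrix(stats::rlnorm(n_samples * n_taxa, meanlog = 1, sdlog = 1),
                   nrow = n_samples)
    host <- vals[, host_index]
    noise <- stats::rnorm(n_samples)
    symb <- corr_strength * host +
      (1 - corr_strength) * noise_sd * stats::sd(host) * noise
    symb <- pmax(symb, 0)
    vals <- cbind(vals, symb)
    read_totals <- round(stats::runif(n_samples, 5e5, 5e6))
  })
  colnames(vals) <- c(sprintf("taxon_%02d", seq_len(n_taxa)), "symbiont_16S")
  rownames(vals) <- sprintf("sample_%02d", seq_len(n_samples))
  am <- abundance_matrix(vals, read_totals = stats::setNames(
    read_totals, rownames(vals)))
  attr(am, "host_column") <- colnames(vals)[host_index]
  am
}

#' Simulate a contig mixture of symbiont targets and background
#'
#' GC fractions are normal draws clipped to \[0, 1\], coverages are normal
#' draws truncated below at a small positive value, and lengths are log-uniform
#' on \[500, 60000\] bp. The true class of every contig is recorded.
#'
#' @param n_target,n_background contig counts per class (>= 0).
#' @param target_gc,background_gc length-2 numeric `(mean, sd)` of GC fraction.
#' @param target_cov,background_cov length-2 numeric `(mean, sd)` of
#'   fold-coverage.
#' @param seed integer seed.
#' @return data frame with `contig_id`, `length`, `gc`, `mean_coverage`,
#'   `true_label` ("target"/"background").
#' @export
simulate_contig_set <- function(n_target, n_background,
                                target_gc = c(0.33, 0.02),
                                background_gc = c(0.55, 0.03),
                                target_cov = c(16, 3),
                                background_cov = c(60, 15),
                                seed = 1) {
  stopifnot(n_target >= 0, n_background >= 0,
            target_gc[2] >= 0, background_gc[2] >= 0,
            target_cov[2] >= 0, background_cov[2] >= 0)
  n <- n_target + n_background
  lab <- rep(c("target", "background"), c(n_target, n_background))
  withr::with_seed(seed, {
    gc <- c(stats::rnorm(n_target, target_gc[1], target_gc[2]),
            stats::rnorm(n_background, background_gc[1], background_gc[2]))
    cov <- c(stats::rnorm(n_target, target_cov[1], target_cov[2]),
             stats::rnorm(n_background, background_cov[1], background_cov[2]))
    len <- round(exp(stats::runif(n, log(500), log(60000))))
  })
  data.frame(contig_id = sprintf("contig_%04d", seq_len(n)),
             length = as.integer(len),
             gc = pmin(pmax(gc, 0), 1),
             mean_coverage = pmax(cov, 0.01),
             true_label = lab)
}
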