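# Coverage conversion, read-count normalization, Spearman midrank correlation,
# and BH-corrected all-pairs association screening.

#' Convert kmer coverage to total read coverage
#'
#' Assemblers report coverage in kmer space; total coverage follows from
#' `C = C_K * R / (R - K + 1)` for kmer length K and read length R.
#'
#' @param c_k kmer coverage (>= 0).
#' @param k kmer length in bp, `1 <= k <= r`.
#' @param r read length in bp.
#' @return total coverage.
#' @examples
#' kmer_to_total_coverage(10, k = 25, r = 150)
#' @export
kmer_to_total_coverage <- function(c_k, k, r) {
  if (any(c_k < 0)) stop("c_k must be nonnegative", call. = FALSE)
  if (any(k < 1) || any(k > r)) {
    stop("kmer length must satisfy 1 <= k <= r", call. = FALSE)
  }
  c_k * r / (r - k + 1)
}

#' Sample-by-taxon abundance matrix
#'
#' @param values numeric matrix, samples as rows and taxa as columns, with
#'   unique column names and no negative entries.
#' @param read_totals optional per-sample total read counts (named by sample or
#'   in row order), required by [normalize_matrix()].
#' @return an object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, read_totals = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("values must have unique column names", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("abundance values must be nonnegative", call. = FALSE)
  }
  if (!is.null(read_totals)) {
    if (length(read_totals) != nrow(values)) {
      stop("read_totals must have one entry per sample", call. = FALSE)
    }
    if (any(is.na(read_totals)) || any(read_totals <= 0)) {
      stop("read_totals must be positive for every sample", call. = FALSE)
    }
  }
  structure(list(values = values, read_totals = read_totals),
            class = "abundance_matrix")
}

#' Normalize an abundance matrix to the total number of reads
#'
#' Divides every value by its sample's total read count and scales by 10^6
#' (coverage per million reads). The scale is cosmetic for rank correlations.
#'
#' @param matrix an [abundance_matrix()] with `read_totals` set.
#' @return a normalized [abundance_matrix()] (with `read_totals` cleared).
#' @export
normalize_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (is.null(matrix$read_totals)) {
    stop("read_totals are required for normalization", call. = FALSE)
  }
  vals <- sweep(matrix$values, 1, matrix$read_totals, "/") * 1e6
  abundance_matrix(vals, read_totals = NULL)
}

#' Spearman correlation on midranks with a t-approximation p-value
#'
#' Pairs with a missing element in either vector are dropped (pairwise-complete
#' deletion). rho is the Pearson correlation of midranks (ties receive their
#' average rank); the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom, with
#' `p = 0` when `|rho| = 1`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_raw`, `n_used`.
#' @examples
#' spearman_midrank(c(1, 2, 2, 4), c(1, 3, 2, 4))
#' @export
spearman_midrank <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) {
    stop("fewer than 3 complete pairs of observations", call. = FALSE)
  }
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("degenerate input: a vector is constant after ranking",
         call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_raw = p, n_used = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] with `method = "BH"` after validating the input
#' range.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' All-pairs Spearman association screen with BH correction
#'
#' Computes [spearman_midrank()] for every pair of columns, applies
#' [bh_adjust()] across all pairwise tests, and reports results with the
#' symbiont-column pairs first, sorted by rho descending. Degenerate columns
#' (constant after ranking) are excluded with a message rather than failing the
#' screen.
#'
#' @param matrix an [abundance_matrix()] (normalize first if desired).
#' @param symbiont_column column id of the symbiont marker.
#' @return data frame with `col_i`, `col_j`, `rho`, `p_raw`, `p_adj`, `n_used`,
#'   and logical `symbiont_pair`; excluded column ids in
#'   `attr(, "excluded_columns")`.
#' @export
association_screen <- function(matrix, symbiont_column) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  vals <- matrix$values
  if (!symbiont_column %in% colnames(vals)) {
    stop("symbiont column '", symbiont_column, "' not found", call. = FALSE)
  }
  if (ncol(vals) < 3) {
    stop("at least 2 columns besides the symbiont are required",
         call. = FALSE)
  }
  degenerate <- colnames(vals)[apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 3 || stats::sd(rank(v, ties.method = "average")) == 0
  })]
  if (length(degenerate) > 0) {
    message("excluding degenerate column(s): ",
            paste(degenerate, collapse = ", "))
    vals <- vals[, setdiff(colnames(vals), degenerate), drop = FALSE]
  }
  cols <- colnames(vals)
  pairs <- utils::combn(cols, 2)
  res <- apply(pairs, 2, function(pr) {
    s <- spearman_midrank(vals[, pr[1]], vals[, pr[2]])
    c(rho = s$rho, p_raw = s$p_raw, n_used = s$n_used)
  })
  out <- data.frame(col_i = pairs[1, ], col_j = pairs[2, ],
                    rho = res["rho", ], p_raw = res["p_raw", ],
                    n_used = as.integer(res["n_used", ]))
  out$p_adj <- bh_adjust(out$p_raw)
  out$symbiont_pair <- out$col_i == symbiont_column |
    out$col_j == symbiont_column
  out <- out[order(-out$symbiont_pair, -out$rho), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_columns") <- degenerate
  out
}
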