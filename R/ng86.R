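# Nei-Gojobori (1986) pairwise Ka/Ks with Jukes-Cantor correction.
#
# Site counts and per-codon-pair difference counts are precomputed once per
# genetic code into lookup tables (cached in .ng86_cache), so window scans
# reduce to table lookups and sums.

.ng86_cache <- new.env(parent = emptyenv())

.ng86_bases <- c("T", "C", "A", "G")

#' @noRd
.ng86_tables <- function(code_table = "11") {
  key <- paste0("code", code_table)
  cached <- get0(key, envir = .ng86_cache)
  if (!is.null(cached)) return(cached)

  gcode <- Biostrings::getGeneticCode(code_table)
  codons <- names(gcode)
  aa <- unname(gcode)
  names(aa) <- codons
  is_stop <- aa == "*"

  mutate1 <- function(codon, pos, base) {
    substr(codon, pos, pos) <- base
    codon
  }

  # Per codon x position: fraction of the three single-nucleotide changes that
  # are synonymous. Changes to stop codons count as nonsynonymous (they stay in
  # the denominator), so S + N = 3 per position.
  syn_frac <- matrix(0, nrow = 64, ncol = 3, dimnames = list(codons, NULL))
  # Alternative bases for the simulator: synonymous and nonsynonymous-non-stop.
  syn_alts <- vector("list", 64L * 3L)
  non_alts <- vector("list", 64L * 3L)
  dim(syn_alts) <- dim(non_alts) <- c(64L, 3L)
  dimnames(syn_alts) <- dimnames(non_alts) <- list(codons, NULL)

  for (cod in codons[!is_stop]) {
    for (pos in 1:3) {
      ref_base <- substr(cod, pos, pos)
      alts <- setdiff(.ng86_bases, ref_base)
      alt_codons <- vapply(alts, mutate1, character(1), codon = cod, pos = pos)
      syn <- !is_stop[alt_codons] & aa[alt_codons] == aa[cod]
      non <- !is_stop[alt_codons] & !syn
      syn_frac[cod, pos] <- sum(syn) / 3
      syn_alts[[cod, pos]] <- alts[syn]
      non_alts[[cod, pos]] <- alts[non]
    }
  }
  syn_sites <- rowSums(syn_frac)

  # Difference counts per codon pair: average over all minimal substitution
  # pathways, excluding pathways that pass through a stop codon. If every
  # pathway is blocked by a stop (possible only for some 3-difference pairs),
  # fall back to averaging over all pathways.
  perms <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  sd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  nd_tab <- matrix(0, 64, 64, dimnames = list(codons, codons))
  sense <- codons[!is_stop]
  for (c1 in sense) {
    for (c2 in sense) {
      if (c1 == c2) next
      pos_diff <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      nd <- length(pos_diff)
      path_s <- path_n <- numeric(0)
      blocked_s <- blocked_n <- numeric(0)
      for (ord in perms[[nd]]) {
        cur <- c1
        s <- n <- 0
        blocked <- FALSE
        for (p in pos_diff[ord]) {
          nxt <- mutate1(cur, p, substr(c2, p, p))
          if (is_stop[nxt]) blocked <- TRUE
          if (!is_stop[nxt] && !is_stop[cur] && aa[nxt] == aa[cur]) {
            s <- s + 1
          } else {
            n <- n + 1
          }
          cur <- nxt
        }
        if (blocked) {
          blocked_s <- c(blocked_s, s); blocked_n <- c(blocked_n, n)
        } else {
          path_s <- c(path_s, s); path_n <- c(path_n, n)
        }
      }
      if (length(path_s) == 0L) {
        path_s <- blocked_s; path_n <- blocked_n
      }
      sd_tab[c1, c2] <- mean(path_s)
      nd_tab[c1, c2] <- mean(path_n)
    }
  }

  tabs <- list(codons = codons, aa = aa, is_stop = is_stop,
               syn_frac = syn_frac, syn_sites = syn_sites,
               syn_alts = syn_alts, non_alts = non_alts,
               sd = sd_tab, nd = nd_tab)
  assign(key, tabs, envir = .ng86_cache)
  tabs
}

#' @noRd
.split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' @noRd
.check_codon_seq <- function(seq, label, tabs) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) {
    stop(label, " contains characters other than A/C/G/T; remove gaps and ",
         "ambiguities before estimation", call. = FALSE)
  }
  cods <- .split_codons(seq)
  stops <- which(tabs$is_stop[cods])
  if (length(stops) > 0L) {
    stop(label, " contains a stop codon at codon index ", stops[1L],
         call. = FALSE)
  }
  cods
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p proportion of observed differences per site.
#' @return corrected distance, or `NA` where `(4/3) * p >= 1` (saturation).
#' @noRd
.jukes_cantor <- function(p) {
  ifelse(4 / 3 * p >= 1, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Estimates nonsynonymous and synonymous substitution rates for a pair of
#' gap-free, in-frame codon sequences. Synonymous site fractions are counted
#' per codon position (changes to stop codons count as nonsynonymous) and
#' averaged over the two sequences; observed differences are resolved by
#' averaging over all minimal substitution pathways with equal weights,
#' excluding pathways that pass through a stop codon. Proportions are corrected
#' for multiple hits with the Jukes-Cantor formula
#' \eqn{d = -3/4 \log(1 - 4p/3)}, undefined (`NA`) at saturation.
#'
#' @param seq_a,seq_b nucleotide strings of equal length divisible by 3, with
#'   no gaps, ambiguities, or stop codons.
#' @param code_table NCBI genetic code id passed to
#'   [Biostrings::getGeneticCode()]; `"11"` (bacterial) by default. Tables 1
#'   and 11 translate all sense codons identically.
#' @return a list with elements `ka`, `ks`, `ratio` (`ka/ks`, `NA` if `ks` is
#'   zero or either correction is undefined), `s_sites`, `n_sites` (site
#'   counts; they sum to the sequence length), and `sd`, `nd` (synonymous and
#'   nonsynonymous difference counts).
#' @examples
#' ng86_pair("TTTGGGAAA", "TTTGGGAAG")
#' @export
ng86_pair <- function(seq_a, seq_b, code_table = "11") {
  if (!is.character(seq_a) || !is.character(seq_b) ||
      length(seq_a) != 1L || length(seq_b) != 1L) {
    stop("seq_a and seq_b must be single strings", call. = FALSE)
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences differ in length (", nchar(seq_a), " vs ", nchar(seq_b),
         ")", call. = FALSE)
  }
  if (nchar(seq_a) == 0L || nchar(seq_a) %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3, got ",
         nchar(seq_a), call. = FALSE)
  }
  tabs <- .ng86_tables(code_table)
  cods_a <- .check_codon_seq(seq_a, "seq_a", tabs)
  cods_b <- .check_codon_seq(seq_b, "seq_b", tabs)

  s_sites <- (sum(tabs$syn_sites[cods_a]) + sum(tabs$syn_sites[cods_b])) / 2
  n_sites <- 3 * length(cods_a) - s_sites
  sd <- sum(tabs$sd[cbind(cods_a, cods_b)])
  nd <- sum(tabs$nd[cbind(cods_a, cods_b)])

  ks <- if (s_sites > 0) .jukes_cantor(sd / s_sites) else NA_real_
  ka <- if (n_sites > 0) .jukes_cantor(nd / n_sites) else NA_real_
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks

  list(ka = ka, ks = ks, ratio = ratio,
       s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd)
}
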