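# Independent oracles, deliberately written as naive direct translations of
# the definitions (recursive pathway enumeration, explicit log-factorial
# sums) so they share no code with the package implementation.

.oracle_code <- Biostrings::getGeneticCode("11")

oracle_syn_sites <- function(codon) {
  gc <- .oracle_code
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# exhaustive pathway enumeration between two sense codons; returns all
# complete pathways as rows (syn steps, nonsyn steps, passes through stop)
oracle_pathways <- function(c1, c2) {
  gc <- .oracle_code
  recurse <- function(cur, stepped_stop) {
    if (cur == c2) {
      return(list(c(s = 0, n = 0, blocked = as.numeric(stepped_stop))))
    }
    out <- list()
    for (pos in 1:3) {
      if (substr(cur, pos, pos) != substr(c2, pos, pos)) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        syn <- gc[[nxt]] != "*" && gc[[cur]] != "*" && gc[[nxt]] == gc[[cur]]
        tails <- recurse(nxt, stepped_stop || gc[[nxt]] == "*")
        for (tl in tails) {
          out[[length(out) + 1]] <-
            c(s = unname(tl["s"]) + syn, n = unname(tl["n"]) + !syn,
              blocked = unname(tl["blocked"]))
        }
      }
    }
    out
  }
  do.call(rbind, recurse(c1, FALSE))
}

# full naive NG86 on two codon-string vectors
oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split3(toupper(seq_a))
  cb <- split3(toupper(seq_b))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sd_tot <- nd_tot <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    paths <- oracle_pathways(ca[i], cb[i])
    ok <- paths[, "blocked"] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(paths))
    sd_tot <- sd_tot + mean(paths[ok, "s"])
    nd_tot <- nd_tot + mean(paths[ok, "n"])
  }
  jc <- function(p) if (4 / 3 * p >= 1) NA_real_ else -0.75 * log(1 - 4 / 3 * p)
  list(s_sites = S, n_sites = N, sd = sd_tot, nd = nd_tot,
       ks = if (S > 0) jc(sd_tot / S) else NA_real_,
       ka = if (N > 0) jc(nd_tot / N) else NA_real_)
}

sense_codons <- function() {
  names(.oracle_code)[.oracle_code != "*"]
}

# hypergeometric upper tail by explicit log-factorial summation
oracle_fisher_tail <- function(sc, st, uc, ut) {
  lf <- function(x) lgamma(x + 1)
  lch <- function(n, k) lf(n) - lf(k) - lf(n - k)
  ks <- seq.int(sc, min(st, uc))
  if (length(ks) == 0) return(0)
  sum(exp(lch(uc, ks) + lch(ut - uc, st - ks) - lch(ut, st)))
}

# a small hand-checkable OBO file: one root, a diamond, a leaf, one obsolete
write_fixture_obo <- function(path) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: branch A1",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: branch A2",
    "namespace: biological_process", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000004", "name: diamond child B",
    "namespace: biological_process", "alt_id: GO:0000099",
    "is_a: GO:0000002", "is_a: GO:0000003", "",
    "[Term]", "id: GO:0000005", "name: leaf under B",
    "namespace: biological_process", "is_a: GO:0000004", "",
    "[Term]", "id: GO:0000006", "name: gone",
    "namespace: biological_process", "is_a: GO:0000001",
    "is_obsolete: true"), path)
  path
}
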