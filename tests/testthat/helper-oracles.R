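# Independent brute-force oracle: enumerate every gamete of each parent by
# picking one allele per locus (unlinked loci, each choice probability 1/2),
# pair all gametes, and tally offspring genotype strings. Written without
# touching the enumeration code it checks.
brute_force_cross <- function(mother, father) {
  loci <- sort(names(mother))
  gametes <- function(parent) {
    picks <- expand.grid(rep(list(1:2), length(loci)))
    out <- list()
    for (i in seq_len(nrow(picks))) {
      hap <- vapply(seq_along(loci), function(j) parent[[loci[j]]][picks[i, j]], "")
      names(hap) <- loci
      key <- paste(hap, collapse = ";")
      out[[key]] <- list(hap = hap,
                         prob = (out[[key]]$prob %||% 0) + 0.5^length(loci))
    }
    out
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  gm <- gametes(mother); gf <- gametes(father)
  acc <- list()
  for (a in gm) for (b in gf) {
    dips <- lapply(loci, function(l) c(a$hap[[l]], b$hap[[l]]))
    names(dips) <- loci
    key <- format_genotype(do.call(genotype, dips))
    acc[[key]] <- (acc[[key]] %||% 0) + a$prob * b$prob
  }
  data.frame(genotype = names(acc), prob = unlist(acc), row.names = NULL,
             stringsAsFactors = FALSE)
}

# random multilocus genotype over k loci with up to 4 alleles per locus
random_parent <- function(k, alleles = c("pet", "fav", "mel.a1", "mel.a2")) {
  dips <- lapply(seq_len(k), function(i) sample(alleles, 2, replace = TRUE))
  names(dips) <- paste0("L", seq_len(k))
  do.call(genotype, dips)
}

# collapse a genotype distribution to unordered diplotypes (phase dropped)
collapse_phase <- function(dist) {
  key <- vapply(dist$genotype, function(s) {
    g <- parse_genotype(s)
    paste(vapply(sort(names(g)), function(l)
      paste0(l, ":", paste(sort(g[[l]]), collapse = "/")), ""), collapse = ";")
  }, "")
  agg <- rowsum(dist$prob, key)
  data.frame(genotype = rownames(agg), prob = as.numeric(agg))
}

erato_refs <- function(tab = diagnostic_snps()) {
  c(LRR = synthetic_reference("LRR", tab),
    ReqQ = synthetic_reference("ReqQ", tab),
    Mat = synthetic_reference("Mat", tab))
}

race_truth <- function(brood, locus) {
  vapply(as.data.frame(brood)$genotype, function(s) {
    d <- parse_genotype(s)[[locus]]
    r <- allele_race(d)
    if (r[1] != r[2]) "hybrid" else paste0("pure_", r[1])
  }, "", USE.NAMES = FALSE)
}
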