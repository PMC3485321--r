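#' @title Race-labelled, phase-aware genotypes and Mendelian enumeration
#'
#' @description
#' Alleles are plain strings carrying a race-of-origin tag and an optional
#' sub-allele tag separated by a dot, e.g. `"pet"`, `"fav"`, `"mel.a1"`.
#' A diplotype is an *ordered* pair `(maternal, paternal)`; the order is never
#' silently swapped, so the parental origin of every allele in a brood is
#' traceable. A multilocus genotype maps locus names to diplotypes.
#'
#' @name genetics
NULL

#' Race tag of an allele label
#' @param allele character vector of allele labels such as `"mel.a1"`.
#' @return the race component (text before the first dot).
#' @export
allele_race <- function(allele) sub("\\..*$", "", allele)

#' Define a locus
#'
#' @param name locus identifier, e.g. `"Cr"`, `"Sd"`, `"Yb"`.
#' @param alleles character vector of allowed allele labels (race tag plus
#'   optional `.sub` tag).
#' @param linkage_group identifier; loci sharing a group are linked. Defaults
#'   to the locus name (i.e. unlinked to everything else).
#' @param aliases alternative names accepted in input files (the Sd locus is
#'   also written "Sb" in some sources).
#' @return an object of class `locus_def`.
#' @export
locus_def <- function(name, alleles, linkage_group = name, aliases = character()) {
  stopifnot(is.character(name), nchar(name) > 0, length(alleles) >= 1)
  structure(list(name = name, alleles = alleles,
                 linkage_group = linkage_group, aliases = aliases),
            class = "locus_def")
}

#' Construct a multilocus genotype
#'
#' @param ... named length-2 character vectors, one per locus, in
#'   `(maternal, paternal)` order, e.g. `Cr = c("pet", "fav")`.
#' @return an object of class `multilocus_genotype` (named list of ordered
#'   allele pairs).
#' @examples
#' g <- genotype(Cr = c("pet", "fav"), Sd = c("fav", "fav"))
#' format_genotype(g)  # "Cr:pet/fav;Sd:fav/fav"
#' @export
genotype <- function(...) {
  dips <- list(...)
  if (length(dips) == 0 || is.null(names(dips)) || any(names(dips) == "")) {
    stop("genotype() needs named per-locus allele pairs", call. = FALSE)
  }
  ok <- vapply(dips, function(d) is.character(d) && length(d) == 2L, logical(1))
  if (!all(ok)) stop("each diplotype must be 2 allele labels", call. = FALSE)
  if (anyDuplicated(names(dips))) stop("duplicate locus in genotype", call. = FALSE)
  structure(dips[order(names(dips))], class = "multilocus_genotype")
}

#' Serialise a genotype as a string
#'
#' Canonical form `"Cr:pet/fav;Sd:fav/fav"` with loci sorted by name and the
#' maternal allele written first.
#' @param g a `multilocus_genotype`.
#' @return character scalar.
#' @export
format_genotype <- function(g) {
  g <- g[order(names(g))]
  paste(vapply(names(g), function(l) sprintf("%s:%s/%s", l, g[[l]][1], g[[l]][2]),
               ""), collapse = ";")
}

#' Parse a genotype string
#'
#' @param s string in the form produced by [format_genotype()].
#' @param aliases optional named character vector mapping alternative locus
#'   names to canonical ones (e.g. `c(Sb = "Sd")`).
#' @return a `multilocus_genotype`.
#' @export
parse_genotype <- function(s, aliases = c(Sb = "Sd")) {
  stopifnot(is.character(s), length(s) == 1L)
  if (is.na(s) || !nzchar(s)) return(NULL)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  dips <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^([^:]+):([^/]+)/(.+)$", p))[[1]]
    if (length(m) != 4) stop("malformed genotype field: '", p, "'", call. = FALSE)
    loc <- m[2]
    if (loc %in% names(aliases)) loc <- aliases[[loc]]
    dips[[loc]] <- c(m[3], m[4])
  }
  do.call(genotype, dips)
}

#' Is a genotype hybrid at a locus?
#'
#' Hybrid means the two alleles carry different race tags (sub-allele tags are
#' ignored), matching the usage "one allele of each race".
#' @param g a `multilocus_genotype`.
#' @param locus locus name.
#' @return logical.
#' @export
is_hybrid <- function(g, locus) {
  d <- g[[locus]]
  if (is.null(d)) stop("locus '", locus, "' not in genotype", call. = FALSE)
  allele_race(d[1]) != allele_race(d[2])
}

#' Is a genotype race-homozygous at a locus?
#' @inheritParams is_hybrid
#' @return logical: both alleles carry the same race tag.
#' @export
is_homozygous <- function(g, locus) !is_hybrid(g, locus)

#' Specify a two-parent cross
#'
#' @param mother,father `multilocus_genotype` objects covering the same loci.
#' @param cross_id identifier for the brood, e.g. `"L15"`.
#' @param mother_race,father_race race labels of the parents (used by
#'   direction-dependent sterility rules).
#' @return an object of class `cross_spec`.
#' @export
cross_spec <- function(mother, father, cross_id,
                       mother_race = NA_character_, father_race = NA_character_) {
  if (!setequal(names(mother), names(father))) {
    stop("mother and father must cover the same loci (mother: ",
         paste(names(mother), collapse = ","), "; father: ",
         paste(names(father), collapse = ","), ")", call. = FALSE)
  }
  structure(list(mother = mother, father = father, cross_id = cross_id,
                 mother_race = mother_race, father_race = father_race),
            class = "cross_spec")
}

#' Pairwise recombination map
#'
#' Loci sharing a `linkage_group` recombine at the fraction given in `r`
#' (default 0, i.e. a marker collapsed onto the patterning locus it tags);
#' loci on different groups assort independently (r = 0.5). Within a group,
#' loci are ordered as listed and recombination is applied between adjacent
#' pairs with no interference.
#'
#' @param linkage_groups named character vector: locus name -> group id.
#' @param r optional data.frame with columns `locus1`, `locus2`, `r`
#'   (0 <= r <= 0.5) overriding the within-group default of 0.
#' @return an object of class `recomb_map`.
#' @export
recomb_map <- function(linkage_groups, r = NULL) {
  stopifnot(is.character(linkage_groups), !is.null(names(linkage_groups)))
  if (!is.null(r)) {
    stopifnot(is.data.frame(r), all(c("locus1", "locus2", "r") %in% names(r)))
    if (any(r$r < 0 | r$r > 0.5)) stop("recombination fractions must lie in [0, 0.5]",
                                       call. = FALSE)
  }
  structure(list(linkage_groups = linkage_groups, r = r), class = "recomb_map")
}

#' Default map: every locus on its own linkage group
#' @param loci character vector of locus names (or a `cross_spec`).
#' @return a `recomb_map` with all loci unlinked.
#' @export
default_recomb_map <- function(loci) {
  if (inherits(loci, "cross_spec")) loci <- names(loci$mother)
  recomb_map(stats::setNames(loci, loci))
}

r_between <- function(map, l1, l2) {
  g <- map$linkage_groups
  if (g[[l1]] != g[[l2]]) return(0.5)
  if (!is.null(map$r)) {
    hit <- (map$r$locus1 == l1 & map$r$locus2 == l2) |
      (map$r$locus1 == l2 & map$r$locus2 == l1)
    if (any(hit)) return(map$r$r[which(hit)[1]])
  }
  0 # linked loci are completely linked unless told otherwise
}

#' Enumerate gametes of a parent
#'
#' Exact enumeration of the haplotypes a parent transmits, with
#' probabilities. Within each linkage group the parental-origin chain is
#' enumerated with recombination between adjacent loci; groups combine
#' independently. All probabilities in the supported designs are dyadic
#' rationals, represented exactly in doubles.
#'
#' @param parent a `multilocus_genotype`.
#' @param map a `recomb_map` covering all parent loci.
#' @return data.frame with one column per locus (transmitted allele) plus
#'   `prob`; probabilities sum to 1.
#' @examples
#' f1 <- genotype(Cr = c("pet", "fav"), Sd = c("pet", "fav"))
#' enumerate_gametes(f1, default_recomb_map(c("Cr", "Sd")))
#' @export
enumerate_gametes <- function(parent, map) {
  loci <- names(parent)
  unknown <- setdiff(loci, names(map$linkage_groups))
  if (length(unknown) > 0) {
    stop("loci missing from recombination map: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # order loci as in the map, grouped by linkage group
  ord <- intersect(names(map$linkage_groups), loci)
  groups <- split(ord, map$linkage_groups[ord])

  group_tables <- lapply(groups, function(gl) {
    k <- length(gl)
    origins <- as.matrix(expand.grid(rep(list(1:2), k)))
    probs <- apply(origins, 1, function(o) {
      p <- 0.5
      if (k > 1) for (i in 2:k) {
        r <- r_between(map, gl[i - 1], gl[i])
        p <- p * if (o[i] == o[i - 1]) 1 - r else r
      }
      p
    })
    alleles <- matrix("", nrow(origins), k, dimnames = list(NULL, gl))
    for (j in seq_len(k)) alleles[, j] <- parent[[gl[j]]][origins[, j]]
    df <- as.data.frame(alleles, stringsAsFactors = FALSE)
    df$prob <- probs
    df
  })

  out <- Reduce(function(a, b) {
    m <- merge(a, b, by = NULL) # cartesian product
    m$prob <- m$prob.x * m$prob.y
    m$prob.x <- m$prob.y <- NULL
    m
  }, group_tables)

  # aggregate duplicate haplotypes (homozygous loci)
  key <- do.call(paste, c(out[loci], sep = "\r"))
  agg <- rowsum(out$prob, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  res <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(res) <- loci
  res$prob <- as.numeric(agg)
  res <- res[res$prob > 0, , drop = FALSE]
  rownames(res) <- NULL
  res[order(do.call(paste, res[loci])), , drop = FALSE]
}

#' Exact offspring genotype distribution of a cross
#'
#' Product of the parental gamete distributions; offspring diplotypes store
#' the maternal allele first.
#'
#' @param cross a `cross_spec`.
#' @param map a `recomb_map`; defaults to all loci unlinked.
#' @return object of class `genotype_distribution`: data.frame with columns
#'   `genotype` (canonical string, see [format_genotype()]) and `prob`.
#' @examples
#' bc <- cross_spec(genotype(Cr = c("pet", "pet")), genotype(Cr = c("pet", "fav")),
#'                  "testcross")
#' cross_distribution(bc)
#' @export
cross_distribution <- function(cross, map = default_recomb_map(cross)) {
  gm <- enumerate_gametes(cross$mother, map)
  gf <- enumerate_gametes(cross$father, map)
  loci <- sort(names(cross$mother))
  rows <- vector("list", nrow(gm) * nrow(gf))
  idx <- 1L
  for (i in seq_len(nrow(gm))) {
    for (j in seq_len(nrow(gf))) {
      dips <- lapply(loci, function(l) c(gm[[l]][i], gf[[l]][j]))
      names(dips) <- loci
      rows[[idx]] <- data.frame(
        genotype = format_genotype(structure(dips, class = "multilocus_genotype")),
        prob = gm$prob[i] * gf$prob[j], stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  out <- do.call(rbind, rows)
  agg <- rowsum(out$prob, out$genotype)
  res <- data.frame(genotype = rownames(agg), prob = as.numeric(agg),
                    stringsAsFactors = FALSE)
  res <- res[order(res$genotype), , drop = FALSE]
  rownames(res) <- NULL
  total <- sum(res$prob)
  if (abs(total - 1) > 1e-12) stop("internal: probabilities sum to ", total)
  structure(res, class = c("genotype_distribution", "data.frame"),
            loci = loci, cross_id = cross$cross_id)
}
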