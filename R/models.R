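#' Phenotype classes
#'
#' The four mutually exclusive hindwing phenotype classes used throughout:
#' `YELLOW_BAR` (full sharp yellow bar), `FUZZY_BAR` (F1-like broken bar with
#' melanic scales invading the proximal bar), `BLACK_HINDWING` (almost no
#' yellow scales), and `SHADOW_BAR` (melanic shadow with altered reflectance
#' but no yellow pigment; the H. melpomene heterozygote). Pigmented melpomene
#' bars additionally carry a `fuzzy`/`full` sub-variant tag kept separate from
#' the class.
#' @export
PHENOTYPE_CLASSES <- c("YELLOW_BAR", "FUZZY_BAR", "BLACK_HINDWING", "SHADOW_BAR")

#' Construct a genotype-to-phenotype architecture model
#'
#' A model is an ordered rule list; the first rule whose predicate matches a
#' genotype determines its phenotype-class distribution (first-match-wins with
#' an explicit catch-all, which makes exhaustiveness testable).
#'
#' Each rule is a list with elements:
#' \describe{
#'   \item{when}{named list (locus -> predicate); empty list = catch-all.
#'     Predicates: the strings `"hybrid"` / `"hom_same_race"` / `"any"`, or a
#'     one-element list such as `list(hom_race = "fav")`,
#'     `list(both_in = c("ros", "ama"))`, `list(any_in = ...)`,
#'     `list(none_in = ...)`.}
#'   \item{then}{named vector of class probabilities; values may be numbers or
#'     strings referencing model parameters (e.g. `"p_black"`,
#'     `"1 - p_black"`).}
#'   \item{subvariant}{optional named probability vector drawn independently
#'     of the class (e.g. the fuzzy/full 0.5/0.5 split of pigmented melpomene
#'     bars).}
#' }
#'
#' @param name model identifier.
#' @param loci character vector of locus names the model reads.
#' @param rules list of rules as described above.
#' @param params named list of model parameters referenced by rules.
#' @param free_parameter_count integer; used as a parsimony tie-break when
#'   ranking models.
#' @param observed optional list of `when`-style predicate sets describing the
#'   genotype combinations actually observed in the crosses the model was
#'   inferred from; predictions outside them are flagged "extrapolated".
#' @param description free-text note.
#' @return object of class `architecture_model`.
#' @seealso [builtin_model()] for the shipped models.
#' @export
architecture_model <- function(name, loci, rules, params = list(),
                               free_parameter_count = 0L, observed = NULL,
                               description = "") {
  stopifnot(is.character(name), is.character(loci), length(rules) >= 1)
  structure(list(name = name, loci = loci, rules = rules, params = params,
                 free_parameter_count = as.integer(free_parameter_count),
                 observed = observed, description = description),
            class = "architecture_model")
}

match_predicate <- function(g, locus, pred) {
  d <- g[[locus]]
  races <- allele_race(d)
  if (is.character(pred) && length(pred) == 1L) {
    return(switch(pred,
      any = TRUE,
      hybrid = races[1] != races[2],
      hom_same_race = races[1] == races[2],
      stop("unknown predicate '", pred, "' for locus ", locus, call. = FALSE)))
  }
  if (is.list(pred) && length(pred) == 1L) {
    val <- pred[[1]]
    return(switch(names(pred),
      hom_race = all(races == val),
      both_in = all(d %in% val),
      any_in = any(d %in% val),
      none_in = !any(d %in% val),
      allele_pair = setequal(sort(d), sort(val)) && length(val) == 2L,
      stop("unknown predicate type '", names(pred), "'", call. = FALSE)))
  }
  stop("malformed predicate for locus ", locus, call. = FALSE)
}

rule_matches <- function(g, when) {
  if (length(when) == 0) return(TRUE)
  missing <- setdiff(names(when), names(g))
  if (length(missing) > 0) {
    stop("genotype missing loci required by rule: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  all(vapply(names(when), function(l) match_predicate(g, l, when[[l]]), logical(1)))
}

resolve_probs <- function(then, params) {
  env <- list2env(params, parent = baseenv())
  p <- vapply(then, function(v) {
    if (is.numeric(v)) v else eval(parse(text = v), envir = env)
  }, numeric(1))
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-9) {
    stop("rule probabilities must be non-negative and sum to 1", call. = FALSE)
  }
  p[p > 0]
}

#' Predict the phenotype-class distribution of a genotype
#'
#' @param g a `multilocus_genotype` covering all model loci.
#' @param model an `architecture_model`.
#' @return named numeric vector of class probabilities (a point mass unless a
#'   stochastic rule applies). The matched rule's `subvariant` distribution,
#'   if any, is attached as attribute `"subvariant"`.
#' @examples
#' m <- builtin_model("ERATO_UNIFIED")
#' predict_phenotype(genotype(Cr = c("pet", "fav"), Sd = c("pet", "fav")), m)
#' @export
predict_phenotype <- function(g, model) {
  missing <- setdiff(model$loci, names(g))
  if (length(missing) > 0) {
    stop("genotype missing model loci: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (rule in model$rules) {
    if (rule_matches(g, rule$when)) {
      p <- resolve_probs(rule$then, model$params)
      attr(p, "subvariant") <- rule$subvariant
      return(p)
    }
  }
  stop("no rule of model '", model$name, "' matches genotype ",
       format_genotype(g), call. = FALSE)
}

#' Flag genotypes outside the model's observational support
#'
#' Built-in models record which genotype combinations were actually observed
#' in the crosses they were inferred from; predictions for other combinations
#' are extrapolations and are flagged as such in reports.
#' @inheritParams predict_phenotype
#' @return logical; `NA` when the model records no observational support.
#' @export
is_extrapolated <- function(g, model) {
  if (is.null(model$observed)) return(NA)
  !any(vapply(model$observed, function(w) rule_matches(g, w), logical(1)))
}

#' Expected phenotype-class ratios of a cross under a model
#'
#' Composes [cross_distribution()] with [predict_phenotype()] and
#' marginalises over genotypes.
#' @param cross a `cross_spec`.
#' @param model an `architecture_model`.
#' @param map a `recomb_map` (default: loci unlinked).
#' @return named numeric vector of class probabilities summing to 1.
#' @examples
#' cr <- cross_fixture("L15")
#' expected_phenotype_ratios(cr, builtin_model("ERATO_UNIFIED"))  # 3:1
#' @export
expected_phenotype_ratios <- function(cross, model, map = default_recomb_map(cross)) {
  dist <- cross_distribution(cross, map)
  acc <- stats::setNames(numeric(length(PHENOTYPE_CLASSES)), PHENOTYPE_CLASSES)
  extra <- numeric(0)
  for (i in seq_len(nrow(dist))) {
    g <- parse_genotype(dist$genotype[i])
    p <- predict_phenotype(g, model)
    for (cls in names(p)) {
      if (!cls %in% names(acc)) acc[cls] <- 0
      acc[cls] <- acc[cls] + dist$prob[i] * p[[cls]]
    }
  }
  acc[acc > 0]
}

# ---- model (de)serialisation ------------------------------------------------

#' Read an architecture model from JSON
#' @param path path to a model JSON file (see the packaged files under
#'   `system.file("extdata/models", package = "heliocross")` for the format).
#' @return an `architecture_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(x$rules, function(r) {
    list(when = lapply(r$when, function(p) if (is.list(p)) lapply(p, unlist) else p),
         then = unlist(r$then),
         subvariant = if (!is.null(r$subvariant)) unlist(r$subvariant))
  })
  observed <- if (!is.null(x$observed)) {
    lapply(x$observed, function(w) lapply(w, function(p) if (is.list(p)) lapply(p, unlist) else p))
  }
  architecture_model(name = x$name, loci = unlist(x$loci), rules = rules,
                     params = if (is.null(x$params)) list() else lapply(x$params, unlist),
                     free_parameter_count = x$free_parameter_count %||% 0L,
                     observed = observed,
                     description = x$description %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an architecture model to JSON
#' @param model an `architecture_model`.
#' @param path output file path.
#' @export
write_model_json <- function(model, path) {
  x <- unclass(model)
  x$rules <- lapply(x$rules, function(r) {
    r$then <- as.list(r$then)
    if (!is.null(r$subvariant)) r$subvariant <- as.list(r$subvariant)
    r
  })
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Names of the shipped architecture models
#' @return character vector of model names accepted by [builtin_model()].
#' @export
builtin_model_names <- function() {
  sub("\\.json$", "", dir(system.file("extdata", "models", package = "heliocross"),
                          pattern = "\\.json$"))
}

#' Load a shipped architecture model
#'
#' Seven models ship with the package:
#' \describe{
#'   \item{ERATO_UNIFIED}{Two-locus epistatic control in *H. erato*: yellow bar
#'     iff Cr is race-homozygous or Sd is fav/fav; Cr-hybrids otherwise show the
#'     F1-like fuzzy bar.}
#'   \item{ERATO_SINGLE_LOCUS}{Single-locus null (Cr alone) that the
#'     favorinus backcross data reject.}
#'   \item{ERATO_UNIFIED_MODIFIER}{As ERATO_UNIFIED but Cr-hybrid fuzzy
#'     individuals turn black-hindwing with penetrance `p_black`
#'     (default 0.5) — the speculative third-locus effect as a penetrance
#'     parameter.}
#'   \item{ERATO_MODIFIER_LOCUS}{The same effect encoded as an explicit
#'     unlinked biallelic modifier locus `Mod` (black iff Cr hybrid and the
#'     `pet.b` modifier allele is carried).}
#'   \item{MELPOMENE_YB}{Classical co-dominant Yb: yb/yb yellow bar, Yb/yb
#'     shadow bar, Yb/Yb black hindwing.}
#'   \item{MELPOMENE_CRYPTIC}{Cryptic variation segregating in the
#'     melpomene father: paternal allele a1 behaves as yb (pigmented bar,
#'     fuzzy/full split 0.5/0.5), a2 as Yb (shadow bar).}
#'   \item{MELPOMENE_COMPLEMENTING}{rosina and amaryllis yb alleles are
#'     interchangeable: every genotype yields the full yellow bar.}
#' }
#' @param name one of [builtin_model_names()].
#' @return an `architecture_model`.
#' @export
builtin_model <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "heliocross")
  if (!nzchar(path)) {
    stop("unknown built-in model '", name, "'; available: ",
         paste(builtin_model_names(), collapse = ", "), call. = FALSE)
  }
  read_model_json(path)
}
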