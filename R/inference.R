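#' @title Scoring and ranking candidate genetic architectures
#' @description
#' Operationalises "most parsimonious hypothesis" reasoning: each candidate
#' model is scored against a brood's phenotype counts (multinomial
#' log-likelihood and chi-square against the model's expected ratios) and
#' against per-individual genotype calls (the fraction of genotyped
#' individuals whose phenotype has non-zero probability given their called
#' genotype). Ranking is by consistency fraction, then log-likelihood, then
#' fewer free parameters, then model name.
#' @name inference
NULL

# constraint matching: does a genotype satisfy a per-locus call?
# calls: named list locus -> one of "hybrid", "pure_<race>", an explicit
# "x/y" allele pair string, or NA/"missing"/"conflict" (no constraint)
genotype_matches_calls <- function(g, calls) {
  for (loc in names(calls)) {
    val <- calls[[loc]]
    if (is.null(val) || is.na(val) || val %in% c("missing", "conflict")) next
    d <- g[[loc]]
    if (is.null(d)) return(FALSE)
    ok <- if (identical(val, "hybrid")) {
      allele_race(d[1]) != allele_race(d[2])
    } else if (startsWith(val, "pure_")) {
      race <- sub("^pure_", "", val)
      all(allele_race(d) == race)
    } else if (grepl("/", val, fixed = TRUE)) {
      pair <- strsplit(val, "/", fixed = TRUE)[[1]]
      identical(sort(d), sort(pair)) # unordered allele-pair match
    } else {
      stop("unrecognised genotype call '", val, "'", call. = FALSE)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

definite_calls <- function(calls) {
  keep <- !vapply(calls, function(v) is.null(v) || is.na(v) ||
                    v %in% c("missing", "conflict"), logical(1))
  calls[keep]
}

calls_for_individual <- function(row, calls_df = NULL) {
  out <- list()
  if (!is.null(calls_df)) {
    sub <- calls_df[calls_df$id == row$id, , drop = FALSE]
    for (i in seq_len(nrow(sub))) out[[sub$locus[i]]] <- sub$label[i]
  } else {
    g <- tryCatch(parse_genotype(row$genotype), error = function(e) NULL)
    if (!is.null(g)) for (loc in names(g)) {
      out[[loc]] <- paste(g[[loc]], collapse = "/")
    }
  }
  out
}

#' Per-individual genotype-phenotype consistency under a model
#'
#' For each individual with a definite phenotype and at least one definite
#' genotype call, the verdict is `consistent` iff the observed phenotype has
#' probability > 0 given the called genotype under the model, marginalising
#' over uncalled loci with the cross's genotype distribution conditioned on
#' the calls. Individuals with no definite call are `uninformative` and are
#' excluded from the consistency fraction.
#'
#' @param brood a `brood_table`.
#' @param cross the `cross_spec` that produced the brood.
#' @param model an `architecture_model`.
#' @param map a `recomb_map`.
#' @param calls optional data.frame of genotype calls with columns `id`,
#'   `locus`, `label` (as produced by [call_brood_genotypes()]); when absent,
#'   the brood's own genotype strings are used as calls.
#' @param survivors_only drop non-survivors first.
#' @return data.frame with columns `id`, `phenotype`, `verdict`
#'   (`consistent` / `inconsistent` / `uninformative`) and `extrapolated`
#'   (any matching genotype outside the model's observational support).
#' @export
consistency_check <- function(brood, cross, model, map = default_recomb_map(cross),
                              calls = NULL, survivors_only = TRUE) {
  df <- as.data.frame(brood)
  if (survivors_only && "survived" %in% names(df)) df <- df[df$survived, , drop = FALSE]
  if (!is.null(calls)) {
    bad <- setdiff(unique(calls$id), df$id)
    if (length(bad) > 0) stop("genotype calls reference unknown individuals: ",
                              paste(bad, collapse = ", "), call. = FALSE)
  }
  dist <- cross_distribution(cross, map)
  genos <- lapply(dist$genotype, parse_genotype)
  support <- lapply(genos, function(g) names(predict_phenotype(g, model)))
  extrap <- vapply(genos, is_extrapolated, model = model, logical(1))

  out <- data.frame(id = df$id, phenotype = df$phenotype,
                    verdict = "uninformative", extrapolated = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$phenotype[i]) || !nzchar(df$phenotype[i])) next
    cl <- definite_calls(calls_for_individual(df[i, ], calls))
    if (length(cl) == 0) next
    match_idx <- which(vapply(genos, genotype_matches_calls, calls = cl, logical(1)))
    if (length(match_idx) == 0) {
      out$verdict[i] <- "inconsistent" # call impossible under the cross
      next
    }
    classes <- unique(unlist(support[match_idx]))
    out$verdict[i] <- if (df$phenotype[i] %in% classes) "consistent" else "inconsistent"
    out$extrapolated[i] <- any(extrap[match_idx], na.rm = TRUE)
  }
  out
}

profile_p_black <- function(counts, cross, model, map) {
  loglik_at <- function(p) {
    m <- model
    m$params$p_black <- p
    multinomial_loglik(counts, expected_phenotype_ratios(cross, m, map))
  }
  opt <- stats::optimize(loglik_at, c(0, 1), maximum = TRUE, tol = 1e-6)
  # optimize never evaluates the interval ends; check them explicitly
  cand <- c(opt$maximum, 0, 1)
  ll <- vapply(cand, loglik_at, numeric(1))
  best <- which.max(ll)
  list(p_black = cand[best], loglik = ll[best])
}

multinomial_loglik <- function(counts, probs) {
  classes <- union(names(probs), names(counts))
  x <- stats::setNames(rep(0, length(classes)), classes)
  x[names(counts)] <- counts
  p <- stats::setNames(rep(0, length(classes)), classes)
  p[names(probs)] <- probs
  if (any(x > 0 & p == 0)) return(-Inf)
  keep <- p > 0 & x > 0
  # per-individual log-likelihood sum(x * log p); the multinomial coefficient
  # is constant across models for fixed counts, so it is omitted — rankings
  # are unchanged and the total never increases when an individual is added
  sum(x[keep] * log(p[keep] / sum(p[p > 0])))
}

#' Score one architecture model against a brood
#'
#' @inheritParams consistency_check
#' @return object of class `model_score`: model name, profiled parameter
#'   MLEs (stochastic penetrance parameters are profiled, not fixed),
#'   multinomial log-likelihood of the observed phenotype counts,
#'   chi-square/df/p against the expected class ratios, consistency fraction
#'   with its numerator/denominator, free parameter count, and extrapolation
#'   flags.
#' @examples
#' b <- brood_fixture("L15")
#' score_model(b, cross_fixture("L15"), builtin_model("ERATO_UNIFIED"))
#' @export
score_model <- function(brood, cross, model, map = default_recomb_map(cross),
                        calls = NULL, survivors_only = TRUE) {
  counts <- phenotype_counts(brood, survivors_only = survivors_only)
  if (sum(counts) == 0) stop("empty brood: no phenotyped survivors", call. = FALSE)

  mle <- list()
  if ("p_black" %in% names(model$params)) {
    prof <- profile_p_black(counts, cross, model, map)
    model$params$p_black <- prof$p_black
    mle$p_black <- prof$p_black
  }
  exp_ratios <- expected_phenotype_ratios(cross, model, map)
  ll <- multinomial_loglik(counts, exp_ratios)

  zero_exp <- setdiff(names(counts)[counts > 0], names(exp_ratios))
  if (length(zero_exp) > 0) {
    statistic <- Inf; df <- NA_integer_; p <- 0
  } else {
    gt <- chisq_gof(counts, exp_ratios[exp_ratios > 0])
    statistic <- gt$statistic; df <- gt$df; p <- gt$p
  }

  cons <- consistency_check(brood, cross, model, map, calls, survivors_only)
  informative <- cons$verdict != "uninformative"
  n_inf <- sum(informative)
  frac <- if (n_inf == 0) NA_real_ else sum(cons$verdict == "consistent") / n_inf

  structure(list(model = model$name, mle = mle, loglik = ll,
                 statistic = statistic, df = df, p = p,
                 consistency = frac,
                 n_consistent = sum(cons$verdict == "consistent"),
                 n_informative = n_inf,
                 free_parameters = model$free_parameter_count,
                 expected = exp_ratios, observed = counts,
                 consistency_table = cons,
                 n_extrapolated = sum(cons$extrapolated)),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("%s: logL = %.3f, X2 = %.3f (df %s, p = %.3g), consistency %s\n",
              x$model, x$loglik, x$statistic, x$df,
              x$p, if (is.na(x$consistency)) "n/a"
              else sprintf("%d/%d", x$n_consistent, x$n_informative)))
  invisible(x)
}

#' Rank candidate architecture models on a brood
#'
#' Ranking keys, in order: consistency fraction (descending; `NA` sorts
#' last), log-likelihood (descending), fewer free parameters, model name.
#' Log-likelihoods within 1e-6 are treated as tied so that a profiled
#' penetrance parameter sitting at a boundary cannot win on numerical
#' noise.
#'
#' @inheritParams consistency_check
#' @param candidates list of `architecture_model` objects (>= 1).
#' @return object of class `inference_report`: `scores` (ranked list of
#'   `model_score`), `winner` (name), and `ranking` (data.frame of the keys).
#' @examples
#' rank_models(brood_fixture("L15"), cross_fixture("L15"),
#'             list(builtin_model("ERATO_SINGLE_LOCUS"),
#'                  builtin_model("ERATO_UNIFIED")))
#' @export
rank_models <- function(brood, cross, candidates, map = default_recomb_map(cross),
                        calls = NULL, survivors_only = TRUE) {
  if (length(candidates) < 1) stop("need at least one candidate model", call. = FALSE)
  scores <- lapply(candidates, function(m)
    score_model(brood, cross, m, map, calls, survivors_only))
  cons <- vapply(scores, function(s) if (is.na(s$consistency)) -1 else s$consistency,
                 numeric(1))
  ll <- round(vapply(scores, function(s) s$loglik, numeric(1)) / 1e-6) * 1e-6
  fp <- vapply(scores, function(s) s$free_parameters, integer(1))
  nm <- vapply(scores, function(s) s$model, character(1))
  ord <- order(-cons, -ll, fp, nm)
  ranking <- data.frame(model = nm[ord], consistency = cons[ord],
                        loglik = vapply(scores, function(s) s$loglik, numeric(1))[ord],
                        free_parameters = fp[ord], stringsAsFactors = FALSE)
  ranking$consistency[ranking$consistency < 0] <- NA_real_
  structure(list(scores = scores[ord], winner = nm[ord][1], ranking = ranking),
            class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("model ranking (winner first):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Serialise an inference report to JSON
#' @param report an `inference_report`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_inference_report <- function(report, path = NULL) {
  x <- list(winner = report$winner, ranking = report$ranking,
            scores = lapply(report$scores, function(s) {
              s$consistency_table <- NULL
              unclass(s)
            }))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                           force = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
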