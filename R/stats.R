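#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, the p-value attached to
#' every goodness-of-fit statistic here. For df = 1 this equals
#' `2 * (1 - pnorm(sqrt(x)))`.
#' @param x non-negative statistic.
#' @param df integer degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @export
chisq_upper_tail <- function(x, df) {
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    stop("df must be a positive integer", call. = FALSE)
  }
  if (any(x < 0)) stop("statistic must be non-negative", call. = FALSE)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Chi-square goodness of fit against a ratio hypothesis
#'
#' Pearson statistic `sum((O - E)^2 / E)` with expectations from the
#' normalised ratio weights, df = number of categories - 1, and p from the
#' chi-square upper tail. No continuity correction is applied anywhere: the
#' published statistic for counts 13:5 against 1:1 (3.56) is the uncorrected
#' value (Yates-corrected would be 2.72). Any pooling of phenotype classes
#' (e.g. fuzzy + black into one non-yellow class for a 1:1 test) must be done
#' by the caller and declared via `pooling` — it is never inferred.
#'
#' @param observed named non-negative integer counts.
#' @param ratio named positive weights, e.g. `c(yellow = 3, fuzzy = 1)`;
#'   scale-invariant. Must cover every observed category; ratio categories
#'   absent from `observed` count as zero.
#' @param pooling optional free-text description of the pooling applied
#'   before counting (recorded in the result).
#' @return object of class `seg_test`: `statistic`, `df`, `p`, `observed`,
#'   `expected`, `ratio`, `pooling`.
#' @examples
#' chisq_gof(c(yellow = 13, f1_like = 5), c(yellow = 1, f1_like = 1))
#' chisq_gof(c(f1_like = 5, yellow = 13), c(f1_like = 1, yellow = 3))
#' @export
chisq_gof <- function(observed, ratio, pooling = NULL) {
  if (is.null(names(observed)) || is.null(names(ratio))) {
    stop("observed and ratio must be named", call. = FALSE)
  }
  if (any(observed < 0) || any(observed != round(observed))) {
    stop("observed counts must be non-negative integers", call. = FALSE)
  }
  if (any(ratio <= 0)) stop("ratio weights must be positive (an expected count of ",
                            "zero is not testable)", call. = FALSE)
  extra <- setdiff(names(observed), names(ratio))
  if (length(extra) > 0) {
    stop("observed categories absent from hypothesis: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  counts <- stats::setNames(rep(0, length(ratio)), names(ratio))
  counts[names(observed)] <- observed
  n <- sum(counts)
  if (n < 1) stop("total count must be at least 1", call. = FALSE)
  expected <- n * ratio / sum(ratio)
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(ratio) - 1L
  # a single-category hypothesis is degenerate: the fit is exact by construction
  p <- if (df == 0L) 1 else chisq_upper_tail(statistic, df)
  structure(list(statistic = statistic, df = df, p = p,
                 observed = counts, expected = expected, ratio = ratio,
                 pooling = pooling),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, digits = 3, ...) {
  cat(sprintf("chi-square goodness of fit: X2 = %s, df = %d, p = %s\n",
              format(format_signif(x$statistic, digits)), x$df,
              format(format_signif(x$p, 2))))
  cat("observed:", paste(sprintf("%s=%g", names(x$observed), x$observed),
                         collapse = ", "), "\n")
  cat("expected ratio:", paste(sprintf("%s=%g", names(x$ratio), x$ratio),
                               collapse = ":"), "\n")
  if (!is.null(x$pooling)) cat("pooling:", x$pooling, "\n")
  invisible(x)
}

#' Exact probability of a perfect co-segregation
#'
#' Under independent 1:1 segregation, the chance that all `n` informative
#' offspring show the observed perfect genotype-phenotype association is
#' `(1/2)^n`. Every counted individual must have both a definite genotype
#' call and a definite phenotype class; missing or conflicting calls are
#' excluded *before* counting.
#'
#' @param n_informative number of informative individuals (>= 0).
#' @param description free-text note of the association tested.
#' @return object of class `coseg_result`: `n`, `probability`, `description`.
#' @examples
#' cosegregation_probability(21)$probability  # (1/2)^21 = 4.768e-07
#' @export
cosegregation_probability <- function(n_informative, description = "") {
  if (!is.numeric(n_informative) || length(n_informative) != 1L ||
      n_informative < 0 || n_informative != round(n_informative)) {
    stop("n_informative must be a non-negative integer", call. = FALSE)
  }
  structure(list(n = as.integer(n_informative),
                 probability = 0.5^n_informative,
                 description = description),
            class = "coseg_result")
}

#' @export
print.coseg_result <- function(x, digits = 2, mode = "round", ...) {
  cat(sprintf("perfect co-segregation over n = %d informative individuals: P = %g\n",
              x$n, format_signif(x$probability, digits, mode)))
  if (nzchar(x$description)) cat(x$description, "\n")
  invisible(x)
}

#' Co-segregation test on a brood table
#'
#' Counts individuals with both a definite phenotype and a definite genotype
#' at `locus`, classifies their genotype (by race pattern, or by which
#' paternal allele they inherited), and — if the genotype-phenotype
#' association is perfect, i.e. no phenotype class occurs in more than one
#' genotype class — returns the exact `(1/2)^n` probability of that
#' association arising under independent 1:1 segregation.
#'
#' @param brood a `brood_table`.
#' @param locus locus name to read from the genotype column.
#' @param classify `"race"` (pure vs hybrid by race tags) or
#'   `"paternal_allele"` (which paternal allele was inherited, for crosses
#'   where the father is heterozygous for same-race sub-alleles).
#' @param survivors_only drop non-survivors first (default TRUE).
#' @return a `coseg_result` with the contingency table attached as attribute
#'   `"table"`; `probability` is `NA` if the association is not perfect.
#' @export
coseg_test <- function(brood, locus, classify = c("race", "paternal_allele"),
                       survivors_only = TRUE) {
  classify <- match.arg(classify)
  df <- as.data.frame(brood)
  if (survivors_only && "survived" %in% names(df)) df <- df[df$survived, , drop = FALSE]
  gclass <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    g <- tryCatch(parse_genotype(df$genotype[i]), error = function(e) NULL)
    if (is.null(g) || is.null(g[[locus]])) next
    d <- g[[locus]]
    gclass[i] <- if (classify == "race") {
      if (allele_race(d[1]) != allele_race(d[2])) "hybrid"
      else paste0("pure_", allele_race(d[1]))
    } else {
      paste0("paternal_", d[2])
    }
  }
  keep <- !is.na(gclass) & !is.na(df$phenotype) & nzchar(df$phenotype)
  tab <- table(genotype = gclass[keep], phenotype = df$phenotype[keep])
  perfect <- all(colSums(tab > 0) <= 1)
  res <- cosegregation_probability(sum(keep),
    description = sprintf("association between %s genotype class (%s) and phenotype in brood %s",
                          locus, classify,
                          attr(brood, "cross_id") %||% unique(df$cross_id)[1]))
  if (!perfect) res$probability <- NA_real_
  attr(res, "table") <- tab
  attr(res, "perfect") <- perfect
  res
}

#' Test a brood's sex ratio against 1:1
#'
#' Chi-square goodness of fit of the surviving female/male counts against
#' equal numbers; individuals of unknown sex are excluded.
#' @param brood a `brood_table` (or data.frame with a `sex` column).
#' @param survivors_only drop non-survivors first (default TRUE).
#' @return a `seg_test`.
#' @examples
#' # 10 females vs 34 males: X2 = 13.09, p = 3.0e-04
#' @export
sex_ratio_test <- function(brood, survivors_only = TRUE) {
  df <- as.data.frame(brood)
  if (survivors_only && "survived" %in% names(df)) df <- df[df$survived, , drop = FALSE]
  sex <- df$sex[df$sex %in% c("female", "male")]
  if (length(sex) == 0) stop("brood has no sexed individuals", call. = FALSE)
  counts <- c(female = sum(sex == "female"), male = sum(sex == "male"))
  chisq_gof(counts, c(female = 1, male = 1))
}
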