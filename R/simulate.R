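#' Simulation configuration for synthetic broods
#'
#' @param seed integer master seed; each brood derives its own RNG stream
#'   from `(seed, cross_id)`, so adding a brood to a run never perturbs
#'   another brood's output.
#' @param n_offspring number of offspring conceived (before viability
#'   thinning).
#' @param female_viability relative viability of females in `[0, 1]` (males
#'   always survive in this parameterisation). With conception sex ratio
#'   1:1, the expected surviving female fraction is `v / (1 + v)`; the value
#'   `10/34` reproduces the published melpomene-direction brood's 10:34
#'   adult ratio in expectation.
#' @param sterility_rules list of lists with fields `father_race`,
#'   `mother_race`, `affected_sex`; offspring of the affected sex from a
#'   matching cross direction are marked infertile.
#' @param error_rate per-base substitution error rate for simulated marker
#'   sequences (default 0).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_offspring, female_viability = 1,
                              sterility_rules = list(), error_rate = 0) {
  stopifnot(n_offspring >= 0,
            female_viability >= 0, female_viability <= 1,
            error_rate >= 0, error_rate <= 1)
  for (r in sterility_rules) {
    if (!all(c("father_race", "mother_race", "affected_sex") %in% names(r))) {
      stop("each sterility rule needs father_race, mother_race, affected_sex",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_offspring = as.integer(n_offspring),
                 female_viability = female_viability,
                 sterility_rules = sterility_rules, error_rate = error_rate),
            class = "simulation_config")
}

#' The one-way hybrid female sterility rule
#'
#' Offspring females of a melpomene father x rosina mother cross are
#' sterile; the reverse direction is unaffected.
#' @return list usable as `sterility_rules` in [simulation_config()].
#' @export
melpomene_sterility_rules <- function() {
  list(list(father_race = "mel", mother_race = "ros", affected_sex = "female"))
}

brood_stream_seed <- function(seed, cross_id) {
  as.integer((seed + fnv1a32(cross_id)) %% (2^31 - 1))
}

#' Simulate a brood
#'
#' Forward simulation of a single two-generation cross: offspring genotypes
#' are i.i.d. draws from the exact [cross_distribution()], sex is a fair
#' Bernoulli at conception, female survival is thinned by
#' `female_viability` (post-conception inviability; egg hatchability is
#' normal in the emulated cross, the loss is larval), phenotypes (and
#' sub-variants) are drawn from [predict_phenotype()], and sterility rules
#' matching the cross direction mark offspring infertile. Reproducible:
#' identical configuration gives byte-identical output.
#'
#' @param cross a `cross_spec`.
#' @param model an `architecture_model` covering the cross loci.
#' @param config a `simulation_config`.
#' @param map a `recomb_map` (default: loci unlinked).
#' @return a `brood_table` (see [brood_table()]); non-survivors are kept as
#'   rows with `survived = FALSE` and are excluded by the counting helpers.
#' @examples
#' b <- simulate_brood(cross_fixture("L15"), builtin_model("ERATO_UNIFIED"),
#'                     simulation_config(seed = 1, n_offspring = 100))
#' phenotype_counts(b)
#' @export
simulate_brood <- function(cross, model, config, map = default_recomb_map(cross)) {
  stopifnot(inherits(cross, "cross_spec"), inherits(model, "architecture_model"),
            inherits(config, "simulation_config"))
  missing <- setdiff(model$loci, names(cross$mother))
  if (length(missing) > 0) {
    stop("cross does not cover model loci: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- config$n_offspring
  dist <- cross_distribution(cross, map)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(brood_stream_seed(config$seed, cross$cross_id))

  if (n == 0) {
    df <- data.frame(id = character(), cross_id = character(), sex = character(),
                     phenotype = character(), subvariant = character(),
                     genotype = character(), survived = logical(),
                     fertile = logical(), stringsAsFactors = FALSE)
    return(brood_table(df, cross_id = cross$cross_id, provenance = "simulated",
                       seed = config$seed))
  }

  gidx <- sample.int(nrow(dist), n, replace = TRUE, prob = dist$prob)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  survived <- ifelse(sex == "female",
                     stats::runif(n) < config$female_viability, TRUE)

  # phenotype draw per individual from the genotype's class distribution
  geno_cache <- lapply(dist$genotype, parse_genotype)
  pred_cache <- lapply(geno_cache, predict_phenotype, model = model)
  phenotype <- character(n)
  subvariant <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- pred_cache[[gidx[i]]]
    phenotype[i] <- if (length(p) == 1L) names(p) else
      sample(names(p), 1L, prob = as.numeric(p))
    sv <- attr(p, "subvariant")
    if (!is.null(sv) && phenotype[i] %in% c("YELLOW_BAR", "FUZZY_BAR")) {
      subvariant[i] <- sample(names(sv), 1L, prob = as.numeric(sv))
    }
  }

  fertile <- rep(TRUE, n)
  for (r in config$sterility_rules) {
    if (identical(r$father_race, cross$father_race) &&
        identical(r$mother_race, cross$mother_race)) {
      fertile[sex == r$affected_sex] <- FALSE
    }
  }

  df <- data.frame(
    id = sprintf("%s_%04d", cross$cross_id, seq_len(n)),
    cross_id = cross$cross_id, sex = sex, phenotype = phenotype,
    subvariant = subvariant, genotype = dist$genotype[gidx],
    survived = survived, fertile = fertile, stringsAsFactors = FALSE)
  brood_table(df, cross_id = cross$cross_id, provenance = "simulated",
              seed = config$seed, config_hash = config_hash(unclass(config)))
}

#' Construct a brood table
#'
#' The unit every statistic consumes: one row per offspring with sex,
#' phenotype class, optional fuzzy/full sub-variant, optional genotype
#' string (see [format_genotype()]), and survival/fertility flags.
#' @param df data.frame with at least `id`, `cross_id`, `sex`, `phenotype`;
#'   missing optional columns (`subvariant`, `genotype`, `survived`,
#'   `fertile`) are filled with defaults.
#' @param cross_id brood identifier.
#' @param provenance `"simulated"` or `"observed"`.
#' @param seed,config_hash optional reproducibility metadata embedded in
#'   written files.
#' @return data.frame of class `brood_table`.
#' @export
brood_table <- function(df, cross_id, provenance = c("observed", "simulated"),
                        seed = NULL, config_hash = NULL) {
  provenance <- match.arg(provenance)
  req <- c("id", "cross_id", "sex", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("brood table missing columns: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (!"subvariant" %in% names(df)) df$subvariant <- rep(NA_character_, nrow(df))
  if (!"genotype" %in% names(df)) df$genotype <- rep("", nrow(df))
  if (!"survived" %in% names(df)) df$survived <- rep(TRUE, nrow(df))
  if (!"fertile" %in% names(df)) df$fertile <- rep(TRUE, nrow(df))
  bad_sex <- !df$sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) stop("invalid sex values: ",
                         paste(unique(df$sex[bad_sex]), collapse = ", "),
                         call. = FALSE)
  bad_ph <- !(df$phenotype %in% PHENOTYPE_CLASSES | is.na(df$phenotype) |
                df$phenotype == "")
  if (any(bad_ph)) stop("unknown phenotype labels: ",
                        paste(unique(df$phenotype[bad_ph]), collapse = ", "),
                        call. = FALSE)
  structure(df, class = c("brood_table", "data.frame"), cross_id = cross_id,
            provenance = provenance, seed = seed, config_hash = config_hash)
}

#' Phenotype-class counts of a brood
#' @param brood a `brood_table`.
#' @param survivors_only count survivors only (default TRUE).
#' @param by_subvariant split pigmented classes by their fuzzy/full tag.
#' @return named integer vector of counts.
#' @export
phenotype_counts <- function(brood, survivors_only = TRUE, by_subvariant = FALSE) {
  df <- as.data.frame(brood)
  if (survivors_only && "survived" %in% names(df)) df <- df[df$survived, , drop = FALSE]
  lab <- df$phenotype
  if (by_subvariant) {
    has_sv <- !is.na(df$subvariant) & nzchar(df$subvariant)
    lab[has_sv] <- paste0(lab[has_sv], ".", df$subvariant[has_sv])
  }
  tab <- table(lab[!is.na(lab) & nzchar(lab)])
  stats::setNames(as.integer(tab), names(tab))
}

#' Simulate aligned marker sequences for a brood
#'
#' Inverse of the genotyping step: writes one sequence per individual per
#' marker locus, copying the reference everywhere except the diagnostic
#' positions, where homozygotes carry their race's base and hybrids the
#' IUPAC ambiguity code covering both races' bases. Headers follow
#' `individualID|locus`.
#'
#' @param brood a `brood_table` with genotype strings.
#' @param table a `diagnostic_table`; its `region` column links each marker
#'   locus to the patterning locus whose genotype it reports.
#' @param references named character vector or `DNAStringSet` of reference
#'   sequences, one per marker locus.
#' @param error_rate per-base substitution error rate (default 0); errors
#'   are drawn from the brood's RNG stream when `seed` is given.
#' @param seed optional integer for the error process.
#' @return a `Biostrings::DNAStringSet`.
#' @seealso [synthetic_reference()] to generate reference fixtures,
#'   [call_brood_genotypes()] for the inverse operation.
#' @export
simulate_marker_fasta <- function(brood, table, references, error_rate = 0,
                                  seed = NULL) {
  refs <- stats::setNames(toupper(as.character(references)), names(references))
  if (is.null(names(refs))) stop("references must be named by marker locus",
                                 call. = FALSE)
  df <- as.data.frame(brood)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  out <- character(0)
  for (marker in intersect(unique(table$locus), names(refs))) {
    rows <- table[table$locus == marker, , drop = FALSE]
    ref <- refs[[marker]]
    if (any(rows$position > nchar(ref))) {
      stop("diagnostic position beyond reference length for marker '", marker,
           "'", call. = FALSE)
    }
    if (!all(grepl("^[ACGT]$", c(rows$base_A, rows$base_B)))) {
      stop("marker '", marker, "' has non-ACGT diagnostic bases; cannot ",
           "simulate sequences for it", call. = FALSE)
    }
    region <- rows$region[1]
    for (i in seq_len(nrow(df))) {
      g <- tryCatch(parse_genotype(df$genotype[i]), error = function(e) NULL)
      if (is.null(g) || is.null(g[[region]])) next
      races <- allele_race(g[[region]])
      s <- ref
      for (j in seq_len(nrow(rows))) {
        bases <- c(rows$base_A[j], rows$base_B[j])
        names(bases) <- c(rows$race_A[j], rows$race_B[j])
        if (!all(races %in% names(bases))) {
          stop("no diagnostic base for race ", paste(setdiff(races, names(bases)),
                                                     collapse = ","),
               " at marker '", marker, "' position ", rows$position[j],
               call. = FALSE)
        }
        sym <- encode_iupac(bases[races])
        substr(s, rows$position[j], rows$position[j]) <- sym
      }
      if (error_rate > 0) {
        hit <- which(stats::runif(nchar(s)) < error_rate)
        for (p in hit) {
          cur <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
      }
      out[paste0(df$id[i], "|", marker)] <- s
    }
  }
  Biostrings::DNAStringSet(out)
}

#' Generate a synthetic marker reference sequence
#'
#' Random A/C/G/T sequence used as a stand-in reference for simulated
#' genotyping fixtures (real reference sequences are not redistributed with
#' the package); the diagnostic base of `fill_race` is written at each
#' diagnostic position so the reference itself reads as that race.
#'
#' @param marker marker locus name present in `table`.
#' @param table a `diagnostic_table`.
#' @param length sequence length; defaults to 60 past the last diagnostic
#'   position.
#' @param seed integer seed.
#' @param fill_race which race's diagnostic bases the backbone carries
#'   (default: the table's `race_A`).
#' @return character scalar sequence.
#' @export
synthetic_reference <- function(marker, table, length = NULL, seed = 1,
                                fill_race = NULL) {
  rows <- table[table$locus == marker, , drop = FALSE]
  if (nrow(rows) == 0) stop("marker '", marker, "' not in table", call. = FALSE)
  if (is.null(length)) length <- max(rows$position) + 60L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed + fnv1a32(marker) %% 1e6))
  s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  if (is.null(fill_race)) fill_race <- rows$race_A[1]
  for (j in seq_len(nrow(rows))) {
    base <- if (rows$race_A[j] == fill_race) rows$base_A[j] else rows$base_B[j]
    substr(s, rows$position[j], rows$position[j]) <- base
  }
  s
}
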