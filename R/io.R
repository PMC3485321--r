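#' Write a brood table to TSV
#'
#' UTF-8 tab-separated output with `#key=value` metadata header lines
#' (cross id, provenance, seed and configuration hash when present) so
#' reruns can be matched to their configuration; [read_brood_table()]
#' restores the metadata, making write-then-read the identity.
#' @param brood a `brood_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brood_table <- function(brood, path) {
  meta <- c(cross_id = attr(brood, "cross_id"),
            provenance = attr(brood, "provenance"),
            seed = attr(brood, "seed"),
            config_hash = attr(brood, "config_hash"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#%s=%s", names(meta), unlist(meta)), con)
  utils::write.table(as.data.frame(brood), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a brood table from TSV
#'
#' @param path TSV file as written by [write_brood_table()] (leading
#'   `#key=value` lines optional). Required columns: `id`, `cross_id`,
#'   `sex`, `phenotype`; optional: `subvariant`, `genotype`, `survived`,
#'   `fertile`. Unknown phenotype labels are rejected with the offending
#'   line number.
#' @return a `brood_table`; an empty file (header only) yields an empty
#'   brood with a warning.
#' @export
read_brood_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)] # leading block only
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- sub("^#", "", l)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  if (length(body) == 0) stop("no header line in ", path, call. = FALSE)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(df) == 0) warning("empty brood table: ", path, call. = FALSE)
  # character columns may be read as logical NA when empty
  for (col in c("subvariant", "genotype")) {
    if (col %in% names(df)) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][is.na(df[[col]])] <- if (col == "genotype") "" else NA_character_
    }
  }
  bad <- which(!(df$phenotype %in% PHENOTYPE_CLASSES | is.na(df$phenotype) |
                   df$phenotype == ""))
  if (length(bad) > 0) {
    line_no <- length(meta_idx) + 1 + bad[1] # header + offset
    stop("line ", line_no, ": unknown phenotype label '", df$phenotype[bad[1]],
         "'", call. = FALSE)
  }
  brood_table(df,
              cross_id = meta$cross_id %||% unique(df$cross_id)[1],
              provenance = meta$provenance %||% "observed",
              seed = if (!is.null(meta$seed)) as.integer(meta$seed),
              config_hash = meta$config_hash)
}

#' Read a run configuration JSON
#'
#' @param path JSON file with optional fields `paths` (named list of input
#'   files), `seed`, `sig_figs` (reporting precision), and `flags`
#'   (`truncate` for truncation-style rounding of reported values,
#'   `search_revcomp` for the digest). Referenced paths must exist.
#' @return list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$seed <- as.integer(x$seed %||% 1L)
  x$sig_figs <- as.integer(x$sig_figs %||% 2L)
  x$flags <- utils::modifyList(list(truncate = FALSE, search_revcomp = TRUE),
                               as.list(x$flags))
  for (p in unlist(x$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p, call. = FALSE)
  }
  structure(x, class = "run_config")
}

#' Write genotype calls to TSV
#' @param calls data.frame from [call_brood_genotypes()].
#' @param path output path.
#' @export
write_genotype_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise segregation-test results to JSON
#'
#' One record per test with the test name, brood, categories, observed
#' counts, expected ratio, statistic, df and p.
#' @param tests named list of `seg_test` objects (names = test labels).
#' @param brood_id brood identifier recorded in each record.
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
write_seg_results <- function(tests, brood_id, path = NULL) {
  recs <- lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    list(test = nm, brood = brood_id, categories = names(t$observed),
         observed = unname(t$observed), expected_ratio = unname(t$ratio),
         statistic = t$statistic, df = t$df, p = t$p,
         pooling = t$pooling %||% "")
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
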