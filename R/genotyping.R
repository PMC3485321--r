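#' Read a diagnostic SNP table
#'
#' Tab-separated table of race-diagnostic positions on named reference
#' sequences, one row per (marker locus, position). Required columns:
#' `locus`, `region` (the patterning locus the marker tags), `position`
#' (1-based on the reference), `base_A`, `race_A`, `base_B`, `race_B`;
#' optional `informative_for` (comma-separated cross ids the row is
#' informative in) and `note`. Coordinates stay 1-based everywhere a user
#' sees them; conversion to offsets happens only inside string arithmetic.
#'
#' @param path file path; defaults to the packaged table transcribing the
#'   published diagnostic positions for the LRR/ReqQ (Cr region), Mat (Sd
#'   region) and B9/Parn (Yb region) markers.
#' @return data.frame of class `diagnostic_table`.
#' @export
read_diagnostic_table <- function(path = system.file("extdata", "diagnostic_snps.tsv",
                                                     package = "heliocross")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  req <- c("locus", "region", "position", "base_A", "race_A", "base_B", "race_B")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("diagnostic table missing columns: ",
                             paste(miss, collapse = ", "), call. = FALSE)
  if (!"informative_for" %in% names(df)) df$informative_for <- ""
  if (!"note" %in% names(df)) df$note <- ""
  df$informative_for[is.na(df$informative_for)] <- ""
  df$note[is.na(df$note)] <- ""
  if (any(df$position < 1)) stop("positions must be >= 1 (1-based coordinates)",
                                 call. = FALSE)
  if (any(df$base_A == df$base_B)) stop("base_A must differ from base_B",
                                        call. = FALSE)
  dup <- duplicated(df[c("locus", "position")])
  if (any(dup)) stop("duplicated position within locus: ",
                     paste(df$locus[dup], df$position[dup], collapse = "; "),
                     call. = FALSE)
  structure(df, class = c("diagnostic_table", "data.frame"))
}

#' The packaged diagnostic SNP table
#' @return a `diagnostic_table` (see [read_diagnostic_table()]).
#' @export
diagnostic_snps <- function() read_diagnostic_table()

informative_rows <- function(table, locus, cross = NULL) {
  rows <- table[table$locus == locus, , drop = FALSE]
  if (!is.null(cross) && any(nzchar(rows$informative_for))) {
    keep <- vapply(strsplit(rows$informative_for, ","),
                   function(x) cross %in% trimws(x), logical(1))
    rows <- rows[keep, , drop = FALSE]
  }
  rows
}

#' Call a pure/hybrid genotype from an aligned marker sequence
#'
#' Classifies every informative diagnostic position of the sequence, then
#' aggregates: unanimous homozygous sites give a pure call; at least one
#' heterozygous site with the remainder compatible gives `hybrid`;
#' contradictory homozygous sites (some pure-A, some pure-B) or a base
#' outside the expected pair give `conflict` (never silently dropped); gaps
#' and Ns are skipped as missing evidence, and a sequence with no usable
#' site is called `missing`.
#'
#' @param seq sequence as a character string or `Biostrings::DNAString`,
#'   aligned to the reference coordinates the table uses (IUPAC codes
#'   permitted; heterozygous Sanger positions are single ambiguity symbols).
#' @param locus marker locus name in the table.
#' @param table a `diagnostic_table`.
#' @param cross optional cross id; restricts to positions marked informative
#'   for that cross (the Sd-region marker lists different positions per
#'   backcross).
#' @param exclude optional integer vector of positions to ignore (per-site
#'   exclusion list for sites known to be polymorphic within races).
#' @return object of class `genotype_call`: list with `locus`, `call`
#'   (`pure_A`/`pure_B`/`hybrid`/`missing`/`conflict`), `race_A`, `race_B`,
#'   `n_sites_used` and an `evidence` data.frame of per-position site calls.
#' @export
call_genotype_at_locus <- function(seq, locus, table, cross = NULL,
                                   exclude = integer()) {
  rows <- informative_rows(table, locus, cross)
  if (nrow(rows) == 0) stop("no diagnostic positions for locus '", locus, "'",
                            call. = FALSE)
  rows <- rows[!rows$position %in% exclude, , drop = FALSE]
  s <- toupper(as.character(seq))
  if (any(rows$position > nchar(s))) {
    stop("diagnostic position beyond sequence length for locus '", locus, "'",
         call. = FALSE)
  }
  site_call <- character(nrow(rows))
  observed <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    sym <- substr(s, rows$position[i], rows$position[i])
    observed[i] <- sym
    if (sym %in% c("N", "-", ".", "?")) { site_call[i] <- "missing"; next }
    set <- tryCatch(decode_iupac(sym), error = function(e) NULL)
    if (is.null(set)) { site_call[i] <- "missing"; next }
    a <- toupper(rows$base_A[i]); b <- toupper(rows$base_B[i])
    site_call[i] <-
      if (setequal(set, a)) "A"
      else if (setequal(set, b)) "B"
      else if (setequal(set, c(a, b))) "het"
      else "incompatible"
  }
  used <- site_call[site_call != "missing"]
  call <-
    if (length(used) == 0) "missing"
    else if (any(used == "incompatible")) "conflict"
    else if (any(used == "A") && any(used == "B")) "conflict"
    else if (any(used == "het")) "hybrid"
    else if (all(used == "A")) "pure_A"
    else "pure_B"
  structure(list(locus = locus, call = call,
                 race_A = rows$race_A[1], race_B = rows$race_B[1],
                 n_sites_used = length(used),
                 evidence = data.frame(position = rows$position,
                                       observed = observed,
                                       site_call = site_call,
                                       stringsAsFactors = FALSE)),
            class = "genotype_call")
}

#' Race-labelled form of a genotype call
#'
#' Translates `pure_A`/`pure_B` into `pure_<race>` using the table's race
#' tags; `hybrid`, `missing` and `conflict` pass through.
#' @param call a `genotype_call`.
#' @return character scalar, e.g. `"pure_pet"`.
#' @export
call_label <- function(call) {
  switch(call$call,
         pure_A = paste0("pure_", call$race_A),
         pure_B = paste0("pure_", call$race_B),
         call$call)
}

#' Call genotypes for a whole brood FASTA
#'
#' Applies [call_genotype_at_locus()] to every record of a multi-FASTA whose
#' headers follow the `individualID|locus` convention used by
#' [simulate_marker_fasta()].
#' @param seqs a named character vector or `Biostrings::DNAStringSet`.
#' @param table a `diagnostic_table`.
#' @param cross optional cross id (see [call_genotype_at_locus()]).
#' @return data.frame with columns `id`, `locus`, `call`, `label`,
#'   `n_sites_used`.
#' @export
call_brood_genotypes <- function(seqs, table, cross = NULL) {
  seqs <- as.character(seqs)
  if (is.null(names(seqs)) || !all(grepl("|", names(seqs), fixed = TRUE))) {
    stop("sequence names must follow 'individualID|locus'", call. = FALSE)
  }
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  out <- lapply(seq_along(seqs), function(i) {
    gc <- call_genotype_at_locus(seqs[[i]], parts[[i]][2], table, cross)
    data.frame(id = parts[[i]][1], locus = parts[[i]][2], call = gc$call,
               label = call_label(gc), n_sites_used = gc$n_sites_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Define a restriction assay
#'
#' @param enzyme enzyme name (default AseI).
#' @param site recognition sequence, plain A/C/G/T (AseI: `ATTAAT`).
#' @param cut_offset cut position within the site, bases after the site
#'   start on the given strand (AseI cuts AT^TAAT, offset 2). Only
#'   cut-vs-uncut pattern identity, not the exact offset, affects genotype
#'   calls.
#' @param diagnostic_position 1-based reference coordinate of the SNP the
#'   site overlaps (required by [call_rflp()]).
#' @return object of class `restriction_assay`.
#' @export
restriction_assay <- function(enzyme = "AseI", site = "ATTAAT", cut_offset = 2L,
                              diagnostic_position = NA_integer_) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) stop("recognition sequence must be non-degenerate A/C/G/T",
                                      call. = FALSE)
  stopifnot(cut_offset >= 0, cut_offset <= nchar(site))
  structure(list(enzyme = enzyme, site = site, cut_offset = as.integer(cut_offset),
                 diagnostic_position = diagnostic_position),
            class = "restriction_assay")
}

#' In-silico restriction digest
#'
#' Cuts a plain A/C/G/T sequence at every occurrence of the recognition site
#' (overlapping occurrences included) and returns fragment lengths, which
#' always sum to the input length. By default the reverse-complement of the
#' site is searched too; for palindromic sites such as ATTAAT this is inert.
#'
#' @param seq character string or `Biostrings::DNAString`.
#' @param assay a `restriction_assay`.
#' @param search_revcomp also search the reverse-complement of the site.
#' @return integer vector of fragment lengths (empty for an empty sequence;
#'   a single full-length fragment when no site occurs).
#' @examples
#' in_silico_digest(paste0(strrep("C", 40), "ATTAAT", strrep("C", 54)),
#'                  restriction_assay())  # 42 58
#' @export
in_silico_digest <- function(seq, assay, search_revcomp = TRUE) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n == 0) return(integer(0))
  if (!grepl("^[ACGT]+$", s)) {
    stop("digest input must be plain A/C/G/T; resolve ambiguity codes first ",
         "(see call_rflp)", call. = FALSE)
  }
  pats <- assay$site
  if (search_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(assay$site)))
    pats <- unique(c(pats, rc))
  }
  starts <- integer(0)
  for (p in pats) {
    m <- Biostrings::matchPattern(p, Biostrings::DNAString(s))
    starts <- c(starts, Biostrings::start(m))
  }
  cuts <- sort(unique(starts - 1L + assay$cut_offset))
  cuts <- cuts[cuts > 0 & cuts < n]
  diff(c(0L, cuts, n))
}

#' RFLP genotype call at a diagnostic SNP
#'
#' Expands the (possibly ambiguous) base at the assay's diagnostic position
#' into the two allele sequences, digests each, and calls `heterozygote` if
#' the fragment patterns differ, `homozygote` otherwise.
#'
#' @param seq sequence record with at most a two-base IUPAC code at the
#'   diagnostic position.
#' @param assay a `restriction_assay` with `diagnostic_position` set.
#' @return list of class `rflp_call`: `call` (`"homozygote"`/
#'   `"heterozygote"`), `cut` (logical per allele: does the site cut near the
#'   SNP), `alleles` (the expanded bases) and `fragments` (list of fragment
#'   length vectors).
#' @export
call_rflp <- function(seq, assay) {
  if (is.na(assay$diagnostic_position)) {
    stop("assay has no diagnostic_position", call. = FALSE)
  }
  s <- toupper(as.character(seq))
  pos <- assay$diagnostic_position
  if (pos < 1 || pos > nchar(s)) stop("diagnostic position outside sequence",
                                      call. = FALSE)
  bases <- decode_iupac(substr(s, pos, pos))
  if (length(bases) > 2) {
    stop("ambiguity code at diagnostic position expands to more than two bases; ",
         "assay unsupported", call. = FALSE)
  }
  alleles <- vapply(bases, function(b) `substr<-`(s, pos, pos, b), "")
  frags <- lapply(alleles, in_silico_digest, assay = assay)
  patterns <- vapply(frags, function(f) paste(sort(f), collapse = ","), "")
  cut <- vapply(frags, function(f) length(f) > 1, logical(1))
  structure(list(call = if (length(unique(patterns)) > 1) "heterozygote" else "homozygote",
                 cut = cut, alleles = bases, fragments = frags),
            class = "rflp_call")
}
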