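#' Round or truncate to significant figures
#'
#' Reporting utility used to reproduce printed statistics. `mode = "round"`
#' applies IEEE round-half-even via [signif()]; `mode = "truncate"` drops
#' digits beyond the requested precision toward zero, which is how some
#' printed values (e.g. probabilities reported as `4.7e-07` when the computed
#' value is `4.768e-07`) were evidently produced.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (>= 1).
#' @param mode `"round"` (default) or `"truncate"`.
#' @return numeric vector at the requested precision.
#' @examples
#' format_signif(0.5^21, 2)              # 4.8e-07
#' format_signif(0.5^21, 2, "truncate")  # 4.7e-07
#' @export
format_signif <- function(x, digits, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), digits >= 1)
  if (mode == "round") return(signif(x, digits))
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi == 0) return(xi)
    s <- 10^(floor(log10(abs(xi))) - digits + 1)
    sign(xi) * floor(abs(xi) / s + 1e-12) * s
  }, numeric(1))
}

# 32-bit FNV-1a hash of a string; used to derive per-brood RNG streams and
# config fingerprints. Arithmetic kept in doubles (exact below 2^53).
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    low <- h %% 256 # xor touches only the low byte; keep arithmetic exact
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiply mod 2^32 without exceeding double precision
    a <- h %/% 65536
    c <- h %% 65536
    h <- (((a * 16777619) %% 65536) * 65536 + c * 16777619) %% 2^32
  }
  h
}

#' Fingerprint a configuration object
#'
#' Stable 8-hex-digit hash of any jsonlite-serialisable object, embedded in
#' output files so reruns can be matched to the configuration that produced
#' them.
#' @param x an R object (list, data.frame, ...).
#' @return character scalar, eight hex digits.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- fnv1a32(as.character(json))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# IUPAC tables built once from Biostrings' canonical map.
.iupac_env <- new.env(parent = emptyenv())

.iupac_tables <- function() {
  if (is.null(.iupac_env$decode)) {
    map <- Biostrings::IUPAC_CODE_MAP
    dec <- lapply(strsplit(unname(map), ""), sort)
    names(dec) <- names(map)
    enc <- names(map)
    names(enc) <- vapply(dec, paste, "", collapse = "")
    .iupac_env$decode <- dec
    .iupac_env$encode <- enc
  }
  .iupac_env
}

#' Decode an IUPAC nucleotide code
#'
#' @param symbol single-character IUPAC code (case-insensitive).
#' @return character vector of the bases the code stands for (sorted);
#'   unambiguous bases return themselves.
#' @examples
#' decode_iupac("R")  # "A" "G"
#' decode_iupac("Y")  # "C" "T"
#' @export
decode_iupac <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  tab <- .iupac_tables()$decode
  sym <- toupper(symbol)
  if (is.null(tab[[sym]])) {
    stop("invalid IUPAC nucleotide code: '", symbol, "'", call. = FALSE)
  }
  tab[[sym]]
}

#' Encode a set of bases as an IUPAC code
#'
#' Inverse of [decode_iupac()]; used when writing heterozygous positions into
#' simulated marker sequences.
#' @param bases character vector of bases from A/C/G/T.
#' @return single IUPAC symbol covering exactly those bases.
#' @export
encode_iupac <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be from A/C/G/T, got: ", paste(bases, collapse = ","),
         call. = FALSE)
  }
  unname(.iupac_tables()$encode[paste(bases, collapse = "")])
}
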