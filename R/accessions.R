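#' Gene accession utilities
#'
#' Accessions identify gene function families from three sources: KEGG
#' Orthology (KO, `K` + five digits, e.g. `"K02588"`), NCBI Clusters of
#' Orthologous Genes (COG, `COG` + digits, e.g. `"COG2710"`), and Enzyme
#' Commission numbers (EC, one to four dot-separated fields, each a positive
#' integer or the wildcard marker `*`/`-`, e.g. `"1.4.1.2"` or `"1.4.*"`).
#' Accessions are plain character strings; `accession_source()` classifies
#' them and `is_valid_accession()` validates.
#'
#' @param x character vector of accession codes.
#' @return `accession_source()` returns a character vector with elements
#'   `"KO"`, `"COG"`, `"EC"` or `NA` for unrecognised codes;
#'   `is_valid_accession()` returns a logical vector.
#' @examples
#' accession_source(c("K02588", "COG2710", "1.4.1.2", "oops"))
#' @export
accession_source <- function(x) {
  stopifnot(is.character(x))
  out <- rep(NA_character_, length(x))
  out[grepl("^K[0-9]{5}$", x)] <- "KO"
  out[grepl("^COG[0-9]+$", x)] <- "COG"
  is_ec <- grepl("^[0-9]+(\\.([0-9]+|\\*|-)){0,3}$", x) &
    vapply(x, ec_wildcard_ok, logical(1))
  out[is.na(out) & is_ec] <- "EC"
  out
}

# wildcard fields ('*' or '-') may only appear as a trailing run
ec_wildcard_ok <- function(code) {
  fields <- strsplit(code, ".", fixed = TRUE)[[1]]
  wild <- fields %in% c("*", "-")
  if (!any(wild)) return(TRUE)
  all(wild[seq(which(wild)[1], length(fields))])
}

#' @rdname accession_source
#' @export
is_valid_accession <- function(x) !is.na(accession_source(x))

#' Normalize an accession code
#'
#' Strips an optional `EC:` prefix from EC codes and leading/trailing
#' whitespace; KO and COG codes pass through unchanged. Unrecognised codes
#' raise an error when `strict = TRUE`.
#'
#' @param x character vector of raw codes.
#' @param strict error on codes that fail validation after normalization.
#' @return character vector of normalized codes.
#' @export
normalize_accession <- function(x, strict = TRUE) {
  x <- trimws(x)
  x <- sub("^(EC|ec):", "", x)
  if (strict && any(bad <- !is_valid_accession(x))) {
    stop("malformed accession token(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

# COG numbers compare by integer value: the literature often drops leading
# zeros ("COG 347" for COG0347). cog_number() returns NA for non-COG codes.
cog_number <- function(x) {
  n <- rep(NA_integer_, length(x))
  is_cog <- grepl("^COG[0-9]+$", x)
  n[is_cog] <- as.integer(sub("^COG", "", x[is_cog]))
  n
}

#' Test whether two accession codes refer to the same entity
#'
#' KO and EC codes compare as exact strings; COG codes compare by their
#' integer part so that `"COG347"` and `"COG0347"` (two spellings of the
#' nitrogen-regulatory PII protein's COG) are equal.
#'
#' @param a,b character vectors, recycled to common length.
#' @return logical vector.
#' @export
accession_equal <- function(a, b) {
  na <- cog_number(a)
  nb <- cog_number(b)
  ifelse(!is.na(na) & !is.na(nb), na == nb, a == b)
}

#' Match an EC number against an EC wildcard pattern
#'
#' Patterns use field-wise prefix semantics on the dot-separated EC fields:
#' `"1.4.*"` matches every EC number whose first field is 1 and second field
#' is 4 (`"1.4.1.2"` yes; `"1.14.13.25"` no — the comparison is per field,
#' not per character). A pattern without a wildcard requires full equality.
#' The wildcard (`*` or `-`) is only allowed as a trailing run of fields.
#'
#' @param pattern a single EC pattern, e.g. `"1.4.*"` or `"3.5.1.5"`.
#' @param ec character vector of EC numbers to test.
#' @return logical vector, one element per `ec`.
#' @examples
#' match_ec_wildcard("1.4.*", c("1.4.1.2", "1.14.13.25"))
#' @export
match_ec_wildcard <- function(pattern, ec) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  pattern <- normalize_accession(pattern, strict = FALSE)
  if (is.na(accession_source(pattern)) || accession_source(pattern) != "EC")
    stop("malformed EC pattern: ", pattern, call. = FALSE)
  pf <- strsplit(pattern, ".", fixed = TRUE)[[1]]
  spec <- pf[!pf %in% c("*", "-")]
  has_wild <- length(spec) < length(pf)
  vapply(ec, function(code) {
    cf <- strsplit(code, ".", fixed = TRUE)[[1]]
    if (has_wild) {
      length(cf) >= length(spec) && all(cf[seq_along(spec)] == spec)
    } else {
      length(cf) == length(spec) && all(cf == spec)
    }
  }, logical(1), USE.NAMES = FALSE)
}
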