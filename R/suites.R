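#' @title Gene-suite screens
#'
#' @description
#' A gene suite is a named list of accession patterns — exact KO/COG codes
#' or EC wildcards such as `"1.4.*"` — screened against a MAG under the
#' ANY rule: the suite is called present as soon as one annotated gene
#' matches one pattern. This is the rule used for transporter gene sets
#' and ammonification hydrolases in Boolean presence/absence heatmaps,
#' where partial pathways still indicate the capability of interest.
#'
#' @name gene_suites
NULL

#' Construct a gene suite
#'
#' @param suite_name suite label, e.g. `"Ammonification Hydrolases"`.
#' @param patterns character vector of accession patterns: exact KO or COG
#'   codes, exact EC numbers, or EC wildcards (`"1.4.*"`). An optional
#'   `EC:` prefix is stripped.
#' @return a `gene_suite` object (rule is always ANY).
#' @export
gene_suite <- function(suite_name, patterns) {
  stopifnot(is.character(suite_name), length(suite_name) == 1L,
            nzchar(suite_name))
  patterns <- normalize_accession(patterns, strict = FALSE)
  if (!length(patterns)) stop("suite needs at least one pattern", call. = FALSE)
  bad <- !is_valid_accession(patterns)
  if (any(bad))
    stop("invalid pattern(s) in suite '", suite_name, "': ",
         paste(patterns[bad], collapse = ", "), call. = FALSE)
  structure(list(suite_name = suite_name, patterns = patterns, rule = "ANY"),
            class = "gene_suite")
}

#' @export
print.gene_suite <- function(x, ...) {
  cat(sprintf("<gene_suite> %s (ANY of %d pattern(s))\n",
              x$suite_name, length(x$patterns)))
  invisible(x)
}

#' Load gene suites from a two-column TSV file
#'
#' Expects columns `suite_name` and `pattern`; rows are grouped by suite
#' in file order, `EC:` prefixes are stripped, and duplicate
#' (suite, pattern) rows are dropped with a warning. Invalid patterns are
#' a format error naming the offending line.
#'
#' @param path path to the suites TSV.
#' @return a named list of `gene_suite` objects, in first-appearance order.
#' @export
load_suites <- function(path) {
  df <- read_tsv_checked(path, c("suite_name", "pattern"), "suites")
  if (!nrow(df)) stop("suites file has no rows: ", path, call. = FALSE)
  df$pattern <- normalize_accession(df$pattern, strict = FALSE)
  bad <- which(!is_valid_accession(df$pattern))
  if (length(bad))
    stop("invalid pattern '", df$pattern[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path, call. = FALSE)
  dup <- duplicated(df[, c("suite_name", "pattern")])
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate (suite, pattern) row(s) in ",
            path, call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  names_in_order <- unique(df$suite_name)
  out <- lapply(names_in_order, function(nm) {
    gene_suite(nm, df$pattern[df$suite_name == nm])
  })
  stats::setNames(out, names_in_order)
}

# accessions a pattern can be matched against within one MAG; EC patterns
# may additionally consult "(EC x.x.x.x)" tags embedded in function text
# when use_function_text_ec = TRUE
mag_match_accessions <- function(mag, use_function_text_ec = FALSE) {
  acc <- mag$annotations$accession
  if (use_function_text_ec) {
    hits <- regmatches(mag$annotations$function_text,
                       gregexpr("\\(EC[: ]([0-9]+(\\.[0-9]+){1,3})\\)",
                                mag$annotations$function_text))
    embedded <- unlist(hits)
    if (length(embedded))
      acc <- c(acc, gsub("^\\(EC[: ]|\\)$", "", embedded))
  }
  unique(acc)
}

#' Screen one MAG for one gene suite
#'
#' @param suite a `gene_suite`.
#' @param mag a `mag_annotation_set`.
#' @param use_function_text_ec also match EC patterns against `(EC x.x.x.x)`
#'   tags embedded in the annotation function text (default `FALSE`).
#' @return a `suite_result`: list with `suite_name`, `mag_id`, `present`
#'   (TRUE iff any annotation matches any pattern) and
#'   `matched_accessions`.
#' @export
screen_suite <- function(suite, mag, use_function_text_ec = FALSE) {
  stopifnot(inherits(suite, "gene_suite"), inherits(mag, "mag_annotation_set"))
  acc <- mag_match_accessions(mag, use_function_text_ec)
  src <- accession_source(acc)
  matched <- character(0)
  for (pat in suite$patterns) {
    psrc <- accession_source(pat)
    hit <- if (psrc == "EC") {
      ec_codes <- acc[!is.na(src) & src == "EC"]
      ec_codes[match_ec_wildcard(pat, ec_codes)]
    } else {
      acc[accession_equal(acc, pat)]
    }
    matched <- c(matched, hit)
  }
  matched <- sort(unique(matched))
  structure(list(suite_name = suite$suite_name, mag_id = mag$mag_id,
                 present = length(matched) > 0L,
                 matched_accessions = matched),
            class = "suite_result")
}

#' Screen every MAG for every suite
#'
#' @param suites named list of `gene_suite` objects.
#' @param mags named list of `mag_annotation_set` objects.
#' @param use_function_text_ec passed to [screen_suite()].
#' @return a data.frame ordered by `(mag_id, suite_name)` with columns
#'   `mag_id`, `suite_name`, `present`, `matched_accessions`
#'   (semicolon-joined).
#' @export
screen_suites <- function(suites, mags, use_function_text_ec = FALSE) {
  if (!length(suites) || !length(mags))
    stop("suites and mags must be non-empty", call. = FALSE)
  mag_ids <- vapply(mags, `[[`, "", "mag_id")
  suite_names <- vapply(suites, `[[`, "", "suite_name")
  rows <- list()
  for (mag in mags[order(mag_ids)]) {
    for (suite in suites[order(suite_names)]) {
      r <- screen_suite(suite, mag, use_function_text_ec)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = r$mag_id, suite_name = r$suite_name, present = r$present,
        matched_accessions = paste(r$matched_accessions, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
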