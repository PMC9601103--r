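#' @title Boolean metabolism-by-MAG matrix
#'
#' @description
#' Assembles the presence/absence matrix behind a metabolism heatmap: one
#' row per feature (a KEGG module called by the completeness engine, a
#' gene suite under the ANY rule, or the nitrogen-fixation screen), one
#' column per MAG. Rows are grouped by benefit direction — metabolisms
#' that might benefit the host versus metabolisms that might use
#' host-provisioned metabolites — and columns by oxygen exposure, host
#' species, tissue and MAG id, so the layout is a pure function of the
#' metadata.
#'
#' @name heatmap_report
NULL

NIF_FEATURE <- "Nitrogen Fixation (nifH+nifD)"

#' Extract the MAG metadata table from a MAG collection
#'
#' @param mags named list of `mag_annotation_set` objects.
#' @return a data.frame with columns `mag_id`, `sample_id`,
#'   `host_species`, `tissue_type`, `oxygen_class`.
#' @export
mags_metadata <- function(mags) {
  out <- do.call(rbind, lapply(mags, function(m) {
    data.frame(mag_id = m$mag_id, sample_id = m$sample_id,
               host_species = m$host_species, tissue_type = m$tissue_type,
               oxygen_class = m$oxygen_class, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the metabolism-by-MAG Boolean matrix
#'
#' @param completeness data.frame from [score_all()] (or `NULL`); module
#'   features use the `present` flag and are named by `module_id`.
#' @param suites data.frame from [screen_suites()] (or `NULL`).
#' @param nif data.frame from [screen_nif_all()] (or `NULL`); contributes
#'   one feature row using the `passes` flag.
#' @param metadata data.frame with columns `mag_id`, `sample_id`,
#'   `host_species`, `tissue_type`, `oxygen_class` (see
#'   [mags_metadata()]). Every MAG referenced by a result must appear here.
#' @param groups optional data.frame with columns `feature_name`,
#'   `benefit_group` mapping features to `"hosts_benefit"` or
#'   `"microbes_benefit"`; unmapped features fall into `"unassigned"`.
#' @return a `metabolism_matrix`: list with `features` (row table),
#'   `mags` (column table) and `values` (logical matrix). Missing
#'   (feature, MAG) pairs are `FALSE` with a warning; rows and columns are
#'   canonically sorted, so permuting the input rows changes nothing.
#' @export
build_matrix <- function(completeness = NULL, suites = NULL, nif = NULL,
                         metadata, groups = NULL) {
  cells <- list()
  add <- function(feature, kind, mag, value) {
    cells[[length(cells) + 1L]] <<- data.frame(
      feature_name = feature, feature_kind = kind, mag_id = mag,
      value = value, stringsAsFactors = FALSE)
  }
  if (!is.null(completeness) && nrow(completeness))
    add(completeness$module_id, "module", completeness$mag_id,
        completeness$present)
  if (!is.null(suites) && nrow(suites))
    add(suites$suite_name, "suite", suites$mag_id, suites$present)
  if (!is.null(nif) && nrow(nif))
    add(NIF_FEATURE, "nif", nif$mag_id, nif$passes)
  if (!length(cells))
    stop("at least one non-empty result table is required", call. = FALSE)
  cells <- do.call(rbind, cells)

  if (anyDuplicated(cells[, c("feature_name", "mag_id")]))
    stop("duplicate (feature, MAG) result rows", call. = FALSE)
  unknown <- setdiff(cells$mag_id, metadata$mag_id)
  if (length(unknown))
    stop("results reference MAG(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  feats <- unique(cells[, c("feature_name", "feature_kind")])
  if (is.null(groups))
    groups <- data.frame(feature_name = character(),
                         benefit_group = character(),
                         stringsAsFactors = FALSE)
  feats$benefit_group <- groups$benefit_group[
    match(feats$feature_name, groups$feature_name)]
  feats$benefit_group[is.na(feats$benefit_group)] <- "unassigned"
  feats <- feats[order(feats$benefit_group, feats$feature_kind,
                       feats$feature_name), , drop = FALSE]
  rownames(feats) <- NULL

  cols <- metadata[, c("mag_id", "sample_id", "host_species", "tissue_type",
                       "oxygen_class")]
  cols <- cols[order(cols$oxygen_class, cols$host_species, cols$tissue_type,
                     cols$mag_id), , drop = FALSE]
  rownames(cols) <- NULL

  values <- matrix(FALSE, nrow = nrow(feats), ncol = nrow(cols),
                   dimnames = list(feats$feature_name, cols$mag_id))
  idx <- cbind(match(cells$feature_name, feats$feature_name),
               match(cells$mag_id, cols$mag_id))
  values[idx] <- cells$value
  n_missing <- nrow(feats) * nrow(cols) - nrow(cells)
  if (n_missing > 0L)
    warning(n_missing, " (feature, MAG) pair(s) had no result; set to FALSE",
            call. = FALSE)

  structure(list(features = feats, mags = cols, values = values),
            class = "metabolism_matrix")
}

#' @export
print.metabolism_matrix <- function(x, ...) {
  cat(sprintf("<metabolism_matrix> %d feature(s) x %d MAG(s), %d present\n",
              nrow(x$features), nrow(x$mags), sum(x$values)))
  invisible(x)
}

#' Write a metabolism matrix to disk
#'
#' The TSV layout is: four `#`-prefixed column-metadata lines (sample,
#' host, tissue, oxygen class), a header row naming the MAG columns, then
#' one 0/1 row per feature. The JSON format mirrors the same structure.
#' Both round-trip exactly through [read_matrix()].
#'
#' @param m a `metabolism_matrix`.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "metabolism_matrix"))
  if (format == "tsv") {
    meta_line <- function(key) {
      paste(c(paste0("#", key), "", "", as.character(m$mags[[key]])),
            collapse = "\t")
    }
    header <- paste(c("feature_name", "feature_kind", "benefit_group",
                      m$mags$mag_id), collapse = "\t")
    rows <- vapply(seq_len(nrow(m$features)), function(i) {
      paste(c(m$features$feature_name[i], m$features$feature_kind[i],
              m$features$benefit_group[i],
              as.integer(m$values[i, ])), collapse = "\t")
    }, "")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c(meta_line("sample_id"), meta_line("host_species"),
                 meta_line("tissue_type"), meta_line("oxygen_class"),
                 header, rows), con, sep = "\n")
  } else {
    obj <- list(features = m$features, mags = m$mags,
                values = unname(apply(m$values, 1L, as.integer,
                                      simplify = FALSE)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a metabolism matrix written by [write_matrix()]
#'
#' @param path file path.
#' @param format `"tsv"` or `"json"`; default guesses from the extension.
#' @return a `metabolism_matrix`.
#' @export
read_matrix <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    v <- obj$values
    if (is.list(v)) v <- do.call(rbind, lapply(v, as.integer))
    values <- matrix(as.logical(as.integer(v)),
                     nrow = length(obj$features$feature_name),
                     ncol = length(obj$mags$mag_id))
    dimnames(values) <- list(obj$features$feature_name, obj$mags$mag_id)
    return(structure(list(features = as.data.frame(obj$features),
                          mags = as.data.frame(obj$mags),
                          values = values),
                     class = "metabolism_matrix"))
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  mag_ids <- header[-(1:3)]
  meta <- lapply(meta_lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  meta_key <- vapply(meta, function(f) sub("^#", "", f[1]), "")
  meta_val <- lapply(meta, function(f) {
    v <- f[-(1:3)]
    length(v) <- length(mag_ids)  # pad truncated trailing NAs
    v[!is.na(v) & v == "NA"] <- NA
    v
  })
  names(meta_val) <- meta_key
  mags <- data.frame(mag_id = mag_ids,
                     sample_id = meta_val[["sample_id"]],
                     host_species = meta_val[["host_species"]],
                     tissue_type = meta_val[["tissue_type"]],
                     oxygen_class = meta_val[["oxygen_class"]],
                     stringsAsFactors = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  features <- data.frame(
    feature_name = vapply(rows, `[[`, "", 1L),
    feature_kind = vapply(rows, `[[`, "", 2L),
    benefit_group = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  values <- do.call(rbind, lapply(rows, function(r)
    as.logical(as.integer(r[-(1:3)]))))
  dimnames(values) <- list(features$feature_name, mags$mag_id)
  structure(list(features = features, mags = mags, values = values),
            class = "metabolism_matrix")
}

#' Render a metabolism matrix as a simple tile plot
#'
#' A convenience base-graphics rendering; the TSV written by
#' [write_matrix()] is the contract, not the plot.
#'
#' @param m a `metabolism_matrix`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `m`.
#' @export
plot_matrix <- function(m, ...) {
  stopifnot(inherits(m, "metabolism_matrix"))
  v <- m$values[rev(seq_len(nrow(m$values))), , drop = FALSE]
  graphics::image(t(v) * 1, axes = FALSE,
                  col = c("grey95", "steelblue4"), ...)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(v)),
                 labels = rownames(v), las = 2, cex.axis = 0.6, tick = FALSE)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(v)),
                 labels = colnames(v), las = 2, cex.axis = 0.6, tick = FALSE)
  invisible(m)
}
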