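#' @title Per-MAG gene annotations
#'
#' @description
#' Readers and helpers for per-MAG gene functional annotations in the
#' shape exported from an anvi'o contigs database: a functions table (one
#' row per gene hit: gene id, contig, annotation source, accession,
#' function text, e-value), a bin-membership table (contig to MAG), and a
#' MAG metadata table (sample, host, tissue, oxygen exposure, completion
#' and redundancy estimates). Genes on contigs absent from the bin table
#' are collected under the reserved MAG id `"UNBINNED"`.
#'
#' @name annotation_store
NULL

UNBINNED_MAG <- "UNBINNED"

TISSUE_TYPES <- c("blade", "rhizome", "sediment", "bulb")
OXYGEN_CLASSES <- c("water_column", "low_oxygen")

#' Construct a MAG annotation set
#'
#' @param mag_id MAG identifier (unique within a collection).
#' @param annotations data.frame with columns `gene_id`, `contig_id`,
#'   `gene_order_on_contig`, `source`, `accession`, `function_text`,
#'   `e_value`.
#' @param sample_id,host_species,tissue_type,oxygen_class sample metadata.
#' @param completion_pct,redundancy_pct single-copy-gene quality estimates
#'   in \[0, 100\] (consumed as metadata, not computed here).
#' @return a `mag_annotation_set` object.
#' @export
mag_annotation_set <- function(mag_id, annotations = empty_annotations(),
                               sample_id = NA_character_,
                               host_species = NA_character_,
                               tissue_type = NA_character_,
                               oxygen_class = NA_character_,
                               completion_pct = NA_real_,
                               redundancy_pct = NA_real_) {
  stopifnot(is.character(mag_id), length(mag_id) == 1L, nzchar(mag_id))
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  needed <- colnames(empty_annotations())
  missing_cols <- setdiff(needed, colnames(annotations))
  if (length(missing_cols))
    stop("annotations table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  annotations <- annotations[, needed]
  if (any(annotations$e_value < 0))
    stop("e_value must be non-negative", call. = FALSE)
  structure(list(
    mag_id = mag_id,
    sample_id = sample_id,
    host_species = host_species,
    tissue_type = tissue_type,
    oxygen_class = oxygen_class,
    completion_pct = completion_pct,
    redundancy_pct = redundancy_pct,
    annotations = annotations,
    contig_ids = unique(annotations$contig_id)
  ), class = "mag_annotation_set")
}

empty_annotations <- function() {
  data.frame(gene_id = character(), contig_id = character(),
             gene_order_on_contig = integer(), source = character(),
             accession = character(), function_text = character(),
             e_value = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.mag_annotation_set <- function(x, ...) {
  cat(sprintf("<mag_annotation_set> %s: %d annotations on %d contig(s)\n",
              x$mag_id, nrow(x$annotations), length(x$contig_ids)))
  invisible(x)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("cannot read ", what, " file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "#")
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop(what, " file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Read annotation, bin-membership and metadata tables
#'
#' Assembles per-MAG annotation sets from three tab-separated files:
#'
#' * `functions_path`: columns `gene_callers_id`, `contig`, `source`,
#'   `accession`, `function`, `e_value` (anvi'o functions export shape);
#' * `bins_path`: columns `contig`, `bin_name`;
#' * `metadata_path` (optional): columns `bin_name`, `sample_id`,
#'   `host_species`, `tissue_type`, `oxygen_class`, `completion_pct`,
#'   `redundancy_pct`.
#'
#' Gene order on each contig is assigned 0-based from file order. Genes on
#' contigs missing from the bin table are routed to the reserved MAG
#' `"UNBINNED"` with a warning. MAGs listed in the metadata but absent from
#' the functions file are created empty.
#'
#' @param functions_path,bins_path,metadata_path file paths; set
#'   `metadata_path = NULL` to skip metadata.
#' @return a named list of `mag_annotation_set` objects, ordered by
#'   `mag_id`.
#' @export
read_annotations <- function(functions_path, bins_path, metadata_path = NULL) {
  fns <- read_tsv_checked(functions_path,
                          c("gene_callers_id", "contig", "source",
                            "accession", "e_value"),
                          "functions")
  if (!"function" %in% colnames(fns)) fns$`function` <- ""
  bins <- read_tsv_checked(bins_path, c("contig", "bin_name"), "bins")
  bin_of <- stats::setNames(bins$bin_name, bins$contig)

  ord <- stats::ave(seq_len(nrow(fns)), fns$contig, FUN = seq_along) - 1L
  mag_id <- unname(bin_of[fns$contig])
  unmapped <- is.na(mag_id)
  if (any(unmapped)) {
    warning(sum(unmapped), " gene(s) on ",
            length(unique(fns$contig[unmapped])),
            " contig(s) absent from the bin table; routed to ", UNBINNED_MAG,
            call. = FALSE)
    mag_id[unmapped] <- UNBINNED_MAG
  }
  ann <- data.frame(
    gene_id = fns$gene_callers_id,
    contig_id = fns$contig,
    gene_order_on_contig = as.integer(ord),
    source = fns$source,
    accession = normalize_accession(fns$accession, strict = FALSE),
    function_text = fns$`function`,
    e_value = as.numeric(fns$e_value),
    stringsAsFactors = FALSE)

  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- read_tsv_checked(metadata_path,
                             c("bin_name", "sample_id", "host_species",
                               "tissue_type", "oxygen_class",
                               "completion_pct", "redundancy_pct"),
                             "metadata")
    rownames(meta) <- meta$bin_name
  }

  ids <- sort(unique(c(mag_id, if (!is.null(meta)) meta$bin_name)))
  out <- lapply(ids, function(id) {
    m <- if (!is.null(meta) && id %in% rownames(meta)) meta[id, ] else NULL
    mag_annotation_set(
      mag_id = id,
      annotations = ann[mag_id == id, , drop = FALSE],
      sample_id = if (is.null(m)) NA_character_ else m$sample_id,
      host_species = if (is.null(m)) NA_character_ else m$host_species,
      tissue_type = if (is.null(m)) NA_character_ else m$tissue_type,
      oxygen_class = if (is.null(m)) NA_character_ else m$oxygen_class,
      completion_pct = if (is.null(m)) NA_real_ else as.numeric(m$completion_pct),
      redundancy_pct = if (is.null(m)) NA_real_ else as.numeric(m$redundancy_pct))
  })
  stats::setNames(out, ids)
}

#' Write annotation sets back to functions/bins/metadata tables
#'
#' Inverse of [read_annotations()] up to column order and float
#' formatting; useful for building reproducible fixtures.
#'
#' @param mags named list of `mag_annotation_set` objects.
#' @param functions_path,bins_path,metadata_path output file paths; any
#'   may be `NULL` to skip that table.
#' @return invisibly, the list of written paths.
#' @export
write_annotations <- function(mags, functions_path = NULL, bins_path = NULL,
                              metadata_path = NULL) {
  mags <- mags[order(vapply(mags, `[[`, "", "mag_id"))]
  if (!is.null(functions_path)) {
    ann <- do.call(rbind, lapply(mags, `[[`, "annotations"))
    fns <- data.frame(gene_callers_id = ann$gene_id, contig = ann$contig_id,
                      source = ann$source, accession = ann$accession,
                      "function" = ann$function_text,
                      e_value = format(ann$e_value, scientific = TRUE, trim = TRUE),
                      stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(fns, functions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bins_path)) {
    rows <- do.call(rbind, lapply(mags, function(m) {
      if (!length(m$contig_ids)) return(NULL)
      data.frame(contig = sort(m$contig_ids), bin_name = m$mag_id,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(rows, bins_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(metadata_path)) {
    meta <- do.call(rbind, lapply(mags, function(m) {
      data.frame(bin_name = m$mag_id, sample_id = m$sample_id,
                 host_species = m$host_species, tissue_type = m$tissue_type,
                 oxygen_class = m$oxygen_class,
                 completion_pct = m$completion_pct,
                 redundancy_pct = m$redundancy_pct, stringsAsFactors = FALSE)
    }))
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(functions_path, bins_path, metadata_path))
}

#' Filter a MAG's annotations by per-source e-value cutoffs
#'
#' The comparison is strictly less-than (`e_value < threshold`), matching
#' the "< 1e-100" convention of marker-gene screens: a hit at exactly the
#' cutoff is removed. Sources absent from `thresholds` pass unfiltered, so
#' an empty map is the identity. Filtering is idempotent.
#'
#' @param mag a `mag_annotation_set`.
#' @param thresholds named numeric vector or list mapping annotation
#'   source (e.g. `"KOfam"`) to its maximum e-value; values must be >= 0.
#' @return the filtered `mag_annotation_set`.
#' @export
filter_by_evalue <- function(mag, thresholds) {
  stopifnot(inherits(mag, "mag_annotation_set"))
  thresholds <- unlist(thresholds)
  if (length(thresholds) == 0L) return(mag)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stop("thresholds must be named by annotation source", call. = FALSE)
  if (any(thresholds < 0)) stop("e-value thresholds must be >= 0", call. = FALSE)
  ann <- mag$annotations
  cut <- thresholds[ann$source]
  keep <- is.na(cut) | ann$e_value < cut
  mag$annotations <- ann[keep, , drop = FALSE]
  rownames(mag$annotations) <- NULL
  mag
}

#' Classify MAG quality from completion and redundancy estimates
#'
#' High quality requires a completion score above 90% and redundancy
#' (contamination) below 10%; medium quality covers completion between 42%
#' and 90% with redundancy between 0% and 11%, endpoints inclusive; all
#' other combinations are unclassified. The high rule is applied first, so
#' the bands are disjoint (a genome with completion > 90 and redundancy in
#' \[10, 11\] is unclassified, falling in neither band).
#'
#' @param completion_pct,redundancy_pct numeric vectors in \[0, 100\],
#'   recycled to a common length.
#' @return character vector with elements `"high"`, `"medium"` or
#'   `"unclassified"`.
#' @examples
#' classify_mag_quality(c(95, 42, 30), c(5, 11, 2))
#' @export
classify_mag_quality <- function(completion_pct, redundancy_pct) {
  n <- max(length(completion_pct), length(redundancy_pct))
  completion_pct <- rep_len(as.numeric(completion_pct), n)
  redundancy_pct <- rep_len(as.numeric(redundancy_pct), n)
  if (any(is.na(completion_pct)) || any(is.na(redundancy_pct)) ||
      any(completion_pct < 0 | completion_pct > 100) ||
      any(redundancy_pct < 0 | redundancy_pct > 100))
    stop("completion_pct and redundancy_pct must lie in [0, 100]", call. = FALSE)
  band <- rep("unclassified", n)
  medium <- completion_pct >= 42 & completion_pct <= 90 & redundancy_pct <= 11
  band[medium] <- "medium"
  high <- completion_pct > 90 & redundancy_pct < 10
  band[high] <- "high"
  band
}

#' The deduplicated set of accessions annotated in a MAG
#'
#' @param mag a `mag_annotation_set`.
#' @return a sorted character vector of unique accession codes across all
#'   genes and annotation sources.
#' @export
accessions_present <- function(mag) {
  stopifnot(inherits(mag, "mag_annotation_set"))
  sort(unique(mag$annotations$accession))
}
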