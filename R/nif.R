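#' @title Nitrogen-fixation marker screen
#'
#' @description
#' Flags MAGs carrying credible nitrogenase genes: both the iron-protein
#' subunit gene *nifH* (KO K02588) and the molybdenum-iron alpha-subunit
#' gene *nifD* (KO K02586) must be hit by KOfam annotations with e-values
#' strictly below 1e-100. COG-based *nifH* calls (COG1348) are reported
#' only as an advisory, never as evidence: that COG also covers the
#' homologous protochlorophyllide reductase subunits of photosynthetic
#' pigment synthesis, a classic *nifH* false-positive trap. For passing
#' MAGs, accessory nitrogen-fixation genes co-located on the *nifH* contig
#' (*nifD* COG2710, the PII regulatory protein COG0347, *nifB* COG0535)
#' are reported with gene-order distances.
#'
#' @name nif_screen
NULL

#' Configuration for the nitrogen-fixation screen
#'
#' @param nifH_ko,nifD_ko KO accessions of the two required markers.
#' @param e_max strict e-value cutoff; a hit at exactly `e_max` does not
#'   count.
#' @param accessory COG accessions reported when co-located on a *nifH*
#'   contig. Spellings without leading zeros (`"COG347"`) are accepted and
#'   match their zero-padded forms.
#' @param exclude homologous accessions reported as advisory only
#'   (default COG1348, which includes protochlorophyllide reductase).
#' @param require_same_contig require *nifH* and *nifD* on the same contig
#'   rather than merely the same MAG (default `FALSE`: same-MAG).
#' @return a `nif_screen_config` list.
#' @export
nif_screen_config <- function(nifH_ko = "K02588", nifD_ko = "K02586",
                              e_max = 1e-100,
                              accessory = c("COG2710", "COG347", "COG535"),
                              exclude = "COG1348",
                              require_same_contig = FALSE) {
  stopifnot(is.numeric(e_max), length(e_max) == 1L, e_max > 0)
  nifH_ko <- normalize_accession(nifH_ko)
  nifD_ko <- normalize_accession(nifD_ko)
  if (identical(nifH_ko, nifD_ko))
    stop("nifH_ko and nifD_ko must differ", call. = FALSE)
  structure(list(nifH_ko = nifH_ko, nifD_ko = nifD_ko, e_max = e_max,
                 accessory = normalize_accession(accessory),
                 exclude = normalize_accession(exclude),
                 require_same_contig = isTRUE(require_same_contig)),
            class = "nif_screen_config")
}

marker_hits <- function(ann, ko, e_max) {
  hit <- ann$source == "KOfam" & accession_equal(ann$accession, ko) &
    ann$e_value < e_max
  ann[hit, c("gene_id", "contig_id", "gene_order_on_contig", "e_value"),
      drop = FALSE]
}

#' Screen one MAG for nitrogen-fixation markers
#'
#' @param mag a `mag_annotation_set`.
#' @param cfg a [nif_screen_config()].
#' @return a `nif_screen_result`: list with `mag_id`, `passes` (both
#'   markers hit below the cutoff), `nifH_hits` and `nifD_hits`
#'   (data.frames of qualifying hits), `homolog_advisory` (data.frame of
#'   excluded-homolog hits, e.g. COG1348), and `cooccurring_accessory`
#'   (filled by [contig_cooccurrence()]; empty here).
#' @export
screen_nif <- function(mag, cfg = nif_screen_config()) {
  stopifnot(inherits(mag, "mag_annotation_set"),
            inherits(cfg, "nif_screen_config"))
  ann <- mag$annotations
  nifH <- marker_hits(ann, cfg$nifH_ko, cfg$e_max)
  nifD <- marker_hits(ann, cfg$nifD_ko, cfg$e_max)
  passes <- nrow(nifH) > 0L && nrow(nifD) > 0L
  if (passes && cfg$require_same_contig)
    passes <- length(intersect(nifH$contig_id, nifD$contig_id)) > 0L
  adv <- ann[vapply(ann$accession, function(a)
    any(accession_equal(a, cfg$exclude)), logical(1)), , drop = FALSE]
  structure(list(
    mag_id = mag$mag_id,
    passes = passes,
    nifH_hits = nifH,
    nifD_hits = nifD,
    homolog_advisory = adv[, c("gene_id", "contig_id", "accession", "e_value"),
                           drop = FALSE],
    cooccurring_accessory = list()
  ), class = "nif_screen_result")
}

#' @export
print.nif_screen_result <- function(x, ...) {
  cat(sprintf("<nif_screen_result> %s: %s (nifH hits: %d, nifD hits: %d)\n",
              x$mag_id, if (x$passes) "PASSES" else "fails",
              nrow(x$nifH_hits), nrow(x$nifD_hits)))
  invisible(x)
}

#' Report accessory nif genes co-located on nifH contigs
#'
#' For each contig bearing a qualifying *nifH* hit in a passing MAG, lists
#' which accessory accessions (by default *nifD* COG2710, PII COG0347,
#' *nifB* COG0535) occur on that same contig, with the gene-order distance
#' to the nearest *nifH* gene. MAGs that fail the screen get an empty map.
#'
#' @param mag the `mag_annotation_set` the screen was run on.
#' @param result the `nif_screen_result` from [screen_nif()] on `mag`.
#' @param cfg the same [nif_screen_config()].
#' @return `result` with `cooccurring_accessory` filled: a named list
#'   (one element per *nifH* contig) of data.frames with columns
#'   `accession`, `gene_id`, `gene_order_distance`.
#' @export
contig_cooccurrence <- function(mag, result, cfg = nif_screen_config()) {
  stopifnot(inherits(mag, "mag_annotation_set"),
            inherits(result, "nif_screen_result"))
  if (!identical(mag$mag_id, result$mag_id))
    stop("result was computed for a different MAG", call. = FALSE)
  result$cooccurring_accessory <- list()
  if (!result$passes) return(result)
  ann <- mag$annotations
  for (ctg in unique(result$nifH_hits$contig_id)) {
    nifH_pos <- result$nifH_hits$gene_order_on_contig[
      result$nifH_hits$contig_id == ctg]
    on_ctg <- ann[ann$contig_id == ctg, , drop = FALSE]
    acc_hit <- on_ctg[vapply(on_ctg$accession, function(a)
      any(accession_equal(a, cfg$accessory)), logical(1)), , drop = FALSE]
    found <- if (nrow(acc_hit)) {
      data.frame(
        accession = acc_hit$accession,
        gene_id = acc_hit$gene_id,
        gene_order_distance = vapply(acc_hit$gene_order_on_contig,
                                     function(p) min(abs(p - nifH_pos)),
                                     numeric(1)),
        stringsAsFactors = FALSE)
    } else {
      data.frame(accession = character(), gene_id = character(),
                 gene_order_distance = numeric(), stringsAsFactors = FALSE)
    }
    result$cooccurring_accessory[[ctg]] <- found
  }
  result
}

#' Run the nitrogen-fixation screen over a MAG collection
#'
#' @param mags named list of `mag_annotation_set` objects.
#' @param cfg a [nif_screen_config()].
#' @return a data.frame ordered by `mag_id` with columns `mag_id`,
#'   `passes`, `nifH_best_e`, `nifD_best_e`, `nifH_contigs`
#'   (semicolon-joined) and `accessory_found` (semicolon-joined
#'   accessions co-located on nifH contigs).
#' @export
screen_nif_all <- function(mags, cfg = nif_screen_config()) {
  mag_ids <- vapply(mags, `[[`, "", "mag_id")
  rows <- lapply(mags[order(mag_ids)], function(mag) {
    r <- contig_cooccurrence(mag, screen_nif(mag, cfg), cfg)
    acc_found <- sort(unique(unlist(
      lapply(r$cooccurring_accessory, function(df) df$accession))))
    data.frame(
      mag_id = r$mag_id,
      passes = r$passes,
      nifH_best_e = if (nrow(r$nifH_hits)) min(r$nifH_hits$e_value) else NA_real_,
      nifD_best_e = if (nrow(r$nifD_hits)) min(r$nifD_hits$e_value) else NA_real_,
      nifH_contigs = paste(sort(unique(r$nifH_hits$contig_id)), collapse = ";"),
      accessory_found = paste(acc_found, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
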