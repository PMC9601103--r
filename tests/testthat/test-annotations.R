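write_lines <- function(lines, fileext = ".tsv") {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

functions_lines <- function(rows) {
  c("gene_callers_id\tcontig\tsource\taccession\tfunction\te_value", rows)
}

test_that("reader assigns genes to MAGs via contig membership", {
  fns <- write_lines(functions_lines(c(
    sprintf("g%02d\tctg_%d\tKOfam\tK%05d\tfn\t1e-50", 1:10, rep(1:2, each = 5), 1:10))))
  bins <- write_lines(c("contig\tbin_name", "ctg_1\tMAG_A", "ctg_2\tMAG_A"))
  mags <- read_annotations(fns, bins)
  expect_length(mags, 1)
  expect_identical(nrow(mags$MAG_A$annotations), 10L)
  # 0-based gene order from file order per contig
  expect_identical(mags$MAG_A$annotations$gene_order_on_contig,
                   rep(0:4, 2))
})

test_that("genes on unmapped contigs are routed to UNBINNED with a warning", {
  fns <- write_lines(functions_lines(c(
    "g1\tctg_1\tKOfam\tK00001\tfn\t1e-50",
    "g2\tctg_9\tKOfam\tK00002\tfn\t1e-50")))
  bins <- write_lines(c("contig\tbin_name", "ctg_1\tMAG_A"))
  expect_warning(mags <- read_annotations(fns, bins), "UNBINNED")
  expect_setequal(names(mags), c("MAG_A", "UNBINNED"))
  expect_identical(mags$UNBINNED$annotations$accession, "K00002")
})

test_that("a missing required column is a format error naming the column", {
  fns <- write_lines(c("gene_callers_id\tcontig\tsource\taccession\tfunction",
                       "g1\tctg_1\tKOfam\tK00001\tfn"))
  bins <- write_lines(c("contig\tbin_name", "ctg_1\tMAG_A"))
  expect_error(read_annotations(fns, bins), "e_value")
})

test_that("metadata is joined and MAGs without annotations appear empty", {
  fns <- write_lines(functions_lines("g1\tctg_1\tKOfam\tK00001\tfn\t1e-50"))
  bins <- write_lines(c("contig\tbin_name", "ctg_1\tMAG_A"))
  meta <- write_lines(c(
    paste("bin_name", "sample_id", "host_species", "tissue_type",
          "oxygen_class", "completion_pct", "redundancy_pct", sep = "\t"),
    "MAG_A\tS01\tPhyllospadix_scouleri\trhizome\tlow_oxygen\t95\t5",
    "MAG_B\tS01\tPhyllospadix_scouleri\tblade\twater_column\t50\t3"))
  mags <- read_annotations(fns, bins, meta)
  expect_setequal(names(mags), c("MAG_A", "MAG_B"))
  expect_identical(mags$MAG_A$oxygen_class, "low_oxygen")
  expect_identical(mags$MAG_A$completion_pct, 95)
  expect_identical(nrow(mags$MAG_B$annotations), 0L)
})

test_that("annotation tables round-trip through write_annotations", {
  dir <- withr::local_tempdir()
  mags <- list(A = make_mag("A", c("K00001", "COG0001"), sample_id = "S01",
                            host_species = "h", tissue_type = "blade",
                            oxygen_class = "water_column",
                            completion_pct = 91, redundancy_pct = 2))
  fp <- file.path(dir, "f.tsv"); bp <- file.path(dir, "b.tsv")
  mp <- file.path(dir, "m.tsv")
  write_annotations(mags, fp, bp, mp)
  back <- read_annotations(fp, bp, mp)
  expect_identical(back$A$annotations$accession, mags$A$annotations$accession)
  expect_identical(back$A$annotations$e_value, mags$A$annotations$e_value)
  expect_identical(back$A$completion_pct, 91)
})

test_that("e-value filtering is strict, per-source, and idempotent", {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    contig_id = "ctg_1", gene_order_on_contig = 0:3,
    source = c("KOfam", "KOfam", "COG", "KOfam"),
    accession = c("K00001", "K00002", "COG0001", "K00003"),
    function_text = "",
    e_value = c(1e-150, 1e-100, 1e-100, 1e-99),
    stringsAsFactors = FALSE)
  mag <- mag_annotation_set("m", ann)
  kept <- filter_by_evalue(mag, c(KOfam = 1e-100))
  # strictly below the cutoff: 1e-150 stays, exactly 1e-100 and 1e-99 go;
  # COG source has no threshold and passes
  expect_setequal(kept$annotations$accession, c("K00001", "COG0001"))
  expect_identical(filter_by_evalue(kept, c(KOfam = 1e-100))$annotations,
                   kept$annotations)
  expect_identical(filter_by_evalue(mag, list())$annotations, mag$annotations)
  expect_error(filter_by_evalue(mag, c(KOfam = -1)), ">= 0")
  expect_lte(nrow(kept$annotations), nrow(mag$annotations))
})

test_that("quality banding reproduces the stated bands", {
  expect_identical(classify_mag_quality(95, 5), "high")
  expect_identical(classify_mag_quality(42, 11), "medium")
  expect_identical(classify_mag_quality(90, 0), "medium")
  expect_identical(classify_mag_quality(30, 2), "unclassified")
  # the high rule wins over the medium band's looser redundancy bound
  expect_identical(classify_mag_quality(95, 10.5), "unclassified")
  expect_error(classify_mag_quality(101, 5), "\\[0, 100\\]")
  expect_error(classify_mag_quality(50, -1), "\\[0, 100\\]")
})

test_that("quality bands are disjoint on an exhaustive half-point grid", {
  g <- expand.grid(completion = seq(0, 100, by = 0.5),
                   redundancy = seq(0, 100, by = 0.5))
  band <- classify_mag_quality(g$completion, g$redundancy)
  high <- g$completion > 90 & g$redundancy < 10
  medium <- g$completion >= 42 & g$completion <= 90 & g$redundancy <= 11
  # the two rules never claim the same point: high demands completion > 90,
  # medium demands completion <= 90
  expect_identical(sum(high & medium), 0L)
  expect_identical(band == "high", high)
  expect_identical(band == "medium", medium)
})

test_that("accessions_present deduplicates across genes and sources", {
  mag <- make_mag("m", c("K02588", "K02588", "COG0001"))
  expect_identical(accessions_present(mag), c("COG0001", "K02588"))
  expect_identical(accessions_present(make_mag("m")), character(0))
})
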