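#' @title Synthetic community generator
#'
#' @description
#' Generates per-MAG annotation tables, bin maps and metadata with planted,
#' exactly-known ground truth, so every pipeline stage can be tested
#' without external data. Accession pools are kept disjoint by
#' construction: synthetic module definitions draw KOs below K10000
#' (skipping the real nitrogenase markers K02588/K02586), suite fixtures
#' draw from K5xxxx, and distractor genes from K9xxxx/COG9xxx, so planting
#' genes for one target can never change another target's truth value.
#' The e-value model is an artifact choice (not a KOfam score model):
#' planted hits draw log10 e-values uniformly from \[-180, -20\],
#' near-threshold decoy distractors from \[-90, -5\], and planted
#' nitrogenase markers from \[-180, -110\] so a planted diazotroph always
#' clears the strict 1e-100 screen cutoff.
#'
#' @name synthetic_data
NULL

#' Describe what to plant in one synthetic MAG
#'
#' @param mag_id MAG identifier.
#' @param planted_modules list of `list(module_id =, target_completeness =,
#'   path_index =)` entries; `target_completeness` is a fraction in
#'   \[0, 1\] and `path_index` selects which alternative path (default 1)
#'   receives the planted genes. The generator marks
#'   `ceiling(target * total_steps)` steps' full accession sets present,
#'   so the realized fraction (reported in the ground truth) may differ
#'   from the target when the target is not a multiple of `1/total_steps`.
#' @param planted_suites list of `list(suite_name =, n_matching_genes =)`
#'   entries; EC wildcard patterns are instantiated with random concrete
#'   EC numbers.
#' @param plant_diazotroph plant qualifying nifH (K02588) and nifD
#'   (K02586) KOfam hits plus same-contig accessory genes (COG2710,
#'   COG0347, COG0535).
#' @param include_homolog_trap plant a strong COG1348 hit (the
#'   protochlorophyllide-reductase homolog of nifH) without the KO
#'   markers; must not cause a nif pass.
#' @param n_distractor_genes number of random non-target genes (half use
#'   the near-threshold decoy e-value range).
#' @param sample_id,host_species,tissue_type,oxygen_class,completion_pct,redundancy_pct
#'   metadata carried to the output tables.
#' @param seed optional per-MAG seed; derived from the community seed when
#'   `NULL`.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(mag_id, planted_modules = list(),
                       planted_suites = list(),
                       plant_diazotroph = FALSE,
                       include_homolog_trap = FALSE,
                       n_distractor_genes = 20L,
                       sample_id = "S01",
                       host_species = "Phyllospadix_scouleri",
                       tissue_type = "rhizome",
                       oxygen_class = "low_oxygen",
                       completion_pct = 95, redundancy_pct = 5,
                       seed = NULL) {
  stopifnot(n_distractor_genes >= 0)
  for (pm in planted_modules) {
    stopifnot(!is.null(pm$module_id),
              pm$target_completeness >= 0, pm$target_completeness <= 1)
  }
  structure(list(mag_id = mag_id, planted_modules = planted_modules,
                 planted_suites = planted_suites,
                 plant_diazotroph = isTRUE(plant_diazotroph),
                 include_homolog_trap = isTRUE(include_homolog_trap),
                 n_distractor_genes = as.integer(n_distractor_genes),
                 sample_id = sample_id, host_species = host_species,
                 tissue_type = tissue_type, oxygen_class = oxygen_class,
                 completion_pct = completion_pct,
                 redundancy_pct = redundancy_pct, seed = seed),
            class = "plant_spec")
}

NIF_H_KO <- "K02588"
NIF_D_KO <- "K02586"
NIF_ACCESSORY <- c("COG2710", "COG0347", "COG0535")
NIF_HOMOLOG <- "COG1348"

# does accession `a` match any pattern of any suite?
matches_any_suite <- function(a, suites) {
  for (s in suites) {
    for (pat in s$patterns) {
      psrc <- accession_source(pat)
      hit <- if (psrc == "EC") {
        !is.na(accession_source(a)) && accession_source(a) == "EC" &&
          match_ec_wildcard(pat, a)
      } else {
        accession_equal(a, pat)
      }
      if (isTRUE(hit)) return(TRUE)
    }
  }
  FALSE
}

rand_evalue <- function(n, lo, hi) 10 ^ stats::runif(n, lo, hi)

#' Generate a synthetic community with known ground truth
#'
#' Writes `functions.tsv`, `bins.tsv` and `metadata.tsv` (the formats
#' consumed by [read_annotations()]) to `out_dir` and returns the ground
#' truth implied by the plant specs. Identical `(specs, seed)` produce
#' byte-identical files. Disjointness of planted, marker and distractor
#' accession pools is asserted; a violation (e.g. a user-supplied module
#' sharing accessions with a suite) is an error, because it would make the
#' ground truth wrong.
#'
#' @param specs list of [plant_spec()] objects (unique `mag_id`s).
#' @param modules named list of `module_definition` objects (names =
#'   module ids). For exact ground truth, modules must not share
#'   accessions with each other (as guaranteed by
#'   [generate_module_fixtures()] with `plantable = TRUE`).
#' @param suites named list of `gene_suite` objects.
#' @param out_dir output directory (created if needed).
#' @param seed integer community seed.
#' @return a list with `paths` (named character vector of the three files)
#'   and `ground_truth`: data.frames `modules` (mag_id, module_id,
#'   expected_completeness), `suites` (mag_id, suite_name,
#'   expected_present) and `nif` (mag_id, expected_pass), covering every
#'   (MAG, target) pair including unplanted ones.
#' @export
generate_community <- function(specs, modules, suites, out_dir, seed) {
  stopifnot(length(specs) > 0)
  mag_ids <- vapply(specs, `[[`, "", "mag_id")
  if (anyDuplicated(mag_ids))
    stop("duplicate mag_id across plant specs", call. = FALSE)
  if (is.null(names(modules)))
    names(modules) <- vapply(modules, `[[`, "", "module_id")
  if (is.null(names(suites)))
    names(suites) <- vapply(suites, `[[`, "", "suite_name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  module_accs <- lapply(modules, function(m) {
    setdiff(unique(unlist(lapply(enumerate_paths(m$root)$paths, unlist))),
            GAP_MARKER)
  })
  # pool disjointness: module accessions vs suites and nif markers
  for (id in names(modules)) {
    for (a in module_accs[[id]]) {
      if (matches_any_suite(a, suites))
        stop("module ", id, " shares accession ", a,
             " with a suite pattern; ground truth would be wrong",
             call. = FALSE)
      if (a %in% c(NIF_H_KO, NIF_D_KO) ||
          any(accession_equal(a, c(NIF_ACCESSORY, NIF_HOMOLOG))))
        stop("module ", id, " uses nitrogen-fixation marker ", a,
             call. = FALSE)
    }
  }

  all_rows <- list()
  bins <- list()
  meta <- list()
  gt_mod <- list()
  gt_suite <- list()
  gt_nif <- list()

  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    spec_seed <- if (is.null(spec$seed)) (seed * 131L + si) %% .Machine$integer.max else spec$seed
    set.seed(spec_seed)
    mag <- spec$mag_id
    contigs <- sprintf("%s_ctg_%03d", mag, seq_len(sample(1:3, 1)))
    rows <- list()
    gid <- 0L
    add_gene <- function(accession, source, e_value, contig = NULL,
                         fn_text = "") {
      gid <<- gid + 1L
      if (is.null(contig)) contig <- contigs[sample(length(contigs), 1)]
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_callers_id = sprintf("%s_g%04d", mag, gid),
        contig = contig, source = source, accession = accession,
        "function" = fn_text, e_value = e_value,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
    src_of <- function(a) switch(accession_source(a),
                                 KO = "KOfam", COG = "COG", EC = "EC")

    planted_accs <- character(0)
    planted_mod_ids <- vapply(spec$planted_modules, `[[`, "", "module_id")
    for (pm in spec$planted_modules) {
      mod <- modules[[pm$module_id]]
      if (is.null(mod)) stop("unknown module in plant spec: ", pm$module_id,
                             call. = FALSE)
      enum <- enumerate_paths(mod$root)
      path_index <- if (is.null(pm$path_index)) 1L else pm$path_index
      path <- enum$paths[[path_index]]
      total <- length(path)
      k <- ceiling(pm$target_completeness * total)
      chosen <- if (k > 0) sort(sample(total, k)) else integer(0)
      realized_steps <- 0L
      for (i in chosen) {
        step <- unlist(path[[i]])
        if (GAP_MARKER %in% step) next  # unsatisfiable: lowers realized fraction
        realized_steps <- realized_steps + 1L
        for (a in step) {
          add_gene(a, src_of(a), rand_evalue(1, -180, -20))
          planted_accs <- c(planted_accs, a)
        }
      }
      gt_mod[[length(gt_mod) + 1L]] <- data.frame(
        mag_id = mag, module_id = pm$module_id,
        expected_completeness = realized_steps / total,
        stringsAsFactors = FALSE)
    }
    for (id in setdiff(names(modules), planted_mod_ids)) {
      gt_mod[[length(gt_mod) + 1L]] <- data.frame(
        mag_id = mag, module_id = id, expected_completeness = 0,
        stringsAsFactors = FALSE)
    }

    planted_suite_names <- vapply(spec$planted_suites, `[[`, "", "suite_name")
    for (ps in spec$planted_suites) {
      suite <- suites[[ps$suite_name]]
      if (is.null(suite)) stop("unknown suite in plant spec: ", ps$suite_name,
                               call. = FALSE)
      n <- if (is.null(ps$n_matching_genes)) 1L else as.integer(ps$n_matching_genes)
      pats <- rep_len(suite$patterns, max(n, 0L))
      for (pat in pats) {
        psrc <- accession_source(pat)
        if (psrc == "EC") {
          fields <- strsplit(pat, ".", fixed = TRUE)[[1]]
          spec_fields <- fields[!fields %in% c("*", "-")]
          extra <- 4L - length(spec_fields)
          a <- paste(c(spec_fields, if (extra > 0) sample(1:30, extra, replace = TRUE)),
                     collapse = ".")
        } else {
          a <- pat
        }
        add_gene(a, src_of(a), rand_evalue(1, -180, -20))
      }
      gt_suite[[length(gt_suite) + 1L]] <- data.frame(
        mag_id = mag, suite_name = ps$suite_name, expected_present = n > 0L,
        stringsAsFactors = FALSE)
    }
    for (nm in setdiff(names(suites), planted_suite_names)) {
      gt_suite[[length(gt_suite) + 1L]] <- data.frame(
        mag_id = mag, suite_name = nm, expected_present = FALSE,
        stringsAsFactors = FALSE)
    }

    if (spec$plant_diazotroph) {
      nif_contig <- contigs[1]
      add_gene(NIF_H_KO, "KOfam", rand_evalue(1, -180, -110), contig = nif_contig,
               fn_text = "nitrogenase iron protein NifH")
      add_gene(NIF_D_KO, "KOfam", rand_evalue(1, -180, -110), contig = nif_contig,
               fn_text = "nitrogenase molybdenum-iron protein alpha chain NifD")
      for (a in NIF_ACCESSORY)
        add_gene(a, "COG", rand_evalue(1, -180, -110), contig = nif_contig)
    }
    if (spec$include_homolog_trap) {
      add_gene(NIF_HOMOLOG, "COG", rand_evalue(1, -180, -110),
               fn_text = "nifH-like / protochlorophyllide reductase iron protein")
    }
    gt_nif[[length(gt_nif) + 1L]] <- data.frame(
      mag_id = mag, expected_pass = spec$plant_diazotroph,
      stringsAsFactors = FALSE)

    if (spec$n_distractor_genes > 0) {
      for (j in seq_len(spec$n_distractor_genes)) {
        a <- if (stats::runif(1) < 0.5) {
          sprintf("K9%04d", sample(0:9999, 1))
        } else {
          sprintf("COG9%03d", sample(0:999, 1))
        }
        if (a %in% planted_accs || matches_any_suite(a, suites) ||
            any(accession_equal(a, c(NIF_H_KO, NIF_D_KO, NIF_ACCESSORY,
                                     NIF_HOMOLOG))) ||
            any(vapply(module_accs, function(s) a %in% s, logical(1))))
          stop("distractor pool collision on ", a, call. = FALSE)
        decoy <- j %% 2L == 0L
        add_gene(a, src_of(a),
                 if (decoy) rand_evalue(1, -90, -5) else rand_evalue(1, -180, -20))
      }
    }

    all_rows[[si]] <- do.call(rbind, rows)
    bins[[si]] <- data.frame(contig = contigs, bin_name = mag,
                             stringsAsFactors = FALSE)
    meta[[si]] <- data.frame(
      bin_name = mag, sample_id = spec$sample_id,
      host_species = spec$host_species, tissue_type = spec$tissue_type,
      oxygen_class = spec$oxygen_class,
      completion_pct = spec$completion_pct,
      redundancy_pct = spec$redundancy_pct, stringsAsFactors = FALSE)
  }

  fns <- do.call(rbind, all_rows)
  fns$e_value <- format(fns$e_value, scientific = TRUE, trim = TRUE, digits = 8)
  paths <- c(functions = file.path(out_dir, "functions.tsv"),
             bins = file.path(out_dir, "bins.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"))
  utils::write.table(fns, paths[["functions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(do.call(rbind, bins), paths[["bins"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, meta), paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  list(paths = paths,
       ground_truth = list(
         modules = {
           df <- do.call(rbind, gt_mod)
           df <- df[order(df$mag_id, df$module_id), ]
           rownames(df) <- NULL
           df
         },
         suites = {
           df <- do.call(rbind, gt_suite)
           df <- df[order(df$mag_id, df$suite_name), ]
           rownames(df) <- NULL
           df
         },
         nif = {
           df <- do.call(rbind, gt_nif)
           df <- df[order(df$mag_id), ]
           rownames(df) <- NULL
           df
         }))
}

#' Generate synthetic KEGG module definitions
#'
#' Writes `n` random, valid module records in the KEGG flat-file dialect
#' (ENTRY/NAME/DEFINITION, `///` terminators). The default mix spans the
#' whole grammar: OR nesting up to depth 3, complexes, optional
#' components, and (for `n >= 3`) one module containing a gap step; at
#' least one module has more than one alternative path. With
#' `plantable = TRUE` the shapes are restricted so planted ground truth is
#' exact: no gaps, OR branches are single steps, and accessions are unique
#' within and across modules (KOs below K10000, skipping the nitrogenase
#' markers).
#'
#' @param n number of modules (>= 1).
#' @param seed integer seed; identical seeds give identical files.
#' @param path output file path; default a tempfile.
#' @param plantable restrict shapes for exact planted recovery.
#' @return the list of `module_definition` objects, invisibly; the file at
#'   `path` is the primary output (attribute `"path"` carries it).
#' @export
generate_module_fixtures <- function(n, seed, path = tempfile(fileext = ".txt"),
                                     plantable = FALSE) {
  stopifnot(n >= 1)
  set.seed(seed)
  counter <- 0L
  next_ko <- function() {
    repeat {
      counter <<- counter + 1L
      if (!counter %in% c(2586L, 2588L)) break  # reserved nitrogenase markers
    }
    sprintf("K%05d", counter)
  }
  rand_step <- function() {
    # a single step: a leaf or a small complex (optionally with an
    # optional subunit)
    r <- stats::runif(1)
    if (r < 0.6 || plantable && r < 0.75) {
      def_leaf(next_ko())
    } else {
      members <- lapply(seq_len(sample(2:3, 1)), function(i) def_leaf(next_ko()))
      if (!plantable && stats::runif(1) < 0.3)
        members <- c(members, list(def_optional(def_leaf(next_ko()))))
      do.call(def_complex, members)
    }
  }
  rand_block <- function(depth) {
    if (depth <= 0 || stats::runif(1) < 0.55) return(rand_step())
    if (stats::runif(1) < 0.5) {
      branches <- lapply(seq_len(sample(2:3, 1)), function(i) {
        if (plantable) rand_step() else rand_block(depth - 1L)
      })
      do.call(def_or, branches)
    } else {
      parts <- lapply(seq_len(sample(2:3, 1)), function(i) rand_block(depth - 1L))
      do.call(def_and, parts)
    }
  }
  mods <- lapply(seq_len(n), function(i) {
    n_steps <- sample(2:5, 1)
    parts <- lapply(seq_len(n_steps), function(j) rand_block(2L))
    if (!plantable && stats::runif(1) < 0.25)
      parts <- c(parts, list(def_optional(rand_step())))
    if (!plantable && i == 3L)
      parts <- c(parts, list(def_gap()))
    root <- do.call(def_and, parts)
    module_definition(sprintf("MS%04d", i), serialize_definition(root),
                      name = sprintf("synthetic module %d", i))
  })
  # contract: at least one module with alternative paths
  if (!any(vapply(mods, function(m) count_paths(m$root) > 1, logical(1)))) {
    ko <- c(next_ko(), next_ko(), next_ko())
    mods[[length(mods)]] <- module_definition(
      sprintf("MS%04d", n),
      sprintf("(%s,%s) %s", ko[1], ko[2], ko[3]),
      name = sprintf("synthetic module %d", n))
  }
  write_kegg_modules(mods, path)
  names(mods) <- vapply(mods, `[[`, "", "module_id")
  attr(mods, "path") <- path
  invisible(mods)
}
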