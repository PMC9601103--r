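# Shared fixtures: random definition trees, an independent completeness
# oracle (exhaustive path enumeration), and quick MAG constructors.

new_ko_counter <- function(start = 0L) {
  i <- start
  function() {
    i <<- i + 1L
    sprintf("K%05d", i)
  }
}

random_complex_member <- function(next_ko, allow_opt = TRUE) {
  r <- stats::runif(1)
  if (r < 0.6) {
    def_leaf(next_ko())
  } else if (r < 0.85) {
    def_or(def_leaf(next_ko()), def_leaf(next_ko()))
  } else if (allow_opt) {
    def_optional(def_leaf(next_ko()))
  } else {
    def_leaf(next_ko())
  }
}

# random normalized tree exercising every node kind
random_tree <- function(depth = 3L, next_ko = new_ko_counter(),
                        allow_gap = TRUE, allow_opt = TRUE) {
  r <- stats::runif(1)
  if (depth <= 0L || r < 0.35) return(def_leaf(next_ko()))
  if (allow_gap && r < 0.42) return(def_gap())
  if (allow_opt && r < 0.50)
    return(def_optional(random_tree(depth - 1L, next_ko, allow_gap = FALSE,
                                    allow_opt = allow_opt)))
  if (r < 0.62) {
    members <- lapply(seq_len(sample(2:3, 1)), function(i)
      random_complex_member(next_ko, allow_opt))
    return(do.call(def_complex, members))
  }
  ctor <- if (r < 0.82) def_and else def_or
  kids <- lapply(seq_len(sample(2:3, 1)), function(i)
    random_tree(depth - 1L, next_ko, allow_gap, allow_opt))
  do.call(ctor, kids)
}

# a tree with at most `max_leaves` leaves (for exhaustive oracles)
random_small_tree <- function(max_leaves = 12L, ...) {
  repeat {
    tree <- random_tree(...)
    if (length(tree_leaves(tree)) <= max_leaves) return(tree)
  }
}

tree_leaves <- function(node) {
  if (node$kind == "LEAF") return(node$accession)
  unique(unlist(lapply(node$children, tree_leaves)))
}

# independent oracle: best satisfied/total over ALL enumerated paths,
# exact integer comparison, zero-step paths skipped
oracle_completeness <- function(root, present) {
  enum <- enumerate_paths(root, max_paths = 1e6)
  stopifnot(!enum$truncated)
  best <- NULL
  for (p in enum$paths) {
    if (!length(p)) next
    pc <- path_completeness(p, present)
    if (is.null(best) ||
        pc$satisfied * best$total > best$satisfied * pc$total) {
      best <- pc
    }
  }
  best  # NULL when every path is zero-step (degenerate)
}

# MAG with one annotation row per accession
make_mag <- function(mag_id, accessions = character(), source = NULL,
                     e_value = 1e-150, contig = "ctg_1", ...) {
  n <- length(accessions)
  if (is.null(source))
    source <- c(KO = "KOfam", COG = "COG", EC = "EC")[accession_source(accessions)]
  ann <- data.frame(
    gene_id = sprintf("%s_g%03d", mag_id, seq_len(n)),
    contig_id = rep_len(contig, n),
    gene_order_on_contig = seq_len(n) - 1L,
    source = rep_len(unname(source), n),
    accession = accessions,
    function_text = rep_len("", n),
    e_value = rep_len(e_value, n),
    stringsAsFactors = FALSE)
  mag_annotation_set(mag_id, ann, ...)
}

# small plantable community used by several tests
demo_community <- function(dir, seed, n_modules = 3L, n_mags = 3L) {
  modules <- generate_module_fixtures(n_modules, seed = seed,
                                      path = file.path(dir, "modules.txt"),
                                      plantable = TRUE)
  suites <- load_suites(system.file("extdata", "example_suites.tsv",
                                    package = "magmetab"))
  specs <- lapply(seq_len(n_mags), function(i) {
    plant_spec(sprintf("MAG_%03d", i),
               planted_modules = list(list(
                 module_id = names(modules)[(i - 1L) %% n_modules + 1L],
                 target_completeness = c(1, 0.5, 2 / 3)[(i - 1L) %% 3L + 1L])),
               planted_suites = if (i %% 2L == 1L)
                 list(list(suite_name = "Carboxylic Acids", n_matching_genes = 1L)),
               plant_diazotroph = i == 1L,
               include_homolog_trap = i == 2L,
               tissue_type = c("blade", "rhizome", "sediment")[(i - 1L) %% 3L + 1L],
               oxygen_class = if (i %% 3L == 1L) "water_column" else "low_oxygen")
  })
  sim <- generate_community(specs, modules, suites, dir, seed = seed)
  list(modules = modules, suites = suites, specs = specs, sim = sim)
}
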