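#' @title Module completeness engine
#'
#' @description
#' Scores a genome's gene content against a KEGG module definition. The
#' completeness of a module is the best fraction of reaction steps
#' satisfied along any alternative path through the module's expression
#' tree, and a metabolism is called present when completeness reaches the
#' detection threshold (default 2/3, the two-thirds reading of a "67% of
#' genes present" criterion).
#'
#' The evaluator is exact: for every subtree it carries the full Pareto
#' frontier of achievable (satisfied steps, total steps) pairs — OR nodes
#' take the union of their children's frontiers, AND nodes the Minkowski
#' sum — so the reported maximum ratio provably equals the maximum over
#' exhaustive path enumeration, with integer arithmetic throughout (no
#' floating-point drift in comparisons).
#'
#' @name completeness_engine
NULL

# frontier entry: list(s, t, path); path is a list of step-sets (witness)
f_entry <- function(s, t, path) list(s = as.integer(s), t = as.integer(t), path = path)

# keep, per total t, the maximal satisfied s; drop dominated entries
# ((s,t) is dominated when some other entry has t' <= t and s' >= s)
reduce_frontier <- function(entries) {
  if (length(entries) <= 1L) return(entries)
  ts <- vapply(entries, `[[`, 0L, "t")
  ss <- vapply(entries, `[[`, 0L, "s")
  ord <- order(ts, -ss, seq_along(entries))
  keep <- list()
  best_s <- -1L
  for (i in ord) {
    if (ss[i] > best_s) {
      keep[[length(keep) + 1L]] <- entries[[i]]
      best_s <- ss[i]
    }
  }
  keep
}

combine_and <- function(f1, f2) {
  out <- vector("list", length(f1) * length(f2))
  k <- 0L
  for (a in f1) for (b in f2) {
    k <- k + 1L
    out[[k]] <- f_entry(a$s + b$s, a$t + b$t, c(a$path, b$path))
  }
  reduce_frontier(out)
}

node_frontier <- function(node, present) {
  switch(node$kind,
    LEAF = list(f_entry(as.integer(node$accession %in% present), 1L,
                        list(node$accession))),
    GAP = list(f_entry(0L, 1L, list(GAP_MARKER))),
    OPTIONAL = list(f_entry(0L, 0L, list())),
    OR = reduce_frontier(unlist(lapply(node$children, node_frontier,
                                       present = present),
                                recursive = FALSE)),
    AND = {
      acc <- list(f_entry(0L, 0L, list()))
      for (ch in node$children) acc <- combine_and(acc, node_frontier(ch, present))
      acc
    },
    COMPLEX = {
      required <- Filter(function(ch) ch$kind != "OPTIONAL", node$children)
      fronts <- lapply(required, node_frontier, present = present)
      fulls <- lapply(fronts, function(f) Filter(function(e) e$s == e$t, f))
      if (all(lengths(fulls) > 0L)) {
        set <- sort(unique(unlist(lapply(fulls, function(f) unlist(f[[1L]]$path)))))
        list(f_entry(1L, 1L, list(set)))
      } else {
        list(f_entry(0L, 1L, list(satisfying_sets(node, 1L)[[1L]])))
      }
    }
  )
}

# exact ratio comparison: is s1/t1 > s2/t2 ? (t == 0 treated as ratio 0)
ratio_gt <- function(s1, t1, s2, t2) {
  if (t1 == 0L) { s1 <- 0L; t1 <- 1L }
  if (t2 == 0L) { s2 <- 0L; t2 <- 1L }
  s1 * t2 > s2 * t1
}

#' Score one step path against a set of present accessions
#'
#' A step counts as satisfied when every accession in its step-set is
#' present; gap steps (marker `"--"`) are never satisfied.
#'
#' @param path a step path: list of character-vector step-sets, as produced
#'   by [enumerate_paths()].
#' @param present character vector of accessions present in the genome.
#' @return a list with integer fields `satisfied` and `total`.
#' @examples
#' path_completeness(list("K00001", c("K00002", "K00003")), c("K00001"))
#' @export
path_completeness <- function(path, present) {
  if (!is.list(path) || length(path) == 0L)
    stop("path must be a non-empty list of step-sets", call. = FALSE)
  sat <- vapply(path, function(step) {
    step <- unlist(step)
    !(GAP_MARKER %in% step) && all(step %in% present)
  }, logical(1))
  list(satisfied = as.integer(sum(sat)), total = length(path))
}

#' Compute the completeness of a module for a set of present accessions
#'
#' Returns the maximum over all alternative paths of the fraction of
#' satisfied steps, together with a witness path achieving it. Ties between
#' paths with equal fractions are broken toward fewer total steps, then by
#' tree order (leftmost alternative), so the witness is deterministic.
#'
#' A module whose only routes consist entirely of optional components has
#' no scorable steps; it is reported with `completeness = 0`,
#' `total_steps = 0` and `degenerate = TRUE`.
#'
#' @param root a `def_node` (see [parse_definition()]).
#' @param present character vector of accessions present in the genome.
#' @return a list with fields `completeness` (numeric in \[0,1\]),
#'   `satisfied_steps`, `total_steps` (integers), `best_path` (list of
#'   step-sets) and `degenerate` (logical).
#' @examples
#' module_completeness(parse_definition("(K00001,K00002) K00003"), "K00002")
#' @export
module_completeness <- function(root, present) {
  stopifnot(inherits(root, "def_node"))
  present <- unique(as.character(present))
  frontier <- node_frontier(root, present)
  pos <- Filter(function(e) e$t > 0L, frontier)
  if (!length(pos)) {
    return(list(completeness = 0, satisfied_steps = 0L, total_steps = 0L,
                best_path = list(), degenerate = TRUE))
  }
  best <- pos[[1L]]
  for (e in pos[-1L]) {
    if (ratio_gt(e$s, e$t, best$s, best$t) ||
        (!ratio_gt(best$s, best$t, e$s, e$t) && e$t < best$t)) {
      best <- e
    }
  }
  list(completeness = best$s / best$t,
       satisfied_steps = best$s,
       total_steps = best$t,
       best_path = best$path,
       degenerate = FALSE)
}

# serialize a step path for reporting: members joined by '+', steps by ' '
format_step_path <- function(path) {
  if (!length(path)) return("")
  paste(vapply(path, function(step) {
    step <- unlist(step)
    if (!length(step)) "()" else paste(step, collapse = "+")
  }, ""), collapse = " ")
}

#' Detect a metabolism in a MAG
#'
#' Scores one module against one MAG's annotation set and calls presence at
#' the detection threshold. The default threshold is the exact fraction 2/3
#' (the conventional "67%" criterion), compared with a small numeric guard
#' so that exactly 2-of-3 steps passes.
#'
#' @param module a `module_definition` (see [module_definition()]).
#' @param mag a `mag_annotation_set` (see [read_annotations()]).
#' @param threshold presence threshold in (0, 1]; default `2/3`.
#' @param count_mode `"steps"` (default) counts reaction steps on the best
#'   path; `"genes"` counts distinct required accessions instead, maximized
#'   over enumerated paths (a sensitivity-analysis mode; a gap contributes
#'   one unsatisfiable pseudo-gene).
#' @param evalue_thresholds optional named list/vector mapping annotation
#'   source to a maximum e-value, applied via [filter_by_evalue()] before
#'   scoring; default no filtering.
#' @param max_paths path-enumeration cap for `count_mode = "genes"`.
#' @return a `completeness_result`: list with `module_id`, `mag_id`,
#'   `completeness`, `satisfied_steps`, `total_steps`, `best_path`,
#'   `present`, `threshold`, `degenerate`.
#' @export
detect_metabolism <- function(module, mag, threshold = 2 / 3,
                              count_mode = c("steps", "genes"),
                              evalue_thresholds = NULL,
                              max_paths = 10000L) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(module, "module_definition"),
            inherits(mag, "mag_annotation_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a fraction in (0, 1]", call. = FALSE)
  if (!is.null(evalue_thresholds))
    mag <- filter_by_evalue(mag, evalue_thresholds)
  present <- accessions_present(mag)

  if (count_mode == "steps") {
    res <- module_completeness(module$root, present)
  } else {
    enum <- enumerate_paths(module$root, max_paths = max_paths)
    if (enum$truncated)
      warning("path enumeration truncated at ", max_paths,
              " paths for module ", module$module_id,
              "; gene-mode completeness is a lower bound", call. = FALSE)
    res <- list(completeness = 0, satisfied_steps = 0L, total_steps = 0L,
                best_path = list(), degenerate = TRUE)
    for (p in enum$paths) {
      genes <- unique(unlist(p))
      tot <- length(genes)
      if (tot == 0L) next
      sat <- sum(genes %in% present & genes != GAP_MARKER)
      if (res$degenerate || ratio_gt(sat, tot, res$satisfied_steps, res$total_steps) ||
          (!ratio_gt(res$satisfied_steps, res$total_steps, sat, tot) &&
           tot < res$total_steps)) {
        res <- list(completeness = sat / tot, satisfied_steps = as.integer(sat),
                    total_steps = as.integer(tot), best_path = p,
                    degenerate = FALSE)
      }
    }
  }

  structure(list(
    module_id = module$module_id,
    module_name = module$name,
    mag_id = mag$mag_id,
    completeness = res$completeness,
    satisfied_steps = res$satisfied_steps,
    total_steps = res$total_steps,
    best_path = res$best_path,
    present = !res$degenerate && res$completeness >= threshold - 1e-9,
    threshold = threshold,
    degenerate = res$degenerate
  ), class = "completeness_result")
}

#' @export
print.completeness_result <- function(x, ...) {
  cat(sprintf("<completeness_result> %s in %s: %d/%d steps (%.3f) -> %s\n",
              x$module_id, x$mag_id, x$satisfied_steps, x$total_steps,
              x$completeness, if (x$present) "PRESENT" else "absent"))
  invisible(x)
}

#' Score every MAG against every module
#'
#' @param mags list of `mag_annotation_set` objects (duplicate `mag_id`s
#'   are an error).
#' @param modules list of `module_definition` objects.
#' @param threshold,count_mode,evalue_thresholds,max_paths passed to
#'   [detect_metabolism()].
#' @return a data.frame with one row per (MAG, module), ordered by
#'   `(mag_id, module_id)`, with columns `mag_id`, `module_id`,
#'   `module_name`, `completeness`, `satisfied_steps`, `total_steps`,
#'   `present`, `degenerate`, `best_path` (serialized step path).
#' @export
score_all <- function(mags, modules, threshold = 2 / 3,
                      count_mode = c("steps", "genes"),
                      evalue_thresholds = NULL, max_paths = 10000L) {
  count_mode <- match.arg(count_mode)
  if (!length(mags) || !length(modules))
    stop("mags and modules must be non-empty lists", call. = FALSE)
  mag_ids <- vapply(mags, `[[`, "", "mag_id")
  if (anyDuplicated(mag_ids))
    stop("duplicate mag_id in input: ",
         paste(unique(mag_ids[duplicated(mag_ids)]), collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (mag in mags[order(mag_ids)]) {
    mod_ids <- vapply(modules, `[[`, "", "module_id")
    for (mod in modules[order(mod_ids)]) {
      r <- detect_metabolism(mod, mag, threshold = threshold,
                             count_mode = count_mode,
                             evalue_thresholds = evalue_thresholds,
                             max_paths = max_paths)
      rows[[length(rows) + 1L]] <- data.frame(
        mag_id = r$mag_id, module_id = r$module_id,
        module_name = r$module_name,
        completeness = r$completeness,
        satisfied_steps = r$satisfied_steps,
        total_steps = r$total_steps,
        present = r$present,
        degenerate = r$degenerate,
        best_path = format_step_path(r$best_path),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
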