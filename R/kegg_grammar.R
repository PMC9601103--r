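#' @title KEGG module definition grammar
#'
#' @description
#' KEGG metabolic modules are defined by Boolean DEFINITION expressions over
#' gene accessions. The dialect implemented here:
#'
#' * a **space** joins consecutive reaction steps (AND);
#' * a **comma** separates alternative routes (OR) and binds *looser* than
#'   the space, so `"(K01007,K01006) K01595,K01958"` is a choice between a
#'   two-step route and a one-step route;
#' * `+` joins subunits of a protein **complex**, which counts as a single
#'   step satisfied only when every required subunit is present;
#' * a leading `-` marks a component as **optional** (non-essential): it is
#'   excluded from both the numerator and the denominator of completeness;
#' * `--` denotes a **gap**: a reaction step with no known gene, which can
#'   never be satisfied but still counts in the denominator;
#' * parentheses group subexpressions.
#'
#' `parse_definition()` builds a normalized expression tree (nested
#' same-kind AND/OR nodes flattened, single-child connectives collapsed);
#' `serialize_definition()` is its inverse up to normalization;
#' `enumerate_paths()` expands the tree into explicit alternative step
#' paths.
#'
#' @name kegg_grammar
NULL

node_kinds <- c("LEAF", "AND", "OR", "COMPLEX", "OPTIONAL", "GAP")

new_node <- function(kind, children = list(), accession = NULL) {
  structure(list(kind = kind, children = children, accession = accession),
            class = "def_node")
}

#' Construct definition-tree nodes
#'
#' Low-level constructors for the expression tree produced by
#' [parse_definition()]. Mainly useful for building test cases and synthetic
#' modules programmatically; all constructors normalize their result.
#'
#' @param accession an accession code string (leaf nodes).
#' @param ... child `def_node` objects (or accession strings, auto-wrapped
#'   into leaves).
#' @param child a single child node for `def_optional()`.
#' @return a `def_node`.
#' @examples
#' def_and(def_or("K00001", "K00002"), "K00003")
#' @export
def_leaf <- function(accession) {
  accession <- normalize_accession(accession)
  new_node("LEAF", accession = accession)
}

as_node <- function(x) if (inherits(x, "def_node")) x else def_leaf(x)

#' @rdname def_leaf
#' @export
def_and <- function(...) normalize_node(new_node("AND", children = lapply(list(...), as_node)))

#' @rdname def_leaf
#' @export
def_or <- function(...) normalize_node(new_node("OR", children = lapply(list(...), as_node)))

#' @rdname def_leaf
#' @export
def_complex <- function(...) normalize_node(new_node("COMPLEX", children = lapply(list(...), as_node)))

#' @rdname def_leaf
#' @export
def_optional <- function(child) normalize_node(new_node("OPTIONAL", children = list(as_node(child))))

#' @rdname def_leaf
#' @export
def_gap <- function() new_node("GAP")

#' @export
print.def_node <- function(x, ...) {
  cat("<def_node> ", serialize_definition(x), "\n", sep = "")
  invisible(x)
}

# Flatten nested same-kind AND/OR/COMPLEX, collapse single-child
# connectives, merge nested OPTIONALs. Idempotent.
normalize_node <- function(node) {
  if (node$kind %in% c("LEAF", "GAP")) return(node)
  node$children <- lapply(node$children, normalize_node)
  if (node$kind == "OPTIONAL") {
    if (node$children[[1]]$kind == "OPTIONAL") return(node$children[[1]])
    return(node)
  }
  kids <- list()
  for (ch in node$children) {
    if (ch$kind == node$kind) kids <- c(kids, ch$children)
    else kids <- c(kids, list(ch))
  }
  if (length(kids) == 1L && node$kind %in% c("AND", "OR", "COMPLEX"))
    return(kids[[1]])
  node$children <- kids
  node
}

## ---- tokenizer -------------------------------------------------------------

# token: list(type, text, offset) ; offset is 1-based character position
tokenize_definition <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- list()
  i <- 1L
  push <- function(type, text, offset) toks[[length(toks) + 1L]] <<- list(type = type, text = text, offset = offset)
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      start <- i
      while (i <= n && chars[i] %in% c(" ", "\t")) i <- i + 1L
      push("SPACE", " ", start)
    } else if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L
    } else if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L
    } else if (ch == ",") { push("COMMA", ",", i); i <- i + 1L
    } else if (ch == "+") { push("PLUS", "+", i); i <- i + 1L
    } else if (ch == "-") {
      if (i < n && chars[i + 1L] == "-") { push("GAP", "--", i); i <- i + 2L }
      else { push("MINUS", "-", i); i <- i + 1L }
    } else {
      start <- i
      while (i <= n && grepl("^[A-Za-z0-9._]$", chars[i])) i <- i + 1L
      if (i == start)
        stop(sprintf("parse error: unexpected character '%s' at offset %d", ch, i),
             call. = FALSE)
      push("ACC", paste(chars[start:(i - 1L)], collapse = ""), start)
    }
  }
  toks
}

## ---- recursive-descent parser ---------------------------------------------

#' Parse a KEGG module DEFINITION string
#'
#' @param raw a single DEFINITION string, e.g.
#'   `"(K00001,K00002) K00003+K00004"`.
#' @return a normalized `def_node` expression tree.
#' @details Whitespace-only differences in `raw` never change the result.
#'   Errors name the offending character offset (unbalanced parentheses),
#'   token (malformed accession), or construct (empty OR branch).
#' @examples
#' parse_definition("(K00001,K00002) K00003+K00004")
#' @seealso [serialize_definition()], [enumerate_paths()]
#' @export
parse_definition <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  raw <- trimws(raw)
  if (!nzchar(raw)) stop("parse error: empty definition", call. = FALSE)
  toks <- tokenize_definition(raw)
  # trim leading/trailing SPACE tokens
  types <- vapply(toks, `[[`, "", "type")
  keep <- seq_along(toks)
  if (length(keep) && types[1] == "SPACE") keep <- keep[-1]
  if (length(keep) && types[keep[length(keep)]] == "SPACE") keep <- keep[-length(keep)]
  toks <- toks[keep]

  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_fail <- function(msg, tok = peek()) {
    at <- if (is.null(tok)) nchar(raw) + 1L else tok$offset
    stop(sprintf("parse error: %s at offset %d", msg, at), call. = FALSE)
  }

  parse_or <- function() {
    branches <- list(parse_and())
    while (!is.null(t <- peek()) && t$type == "COMMA") {
      advance()
      skip_space()
      nxt <- peek()
      if (is.null(nxt) || nxt$type %in% c("COMMA", "RPAREN"))
        expect_fail("empty OR branch")
      branches <- c(branches, list(parse_and()))
    }
    if (length(branches) == 1L) branches[[1]] else new_node("OR", children = branches)
  }

  parse_and <- function() {
    parts <- list(parse_factor())
    while (!is.null(t <- peek()) && t$type == "SPACE") {
      advance()
      nxt <- peek()
      if (is.null(nxt) || nxt$type %in% c("COMMA", "RPAREN")) break
      parts <- c(parts, list(parse_factor()))
    }
    if (length(parts) == 1L) parts[[1]] else new_node("AND", children = parts)
  }

  skip_space <- function() {
    while (!is.null(t <- peek()) && t$type == "SPACE") advance()
  }

  # a factor is a complex chain; a leading '-' makes the whole chain optional
  parse_factor <- function() {
    skip_space()
    t <- peek()
    if (!is.null(t) && t$type == "MINUS") {
      advance()
      return(new_node("OPTIONAL", children = list(parse_complex())))
    }
    parse_complex()
  }

  parse_complex <- function() {
    members <- list(parse_unit())
    repeat {
      t <- peek()
      if (is.null(t)) break
      if (t$type == "PLUS") {
        advance()
        members <- c(members, list(parse_unit()))
      } else if (t$type == "MINUS") {
        advance()
        members <- c(members, list(new_node("OPTIONAL", children = list(parse_unit()))))
      } else break
    }
    if (length(members) == 1L) members[[1]] else new_node("COMPLEX", children = members)
  }

  parse_unit <- function() {
    t <- peek()
    if (is.null(t)) expect_fail("unexpected end of definition")
    if (t$type == "ACC") {
      advance()
      if (!is_valid_accession(t$text))
        stop(sprintf("parse error: malformed accession token '%s' at offset %d",
                     t$text, t$offset), call. = FALSE)
      return(new_node("LEAF", accession = t$text))
    }
    if (t$type == "GAP") { advance(); return(new_node("GAP")) }
    if (t$type == "LPAREN") {
      open <- advance()
      inner <- parse_or()
      t2 <- peek()
      if (is.null(t2) || t2$type != "RPAREN")
        stop(sprintf("parse error: unbalanced parenthesis opened at offset %d",
                     open$offset), call. = FALSE)
      advance()
      return(inner)
    }
    if (t$type == "COMMA") expect_fail("empty OR branch", t)
    if (t$type == "RPAREN")
      stop(sprintf("parse error: unbalanced parenthesis at offset %d", t$offset),
           call. = FALSE)
    expect_fail(sprintf("unexpected token '%s'", t$text), t)
  }

  root <- parse_or()
  if (!is.null(t <- peek()))
    expect_fail(sprintf("unexpected trailing token '%s'", t$text), t)
  normalize_node(root)
}

## ---- serializer ------------------------------------------------------------

#' Serialize a definition tree back to a DEFINITION string
#'
#' The canonical form uses single spaces and minimal parentheses; parsing
#' the output reproduces the input tree exactly (round-trip law).
#'
#' @param node a `def_node`.
#' @return a single definition string.
#' @examples
#' serialize_definition(def_and(def_leaf("K00001"), def_leaf("K00002")))
#' @export
serialize_definition <- function(node) {
  stopifnot(inherits(node, "def_node"))
  ser <- function(n) {
    switch(n$kind,
      LEAF = n$accession,
      GAP = "--",
      OPTIONAL = {
        ch <- n$children[[1]]
        s <- ser(ch)
        if (ch$kind %in% c("AND", "OR", "COMPLEX")) s <- paste0("(", s, ")")
        paste0("-", s)
      },
      AND = paste(vapply(n$children, function(ch) {
        s <- ser(ch)
        if (ch$kind == "OR") paste0("(", s, ")") else s
      }, ""), collapse = " "),
      OR = paste(vapply(n$children, function(ch) {
        s <- ser(ch)
        if (ch$kind == "AND") paste0("(", s, ")") else s
      }, ""), collapse = ","),
      COMPLEX = {
        out <- ""
        for (i in seq_along(n$children)) {
          ch <- n$children[[i]]
          if (ch$kind == "OPTIONAL") {
            inner <- ch$children[[1]]
            s <- ser(inner)
            if (inner$kind %in% c("AND", "OR", "COMPLEX")) s <- paste0("(", s, ")")
            # leading optional member needs explicit grouping so '-' is not
            # read as marking the whole chain optional
            out <- if (i == 1L) paste0("(-", s, ")") else paste0(out, "-", s)
          } else {
            s <- ser(ch)
            if (ch$kind %in% c("AND", "OR", "COMPLEX")) s <- paste0("(", s, ")")
            out <- if (i == 1L) s else paste0(out, "+", s)
          }
        }
        out
      },
      stop("unknown node kind: ", n$kind)
    )
  }
  ser(node)
}

## ---- path enumeration ------------------------------------------------------

# sentinel for a gap step: never a valid accession, so never satisfiable
GAP_MARKER <- "--"

# the set(s) of accessions that fully satisfy a node, used for complexes
satisfying_sets <- function(node, max_sets) {
  switch(node$kind,
    LEAF = list(node$accession),
    GAP = list(GAP_MARKER),
    OPTIONAL = list(character(0)),
    OR = {
      out <- list()
      for (ch in node$children) {
        out <- c(out, satisfying_sets(ch, max_sets - length(out)))
        if (length(out) >= max_sets) break
      }
      out
    },
    {
      # AND / COMPLEX: cross-product union of member sets
      out <- list(character(0))
      for (ch in node$children) {
        sets <- satisfying_sets(ch, max_sets)
        out <- unlist(lapply(out, function(a) {
          lapply(sets, function(b) sort(unique(c(a, b))))
        }), recursive = FALSE)
        if (length(out) > max_sets) out <- out[seq_len(max_sets)]
      }
      out
    }
  )
}

#' Enumerate the alternative step paths through a module
#'
#' Expands the expression tree into explicit paths: each path is one way of
#' satisfying the module, represented as an ordered list of step-sets (the
#' accessions that must all be present for that step to count). OR nodes
#' contribute one path per branch; AND nodes concatenate steps; a complex
#' contributes a single multi-member step; optional components are omitted;
#' a gap contributes one unsatisfiable step (marker `"--"`).
#'
#' @param node a `def_node`.
#' @param max_paths stop enumerating beyond this many paths (default
#'   10000); truncation is reported in the `truncated` flag, and the exact
#'   recursive evaluator in [module_completeness()] is unaffected by it.
#' @return a list with elements `paths` (list of paths; each path a list of
#'   character-vector step-sets) and `truncated` (logical).
#' @examples
#' enumerate_paths(parse_definition("(K00001,K00002) K00003"))
#' @export
enumerate_paths <- function(node, max_paths = 10000L) {
  stopifnot(inherits(node, "def_node"))
  if (!is.numeric(max_paths) || length(max_paths) != 1L || max_paths < 1)
    stop("max_paths must be a positive integer", call. = FALSE)
  max_paths <- as.integer(max_paths)
  truncated <- FALSE

  expand <- function(n, cap) {
    switch(n$kind,
      LEAF = list(list(n$accession)),
      GAP = list(list(GAP_MARKER)),
      OPTIONAL = list(list()),
      OR = {
        out <- list()
        for (ch in n$children) {
          if (length(out) >= cap) { truncated <<- TRUE; break }
          out <- c(out, expand(ch, cap - length(out)))
        }
        if (length(out) > cap) { truncated <<- TRUE; out <- out[seq_len(cap)] }
        out
      },
      AND = {
        out <- list(list())
        for (ch in n$children) {
          sub <- expand(ch, cap)
          new_out <- list()
          for (a in out) {
            for (b in sub) {
              if (length(new_out) >= cap) { truncated <<- TRUE; break }
              new_out[[length(new_out) + 1L]] <- c(a, b)
            }
            if (length(new_out) >= cap && truncated) break
          }
          out <- new_out
        }
        out
      },
      COMPLEX = {
        sets <- satisfying_sets(n, cap + 1L)
        if (length(sets) > cap) { truncated <<- TRUE; sets <- sets[seq_len(cap)] }
        lapply(sets, function(s) list(s))
      }
    )
  }

  paths <- expand(node, max_paths)
  list(paths = paths, truncated = truncated)
}

#' Count the paths implied by a definition tree
#'
#' Exact path count without materializing paths; for trees without gaps or
#' optionals this equals the product over OR nodes of their branch counts.
#'
#' @param node a `def_node`.
#' @return a double (counts can exceed integer range).
#' @export
count_paths <- function(node) {
  switch(node$kind,
    LEAF = 1,
    GAP = 1,
    OPTIONAL = 1,
    OR = sum(vapply(node$children, count_paths, 0)),
    AND = prod(vapply(node$children, count_paths, 0)),
    COMPLEX = prod(vapply(node$children, count_paths, 0))
  )
}

## ---- KEGG flat-file reader -------------------------------------------------

#' Read KEGG module flat files
#'
#' Reads records in the KEGG flat-file dialect: `ENTRY`, `NAME` and
#' `DEFINITION` lines, records terminated by `///`. Records lacking a
#' DEFINITION line are skipped with a warning.
#'
#' @param path path to a text file of module records.
#' @return a list of `module_definition` objects, each with fields
#'   `module_id`, `name`, `raw_definition` and the parsed tree `root`.
#' @export
read_kegg_modules <- function(path) {
  if (!file.exists(path)) stop("cannot read module file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("module file contains no records: ", path, call. = FALSE)
  rec_end <- grepl("^///", lines)
  rec_id <- cumsum(c(TRUE, utils::head(rec_end, -1)))
  records <- split(lines[!rec_end], rec_id[!rec_end])
  out <- list()
  for (rec in records) {
    if (!any(nzchar(trimws(rec)))) next
    field <- function(tag) {
      hit <- grep(paste0("^", tag, "\\b"), rec, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", tag, "\\s*"), "", hit[1]))
    }
    entry <- field("ENTRY")
    entry_id <- if (is.na(entry)) NA_character_ else strsplit(entry, "\\s+")[[1]][1]
    defn <- field("DEFINITION")
    if (is.na(defn) || !nzchar(defn)) {
      warning("skipping module record ",
              if (is.na(entry_id)) "<no ENTRY>" else entry_id,
              ": no DEFINITION line", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- module_definition(
      module_id = if (is.na(entry_id)) sprintf("M%05d", length(out) + 1L) else entry_id,
      name = if (is.na(field("NAME"))) "" else field("NAME"),
      raw_definition = defn
    )
  }
  if (!length(out))
    stop("module file contains no parseable records: ", path, call. = FALSE)
  out
}

#' Create a module definition object
#'
#' @param module_id module identifier, e.g. `"M00165"`.
#' @param raw_definition the DEFINITION string; parsed on construction.
#' @param name human-readable module name.
#' @return a `module_definition`: list with `module_id`, `name`,
#'   `raw_definition`, `root`.
#' @export
module_definition <- function(module_id, raw_definition, name = "") {
  structure(list(module_id = module_id, name = name,
                 raw_definition = raw_definition,
                 root = parse_definition(raw_definition)),
            class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$module_id,
      if (nzchar(x$name)) paste0(" (", x$name, ")"), "\n  ",
      x$raw_definition, "\n", sep = "")
  invisible(x)
}

#' Write module definitions in KEGG flat-file dialect
#'
#' @param modules list of `module_definition` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kegg_modules <- function(modules, path) {
  lines <- unlist(lapply(modules, function(m) {
    c(paste0("ENTRY       ", m$module_id),
      if (nzchar(m$name)) paste0("NAME        ", m$name),
      paste0("DEFINITION  ", m$raw_definition),
      "///")
  }))
  writeLines(lines, path)
  invisible(path)
}
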