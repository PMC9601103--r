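test_that("parser maps spaces to AND, commas to OR, '+' to complexes", {
  expect_identical(parse_definition("K00001 K00002"),
                   def_and(def_leaf("K00001"), def_leaf("K00002")))
  expect_identical(parse_definition("K02588"), def_leaf("K02588"))
  expect_identical(
    parse_definition("(K00001,K00002) K00003+K00004"),
    def_and(def_or(def_leaf("K00001"), def_leaf("K00002")),
            def_complex(def_leaf("K00003"), def_leaf("K00004"))))
  # comma binds looser than space: each comma branch is a whole route
  expect_identical(
    parse_definition("(K00001,K00002) K00003,K00004"),
    def_or(def_and(def_or(def_leaf("K00001"), def_leaf("K00002")),
                   def_leaf("K00003")),
           def_leaf("K00004")))
})

test_that("optional and gap markers parse to OPTIONAL and GAP nodes", {
  t <- parse_definition("K00001-K00002 -K00003 --")
  expect_identical(t$kind, "AND")
  expect_identical(t$children[[1]],
                   def_complex(def_leaf("K00001"),
                               def_optional(def_leaf("K00002"))))
  expect_identical(t$children[[2]], def_optional(def_leaf("K00003")))
  expect_identical(t$children[[3]], def_gap())
})

test_that("whitespace-only differences do not change the parse", {
  a <- parse_definition("K00001  (K00002,K00003)   K00004")
  b <- parse_definition(" K00001 (K00002 , K00003) K00004 ")
  expect_identical(a, b)
})

test_that("parse errors name the offset, token, or empty branch", {
  expect_error(parse_definition("(K00001 K00002"), "offset 1")
  expect_error(parse_definition("K00001)"), "trailing.*offset 7")
  expect_error(parse_definition("K1 K00002"), "malformed accession token 'K1'")
  expect_error(parse_definition("K00001,,K00002"), "empty OR branch")
  expect_error(parse_definition("K00001,"), "empty OR branch")
  expect_error(parse_definition(",K00001"), "empty OR branch")
  expect_error(parse_definition("   "), "empty definition")
})

test_that("serialization is the inverse of parsing (fixed cases)", {
  expect_identical(
    serialize_definition(def_and(def_leaf("K00001"), def_leaf("K00002"))),
    "K00001 K00002")
  expect_identical(serialize_definition(def_leaf("K02588")), "K02588")
  expect_identical(
    serialize_definition(def_or(def_leaf("K00001"),
                                def_and(def_leaf("K00002"), def_leaf("K00003")))),
    "K00001,(K00002 K00003)")
  # leading optional complex member needs explicit grouping
  t <- def_complex(def_optional(def_leaf("K00001")), def_leaf("K00002"))
  expect_identical(parse_definition(serialize_definition(t)), t)
})

test_that("round trip holds on random trees over the full grammar", {
  set.seed(101)
  for (i in 1:300) {
    t <- random_tree(depth = 3L)
    expect_identical(parse_definition(serialize_definition(t)), t)
  }
})

test_that("normalization is idempotent and flattens nested connectives", {
  t <- parse_definition("K00001 (K00002 K00003)")
  expect_identical(t, def_and(def_leaf("K00001"), def_leaf("K00002"),
                              def_leaf("K00003")))
  set.seed(202)
  for (i in 1:100) {
    t <- random_tree(depth = 3L)
    expect_identical(magmetab:::normalize_node(t), t)
  }
})

test_that("path enumeration expands ORs, complexes, optionals and gaps", {
  expect_identical(enumerate_paths(def_leaf("K00001"))$paths,
                   list(list("K00001")))
  e <- enumerate_paths(parse_definition("(K00001,K00002) K00003"))
  expect_false(e$truncated)
  expect_identical(e$paths, list(list("K00001", "K00003"),
                                 list("K00002", "K00003")))
  # complex: one path, one step requiring both subunits
  e <- enumerate_paths(def_complex(def_leaf("K00001"), def_leaf("K00002")))
  expect_identical(e$paths, list(list(c("K00001", "K00002"))))
  # optional contributes no step; gap contributes the unsatisfiable marker
  e <- enumerate_paths(parse_definition("K00001 -K00002 --"))
  expect_identical(e$paths, list(list("K00001", "--")))
})

test_that("truncation flags when the cap is hit and errors on bad cap", {
  big <- parse_definition(paste(rep("(K00001,K00002)", 5), collapse = " "))
  e <- enumerate_paths(big, max_paths = 10)
  expect_true(e$truncated)
  expect_length(e$paths, 10)
  expect_false(enumerate_paths(big, max_paths = 32)$truncated)
  expect_error(enumerate_paths(big, max_paths = 0), "positive integer")
})

test_that("path count equals product of OR branch counts (non-nested ORs)", {
  set.seed(303)
  next_ko <- new_ko_counter()
  for (i in 1:50) {
    n_or <- sample(0:4, 1)
    parts <- c(
      lapply(seq_len(n_or), function(j) {
        branches <- lapply(seq_len(sample(2:3, 1)), function(k) def_leaf(next_ko()))
        do.call(def_or, branches)
      }),
      lapply(seq_len(sample(2:3, 1)), function(j) def_leaf(next_ko())))
    tree <- do.call(def_and, parts[sample(length(parts))])
    expected <- prod(vapply(tree$children, function(ch)
      if (ch$kind == "OR") length(ch$children) else 1, 0))
    e <- enumerate_paths(tree, max_paths = 1e6)
    expect_false(e$truncated)
    expect_length(e$paths, expected)
    expect_equal(count_paths(tree), expected)
  }
})

test_that("count_paths agrees with materialized enumeration", {
  set.seed(404)
  for (i in 1:100) {
    t <- random_small_tree(max_leaves = 10L)
    e <- enumerate_paths(t, max_paths = 1e6)
    expect_false(e$truncated)
    expect_equal(count_paths(t), length(e$paths))
  }
})

test_that("flat-file reader parses records and applies the skip rule", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "ENTRY       M00001",
    "NAME        test module",
    "DEFINITION  K00001 (K00002,K00003)",
    "///",
    "ENTRY       M00002",
    "NAME        record without a definition",
    "///"), path)
  expect_warning(mods <- read_kegg_modules(path), "M00002.*no DEFINITION")
  expect_length(mods, 1)
  expect_identical(mods[[1]]$module_id, "M00001")
  expect_identical(mods[[1]]$root, parse_definition("K00001 (K00002,K00003)"))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), empty)
  expect_error(read_kegg_modules(empty), "no records")
  expect_error(read_kegg_modules("/nonexistent/file.txt"), "cannot read")
})

test_that("module files round-trip through write_kegg_modules", {
  path <- withr::local_tempfile(fileext = ".txt")
  mods <- list(module_definition("M00010", "K00001 K00002", name = "two step"),
               module_definition("M00011", "(K00003,K00004) K00005+K00006"))
  write_kegg_modules(mods, path)
  back <- read_kegg_modules(path)
  expect_identical(lapply(back, `[[`, "root"), lapply(mods, `[[`, "root"))
  expect_identical(vapply(back, `[[`, "", "module_id"), c("M00010", "M00011"))
})
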