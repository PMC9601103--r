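test_that("path_completeness counts fully satisfied step-sets", {
  expect_identical(path_completeness(list("A1", "A2"), c("A1", "A2")),
                   list(satisfied = 2L, total = 2L))
  expect_identical(path_completeness(list("A1", "A2", "A3"), c("A1", "A2")),
                   list(satisfied = 2L, total = 3L))
  # complex step unsatisfied when one subunit is missing
  expect_identical(path_completeness(list(c("A1", "A2"), "A3"), c("A1", "A3")),
                   list(satisfied = 1L, total = 2L))
  # gap steps never satisfied, even against a superset
  expect_identical(path_completeness(list("A1", "--"), c("A1", "--")),
                   list(satisfied = 1L, total = 2L))
  expect_error(path_completeness(list(), "A1"), "non-empty")
})

test_that("module_completeness picks the best alternative route", {
  or2 <- def_or(def_leaf("K00001"), def_leaf("K00002"))
  expect_equal(module_completeness(or2, "K00001")$completeness, 1.0)
  t <- parse_definition("(K00001,K00002) K00003")
  r <- module_completeness(t, "K00002")
  expect_equal(r$completeness, 0.5)
  expect_identical(r$best_path, list("K00002", "K00003"))
  expect_equal(module_completeness(t, character())$completeness, 0)
  # all-optional module is degenerate, not complete
  d <- module_completeness(parse_definition("-K00001"), "K00001")
  expect_true(d$degenerate)
  expect_identical(d$total_steps, 0L)
  expect_equal(d$completeness, 0)
})

test_that("ties between equal-ratio routes break toward fewer steps", {
  # 1/2 on the short branch vs 2/4 on the long one: short branch wins
  t <- def_or(def_and(def_leaf("K00001"), def_leaf("K00002")),
              def_and(def_leaf("K00003"), def_leaf("K00004"),
                      def_leaf("K00005"), def_leaf("K00006")))
  r <- module_completeness(t, c("K00001", "K00003", "K00004"))
  expect_identical(r$total_steps, 2L)
  expect_identical(r$best_path, list("K00001", "K00002"))
})

test_that("recursive evaluator equals the exhaustive-path oracle exactly", {
  set.seed(505)
  for (i in 1:150) {
    tree <- random_small_tree(max_leaves = 12L)
    leaves <- tree_leaves(tree)
    present <- sample(leaves, sample(0:length(leaves), 1))
    got <- module_completeness(tree, present)
    want <- oracle_completeness(tree, present)
    if (is.null(want)) {
      expect_true(got$degenerate)
    } else {
      # exact rational equality via cross-multiplication
      expect_identical(got$satisfied_steps * want$total,
                       want$satisfied * got$total_steps)
    }
  }
})

test_that("the greedy per-node ratio choice would be wrong where DP is right", {
  # choosing the locally best OR branch (1/1 over 9/10) gives 1/11 here;
  # the true optimum is 9/20 and the evaluator must find it
  long <- do.call(def_and, lapply(1:10, function(i) def_leaf(sprintf("K001%02d", i))))
  pad <- do.call(def_and, lapply(1:10, function(i) def_leaf(sprintf("K002%02d", i))))
  tree <- def_and(def_or(def_leaf("K00301"), long), pad)
  present <- c("K00301", sprintf("K001%02d", 1:9))
  r <- module_completeness(tree, present)
  expect_identical(r$satisfied_steps, 9L)
  expect_identical(r$total_steps, 20L)
})

test_that("completeness is monotone, bounded, and 1 iff a path is complete", {
  set.seed(606)
  for (i in 1:40) {
    tree <- random_small_tree(max_leaves = 10L)
    leaves <- tree_leaves(tree)
    present <- sample(leaves, sample(0:length(leaves), 1))
    base <- module_completeness(tree, present)
    expect_gte(base$completeness, 0)
    expect_lte(base$completeness, 1)
    extra <- setdiff(leaves, present)
    if (length(extra)) {
      grown <- module_completeness(tree, c(present, sample(extra, 1)))
      expect_gte(grown$completeness, base$completeness)
    }
    full <- module_completeness(tree, leaves)
    enum <- enumerate_paths(tree, max_paths = 1e6)
    has_gap_free_path <- any(vapply(enum$paths, function(p)
      length(p) > 0 && !any(vapply(p, function(s) "--" %in% unlist(s), NA)),
      NA))
    if (has_gap_free_path) expect_equal(full$completeness, 1)
    else expect_lt(full$completeness, 1)
  }
})

test_that("detect_metabolism applies the two-thirds presence criterion", {
  mod3 <- module_definition("M00001", "K00001 K00002 K00003", "linear 3-step")
  expect_true(detect_metabolism(mod3, make_mag("m", c("K00001", "K00002")))$present)
  expect_false(detect_metabolism(mod3, make_mag("m", "K00001"))$present)
  mod1 <- module_definition("M00002", "K00009")
  expect_true(detect_metabolism(mod1, make_mag("m", "K00009"),
                                threshold = 1)$present)
  expect_error(detect_metabolism(mod3, make_mag("m"), threshold = 1.5),
               "threshold")
})

test_that("gene-counting mode scores distinct accessions on the best path", {
  # complex of 2 genes + 1 step: steps mode 1/2; genes mode 1/3 with only A1
  mod <- module_definition("M00003", "K00001+K00002 K00003")
  mag <- make_mag("m", "K00001")
  expect_equal(detect_metabolism(mod, mag)$completeness, 0)
  g <- detect_metabolism(mod, mag, count_mode = "genes")
  expect_equal(g$completeness, 1 / 3)
  # gap contributes one unsatisfiable pseudo-gene
  modg <- module_definition("M00004", "K00001 --")
  expect_equal(detect_metabolism(modg, mag, count_mode = "genes")$completeness,
               1 / 2)
})

test_that("score_all is complete, ordered, deterministic, and guards dups", {
  mags <- list(make_mag("MAG_B", c("K00001", "K00002")), make_mag("MAG_A"))
  mods <- list(module_definition("M00002", "K00003"),
               module_definition("M00001", "K00001 K00002 K00003"))
  tab <- score_all(mags, mods)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$mag_id, c("MAG_A", "MAG_A", "MAG_B", "MAG_B"))
  expect_identical(tab$module_id, rep(c("M00001", "M00002"), 2))
  expect_true(all(tab$completeness[tab$mag_id == "MAG_A"] == 0))
  expect_identical(tab, score_all(mags, mods))
  expect_error(score_all(c(mags, mags[1]), mods), "duplicate mag_id")
})
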