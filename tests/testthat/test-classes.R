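gadget <- fixtures()$gadget
witness_ltb <- fixtures()$labellable_not_tree_based

test_that("visibility identifies vertices on all root-to-leaf paths", {
  tr <- phylocover:::random_tree_network(5)
  expect_setequal(visible_vertices(tr), tr$vertices)
  vis <- visible_vertices(gadget)
  expect_false(any(c("u", "v") %in% vis))
  expect_true(all(names(gadget$leaf_label) %in% vis))
})

test_that("equal children sets make both vertices invisible", {
  for (s in 1:10) {
    N <- random_network(4 + s %% 4, 1, class = "unrestricted", seed = s,
                        gadget_prob = 1)
    nl <- phylocover:::non_leaf_vertices(N)
    keys <- vapply(nl, function(v) paste(sort(children(N, v)), collapse = ","),
                   character(1))
    vis <- visible_vertices(N)
    for (k in unique(keys[duplicated(keys)])) {
      expect_false(any(nl[keys == k] %in% vis))
    }
  }
})

test_that("tree-child equals all-vertices-visible", {
  expect_true(is_tree_child(cherry_tree()))
  expect_false(isTRUE(is_tree_child(gadget)))
  for (s in 1:15) {
    N <- random_network(4 + s %% 4, 1 + s %% 3,
                        class = if (s %% 2) "nondegenerate" else "unrestricted",
                        seed = s)
    expect_equal(isTRUE(is_tree_child(N)),
                 setequal(visible_vertices(N), N$vertices))
  }
})

test_that("tree-sibling requires a tree-vertex sibling at each reticulation", {
  expect_true(is_tree_sibling(cherry_tree()))
  expect_true(is_tree_sibling(minimal_reticulation_net()))
  res <- is_tree_sibling(gadget)
  expect_false(isTRUE(res))
  expect_setequal(attr(res, "witness"), c("r1", "r2"))
})

test_that("cherries and reticulated cherries are enumerated", {
  expect_equal(find_cherries(cherry_tree()), list(c(1L, 2L)))
  expect_equal(find_cherries(minimal_reticulation_net()), list())
  rc <- find_reticulated_cherries(minimal_reticulation_net())
  expect_setequal(lapply(rc, paste, collapse = "-"), list("3-1", "3-2"))
  expect_equal(find_cherries(gadget), list())
  expect_equal(find_reticulated_cherries(gadget), list())
})

test_that("orchard recognition reduces trees and generated orchard networks", {
  for (s in 1:8) {
    expect_true(is_orchard_binary(phylocover:::random_tree_network(3 + s %% 5)))
    expect_true(is_orchard_binary(
      random_network(4 + s %% 4, 1 + s %% 3, class = "orchard_binary",
                     seed = s)))
  }
  # cherry-free binary networks cannot start a reduction
  expect_false(is_orchard_binary(gadget))
  expect_error(is_orchard_binary(parse_network("((1,2));")), "binary")
})

test_that("the fixed reduction order agrees with exhaustive backtracking", {
  nets <- c(
    lapply(1:6, function(s)
      random_network(3 + s %% 3, 1 + s %% 2, class = "nondegenerate", seed = s)),
    lapply(1:6, function(s)
      random_network(3 + s %% 3, 2, class = "orchard_binary", seed = s)),
    list(gadget, witness_ltb, stacked_reticulation_net())
  )
  for (N in nets) {
    if (!is_binary(N)) next
    expect_equal(is_orchard_binary(N), oracle_orchard(N))
  }
})

test_that("tree-based search and the omnian matching agree", {
  expect_true(is_tree_based(cherry_tree()))
  expect_true(is_tree_based(gadget))
  expect_true(is_tree_based_matching(gadget))
  expect_false(is_tree_based(stacked_reticulation_net()))
  expect_false(is_tree_based_matching(stacked_reticulation_net()))
  for (s in 1:20) {
    N <- random_network(3 + s %% 4, 1 + s %% 3, class = "nondegenerate",
                        seed = 50 + s)
    expect_equal(is_tree_based(N), is_tree_based_matching(N))
  }
})

test_that("labellable and tree-based classes are not nested", {
  # tree-based but not labellable
  expect_true(is_tree_based(gadget))
  expect_false(isTRUE(is_labellable(gadget)))
  # labellable but not tree-based: three vertices whose children are all
  # reticulations compete for two reticulations
  expect_true(isTRUE(is_labellable(witness_ltb)))
  expect_true(is_binary(witness_ltb))
  expect_false(is_tree_based(witness_ltb))
  expect_false(is_tree_based_matching(witness_ltb))
})

test_that("binary tree-based networks are labellable iff reticulation parent sets differ", {
  for (cfg in list(c(2, 2), c(3, 2), c(4, 1))) {
    nets <- enumerate_tree_based_binary(cfg[1], cfg[2])
    for (N in nets) {
      rets <- phylocover:::reticulations(N)
      pkeys <- vapply(rets, function(r)
        paste(sort(parents(N, r)), collapse = ","), character(1))
      expect_equal(isTRUE(is_labellable(N)), !anyDuplicated(pkeys) > 0)
    }
  }
})

test_that("normality excludes shortcut edges", {
  expect_true(is_normal(cherry_tree()))
  sc <- is_normal(shortcut_net())
  expect_false(isTRUE(sc))
  expect_true(isTRUE(is_tree_child(shortcut_net())))
  for (s in 1:8) {
    N <- random_network(4 + s %% 4, 1 + s %% 2, class = "normal", seed = s)
    expect_true(isTRUE(is_normal(N)))
    expect_true(isTRUE(is_tree_child(N)))
    expect_true(is_orchard_binary(N))
    expect_true(isTRUE(is_tree_sibling(N)))
    expect_true(isTRUE(is_labellable(N)))
  }
})

test_that("class containments hold on generated members", {
  for (s in 1:10) {
    tc <- random_network(4 + s %% 4, 1 + s %% 2, class = "tree_child", seed = s)
    expect_true(isTRUE(is_labellable(tc)))
    expect_true(isTRUE(is_tree_sibling(tc)))
    if (is_binary(tc)) expect_true(is_orchard_binary(tc))
    ts <- random_network(4 + s %% 4, 1 + s %% 2, class = "tree_sibling",
                         seed = s)
    expect_true(isTRUE(is_labellable(ts)))
    orc <- random_network(4 + s %% 4, 1 + s %% 2, class = "orchard_binary",
                          seed = s)
    expect_true(isTRUE(is_labellable(orc)))
    # no orchard network contains two vertices with equal children sets
    nl <- phylocover:::non_leaf_vertices(orc)
    keys <- vapply(nl, function(v) paste(sort(children(orc, v)), collapse = ","),
                   character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("the aggregate report collects flags and witnesses", {
  tr <- phylocover:::random_tree_network(4)
  rep_tr <- classify(tr)
  expect_true(rep_tr$labellable && rep_tr$tree_child && rep_tr$tree_sibling &&
                rep_tr$orchard && rep_tr$tree_based && rep_tr$normal)
  rep_g <- classify(gadget)
  expect_false(rep_g$labellable)
  expect_false(rep_g$tree_child)
  expect_false(rep_g$tree_sibling)
  expect_true(rep_g$tree_based)
  expect_length(rep_g$witnesses$labellable, 2L)
  rep_ex <- classify(network_from_cover(fixtures()$ex_cover))
  expect_true(rep_ex$labellable)
  expect_false(rep_ex$nondegenerate)
  expect_true("11" %in% rep_ex$witnesses$nondegenerate)
  # degenerate networks leave the non-degenerate-only predicates absent
  expect_true(is.na(rep_ex$orchard))
  expect_true(is.na(rep_ex$tree_sibling))
})
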