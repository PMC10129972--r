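ex_cover <- fixtures()$ex_cover
fig_cover <- fixtures()$degenerate_cover

test_that("cover extraction matches the worked examples", {
  expect_true(covers_equal(cover_of(cherry_tree()),
                           set_cover(list(c(1, 2)))))
  expect_true(covers_equal(cover_of(network_from_cover(fig_cover)),
                           fig_cover))
  expect_true(covers_equal(cover_of(network_from_cover(ex_cover)),
                           ex_cover))
})

test_that("the implied leaf count is m - |C| + 1", {
  expect_equal(implied_leaf_count(ex_cover), 5L)
  expect_equal(implied_leaf_count(set_cover(list(c(1, 2)))), 2L)
  expect_equal(implied_leaf_count(fig_cover), 5L)
  expect_error(implied_leaf_count(set_cover(list(1, 2, c(1, 2)))),
               "leaf count")
})

test_that("the expanding conditions are checked with witnesses", {
  expect_true(is_expanding(ex_cover))
  bad <- is_expanding(set_cover(list(1, c(1, 2))))
  expect_false(isTRUE(bad))
  expect_match(attr(bad, "reason"), "condition \\(1\\)")
  expect_true(is_expanding(set_cover(list(3, c(1, 2), c(4, 5)))))
  short <- is_expanding(set_cover(list(c(1, 4), c(2, 3), c(3, 4))))
  expect_false(isTRUE(short))
  expect_match(attr(short, "reason"), "condition \\(2\\)")
})

test_that("the labelling order follows the greedy eligible-minimum rule", {
  lo <- labelling_order(ex_cover)
  expect_equal(lo$sequence,
               list(c(2L), c(1L, 6L), c(5L), c(4L, 8L), c(3L, 6L, 9L),
                    c(10L), c(7L, 11L), c(8L, 12L)))
  expect_equal(lo$labels, 6:13)
  expect_equal(labelling_order(set_cover(list(c(1, 2))))$sequence,
               list(c(1L, 2L)))
  expect_equal(labelling_order(set_cover(list(3, c(1, 2), c(4, 5))))$sequence,
               list(c(1L, 2L), 3L, c(4L, 5L)))
})

test_that("the order condition flags exactly the degenerate labels", {
  expect_equal(order_condition_violations(ex_cover), 11L)
  expect_equal(order_condition_violations(fig_cover), c(6L, 8L))
  # a partition with all blocks of size >= 2 has no singletons and no
  # repeats, so no violations
  expect_equal(order_condition_violations(
    set_cover(list(c(1, 2), c(3, 4), c(5, 6, 7)))), integer(0))
  # a singleton final set is a root-degeneracy warning, not a violation
  expect_warning(
    v <- order_condition_violations(set_cover(list(c(1, 2), 3))),
    "out-degree 1")
  expect_equal(v, integer(0))
})

test_that("network reconstruction realises multiplicities as in-degrees", {
  N <- network_from_cover(ex_cover)
  indeg2 <- N$vertices[lengths(N$parents_of) == 2L]
  expect_setequal(indeg2, c("6", "8"))
  expect_true(networks_isomorphic(network_from_cover(set_cover(list(c(1, 2)))),
                                  cherry_tree()))
})

test_that("cover and network round trips are mutually inverse", {
  for (s in 1:40) {
    n <- 2 + s %% 6
    C <- random_expanding_cover(n, n + 1 + s %% 6, seed = s)
    expect_true(covers_equal(cover_of(network_from_cover(C)), C))
    N <- random_network(n + 1, 1 + s %% 3, class = "labellable", seed = s)
    expect_true(networks_isomorphic(network_from_cover(cover_of(N)), N))
    expect_equal(implied_leaf_count(cover_of(N)), N$n)
  }
})

test_that("label multiplicity is in-degree and set size is out-degree", {
  for (s in 1:10) {
    C <- random_expanding_cover(3 + s %% 4, 8 + s %% 4, seed = 100 + s)
    N <- network_from_cover(C)
    mult <- tabulate(unlist(C$sets), nbins = C$m)
    for (k in seq_len(C$m))
      expect_equal(length(parents(N, as.character(k))), mult[k])
    lo <- labelling_order(C)
    n <- implied_leaf_count(C)
    for (i in seq_along(lo$sequence)) {
      v <- if (n + i > C$m) N$root else as.character(n + i)
      expect_equal(length(children(N, v)), length(lo$sequence[[i]]))
    }
  }
})

test_that("partition covers reconstruct to trees", {
  parts <- list(
    set_cover(list(c(1, 2), c(3, 4), c(5, 6, 7))),
    set_cover(list(c(1, 2, 3), c(4, 5))),
    set_cover(list(c(2, 3), c(1, 4)))
  )
  for (P in parts) {
    N <- network_from_cover(P)
    expect_equal(max(lengths(N$parents_of)), 1L)
    expect_true(isTRUE(is_tree_child(N)))
  }
})

test_that("cover text and JSON formats round trip", {
  txt <- "2\n5\n1,6\n4,8\n3,6,9\n10\n7,11\n8,12"
  expect_true(covers_equal(parse_cover(txt), ex_cover))
  expect_true(covers_equal(parse_cover("1,2"), set_cover(list(c(1, 2)))))
  expect_error(parse_cover("1,2\n2,1"), "duplicate")
  expect_error(parse_cover("1,2\n\n4"), "missing|union")
  expect_error(parse_cover('{"m": 3, "sets": [[1,2]]}'), "union|missing")
  for (fmt in c("json", "lines")) {
    expect_true(covers_equal(parse_cover(write_cover(ex_cover, fmt)),
                             ex_cover))
  }
})
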