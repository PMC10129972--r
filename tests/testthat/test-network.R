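test_that("eNewick parsing builds the expected structures", {
  N <- parse_network("((1,2));")
  expect_equal(length(N$vertices), 4L)
  expect_equal(N$n, 2L)
  expect_equal(length(children(N, N$root)), 1L)

  H <- parse_network("((1,(2)#H1),(#H1,3));")
  expect_equal(length(H$vertices), 7L)
  expect_equal(nrow(H$edges), 7L)
  ret <- H$vertices[lengths(H$parents_of) == 2L]
  expect_length(ret, 1L)
  kid <- children(H, ret)
  expect_equal(unname(H$leaf_label[kid]), 2L)
})

test_that("edge-list parsing recognises reticulations and leaf labels", {
  txt <- "r\ta\nr\tb\na\t1\na\tx\nb\tx\nb\t2\nx\t3"
  N <- parse_network(txt, format = "edgelist")
  expect_equal(N$n, 3L)
  expect_setequal(parents(N, "x"), c("a", "b"))
  expect_equal(children(N, "1"), character(0))
  expect_equal(parents(N, "r"), character(0))
})

test_that("invalid networks are rejected with informative errors", {
  expect_error(phylo_network(rbind(c("r", "a"), c("r", "1"), c("a", "1"))),
               "in-degree 1")
  expect_error(phylo_network(rbind(c("r", "1"), c("r2", "2"))),
               "exactly one root")
  expect_error(phylo_network(rbind(c("r", "a"), c("a", "r"), c("r", "1"),
                                   c("a", "2"))),
               "cycle|root")
  expect_error(phylo_network(rbind(c("r", "x"), c("r", "x"), c("x", "1"))),
               "parallel")
  expect_error(phylo_network(rbind(c("r", "lf"), c("r", "2"))),
               "integer")
  expect_error(parse_network("((1,2);"), "position")
})

test_that("vertex classification follows the degree rules", {
  N <- network_from_cover(fixtures()$ex_cover)
  expect_equal(classify_vertex(N, "11"),
               list(role = "tree_vertex", degeneracy = "degenerate_tree"))
  expect_equal(classify_vertex(N, "6")$role, "reticulation")
  expect_equal(classify_vertex(N, N$root)$role, "root")
  expect_equal(classify_vertex(N, "3")$role, "leaf")
  # degenerate reticulation: in 2, out 2
  D <- phylo_network(rbind(c("r", "a"), c("r", "b"), c("a", "x"), c("b", "x"),
                           c("x", "1"), c("x", "2")))
  expect_equal(classify_vertex(D, "x")$degeneracy, "degenerate_reticulation")
  expect_false(is_nondegenerate(D))
})

test_that("binarity requires root out-degree 2 and total degree 3 inside", {
  expect_true(is_binary(cherry_tree()))
  expect_true(is_binary(minimal_reticulation_net()))
  expect_false(is_binary(network_from_cover(fixtures()$degenerate_cover)))
  expect_false(is_binary(parse_network("((1,2));")))
})

test_that("write/parse round trips preserve the leaf-labelled structure", {
  for (fmt in c("enewick", "edgelist")) {
    rt <- parse_network(write_network(cherry_tree(), fmt), fmt)
    expect_true(networks_isomorphic(rt, cherry_tree()))
  }
  N <- network_from_cover(fixtures()$ex_cover)
  rt <- parse_network(write_network(N, "enewick"))
  expect_true(covers_equal(cover_of(rt), fixtures()$ex_cover))
  for (s in 1:25) {
    M <- random_network(3 + (s %% 5), 1 + (s %% 3),
                        class = "nondegenerate", seed = s)
    expect_true(networks_isomorphic(
      parse_network(write_network(M, "enewick")), M))
    expect_true(networks_isomorphic(
      parse_network(write_network(M, "edgelist"), "edgelist"), M))
  }
})

test_that("any partial labelling covering the leaves leaves some vertex with fully labelled children", {
  for (s in 1:10) {
    N <- random_network(4 + (s %% 4), 2, class = "unrestricted", seed = s)
    nl <- setdiff(N$vertices, names(N$leaf_label))
    for (rep in 1:5) {
      labelled <- with_seed_local(100 * s + rep, {
        c(names(N$leaf_label), sample(nl, sample.int(length(nl), 1L) - 1L))
      })
      unlabelled <- setdiff(N$vertices, labelled)
      if (!length(unlabelled)) next
      ready <- Filter(function(v) all(children(N, v) %in% labelled),
                      unlabelled)
      expect_gt(length(ready), 0L)
    }
  }
})
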