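test_that("td parsing, width and round-trip", {
  td <- parse_td("s td 2 3 4\nb 1 1 2 3\nb 2 1 3 4\n1 2")
  expect_equal(length(td$bags), 2)
  expect_setequal(td$bags[["1"]], c("1", "2", "3"))
  expect_equal(decomposition_width(td), 2)

  single <- parse_td("s td 1 0 0\nb 1")
  expect_equal(decomposition_width(single), -1)

  expect_equal(decomposition_width(tree_decomposition()), -1)
  expect_equal(decomposition_width(
    tree_decomposition(list("1" = c("1", "2"), "2" = c("2", "3")),
                       cbind(1, 2))), 1)

  for (seed in 1:4) {
    td <- random_instance(6, 0.4, seed)$td
    rt <- parse_td(write_td(td))
    expect_equal(rt$bags[order(as.integer(names(rt$bags)))],
                 lapply(td$bags, sort)[order(as.integer(names(td$bags)))])
  }

  expect_error(parse_td("s td 2 2 2\nb 1 1\nb 1 2\n1 1"), "repeated")
  expect_error(parse_td("s td 2 2 2\nb 1 1\nb 2 2\n1 3"), "undeclared")
  expect_error(parse_td("s td 2 2 2\nb 1 1\nb 2 2"), "tree")
})

test_that("validator reports lost edges, uncovered and disconnected vertices", {
  k3 <- make_complete(3)
  bad <- tree_decomposition(list("1" = c("1", "2"), "2" = c("2", "3")),
                            cbind(1, 2))
  rep1 <- validate_decomposition(k3, bad)
  expect_false(rep1$ok)
  expect_equal(treediet:::edge_keys(rep1$lost_edges), "1|3")

  good <- single_bag_decomposition(k3)
  expect_true(validate_decomposition(k3, good)$ok)

  p3 <- make_path_graph(3)
  disc <- tree_decomposition(list("1" = c("1", "2"), "2" = c("2", "3"),
                                  "3" = c("1", "3")),
                             cbind(c(1, 2), c(2, 3)))
  rep3 <- validate_decomposition(p3, disc)
  expect_false(rep3$ok)
  expect_equal(rep3$disconnected_vertices, "1")

  vl <- visible_and_lost_edges(k3, bad)
  expect_equal(nrow(vl$visible) + nrow(vl$lost), 3)
  expect_equal(treediet:::edge_keys(vl$lost), "1|3")
})

test_that("heuristic decompositions are valid and reach known widths", {
  tree <- diet_graph(as.character(1:7),
                     data.frame(u = as.character(c(1, 1, 2, 2, 3, 3)),
                                v = as.character(2:7)))
  for (m in c("min-degree", "min-fill", "lex-bfs")) {
    td <- heuristic_decomposition(tree, m, seed = 3)
    expect_true(validate_decomposition(tree, td)$ok)
    expect_equal(decomposition_width(td), 1)   # trees are chordal
  }
  expect_equal(decomposition_width(heuristic_decomposition(make_complete(5))), 4)
  c6 <- make_cycle(6)
  expect_equal(decomposition_width(heuristic_decomposition(c6, "min-fill")),
               exhaustive_treewidth(c6))   # both give 2
  expect_error(heuristic_decomposition(make_cycle(3), "nope"))
  # validity is a property of every random instance
  for (seed in 1:8) {
    inst <- random_instance(3 + (seed %% 6), 0.1 * seed, seed)
    expect_true(validate_decomposition(inst$graph, inst$td)$ok)
    expect_gte(decomposition_width(inst$td), exhaustive_treewidth(inst$graph))
  }
})

test_that("rooting adds an empty root, preserves content, and is idempotent", {
  td <- tree_decomposition(list("1" = c("1", "2")))
  rtd <- root_with_empty_bag(td)
  expect_equal(length(rtd$bags[[as.character(rtd$root)]]), 0)
  expect_equal(length(rtd$bags), 2)
  expect_equal(decomposition_width(rtd), decomposition_width(td))

  path3 <- tree_decomposition(list("1" = "1", "2" = c("1", "2"), "3" = "2"),
                              cbind(c(1, 2), c(2, 3)))
  r3 <- root_with_empty_bag(path3)
  expect_equal(length(r3$bags), 4)
  expect_equal(max_children(r3), 1)

  r3b <- root_with_empty_bag(r3)     # already has an empty bag: no growth
  expect_equal(length(r3b$bags), length(r3$bags))

  g <- make_path_graph(2)
  vl1 <- visible_and_lost_edges(g, td)
  vl2 <- visible_and_lost_edges(g, root_with_empty_bag(td))
  expect_equal(vl1$lost, vl2$lost)
})

test_that("binarization caps children at 2 and preserves validity and width", {
  # root child with 3 leaf children -> chain with 2 copies
  td <- tree_decomposition(list("1" = c("a", "b"), "2" = c("a", "c"),
                                "3" = c("b", "d"), "4" = c("a", "e")),
                           cbind(c(1, 1, 1), c(2, 3, 4)))
  g <- diet_graph(letters[1:5],
                  data.frame(u = c("a", "a", "b", "a"),
                             v = c("b", "c", "d", "e")))
  rtd <- root_with_empty_bag(td)
  b <- binarize(rtd)
  expect_lte(max_children(b), 2)
  expect_equal(decomposition_width(b), decomposition_width(rtd))
  expect_true(validate_decomposition(g, b)$ok)
  expect_equal(length(b$bags), length(rtd$bags) + 1)  # one duplicated copy

  # star of 5 children: c - 1 = 4 chained copies
  star <- tree_decomposition(
    c(list("1" = "h"), stats::setNames(lapply(2:6, function(i)
      c("h", letters[i])), 2:6)), cbind(1, 2:6))
  gs <- diet_graph(c("h", letters[2:6]),
                   data.frame(u = "h", v = letters[2:6]))
  bs <- binarize(root_with_empty_bag(star))
  expect_lte(max_children(bs), 2)
  expect_equal(length(bs$bags), length(star$bags) + 1 + 3)
  expect_true(validate_decomposition(gs, bs)$ok)

  # already binary: same bag count
  bb <- binarize(b)
  expect_equal(length(bb$bags), length(b$bags))
})

test_that("path decompositions are recognized", {
  expect_true(is_path_decomposition(
    tree_decomposition(list("1" = "a", "2" = "a", "3" = "a"),
                       cbind(c(1, 2), c(2, 3)))))
  expect_false(is_path_decomposition(
    tree_decomposition(list("1" = "a", "2" = "a", "3" = "a", "4" = "a"),
                       cbind(1, 2:4))))
  expect_true(is_path_decomposition(tree_decomposition(list("1" = "a"))))
})
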