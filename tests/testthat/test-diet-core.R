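test_that("worked examples: K3, C4, protected backbone, identity diet", {
  k3 <- make_complete(3)
  r1 <- tree_diet(k3, root_with_empty_bag(single_bag_decomposition(k3)), 1)
  expect_equal(r1$objective, 1)
  expect_equal(nrow(r1$lost_edges), 2)
  expect_lte(decomposition_width(r1$thinned), 1)

  c4 <- diet_graph(letters[1:4],
                   data.frame(u = c("a", "b", "c", "a"),
                              v = c("b", "c", "d", "d")))
  td4 <- tree_decomposition(list("1" = c("a", "b", "c"),
                                 "2" = c("a", "c", "d")), cbind(1, 2))
  r2 <- tree_diet(c4, root_with_empty_bag(td4), 1)
  expect_equal(nrow(r2$lost_edges), 2)

  # width-1 diet of a 3-path decomposition must sacrifice a backbone edge
  gp <- diet_graph(as.character(1:4),
                   data.frame(u = as.character(1:3), v = as.character(2:4),
                              backbone = TRUE))
  tdp <- tree_decomposition(list("1" = as.character(1:3),
                                 "2" = as.character(2:4)), cbind(1, 2))
  expect_warning(
    r3 <- tree_diet(gp, root_with_empty_bag(tdp), diet_params(1, "count", TRUE)),
    "backbone")
  expect_equal(nrow(r3$lost_edges), 1)
  expect_true(all(r3$lost_edges$backbone))
  expect_equal(nrow(r3$lost_backbone), 1)

  # target >= input width: identity diet
  r4 <- tree_diet(c4, root_with_empty_bag(td4), 2)
  expect_equal(nrow(r4$lost_edges), 0)
  expect_equal(r4$objective, 4)

  # target -1 deletes everything
  r5 <- tree_diet(k3, root_with_empty_bag(single_bag_decomposition(k3)), -1)
  expect_equal(r5$objective, 0)
  expect_equal(nrow(r5$lost_edges), 3)
})

as_rooted_nonempty <- function(g) {
  treediet:::as_rooted(single_bag_decomposition(g), 1L)
}

test_that("preconditions are enforced", {
  k3 <- make_complete(3)
  bad <- root_with_empty_bag(
    tree_decomposition(list("1" = c("1", "2"), "2" = c("2", "3")),
                       cbind(1, 2)))
  expect_error(tree_diet(k3, bad, 1), "not valid")
  # non-empty root
  rtd <- as_rooted_nonempty(k3)
  expect_error(tree_diet(k3, rtd, 1), "root bag must be empty")
  expect_error(diet_params(-2), ">= -1")
})

test_that("traceback colorings are valid and consistent with the objective", {
  for (seed in 1:10) {
    inst <- random_instance(4 + (seed %% 4), 0.5, seed)
    w <- decomposition_width(inst$td)
    rtd <- root_with_empty_bag(inst$td)
    tw <- max(w - 1 - (seed %% 2), -1)
    res <- tree_diet(inst$graph, rtd, tw)
    expect_true(check_coloring_validity(rtd, res$coloring)$ok)
    expect_equal(res$objective, nrow(res$kept_edges))
    # conservation
    expect_equal(res$objective + nrow(res$lost_edges), nrow(inst$graph$edges))
    # feasibility of the thinned decomposition
    expect_lte(decomposition_width(res$thinned), max(tw, 0))
    kept_g <- diet_graph(inst$graph$vertices, res$kept_edges)
    expect_true(validate_decomposition(kept_g, res$thinned)$ok)
    # per-link count sets partition the realizable set
    acc <- count_set_accounting(inst$graph, rtd, res$coloring)
    expect_false(acc$duplicated)
    expect_equal(acc$total, nrow(res$kept_edges))
    expect_setequal(acc$keys, treediet:::edge_keys(res$kept_edges))
    # state-count bound
    sizes <- vapply(rtd$bags, length, integer(1))
    expect_lte(res$states_visited, sum(3^sizes))
  }
})

test_that("objectives are monotone in the target width and deterministic", {
  inst <- random_instance(7, 0.5, seed = 11)
  rtd <- root_with_empty_bag(inst$td)
  w <- decomposition_width(inst$td)
  objs <- vapply(w:-1, function(tw)
    tree_diet(inst$graph, rtd, tw)$objective, numeric(1))
  expect_true(all(diff(objs) <= 0))      # decreasing width loses more
  expect_equal(objs[1], nrow(inst$graph$edges))

  a <- tree_diet(inst$graph, rtd, w - 1)
  b <- tree_diet(inst$graph, rtd, w - 1)
  expect_identical(a, b)
})

test_that("weighted mode maximizes weight, not count", {
  # a triangle where one heavy edge beats two light ones
  g <- diet_graph(c("a", "b", "c", "d"),
                  data.frame(u = c("a", "b", "c", "a"),
                             v = c("b", "c", "d", "d"),
                             weight = c(10, 1, 1, 1)))
  td <- tree_decomposition(list("1" = c("a", "b", "c"),
                                "2" = c("a", "c", "d")), cbind(1, 2))
  rtd <- root_with_empty_bag(td)
  cnt <- tree_diet(g, rtd, 1)
  wtd <- tree_diet(g, rtd, diet_params(1, "weight"))
  expect_equal(cnt$objective, 2)                 # two edges kept
  expect_gte(wtd$objective, 11)                  # heavy edge must be kept
  expect_true("a|b" %in% treediet:::edge_keys(wtd$kept_edges))
})

test_that("apply_coloring rebuilds decompositions and reattaches vertices", {
  k3 <- make_complete(3)
  rtd <- root_with_empty_bag(single_bag_decomposition(k3))
  cc <- list("2" = character(0), "1" = c("1" = "g", "2" = "g", "3" = "o"))
  thin <- apply_coloring(rtd, cc, k3)
  expect_equal(decomposition_width(thin), 1)
  expect_true("3" %in% unlist(thin$bags))        # reattached singleton
  kept <- diet_graph(k3$vertices, k3$edges[treediet:::edge_keys(k3$edges) == "1|2", ])
  expect_true(validate_decomposition(kept, thin)$ok)

  all_green <- list("2" = character(0),
                    "1" = c("1" = "g", "2" = "g", "3" = "g"))
  expect_equal(length(apply_coloring(rtd, all_green, k3)$bags), 2)

  all_red <- list("2" = character(0),
                  "1" = c("1" = "o", "2" = "r", "3" = "r"))
  # vertices 2 and 3 introduced at bag 1 cannot be red there (R1)
  expect_error(apply_coloring(rtd, all_red, k3), "invalid")
  all_or <- list("2" = character(0),
                 "1" = c("1" = "o", "2" = "o", "3" = "o"))
  thin0 <- apply_coloring(rtd, all_or, k3)
  expect_equal(length(thin0$bags), 5)            # root, empty bag, 3 singletons
  expect_lte(decomposition_width(thin0), 0)
})

test_that("diet_hierarchy runs independent diets with non-increasing keeps", {
  c4 <- diet_graph(letters[1:4],
                   data.frame(u = c("a", "b", "c", "a"),
                              v = c("b", "c", "d", "d")))
  td4 <- tree_decomposition(list("1" = c("a", "b", "c"),
                                 "2" = c("a", "c", "d")), cbind(1, 2))
  rtd <- root_with_empty_bag(td4)
  hs <- diet_hierarchy(c4, rtd, c(2, 1))
  expect_equal(vapply(hs, function(r) nrow(r$lost_edges), numeric(1)), c(0, 2))
  expect_equal(length(diet_hierarchy(c4, rtd, integer(0))), 0)
  single <- diet_hierarchy(c4, rtd, 1)[[1]]
  expect_equal(single$objective, tree_diet(c4, rtd, 1)$objective)
  expect_error(diet_hierarchy(c4, rtd, c(1, 2)), "decreasing")
})
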