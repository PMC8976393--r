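# a 2-bag rooted decomposition used across the rule tests
two_bag_rtd <- function(parent = c("u", "v"), child = c("u", "v")) {
  root_with_empty_bag(
    tree_decomposition(list("1" = parent, "2" = child), cbind(1, 2)))
}

test_that("rules R1-R4 are diagnosed with rule, bag and vertex", {
  rtd <- two_bag_rtd()
  base <- list("3" = character(0),
               "1" = c(u = "g", v = "o"),
               "2" = c(u = "g", v = "g"))

  # parent g -> child o violates R2
  c2 <- base; c2[["1"]] <- c(u = "g", v = "g"); c2[["2"]] <- c(u = "o", v = "g")
  rep2 <- check_coloring_validity(rtd, c2)
  expect_false(rep2$ok)
  expect_match(rep2$messages, "R2", all = FALSE)

  # parent r -> child g violates R3
  c3 <- base; c3[["1"]] <- c(u = "r", v = "g"); c3[["2"]] <- c(u = "g", v = "g")
  rep3 <- check_coloring_validity(rtd, c3)
  expect_match(rep3$messages, "R3", all = FALSE)

  # vertex introduced red violates R1 (u enters at bag 1 under the empty root)
  c1 <- base; c1[["1"]] <- c(u = "r", v = "o"); c1[["2"]] <- c(u = "r", v = "g")
  rep1 <- check_coloring_validity(rtd, c1)
  expect_match(rep1$messages, "R1", all = FALSE)

  # orange alive in two children violates R4
  rtd4 <- root_with_empty_bag(
    tree_decomposition(list("1" = "u", "2" = "u", "3" = "u"),
                       cbind(1, 2:3)))
  c4 <- list("4" = character(0), "1" = c(u = "o"),
             "2" = c(u = "g"), "3" = c(u = "o"))
  rep4 <- check_coloring_validity(rtd4, c4)
  expect_match(rep4$messages, "R4", all = FALSE)
  # exactly one alive child is fine
  c4ok <- c4; c4ok[["3"]] <- c(u = "r")
  expect_true(check_coloring_validity(rtd4, c4ok)$ok)

  # single bag with no children: orange needs no child
  rtd1 <- root_with_empty_bag(tree_decomposition(list("1" = c("a", "b", "c"))))
  cc <- list("2" = character(0), "1" = c(a = "g", b = "g", c = "o"))
  expect_true(check_coloring_validity(rtd1, cc)$ok)
})

test_that("realizable edges are the green-green co-occurrences", {
  g <- make_complete(3)
  rtd <- root_with_empty_bag(single_bag_decomposition(g))
  all_green <- list("2" = character(0),
                    "1" = c("1" = "g", "2" = "g", "3" = "g"))
  expect_equal(nrow(realizable_edges(g, rtd, all_green)), 3)

  # removing one vertex (orange: introduced vertices may not be red)
  c_rem <- all_green; c_rem[["1"]]["3"] <- "o"
  expect_equal(treediet:::edge_keys(realizable_edges(g, rtd, c_rem)), "1|2")

  all_orange <- list("2" = character(0),
                     "1" = c("1" = "o", "2" = "o", "3" = "o"))
  expect_equal(nrow(realizable_edges(g, rtd, all_orange)), 0)

  bad <- all_green; bad[["1"]]["1"] <- "x"
  expect_error(realizable_edges(g, rtd, bad), "invalid coloring")
})

test_that("count sets count child green-green edges not already green above", {
  g <- diet_graph(c("u", "v", "w"),
                  data.frame(u = c("u", "u"), v = c("v", "w")))
  cs1 <- count_set(g, c("u", "v"), c(u = "g", v = "o"),
                   c("u", "v"), c(u = "g", v = "g"))
  expect_equal(treediet:::edge_keys(cs1), "u|v")

  cs2 <- count_set(g, c("u", "v"), c(u = "g", v = "g"),
                   c("u", "v"), c(u = "g", v = "g"))
  expect_equal(nrow(cs2), 0)

  cs3 <- count_set(g, c("v"), c(v = "g"),
                   c("u", "w"), c(u = "g", w = "g"))
  expect_equal(treediet:::edge_keys(cs3), "u|w")
})

test_that("orange assignments enumerate the product over holding children", {
  a1 <- enumerate_orange_assignments(c(u = "o", v = "o"),
                                     list(c("u"), c("u", "v")))
  expect_equal(length(a1), 2)            # u -> {1,2}, v -> {2}
  expect_setequal(vapply(a1, function(m) paste(m["u"], m["v"]), ""),
                  c("1 2", "2 2"))

  a2 <- enumerate_orange_assignments(c(u = "g", v = "r"), list(c("u", "v")))
  expect_equal(length(a2), 1)
  expect_equal(length(a2[[1]]), 0)       # trivial empty map

  a3 <- enumerate_orange_assignments(c(u = "o"), list(c("x"), c("y")))
  expect_equal(length(a3), 1)            # u in no child: omitted
  expect_equal(length(a3[[1]]), 0)
})

test_that("compatible child colorings follow the per-vertex case analysis", {
  f <- c(u = "g", v = "o", w = "r")
  cc <- enumerate_compatible(c("u", "v", "w", "x"), c("u", "v", "w"),
                             f, c(v = 1L), 1L)
  expect_equal(length(cc), 8)            # 2 * 2 * 1 * 2
  for (fj in cc) {
    expect_true(fj[["u"]] %in% c("g", "r"))
    expect_true(fj[["v"]] %in% c("g", "o"))
    expect_equal(fj[["w"]], "r")
    expect_true(fj[["x"]] %in% c("g", "o"))
  }
  # orange assigned elsewhere: forced red
  cc2 <- enumerate_compatible(c("v"), c("u", "v", "w"), f, c(v = 2L), 1L)
  expect_equal(length(cc2), 1)
  expect_equal(cc2[[1]][["v"]], "r")
  # all-red parent subset: single all-red coloring
  cc3 <- enumerate_compatible(c("w"), c("u", "v", "w"), f, c(v = 1L), 2L)
  expect_equal(length(cc3), 1)
  expect_equal(unname(cc3[[1]]), "r")
  # empty child bag
  cc4 <- enumerate_compatible(character(0), c("u"), c(u = "g"),
                              stats::setNames(integer(0), character(0)), 1L)
  expect_equal(length(cc4), 1)
  expect_equal(length(cc4[[1]]), 0)
})
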