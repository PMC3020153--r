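test_that("rollback handles the elementary node kinds", {
  expect_equal(rollback(terminal_node("t", 3.2)), 3.2)
  cn <- chance_node("c",
                    edge("a", 0.5, terminal_node("a", 0)),
                    edge("b", 0.5, terminal_node("b", 2)))
  expect_equal(rollback(cn), 1.0)
  dn <- decision_node("d",
                      edge("lo", NULL, terminal_node("lo", 1)),
                      edge("hi", NULL, cn))
  expect_equal(rollback(dn), 1.0)
})

test_that("a fixed 3-level tree matches exhaustive path enumeration", {
  leafs <- function(a, b) chance_node(
    "l2", edge("x", 0.25, terminal_node("x", a)),
    edge("y", 0.75, terminal_node("y", b)))
  mid <- function(a, b, c, d) chance_node(
    "l1", edge("p", 0.6, leafs(a, b)), edge("q", 0.4, leafs(c, d)))
  tree <- chance_node("root",
                      edge("L", 0.3, mid(1, 2, 3, 4)),
                      edge("R", 0.7, mid(5, 6, 7, 8)))
  # value frozen from the independent path-product oracle:
  # sum over the 8 root-to-leaf paths of prod(edge probs) * payoff
  by_hand <- 0.3 * (0.6 * (0.25 * 1 + 0.75 * 2) + 0.4 * (0.25 * 3 + 0.75 * 4)) +
             0.7 * (0.6 * (0.25 * 5 + 0.75 * 6) + 0.4 * (0.25 * 7 + 0.75 * 8))
  expect_equal(oracle_ev(tree), by_hand)
  expect_equal(rollback(tree), by_hand, tolerance = 1e-12)
  paths <- enumerate_paths(tree)
  expect_equal(nrow(paths), 8L)
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  expect_equal(sum(paths$probability * paths$payoff), by_hand)
})

test_that("enumerate_paths covers the degenerate and nested cases", {
  single <- enumerate_paths(terminal_node("only", 4.5))
  expect_equal(single$probability, 1)
  expect_equal(single$payoff, 4.5)
  expect_equal(single$path, "")
  two <- enumerate_paths(chance_node(
    "c", edge("a", 0.3, terminal_node("a", 1)),
    edge("b", 0.7, terminal_node("b", 2))))
  expect_equal(two$probability, c(0.3, 0.7))
  nested <- enumerate_paths(chance_node(
    "c", edge("a", 0.2, chance_node(
      "d", edge("aa", 0.5, terminal_node("aa", 0)),
      edge("ab", 0.5, terminal_node("ab", 1)))),
    edge("b", 0.8, terminal_node("b", 2))))
  expect_equal(sort(nested$probability), sort(c(0.2 * 0.5, 0.2 * 0.5, 0.8)))
})

test_that("validation rejects malformed trees and resolves complements", {
  bad_sum <- chance_node("node7",
                         edge("a", 0.5, terminal_node("a", 0)),
                         edge("b", 0.4, terminal_node("b", 1)))
  expect_error(rollback(bad_sum), "node7")
  neg <- chance_node("negnode",
                     edge("a", -0.1, terminal_node("a", 0)),
                     edge("b", 1.1, terminal_node("b", 1)))
  expect_error(rollback(neg), "negative")
  comp <- chance_node("c",
                      edge("a", 0.3, terminal_node("a", 0)),
                      edge("b", "complement", terminal_node("b", 10)))
  expect_equal(rollback(comp), 7)
  expect_equal(validate_tree(comp)$children[[2]]$prob, 0.7)
  two_comp <- chance_node("c",
                          edge("a", "complement", terminal_node("a", 0)),
                          edge("b", "complement", terminal_node("b", 1)))
  expect_error(validate_tree(two_comp), "complement")
})

test_that("rollback agrees with the path-enumeration oracle on random trees", {
  set.seed(42)
  for (i in 1:200) {
    tr <- random_tree()
    expect_equal(rollback(tr), oracle_ev(tr), tolerance = 1e-9)
    paths <- enumerate_paths(tr)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-9)
  }
})

test_that("raising a terminal payoff never lowers the rolled-back value", {
  bump_first_leaf <- function(node, by) {
    if (node$kind == "terminal") {
      node$payoff <- node$payoff + by
      return(node)
    }
    node$children[[1]]$node <- bump_first_leaf(node$children[[1]]$node, by)
    node
  }
  set.seed(7)
  for (i in 1:50) {
    tr <- random_tree(4)
    expect_gte(rollback(bump_first_leaf(tr, 1)), rollback(tr))
  }
})

test_that("decision-node ties resolve to the first-listed child with a notice", {
  dn <- decision_node("tie",
                      edge("first", NULL, terminal_node("a", 2)),
                      edge("second", NULL, terminal_node("b", 2)))
  expect_message(v <- rollback(dn), "first")
  expect_equal(v, 2)
})

test_that("recommend compares Full Code and DNI expected values", {
  mk <- function(name, v) strategy(name, terminal_node("t", v))
  r <- recommend(list(mk("Full Code", 5.0), mk("DNI", 4.26)))
  expect_equal(r$delta_qaly, 0.74)
  expect_equal(r$recommended, "Full Code")
  expect_equal(unname(r$ev_by_strategy["DNI"]), 4.26)
  expect_equal(recommend(list(mk("Full Code", 2), mk("DNI", 2)))$recommended,
               "indifferent")
  r2 <- recommend(list(mk("Full Code", 2.0), mk("DNI", 2.1)))
  expect_equal(r2$delta_qaly, -0.1)
  expect_equal(r2$recommended, "DNI")
  # order-independence: DNI listed first still reports Full Code - DNI
  r3 <- recommend(list(mk("DNI", 4.26), mk("Full Code", 5.0)))
  expect_equal(r3$delta_qaly, 0.74)
})

test_that("strategies refuse embedded decision nodes", {
  dn <- decision_node("d", edge("a", NULL, terminal_node("a", 1)))
  expect_error(strategy("Full Code", dn), "decision node")
})

test_that("tree YAML serialization round-trips losslessly", {
  set.seed(11)
  tr <- validate_tree(random_tree(4))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_tree(tr, f)
  back <- read_tree(f)
  expect_equal(rollback(back), rollback(tr), tolerance = 1e-12)
  expect_identical(node_shape <- enumerate_paths(tr)$path,
                   enumerate_paths(back)$path)
  expect_equal(enumerate_paths(back)$probability,
               enumerate_paths(tr)$probability, tolerance = 1e-12)
  # complement markers survive the round trip unresolved
  comp <- chance_node("c", edge("a", 0.3, terminal_node("a", 0)),
                      edge("b", "complement", terminal_node("b", 1)))
  write_tree(comp, f)
  expect_identical(read_tree(f)$children[[2]]$prob, "complement")
})
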