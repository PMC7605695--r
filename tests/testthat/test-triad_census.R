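test_that("classification matches the isomorphism oracle on all 64 labeled digraphs", {
  for (code6 in 0:63) {
    bits <- as.integer(intToBits(code6))[1:6]
    a <- matrix(0L, 3, 3)
    a[1, 2] <- bits[1]; a[2, 1] <- bits[2]
    a[1, 3] <- bits[3]; a[3, 1] <- bits[4]
    a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
    expect_equal(classify_triad(a), oracle_classify(a),
                 info = paste("arc pattern", code6))
  }
})

test_that("named example triads classify as the field expects", {
  a <- matrix(0L, 3, 3)
  a[1, 2] <- 1L; a[2, 3] <- 1L; a[1, 3] <- 1L  # X->Y, Y->Z, X->Z
  expect_equal(classify_triad(a), "030T")
  expect_equal(classify_triad(matrix(0L, 3, 3)), "003")
  m <- matrix(0L, 3, 3); m[1, 2] <- m[2, 1] <- 1L
  expect_equal(classify_triad(m), "102")
  expect_error(classify_triad(matrix(0L, 2, 2)), class = "shape_error")
})

test_that("census equals brute-force per-triple classification on random digraphs", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    net <- rand_network(n, runif(1, 0.1, 0.7))
    cen <- triad_census(net)
    expect_equal(cen$counts, oracle_census(net$adjacency))
    expect_equal(cen$n_triads, choose(n, 3))
  }
})

test_that("census agrees with igraph's independent implementation", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    net <- rand_network(n, runif(1, 0.1, 0.6))
    g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "directed")
    expect_equal(unname(triad_census(net)$counts), igraph::triad_census(g))
  }
})

test_that("census-sum identity holds on many random networks", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    net <- rand_network(n, runif(1, 0, 1))
    expect_equal(sum(triad_census(net)$counts), choose(n, 3))
  }
})

test_that("transposing the network swaps the D/U types and fixes the rest", {
  set.seed(14)
  swap <- c("021D" = "021U", "021U" = "021D", "111D" = "111U",
            "111U" = "111D", "120D" = "120U", "120U" = "120D")
  for (rep in 1:20) {
    net <- rand_network(sample(4:12, 1), runif(1, 0.1, 0.6))
    rev <- binary_network(t(net$adjacency), net$actor_order,
                          net$classroom, net$layer)
    c1 <- triad_census(net)$counts
    c2 <- triad_census(rev)$counts
    expected <- c1
    names(expected)[match(names(swap), names(c1))] <- swap
    expect_equal(c2[names(c1)], setNames(expected[names(c1)], names(c1)))
  }
})

test_that("degenerate and saturated censuses are exact", {
  empty5 <- binary_network(matrix(0L, 5, 5), sprintf("a%d", 1:5))
  cen <- triad_census(empty5)
  expect_equal(unname(cen$counts["003"]), 10L)
  expect_equal(sum(cen$counts), 10L)
  expect_equal(cen$transitive_share, 0)

  full4 <- binary_network(1 - diag(4), letters[1:4])
  cen4 <- triad_census(full4)
  expect_equal(unname(cen4$counts["300"]), 4L)
  expect_equal(cen4$transitive_share, 1)

  tiny <- binary_network(matrix(0L, 2, 2), c("a", "b"))
  cen2 <- triad_census(tiny)
  expect_true(cen2$zero_triads)
  expect_equal(sum(cen2$counts), 0L)
})

test_that("proportions normalise to 100 and refuse zero-triad censuses", {
  cen <- triad_census(binary_network(matrix(0L, 5, 5), sprintf("a%d", 1:5)))
  expect_equal(unname(census_proportions(cen)["003"]), 100)

  half <- matrix(0L, 4, 4)
  half[1, 2] <- half[2, 1] <- half[1, 3] <- half[3, 1] <- half[2, 3] <- half[3, 2] <- 1L
  cenh <- triad_census(binary_network(half, letters[1:4]))
  pr <- census_proportions(cenh)
  expect_equal(unname(pr["300"]), 25)
  set.seed(15)
  for (rep in 1:10) {
    pr <- census_proportions(triad_census(rand_network(sample(3:10, 1), 0.4)))
    expect_equal(sum(pr), 100, tolerance = 1e-9)
  }
  tiny <- triad_census(binary_network(matrix(0L, 2, 2), c("a", "b")))
  expect_error(census_proportions(tiny), class = "undefined_proportion_error")
})

test_that("node profiles double-count each triad exactly three times", {
  empty <- binary_network(matrix(0L, 5, 5), sprintf("a%d", 1:5))
  expect_true(all(node_triad_profile(empty)$transitive == 0))

  full4 <- binary_network(1 - diag(4), letters[1:4])
  expect_true(all(node_triad_profile(full4)$transitive == 3))  # C(3,2)

  set.seed(16)
  for (rep in 1:20) {
    net <- rand_network(sample(4:12, 1), runif(1, 0.1, 0.6))
    prof <- node_triad_profile(net)
    cen <- triad_census(net)
    expect_equal(sum(prof$transitive), 3 * cen$transitive_total)
    expect_equal(sum(prof$intransitive), 3 * cen$intransitive_total)
    expect_true(all(prof$total == choose(length(net$actor_order) - 1, 2)))
  }
})

test_that("closing the arc of a pure two-path makes that triad transitive", {
  # X->Y->Z with X->Z turns 021C into 030T, moving the triad from the
  # intransitive to the transitive side of the default partition
  path <- matrix(0L, 3, 3)
  path[1, 2] <- path[2, 3] <- 1L
  expect_equal(classify_triad(path), "021C")
  closed <- path
  closed[1, 3] <- 1L
  expect_equal(classify_triad(closed), "030T")
  sch <- transitivity_scheme()
  expect_true("021C" %in% sch$intransitive)
  expect_true("030T" %in% sch$transitive)

  # in a network whose only arcs form the open path, closure raises the
  # transitive total from 0 to 1
  n <- 6
  a <- matrix(0L, n, n)
  a[1, 2] <- a[2, 3] <- 1L
  before <- triad_census(binary_network(a, sprintf("a%d", 1:n)))
  a[1, 3] <- 1L
  after <- triad_census(binary_network(a, sprintf("a%d", 1:n)))
  expect_equal(before$transitive_total, 0L)
  expect_equal(after$transitive_total, 1L)
})

test_that("aggregation sums counts and recomputes the share order-independently", {
  set.seed(18)
  c4 <- triad_census(rand_network(4, 0.5))
  c5 <- triad_census(rand_network(5, 0.5))
  doubled <- aggregate_censuses(list(c4, c4))
  expect_equal(doubled$counts, c4$counts * 2L)
  agg <- aggregate_censuses(list(c4, c5))
  expect_equal(agg$n_triads, choose(4, 3) + choose(5, 3))
  expect_equal(sort(agg$n_actors), c(4, 5))

  censuses <- lapply(1:6, function(i) triad_census(rand_network(6, 0.4)))
  split_a <- aggregate_censuses(list(
    aggregate_censuses(censuses[1:2]), aggregate_censuses(censuses[3:6])))
  split_b <- aggregate_censuses(censuses[sample(6)])
  expect_equal(split_a$counts, split_b$counts)
  expect_equal(split_a$transitive_share, split_b$transitive_share)
  expect_error(aggregate_censuses(list()), class = "usage_error")
})

test_that("scheme validation pins the partition and supports a vacuous set", {
  sch <- transitivity_scheme()
  expect_setequal(sch$transitive, c("030T", "120D", "120U", "300"))
  expect_true(all(c("012", "102", "111U") %in% sch$intransitive))
  expect_error(transitivity_scheme(transitive = c("030T")), class = "validation_error")
  expect_error(transitivity_scheme(transitive = c("300", "111U")),
               class = "validation_error")
  expect_error(transitivity_scheme(transitive = c("300", "XYZ")),
               class = "validation_error")

  sch3 <- transitivity_scheme(vacuous = c("003", "012", "102"))
  net <- binary_network(matrix(0L, 5, 5), sprintf("a%d", 1:5))
  cen <- triad_census(net, sch3)
  expect_equal(cen$vacuous_total, 10L)
  expect_equal(cen$intransitive_total, 0L)
})
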