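chain_net <- function(relations) {
  # A -> B -> C ... with the given relation labels
  n <- length(relations) + 1
  nodes <- LETTERS[seq_len(n)]
  build_network(reg_edges(nodes[-n], nodes[-1], relations))
}

test_that("enumerate_action_paths applies blocking rules", {
  net <- chain_net(c("activation", "activation"))
  paths <- enumerate_action_paths(net, drug_profile("D", c(A = "activation")),
                                  hop_max = 2)
  expect_equal(lapply(paths, `[[`, "nodes"),
               list("A", c("A", "B"), c("A", "B", "C")))
  expect_equal(vapply(paths, `[[`, integer(1), "hop"), 0:2)

  blocked <- chain_net(c("inhibition", "activation"))
  p2 <- enumerate_action_paths(blocked, drug_profile("D", c(A = "activation")),
                               hop_max = 2)
  expect_equal(lapply(p2, `[[`, "nodes"), list("A", c("A", "B")))
  expect_equal(p2[[2]]$net_sign, -1L)

  p3 <- enumerate_action_paths(chain_net("activation"),
                               drug_profile("D", c(A = "inhibition")), 2)
  expect_equal(lapply(p3, `[[`, "nodes"), list("A"))
  expect_equal(p3[[1]]$net_sign, -1L)
})

test_that("action paths are simple, bounded, and all-positive before the end", {
  set.seed(31)
  for (i in 1:30) {
    rt <- random_edge_table(9, 25)
    net <- build_network(rt$edges, nodes = rt$nodes)
    prof <- random_profile(rt$nodes, 3)
    for (p in enumerate_action_paths(net, prof, hop_max = 3)) {
      expect_false(anyDuplicated(p$nodes) > 0)
      expect_lte(p$hop, 3)
      expect_equal(p$hop, length(p$nodes) - 1)
      if (p$hop > 1) expect_true(all(p$edge_signs[-p$hop] == 1))
      if (p$hop > 0) expect_equal(p$drug_sign, 1L)
      expect_equal(p$net_sign, p$drug_sign * prod(c(1L, p$edge_signs)))
    }
  }
})

test_that("compute_ia matches direct evaluation on worked examples", {
  lone <- build_network(nodes = "A")
  eff <- compute_ia(lone, drug_profile("D", c(A = "activation")))
  expect_equal(unname(eff$ia["A"]), 1)

  inh <- chain_net("inhibition")
  eff2 <- compute_ia(inh, drug_profile("D", c(A = "activation")),
                     attenuation_params(1.5, 1.1))
  expect_equal(unname(eff2$ia["B"]), -1 / 1.1)
  expect_equal(eff2$negative_set, "B")

  # diamond: two positive 2-hop routes into D
  dia <- build_network(reg_edges(c("A", "B", "A", "C"),
                                 c("B", "D", "C", "D"), "activation"))
  eff3 <- compute_ia(dia, drug_profile("D", c(A = "activation")),
                     attenuation_params(1.5, 1.1))
  expect_equal(unname(eff3$ia["D"]), 2 / 1.5^2)

  # attenuation-free limit: IA is the signed count of admissible paths
  eff4 <- compute_ia(dia, drug_profile("D", c(A = "activation")),
                     attenuation_params(1, 1))
  expect_equal(unname(eff4$ia[c("A", "B", "C", "D")]), c(1, 1, 1, 2))
})

test_that("compute_ia equals the brute-force path-enumeration oracle", {
  set.seed(91)
  for (i in 1:60) {
    rt <- random_edge_table(10, sample(8:30, 1))
    net <- build_network(rt$edges, nodes = rt$nodes)
    prof <- random_profile(rt$nodes, sample(1:4, 1))
    dp <- runif(1, 1, 2.5)
    dn <- runif(1, 1, 2.5)
    hops <- sample(0:3, 1)
    eff <- compute_ia(net, prof, attenuation_params(dp, dn, hops))
    want <- oracle_ia(net, prof, dp, dn, hops)
    got <- setNames(numeric(length(rt$nodes)), rt$nodes)
    got[names(eff$ia)] <- eff$ia
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12)
  }
})

test_that("IA is local and bounded by the admissible path count", {
  set.seed(17)
  for (i in 1:20) {
    rt <- random_edge_table(10, 22)
    net <- build_network(rt$edges, nodes = rt$nodes)
    prof <- random_profile(rt$nodes, 3)
    eff <- compute_ia(net, prof, attenuation_params(1.4, 1.2, 2))
    g <- as_igraph(net)
    d <- igraph::distances(g, v = names(profile_signs(prof)), mode = "out")
    reachable <- colnames(d)[apply(d, 2, min) <= 2]
    expect_true(all(names(eff$ia)[eff$ia != 0] %in% reachable))
    # |IA| bounded by the number of admissible paths ending at each node
    ends <- vapply(enumerate_action_paths(net, prof, 2),
                   function(p) p$nodes[length(p$nodes)], character(1))
    counts <- table(ends)
    expect_true(all(abs(eff$ia) <=
                      as.numeric(counts[names(eff$ia)]) + 1e-12))
  }
})

test_that("increasing delta_pos shrinks all-positive contributions", {
  dia <- build_network(reg_edges(c("A", "B", "A", "C"),
                                 c("B", "D", "C", "D"), "activation"))
  prof <- drug_profile("D", c(A = "activation"))
  ia1 <- compute_ia(dia, prof, attenuation_params(1.2, 1.1))$ia
  ia2 <- compute_ia(dia, prof, attenuation_params(2.0, 1.1))$ia
  expect_true(all(abs(ia2[c("B", "C", "D")]) <= abs(ia1[c("B", "C", "D")])))
})

test_that("partition_nodes splits by exact IA sign", {
  expect_equal(partition_nodes(c(A = 1, B = -0.9)),
               list(positive_set = "A", negative_set = "B"))
  expect_equal(partition_nodes(c(A = 0)),
               list(positive_set = character(0), negative_set = character(0)))
  expect_equal(partition_nodes(c(A = 1, B = 0.44, C = -0.2)),
               list(positive_set = c("A", "B"), negative_set = "C"))
})

test_that("missing targets warn and empty profiles give empty effects", {
  net <- chain_net("activation")
  expect_warning(eff <- compute_ia(net, drug_profile("D", c(Z = "activation",
                                                            A = "activation"))),
                 "absent from the network")
  expect_equal(names(eff$ia), c("A", "B"))
  expect_warning(
    expect_warning(e2 <- compute_ia(net, drug_profile("D", c(Z = "activation"))),
                   "absent"),
    "empty effect profile")
  expect_length(e2$ia, 0)
})

test_that("attenuation_params validates its domain", {
  expect_error(attenuation_params(0.9), ">= 1")
  expect_error(attenuation_params(1.5, 0.5), ">= 1")
  expect_error(attenuation_params(hop_max = -1), "hop_max")
  expect_equal(attenuation_params()$hop_max, 2L)
})
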