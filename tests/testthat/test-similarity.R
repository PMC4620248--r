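test_that("matching index reproduces hand-computed and degenerate cases", {
  # d1 -> {t1,t2}, d2 -> {t2,t3}, T = 4: (4 - 2 - 2 + 2*1)/4 = 0.5
  net <- interaction_network(rbind(c(1, 1, 0, 0), c(0, 1, 1, 0)),
                             c("d1", "d2"), paste0("t", 1:4))
  expect_equal(mi_similarity(net, "drugs")$S["d1", "d2"], 0.5)

  # identical target sets -> MI 1
  net2 <- interaction_network(rbind(c(1, 1, 0), c(1, 1, 0)),
                              c("d1", "d2"), paste0("t", 1:3))
  expect_equal(mi_similarity(net2, "drugs")$S["d1", "d2"], 1)

  # disjoint sets covering all targets -> MI 0
  net3 <- interaction_network(rbind(c(1, 1, 0), c(0, 0, 1)),
                              c("d1", "d2"), paste0("t", 1:3))
  expect_equal(mi_similarity(net3, "drugs")$S["d1", "d2"], 0)
})

test_that("matching index equals the brute-force count ratio on random networks", {
  set.seed(42)
  for (rep in 1:40) {
    net <- rand_net(sample(2:8, 1), sample(2:8, 1), stats::runif(1, 0.1, 0.9))
    Sd <- mi_similarity(net, "drugs")
    St <- mi_similarity(net, "targets")
    for (i in seq_along(net$drug_ids))
      for (j in seq_along(net$drug_ids))
        expect_identical(Sd$S[i, j],
                         if (i == j) 1 else oracle_mi_drugs(net, i, j))
    for (p in seq_along(net$target_ids))
      for (q in seq_along(net$target_ids))
        expect_identical(St$S[p, q],
                         if (p == q) 1 else oracle_mi_targets(net, p, q))
  }
})

test_that("matching index is a valid similarity and grows with jointly-absent targets", {
  set.seed(7)
  for (rep in 1:10) {
    net <- rand_net(5, 6, 0.5)
    S <- mi_similarity(net, "drugs")$S
    expect_identical(S, t(S))
    expect_true(all(diag(S) == 1))
    expect_true(all(S >= 0 & S <= 1))

    # appending a target interacting with no drug raises every MI < 1
    A2 <- cbind(net$A, 0L)
    net2 <- interaction_network(A2, net$drug_ids,
                                c(net$target_ids, "t_new"))
    S2 <- mi_similarity(net2, "drugs")$S
    off <- upper.tri(S)
    expect_true(all(S2[off][S[off] < 1] > S[off][S[off] < 1]))
    expect_true(all(S2[off][S[off] == 1] == 1))
  }
})

test_that("degree thresholds follow u = max/2, l = mean", {
  # target degrees 1,2,3,6 -> u = 3, l = 3
  A <- matrix(0L, 6, 4)
  A[1, 1] <- 1L
  A[1:2, 2] <- 1L
  A[1:3, 3] <- 1L
  A[1:6, 4] <- 1L
  net <- interaction_network(A, paste0("d", 1:6), paste0("t", 1:4))
  thr <- degree_thresholds(net, "targets")
  expect_equal(thr$u, 3)
  expect_equal(thr$l, 3)

  # degrees 1,1,4 -> u = 2, l = 2
  B <- matrix(0L, 4, 3)
  B[1, 1] <- 1L; B[2, 2] <- 1L; B[1:4, 3] <- 1L
  thr2 <- degree_thresholds(interaction_network(B, paste0("d", 1:4),
                                                paste0("t", 1:3)),
                            "targets")
  expect_equal(thr2$u, 2)
  expect_equal(thr2$l, 2)

  # drug-side thresholds use row sums, zero-degree nodes included
  C <- rbind(c(1, 1), c(0, 0))
  thr3 <- degree_thresholds(interaction_network(C, c("d1", "d2"),
                                                c("t1", "t2")),
                            "drugs")
  expect_equal(thr3$u, 1)
  expect_equal(thr3$l, 1)
})

test_that("adaptive combination selects branches in fixed evaluation order", {
  set.seed(9)
  net <- rand_net(4, 4)
  ids <- c("a", "b", "c")
  primary <- similarity_matrix(matrix(c(1, .3, .2, .3, 1, .4, .2, .4, 1), 3),
                               ids)
  topo <- similarity_matrix(matrix(c(1, .7, .1, .7, 1, .6, .1, .6, 1), 3),
                            ids)
  thr <- structure(list(u = 3, l = 3, degrees = c(1, 2, 3, 6)),
                   class = "degree_thresholds")
  # g = 6 >= u -> primary; g = 3 >= u (first branch wins) -> primary
  expect_identical(adaptive_similarity(primary, topo, 6, thr), primary)
  expect_identical(adaptive_similarity(primary, topo, 3, thr), primary)
  # g = 1 <= l -> topo
  expect_identical(adaptive_similarity(primary, topo, 1, thr), topo)
  # middle branch takes the elementwise max
  thr2 <- structure(list(u = 4, l = 2, degrees = integer(0)),
                    class = "degree_thresholds")
  mid <- adaptive_similarity(primary, topo, 3, thr2)
  expect_equal(mid$S["a", "b"], 0.7)
  expect_equal(mid$S["a", "c"], 0.2)

  # output always bounded by the two inputs pointwise
  for (g in 0:6) {
    out <- adaptive_similarity(primary, topo, g, thr2)
    expect_true(all(out$S >= pmin(primary$S, topo$S) - 1e-12))
    expect_true(all(out$S <= pmax(primary$S, topo$S) + 1e-12))
  }

  # mismatched id order is rejected
  topo_perm <- similarity_matrix(topo$S[c(2, 1, 3), c(2, 1, 3)],
                                 ids[c(2, 1, 3)])
  expect_error(adaptive_similarity(primary, topo_perm, 1, thr),
               "identifier order")
})

test_that("linear combination interpolates and validates alpha", {
  ids <- c("a", "b")
  primary <- similarity_matrix(matrix(c(1, .2, .2, 1), 2), ids)
  topo <- similarity_matrix(matrix(c(1, .6, .6, 1), 2), ids)
  expect_identical(linear_combination(primary, topo, 1)$S, primary$S)
  expect_identical(linear_combination(primary, topo, 0)$S, topo$S)
  expect_equal(linear_combination(primary, topo, 0.5)$S["a", "b"], 0.4)
  expect_error(linear_combination(primary, topo, 1.5), "alpha")
  expect_error(linear_combination(primary, topo, -0.1), "alpha")
})
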