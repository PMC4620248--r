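test_that("motif classification follows the degree table", {
  # d1 -> t1,t2,t3 ; d2 -> t1 ; d3 -> t4 (t1 deg 2, t2/t3 deg 1, t4 deg 1)
  A <- rbind(c(1, 1, 1, 0), c(1, 0, 0, 0), c(0, 0, 0, 1))
  net <- interaction_network(A, paste0("d", 1:3), paste0("t", 1:4))
  expect_equal(classify_motif(net, 1, 1), "multiple")
  expect_equal(classify_motif(net, 1, 2), "drug_centered")
  expect_equal(classify_motif(net, 2, 1), "target_centered")
  expect_equal(classify_motif(net, 3, 4), "single")
  expect_error(classify_motif(net, 2, 2), "unapproved")
})

test_that("view scores reproduce hand examples and empty-set nulls", {
  # d1 -> {t1, t2}; query t3 with St(t3,t1)=0.4, St(t3,t2)=0.7
  A <- rbind(c(1, 1, 0), c(0, 0, 1))
  net <- interaction_network(A, c("d1", "d2"), paste0("t", 1:3))
  S <- diag(3); S[3, 1] <- S[1, 3] <- 0.4; S[3, 2] <- S[2, 3] <- 0.7
  S[1, 2] <- S[2, 1] <- 0.1
  St <- similarity_matrix(S, net$target_ids)
  sc <- target_view_scores(net, St, 3, 1)
  expect_equal(unname(sc["ctw"]), 0.7)
  expect_equal(unname(sc["ctb"]), NA_real_)  # only non-target of d1 is t3 itself

  # drug interacting with every target except the query -> empty complement
  sc2 <- target_view_scores(net, St, 3, 1, exclude_pair = FALSE)
  expect_true(is.na(sc2["ctb"]))

  # known pair where t is the drug's only target, excluded -> null within
  A3 <- rbind(c(1, 0), c(0, 1))
  net3 <- interaction_network(A3, c("d1", "d2"), c("t1", "t2"))
  St3 <- similarity_matrix(matrix(c(1, .3, .3, 1), 2), net3$target_ids)
  sc3 <- target_view_scores(net3, St3, 1, 1, exclude_pair = TRUE)
  expect_true(is.na(sc3["ctw"]))
  expect_equal(unname(sc3["ctb"]), 0.3)

  # drug view: t1 drugs {d1,d2}; query d3 with Sd(d3,d1)=0.9, Sd(d3,d2)=0.1
  A4 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  net4 <- interaction_network(A4, paste0("d", 1:3), c("t1", "t2"))
  Sm <- diag(3); Sm[3, 1] <- Sm[1, 3] <- 0.9; Sm[3, 2] <- Sm[2, 3] <- 0.1
  Sm[1, 2] <- Sm[2, 1] <- 0.5
  Sd4 <- similarity_matrix(Sm, net4$drug_ids)
  sc4 <- drug_view_scores(net4, Sd4, 3, 1)
  expect_equal(unname(sc4["cdw"]), 0.9)

  # target whose only drug is the query, excluded -> within null,
  # between over all other drugs
  sc5 <- drug_view_scores(net4, Sd4, 3, 2, exclude_pair = TRUE)
  expect_equal(unname(sc5["cdw"]), NA_real_)
  sc6 <- drug_view_scores(net4, Sd4, 1, 2)
  expect_equal(unname(sc6["cdw"]), 0.9)       # d3 interacts with t2
  expect_equal(unname(sc6["cdb"]), 0.5)       # complement {d2}
})

test_that("scores equal enumerated-set maxima on random instances", {
  set.seed(101)
  for (rep in 1:30) {
    D <- sample(2:7, 1); T_ <- sample(2:7, 1)
    net <- rand_net(D, T_, stats::runif(1, 0.15, 0.85))
    Sd <- rand_sim(D, net$drug_ids)
    St <- rand_sim(T_, net$target_ids)
    for (y in seq_len(D)) for (x in seq_len(T_)) {
      excl <- net$A[y, x] == 1L
      tv <- target_view_scores(net, St, x, y, exclude_pair = excl)
      dv <- drug_view_scores(net, Sd, y, x, exclude_pair = excl)
      expect_identical(unname(tv), oracle_target_view(net, St, x, y, excl))
      expect_identical(unname(dv), oracle_drug_view(net, Sd, y, x, excl))
    }
  }
})

test_that("feature matrix agrees with per-pair view scores for every combiner", {
  set.seed(202)
  for (cb in list("primary", "topo", "linear:0.3", "adaptive")) {
    net <- rand_net(6, 5, 0.4)
    Sd <- rand_sim(6, net$drug_ids)
    St <- rand_sim(5, net$target_ids)
    feats <- feature_matrix(net, Sd, St, cb)
    expect_equal(nrow(feats), 30)

    # reconstruct the effective similarity per pair and compare
    comb <- parse_combiner(cb)
    Sd_topo <- mi_similarity(net, "drugs")
    St_topo <- mi_similarity(net, "targets")
    thr_t <- degree_thresholds(net, "targets")
    thr_d <- degree_thresholds(net, "drugs")
    for (y in seq_len(6)) for (x in seq_len(5)) {
      Sd_eff <- switch(comb$kind,
        primary = Sd, topo = Sd_topo,
        linear = linear_combination(Sd, Sd_topo, comb$alpha),
        adaptive = adaptive_similarity(Sd, Sd_topo,
                                       sum(net$A[, x]), thr_t))
      St_eff <- switch(comb$kind,
        primary = St, topo = St_topo,
        linear = linear_combination(St, St_topo, comb$alpha),
        adaptive = adaptive_similarity(St, St_topo,
                                       sum(net$A[y, ]), thr_d))
      excl <- net$A[y, x] == 1L
      tv <- oracle_target_view(net, St_eff, x, y, excl)
      dv <- oracle_drug_view(net, Sd_eff, y, x, excl)
      expected <- ifelse(is.na(c(tv, dv)), 1, c(tv, dv))
      row <- feats[(y - 1) * 5 + x, ]
      expect_equal(unlist(row[, c("ctw", "ctb", "cdw", "cdb")],
                          use.names = FALSE), expected)
      expect_equal(unlist(row[, c("null_ctw", "null_ctb", "null_cdw",
                                  "null_cdb")], use.names = FALSE),
                   is.na(c(tv, dv)))
    }
  }
})

test_that("null patterns of known pairs match their motif", {
  set.seed(303)
  for (rep in 1:25) {
    net <- rand_net(sample(2:7, 1), sample(2:7, 1), stats::runif(1, .2, .8))
    if (sum(net$A) == 0) next
    Sd <- rand_sim(nrow(net$A), net$drug_ids)
    St <- rand_sim(ncol(net$A), net$target_ids)
    feats <- feature_matrix(net, Sd, St, "adaptive")
    known <- feats[feats$is_known, ]
    for (r in seq_len(nrow(known))) {
      mask <- unlist(known[r, c("null_ctw", "null_cdw")], use.names = FALSE)
      expected <- switch(known$motif[r],
        multiple = c(FALSE, FALSE),
        drug_centered = c(FALSE, TRUE),
        target_centered = c(TRUE, FALSE),
        single = c(TRUE, TRUE))
      expect_identical(mask, expected)
    }
    # filled vectors always lie in [0,1]^4
    X <- as.matrix(feats[, c("ctw", "ctb", "cdw", "cdb")])
    expect_true(all(X >= 0 & X <= 1))
    expect_true(all(X[as.matrix(feats[, paste0("null_",
      c("ctw", "ctb", "cdw", "cdb"))])] == 1))
  }
})

test_that("feature multiset is invariant under drug permutation", {
  set.seed(404)
  net <- rand_net(5, 4, 0.5)
  Sd <- rand_sim(5, net$drug_ids)
  St <- rand_sim(4, net$target_ids)
  feats <- feature_matrix(net, Sd, St, "adaptive")

  perm <- sample(5)
  net2 <- interaction_network(net$A[perm, ], net$drug_ids[perm],
                              net$target_ids)
  Sd2 <- similarity_matrix(Sd$S[perm, perm], Sd$ids[perm])
  feats2 <- feature_matrix(net2, Sd2, St, "adaptive")

  key <- function(f) f[order(f$drug_id, f$target_id), ]
  expect_equal(key(feats), key(feats2), ignore_attr = TRUE)
})

test_that("score histograms bin into 38 fixed intervals and normalize per group", {
  set.seed(505)
  net <- rand_net(6, 6, 0.4)
  Sd <- rand_sim(6, net$drug_ids)
  St <- rand_sim(6, net$target_ids)
  feats <- feature_matrix(net, Sd, St, "primary")
  h <- score_histograms(feats, "ctw")
  expect_equal(nrow(h), 5 * 38)
  expect_equal(diff(h$bin_left[1:38]), rep(0.02, 37))
  expect_equal(h$bin_left[1], 0.35)
  expect_equal(h$bin_right[38], 1.11)
  for (g in unique(h$group)) {
    s <- sum(h$height[h$group == g])
    expect_true(abs(s - 1) < 1e-12 || s == 0)
  }
  expect_true(all(attr(h, "empty_groups") %in% unique(h$group)))

  # all scores exactly 1 concentrate in a single bin
  feats1 <- feats
  feats1$ctw <- 1
  h1 <- score_histograms(feats1, "ctw")
  top <- h1[h1$group == "unapproved", ]
  expect_equal(max(top$height), 1)
  expect_equal(sum(top$height), 1)
  expect_true(top$bin_left[top$height == 1] <= 1 &&
              top$bin_right[top$height == 1] > 1)

  # out-of-range values clamp into the first and last bins
  feats_lo <- feats; feats_lo$ctw <- 0.05
  h_lo <- score_histograms(feats_lo, "ctw")
  expect_equal(h_lo$height[h_lo$group == "unapproved"][1], 1)
  feats_hi <- feats; feats_hi$ctw <- 1.2
  h_hi <- score_histograms(feats_hi, "ctw")
  expect_equal(h_hi$height[h_hi$group == "unapproved"][38], 1)

  # disjoint supports give zero histogram overlap
  feats2 <- feats
  feats2$ctw[feats2$is_known] <- 0.36
  feats2$ctw[!feats2$is_known] <- 0.80
  h2 <- score_histograms(feats2, "ctw")
  overlap <- sapply(split(h2, h2$group), function(d) which(d$height > 0))
  expect_length(intersect(unlist(overlap[names(overlap) != "unapproved"]),
                          overlap$unapproved), 0)
})
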