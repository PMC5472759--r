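test_that("rank_by_t orders by descending t with lexicographic ties", {
  r <- rank_by_t(c(A = 1, B = 3, C = 2))
  expect_identical(r$gene, c("B", "C", "A"))
  expect_identical(r$rank, 1:3)
  expect_identical(rank_by_t(c(z = 1, a = 1, m = 1))$gene, c("a", "m", "z"))
  set.seed(8)
  t <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  r2 <- rank_by_t(t)
  expect_identical(r2$gene, names(sort(t, decreasing = TRUE)))
  expect_false(is.unsorted(-r2$statistic))
  expect_error(rank_by_t(c(A = 1, B = NA)), "B")
  expect_error(rank_by_t(welch_t(toy_expr(matrix(rnorm(16), 2, 8),
                                          samples = sprintf("s%d", 1:8)),
                                 sprintf("s%d", 1:4),
                                 sprintf("s%d", 5:8))[, c("gene", "statistic")]),
               NA)
})

test_that("ks_uniformity matches its definition and an independent reference", {
  # lattice limit: the whole list is the set
  fx <- ranked_fixture(100, 1:100)
  ks <- ks_uniformity(fx$ranked, fx$members)
  expect_equal(ks$D, 1 / 100, tolerance = 1e-12)
  expect_gt(ks$p_value, 0.999)

  # 20 members at the top of 2000: D ~ 0.99, p tiny
  fx2 <- ranked_fixture(2000, 1:20)
  ks2 <- ks_uniformity(fx2$ranked, fx2$members)
  expect_equal(ks2$D, 1 - 20 / 2000, tolerance = 1e-12)
  expect_lt(ks2$p_value, 1e-6)

  # D agrees with stats::ks.test on random member sets, across both the
  # exact (m <= 35) and asymptotic (m > 35) p-value regimes
  set.seed(9)
  for (i in 1:100) {
    n <- sample(200:2000, 1)
    m <- sample(5:80, 1)
    ranks <- sort(sample(n, m))
    fx3 <- ranked_fixture(n, ranks)
    mine <- ks_uniformity(fx3$ranked, fx3$members)
    ref <- suppressWarnings(ks.test(ranks / n, "punif"))
    expect_lt(abs(mine$D - ref$statistic), 1e-10)
    if (m <= 35) { # same exact-null regime as the reference
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    }
  }
  expect_error(ks_uniformity(fx$ranked, c("absent1", "absent2")), "no set genes")
})

test_that("random member ranks give approximately uniform K-S p-values", {
  set.seed(10)
  p <- replicate(200, {
    fx <- ranked_fixture(500, sort(sample(500, 25)))
    ks_uniformity(fx$ranked, fx$members)$p_value
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("partial_auc_top equals the brute-force step integration", {
  # no members in the top k
  fx <- ranked_fixture(1000, 900:950)
  expect_identical(partial_auc_top(fx$ranked, fx$members, 0.1), 0)

  # all m members at ranks 1..m
  fx2 <- ranked_fixture(1000, 1:30)
  k <- 100; m <- 30
  walk <- pauc_bruteforce(c(rep(TRUE, m), rep(FALSE, 1000 - m))[1:1000], 0.1)
  expect_equal(partial_auc_top(fx2$ranked, fx2$members, 0.1), walk,
               tolerance = 1e-14)

  # oracle equivalence and invariance properties on random rankings
  set.seed(11)
  for (i in 1:50) {
    n <- sample(100:1000, 1)
    mem <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9))
    if (!any(mem)) mem[1] <- TRUE
    fx3 <- ranked_fixture(n, which(mem))
    frac <- sample(c(0.05, 0.1, 0.25), 1)
    auc <- partial_auc_top(fx3$ranked, fx3$members, frac)
    expect_equal(auc, pauc_bruteforce(mem, frac), tolerance = 1e-12)
    expect_true(auc >= 0 && auc <= 1)

    # permuting genes below the cutoff leaves the score unchanged
    kk <- ceiling(frac * n)
    below <- which(seq_len(n) > kk)
    perm <- c(seq_len(kk), sample(below))
    fx4 <- ranked_fixture(n, match(which(mem), perm))
    expect_equal(partial_auc_top(fx4$ranked, fx4$members, frac), auc,
                 tolerance = 1e-12)

    # adding a member above the cutoff never decreases the score
    free <- setdiff(seq_len(kk), which(mem))
    if (length(free)) {
      mem2 <- mem; mem2[free[1]] <- TRUE
      fx5 <- ranked_fixture(n, which(mem2))
      expect_gte(partial_auc_top(fx5$ranked, fx5$members, frac) + 1e-12, auc)
    }
  }
})

test_that("enrich flags the planted set and orders the output by AUC", {
  spec <- simulation_spec(n_genes = 2000, n_samples_per_group = 10,
                          signal_set_size = 50, seed = 21)
  sim <- simulate_gene_set_cohort(spec, collection_size = 10)
  g1 <- sim$groups$sample[sim$groups$group == "group1"]
  g2 <- sim$groups$sample[sim$groups$group == "group2"]
  res <- enrich(sim$expr, g1, g2, sim$collection)
  expect_identical(res$set[1], sim$activated_set)
  expect_true(res$pass_ks[1] && res$pass_auc[1])
  expect_true(all(res$q_ks >= res$p_ks, na.rm = TRUE))
  expect_true(all(diff(res$auc_top[res$pass_ks]) <= 0))

  # a set absent from the matrix is carried through without statistics
  coll2 <- gene_set_collection(c(unclass(sim$collection)[],
                                 list(ABSENT = c("nope1", "nope2"))))
  res2 <- enrich(sim$expr, g1, g2, coll2)
  row <- res2[res2$set == "ABSENT", ]
  expect_identical(row$n_in_list, 0L)
  expect_true(is.na(row$D) && is.na(row$q_ks))

  # one set equal to the whole gene list is a perfect lattice: no pass
  whole <- gene_set_collection(list(ALL = rownames(sim$expr),
                                    ALSO = rownames(sim$expr)[1:30]))
  res3 <- enrich(sim$expr, g1, g2, whole)
  expect_false(res3$pass_ks[res3$set == "ALL"])

  # reversing the contrast direction scores down-shifted sets
  res4 <- enrich(sim$expr, g2, g1, sim$collection, direction = "down")
  expect_identical(res4$set[1], sim$activated_set)
})

test_that("signature_scores standardizes across the cohort and calls activation", {
  # hand z-score example: scores (1,2,3,4,100), only the outlier activates
  vals <- rbind(c(1, 2, 3, 4, 100))
  m <- toy_expr(vals, genes = "sig1", samples = sprintf("s%d", 1:5))
  # single-gene signature: raw score is the centred gene value
  sc <- signature_scores(m, "sig1")
  centred <- vals[1, ] - median(vals[1, ])
  expect_equal(sc$score, unname(centred))
  z <- (centred - mean(centred)) / sd(centred)
  expect_equal(sc$z, unname(z))
  expect_identical(sc$activated, unname(z > 1))
  expect_identical(sum(sc$activated), 1L)
  expect_equal(max(sc$z), 1.78827, tolerance = 1e-5)

  # constant matrix: no activation, warning
  cm <- toy_expr(matrix(5, 3, 4))
  expect_warning(sc2 <- signature_scores(cm, c("g01", "g02")), "zero cohort")
  expect_true(all(!sc2$activated) && all(sc2$z == 0))

  # multi-gene signature equals the mean of centred member rows
  set.seed(12)
  mm <- toy_expr(matrix(rnorm(50), 5, 10))
  sig <- c("g01", "g03", "g04")
  sc3 <- signature_scores(mm, c(sig, "missing_gene"))
  manual <- colMeans(unclass(median_center_genes(mm))[sig, ])
  expect_equal(sc3$score, unname(manual))
  expect_equal(mean(sc3$z), 0, tolerance = 1e-12)
  expect_equal(sd(sc3$z), 1, tolerance = 1e-12)
  expect_error(signature_scores(mm, "missing_gene"), "no signature genes")
})
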