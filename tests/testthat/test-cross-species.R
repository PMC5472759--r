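test_that("collapse_homologs keeps strict 1:1 pairs and renames", {
  m <- toy_expr(matrix(1:12, 4, 3), genes = c("Myc", "Vhl", "Cdkn2a", "Trp53"))
  map <- tibble::tibble(source = c("Myc", "Vhl", "Cdkn2a", "Cdkn2a"),
                        target = c("MYC", "VHL", "CDKN2A", "CDKN2AP1"))
  out <- suppressMessages(collapse_homologs(m, map))
  expect_setequal(rownames(out), c("MYC", "VHL"))
  expect_equal(unclass(out)["MYC", ], unclass(m)["Myc", ], ignore_attr = TRUE)

  # two sources onto one target also dropped
  map2 <- tibble::tibble(source = c("Myc", "Trp53"), target = c("TP53", "TP53"))
  expect_error(suppressMessages(collapse_homologs(m, map2)), "no 1:1")

  # brute-force 1:1 filter on random maps
  set.seed(16)
  for (i in 1:10) {
    src <- sprintf("m%02d", 1:30)
    mm <- toy_expr(matrix(rnorm(60), 30, 2), genes = src)
    map3 <- tibble::tibble(
      source = sample(src, 40, replace = TRUE),
      target = sprintf("H%02d", sample(1:30, 40, replace = TRUE)))
    map3 <- dplyr::distinct(map3)
    ok <- !(map3$source %in% map3$source[duplicated(map3$source)]) &
      !(map3$target %in% map3$target[duplicated(map3$target)])
    expected <- map3$source[ok]
    if (!length(expected)) next
    out3 <- suppressMessages(collapse_homologs(mm, map3))
    expect_setequal(rownames(out3), map3$target[ok])
  }
})

test_that("adjust_batches removes cohort-constant shifts", {
  set.seed(17)
  base <- matrix(rnorm(80), 8, 10)
  a <- toy_expr(base, samples = sprintf("a%02d", 1:10))
  b <- toy_expr(base + 5, samples = sprintf("b%02d", 1:10)) # constant shift
  adj <- adjust_batches(list(A = a, B = b))
  expect_equal(unclass(adj$expr)[, 1:10], unclass(adj$expr)[, 11:20],
               ignore_attr = TRUE)
  expect_identical(adj$cohort$cohort, rep(c("A", "B"), each = 10))

  # within-cohort gene medians are exactly zero
  c1 <- toy_expr(matrix(rnorm(60, 3), 6, 10), samples = sprintf("c%02d", 1:10))
  c2 <- toy_expr(matrix(rnorm(42, -2), 6, 7), samples = sprintf("d%02d", 1:7))
  adj2 <- adjust_batches(list(one = c1, two = c2))
  for (co in unique(adj2$cohort$cohort)) {
    sub <- unclass(adj2$expr)[, adj2$cohort$sample[adj2$cohort$cohort == co]]
    expect_equal(unname(apply(sub, 1, median)), rep(0, 6))
  }

  # single cohort equals plain gene median-centring
  adj3 <- adjust_batches(list(solo = c1))
  expect_equal(unclass(adj3$expr), unclass(median_center_genes(c1)))

  bad <- toy_expr(matrix(1:12, 2, 6), genes = c("x1", "x2"))
  expect_error(adjust_batches(list(A = a, B = bad)), "mismatch")
})

test_that("centroids are per-gene medians with the midpoint convention", {
  m <- toy_expr(matrix(c(1, 5, 9, 2, 4, 8, 0, 6, 7), 3, 3, byrow = FALSE))
  expect_equal(unname(centroid(m, "s01")), unclass(m)[, "s01"],
               ignore_attr = TRUE)
  two <- centroid(m, c("s01", "s02"))
  expect_equal(unname(two), (unclass(m)[, 1] + unclass(m)[, 2]) / 2,
               ignore_attr = TRUE)
  three <- centroid(toy_expr(matrix(c(1, 5, 9), 1, 3), genes = "g"),
                    sprintf("s%02d", 1:3))
  expect_equal(unname(three), 5)
  expect_error(centroid(m, character()), "empty")
})

test_that("centroid correlations behave as Pearson and flag degeneracies", {
  set.seed(18)
  v <- rnorm(50); names(v) <- sprintf("g%02d", 1:50)
  cors <- centroid_correlations(list(a = v), list(self = v, neg = -v))
  expect_equal(cors["a", "self"], 1)
  expect_equal(cors["a", "neg"], -1)
  flat <- v; flat[] <- 2
  expect_error(centroid_correlations(list(a = v), list(flat = flat)), "flat")

  # adding a cohort-wide constant changes nothing once batches are adjusted
  a <- toy_expr(matrix(rnorm(120), 20, 6), samples = sprintf("a%02d", 1:6))
  b <- toy_expr(matrix(rnorm(120), 20, 6), samples = sprintf("b%02d", 1:6))
  b_shifted <- toy_expr(unclass(b) + 7, samples = colnames(b))
  # centroids over sub-cohorts (a full cohort's median is 0 by construction)
  cents <- function(bb) {
    adj <- adjust_batches(list(A = a, B = bb))
    list(A = centroid(adj$expr, colnames(a)[1:3]),
         B = centroid(adj$expr, colnames(bb)[1:3]))
  }
  c1 <- cents(b); c2 <- cents(b_shifted)
  expect_equal(centroid_correlations(c1["A"], c1["B"]),
               centroid_correlations(c2["A"], c2["B"]), tolerance = 1e-12)
})

test_that("cross-species recovery: matched centroids win and clusters split", {
  spec <- simulation_spec(n_genes = 800, n_samples_per_group = 6, seed = 19)
  sim <- simulate_cross_species(spec, n_subtypes = 2, batch_shift = 2,
                                frac_one_to_one = 0.8, snr = 3)
  src <- suppressMessages(collapse_homologs(sim$source, sim$homologs))
  shared <- intersect(rownames(src), rownames(sim$target))
  adj <- adjust_batches(list(mouse = src[shared, ],
                             human = sim$target[shared, ]))
  truth <- sim$truth
  cent_of <- function(species) {
    ss <- truth[truth$species == species, ]
    lapply(split(ss$sample, ss$subtype), function(s) centroid(adj$expr, s))
  }
  mouse_c <- cent_of("mouse"); human_c <- cent_of("human")
  cors <- centroid_correlations(mouse_c, human_c)
  expect_true(all(diag(cors) > cors[cbind(1:2, 2:1)]))

  # nearest-centroid assignment of mouse samples to human subtypes
  mouse_samples <- truth$sample[truth$species == "mouse"]
  asg <- nearest_centroid(adj$expr[, mouse_samples], human_c)
  expect_identical(asg$assigned,
                   truth$subtype[match(asg$sample, truth$sample)])

  # co-clustering cut at 2 recovers the subtypes across both species
  cl <- average_linkage_cluster(adj$expr, gene_filter_fraction = 1, k = 2)
  split_tab <- table(cl$labels, truth$subtype[match(names(cl$labels),
                                                    truth$sample)])
  # clusters and subtypes agree up to label permutation
  expect_true(all(rowSums(split_tab > 0) == 1))
  expect_true(all(colSums(split_tab > 0) == 1))
})

test_that("average linkage clustering satisfies its structural properties", {
  set.seed(20)
  blk <- matrix(rnorm(40 * 10, sd = 0.2), 40, 10)
  # two separated sample blocks with opposite gene programmes
  blk[1:20, 1:5] <- blk[1:20, 1:5] + 3
  blk[21:40, 6:10] <- blk[21:40, 6:10] + 3
  m <- toy_expr(blk)
  cl <- average_linkage_cluster(m, k = 2)
  expect_identical(unname(cl$labels[1:5] == cl$labels[1]), rep(TRUE, 5))
  expect_identical(unname(cl$labels[6:10] == cl$labels[6]), rep(TRUE, 5))
  expect_false(cl$labels[1] == cl$labels[6])
  # merge heights non-decreasing
  expect_false(is.unsorted(cl$hclust$height))

  # duplicated sample sits at distance zero and merges first
  dup <- toy_expr(cbind(blk[, 1], blk[, 1], blk[, 3:10]),
                  samples = sprintf("s%02d", 1:10))
  cld <- average_linkage_cluster(dup, k = 2)
  expect_equal(cld$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(average_linkage_cluster(m[, 1, drop = FALSE]), ">= 2 samples")
})
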