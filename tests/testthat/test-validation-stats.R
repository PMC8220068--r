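test_that("confusion counting follows the one-count-per-reported-label rule", {
  labels <- c("A", "B", "C")
  correct <- data.frame(subject = 1, block = 1,
                        true_class = c("A", "B", "C"),
                        reported = c("A", "B", "C"))
  M <- build_confusion(correct, labels)
  expect_equal(unclass(M), diag(3L), ignore_attr = TRUE)

  multi <- data.frame(subject = 1, block = 1, true_class = "A",
                      reported = "A;B")
  M2 <- build_confusion(multi, labels)
  expect_identical(M2["A", "A"], 1L)
  expect_identical(M2["A", "B"], 1L)
  expect_identical(sum(M2), 2L)

  empty <- correct[0, ]
  expect_true(all(build_confusion(empty, labels) == 0L))

  bad <- data.frame(subject = 1, block = 1, true_class = "A",
                    reported = "Zebra")
  expect_error(build_confusion(bad, labels), "Zebra")
})

test_that("recall, precision and F1 match hand computation and the loop oracle", {
  M <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  met <- classification_metrics(M)
  expect_equal(met$recall, c(0.8, 0.9))
  expect_equal(met$precision, c(8 / 9, 9 / 11))
  expect_equal(met$f1[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))

  ident <- classification_metrics(diag(5))
  expect_true(all(ident$recall == 1) && all(ident$precision == 1) &&
                all(ident$f1 == 1))

  # undefined cells (empty row and column) are NA, not zero
  M0 <- matrix(c(3, 0, 0, 0), 2, 2, byrow = TRUE)
  met0 <- classification_metrics(M0)
  expect_true(is.na(met0$recall[2]))
  expect_true(is.na(met0$precision[2]))

  set.seed(31)
  for (rep in 1:25) {
    R <- matrix(sample(0:10, 25, replace = TRUE), 5, 5)
    got <- classification_metrics(R)
    want <- oracle_metrics(R)
    expect_identical(got$recall, want$recall)
    expect_identical(got$precision, want$precision)
    expect_identical(got$f1, want$f1)
  }
})

test_that("mislabeling probabilities match hand computation and normalize to one", {
  M <- matrix(c(5, 3, 1, 5), 2, 2, byrow = TRUE)
  expect_equal(mislabeling_probability(M)[1, 2], 1)

  M3 <- matrix(0, 3, 3)
  M3[1, 2] <- 2; M3[1, 3] <- 1; M3[3, 1] <- 1
  P3 <- mislabeling_probability(M3)
  expect_equal(P3[1, 2], 0.5)
  expect_equal(P3[1, 3], 0.5)
  expect_equal(P3[2, 3], 0)

  expect_error(mislabeling_probability(diag(4)), "off-diagonal")

  set.seed(8)
  for (rep in 1:25) {
    R <- matrix(sample(0:7, 25, replace = TRUE), 5, 5)
    if (sum(R) - sum(diag(R)) == 0) next
    P <- mislabeling_probability(R)
    expect_equal(sum(P[upper.tri(P)]), 1)
    expect_equal(unclass(P), oracle_pms(R), ignore_attr = TRUE)
  }
})

test_that("block-wise learning fits recover programmed trends and degenerate shapes", {
  labels <- c("A", "B")
  # constant performance: everything always correct
  const <- expand.grid(subject = 1:3, block = 1:5,
                       true_class = labels, stringsAsFactors = FALSE)
  const$reported <- const$true_class
  fit <- suppressWarnings(blockwise_learning_fit(const, labels))
  expect_equal(fit$slope, rep(0, 3))
  expect_identical(fit$df, rep(3L, 3))

  # exactly linear recall: block b gets 2b of 10 class-A trials right
  rows <- do.call(rbind, lapply(1:5, function(b) {
    correct_a <- rep(c("A", "B"), c(2 * b, 10 - 2 * b))
    data.frame(subject = 1, block = b,
               true_class = rep(c("A", "B"), each = 10),
               reported = c(correct_a, rep("B", 10)))
  }))
  lin <- suppressWarnings(blockwise_learning_fit(rows, labels))
  rec <- lin[lin$metric == "recall", ]
  expect_equal(rec$slope, 0.1)  # recall averages A (linear) and B (1)... /2
  expect_lt(rec$p, 1e-6)

  expect_error(blockwise_learning_fit(const[const$block <= 2, ], labels),
               "3 blocks")
})

test_that("the animacy mixed model honors sum-to-zero constraints and the df convention", {
  # constant ratings: pure grand mean
  flat <- expand.grid(subject = 1:3, agent = c("a1", "a2"),
                      class = c("X", "Y", "Z"), stringsAsFactors = FALSE)
  flat$rating <- 50
  fit <- fit_animacy_model(flat)
  expect_equal(fit$alpha0, 50, tolerance = 1e-6)
  expect_equal(max(abs(fit$beta)), 0, tolerance = 1e-6)
  expect_equal(max(abs(fit$gamma)), 0, tolerance = 1e-6)
  expect_equal(fit$sigma2, 0, tolerance = 1e-6)

  # paper-scale design: 13 x 2 x 12 gives residual df 299
  spec <- response_generator_spec(seed = 17L)
  ratings <- generate_animacy_ratings(spec)
  big <- fit_animacy_model(ratings)
  expect_identical(big$df_residual, 312L - 13L)
  expect_identical(big$class_F$df1, 11L)
  expect_identical(big$class_F$df2, 299L)
  expect_lt(abs(sum(big$beta)), 1e-8)
  expect_lt(abs(sum(big$gamma)), 1e-8)

  # missing design cells are a hard error naming the cell
  broken <- flat[!(flat$agent == "a2" & flat$class == "Z"), ]
  expect_error(fit_animacy_model(broken), "a2:Z")
})

test_that("post-hoc class contrasts cover all pairs with Bonferroni monotonicity", {
  spec <- response_generator_spec(seed = 23L)
  fit <- fit_animacy_model(generate_animacy_ratings(spec))
  ph <- posthoc_class_contrasts(fit)
  expect_identical(nrow(ph), 66L)  # 12 * 11 / 2
  expect_true(all(ph$p_adj >= ph$p - 1e-15))
  expect_true(all(ph$p_adj <= 1))
  expect_identical(unique(ph$df2), 299L)

  # identical generated class means: adjusted p-values pile up at 1
  null_params <- default_animacy_params()
  null_params$gamma[] <- 0
  spec0 <- response_generator_spec(animacy_params = null_params,
                                   seed = 29L)
  fit0 <- fit_animacy_model(generate_animacy_ratings(spec0))
  ph0 <- posthoc_class_contrasts(fit0)
  expect_gt(mean(ph0$p_adj == 1), 0.8)
})

test_that("similarity ratings transform to distances by complement and scale-maximum rescaling", {
  lab <- c("A", "B")
  m <- function(s) matrix(c(0, s, s, 0), 2, 2,
                          dimnames = list(lab, lab)) + diag(c(10, 10))
  expect_equal(similarity_to_distance(list(m(10)))["A", "B"], 0)
  expect_equal(similarity_to_distance(list(m(0)))["A", "B"], 1)
  expect_equal(similarity_to_distance(list(m(4), m(6)))["A", "B"], 0.5)
  expect_error(similarity_to_distance(list(m(11))), "0, 10")
})

test_that("non-metric MDS embeds planar configurations and preserves block structure", {
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(pts))
  D <- D / max(D)
  sol <- nonmetric_mds(D, seed = 3)
  expect_lt(sol$stress, 1e-3)
  expect_equal(colMeans(sol$points), c(0, 0), tolerance = 1e-8)

  DB <- synthetic_semantic_distance(LETTERS[1:8], n_clusters = 2,
                                    within = 0.1, between = 0.9)
  grp <- rep(1:2, length.out = 8)
  emb <- nonmetric_mds(DB, seed = 4)
  ed <- as.matrix(dist(emb$points))
  same <- ed[outer(grp, grp, `==`) & upper.tri(ed)]
  diff_ <- ed[outer(grp, grp, `!=`) & upper.tri(ed)]
  expect_gt(min(diff_), max(same))

  expect_error(nonmetric_mds(matrix(0, 4, 4)), "all distances are zero")
})

test_that("Ward clustering cuts at 0.7 of the maximum merge height into a clean partition", {
  lab <- c("A1", "A2", "B1", "B2")
  D <- matrix(0.9, 4, 4, dimnames = list(lab, lab))
  D[1, 2] <- D[2, 1] <- 0
  D[3, 4] <- D[4, 3] <- 0
  diag(D) <- 0
  wc <- ward_clusters(D)
  expect_identical(wc$n_clusters, 2L)
  expect_identical(unname(wc$assignments["A1"]),
                   unname(wc$assignments["A2"]))
  expect_false(wc$assignments["A1"] == wc$assignments["B1"])
  expect_equal(wc$cutoff, 0.7 * max(wc$tree$height))
  expect_true(all(table(wc$assignments) >= 1))
  expect_length(wc$assignments, 4L)

  # Ward merge heights are non-decreasing on random distance matrices
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    X <- matrix(runif(n * n), n, n)
    R <- (X + t(X)) / 2
    diag(R) <- 0
    expect_true(all(diff(ward_clusters(R)$tree$height) >= -1e-12))
  }
})

test_that("the mislabeling-distance correlation reports Pearson r with n-2 degrees of freedom", {
  labels <- experiment_label_set()
  D <- synthetic_semantic_distance(labels)
  P <- 1 - unclass(D)
  diag(P) <- 0
  res <- mislabeling_distance_correlation(P, D)
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_identical(res$n_pairs, 66L)
  expect_identical(res$df, 64L)

  expect_error(
    mislabeling_distance_correlation(matrix(0, 2, 2), matrix(0, 2, 2)),
    "insufficient|diagonal|3 class")

  # Monte-Carlo: a programmed r = -0.6 is recovered within +/- 0.15
  set.seed(6)
  dvec <- runif(66)
  zd <- scale(dvec)[, 1]
  hits <- replicate(200, {
    pvec <- -0.6 * zd + sqrt(1 - 0.36) * rnorm(66)
    abs(cor(pvec, dvec) - (-0.6)) < 0.15
  })
  expect_gte(mean(hits), 0.9)
})
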