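test_that("kNN probabilities are neighbour-class fractions", {
  train <- matrix(c(0, 0, 1, 0, 0, 1, 5, 5), ncol = 2, byrow = TRUE)
  labels <- c("NPDA", "NPDA", "NPDB", "Neutral")
  p <- knn_probabilities(c(0.1, 0.1), train, labels, k = 3)
  expect_equal(unname(p[1, ]), c(2 / 3, 1 / 3, 0))
  # query identical to a lone Neutral training point, k = 1
  p1 <- knn_probabilities(c(5, 5), train, labels, k = 1)
  expect_equal(unname(p1[1, ]), c(0, 0, 1))
  # clamping warns
  expect_warning(knn_probabilities(c(0, 0), train, labels, k = 10),
                 "clamped")
  # annotation labels N/A/B are accepted
  p2 <- knn_probabilities(c(0.1, 0.1), train, c("A", "A", "B", "N"), k = 3)
  expect_equal(p, p2)
})

test_that("kNN matches an exhaustive all-pairs sort oracle", {
  set.seed(17)
  train <- matrix(rnorm(50 * 5), ncol = 5)
  labels <- sample(c("NPDA", "NPDB", "Neutral"), 50, replace = TRUE)
  queries <- matrix(rnorm(20 * 5), ncol = 5)
  p <- knn_probabilities(queries, train, labels, k = 7)
  for (i in 1:20) {
    expect_equal(unname(p[i, ]),
                 unname(naive_knn(queries[i, ], train, labels, 7)))
  }
})

test_that("tied distances at the k-th rank include all tied points", {
  # four training points at equal distance 1 from the origin
  train <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  labels <- c("NPDA", "NPDB", "Neutral", "Neutral")
  p <- knn_probabilities(c(0, 0), train, labels, k = 2)
  expect_equal(unname(p[1, ]), c(0.25, 0.25, 0.5))
  # permuting training order never changes probabilities
  set.seed(4)
  for (rep in 1:10) {
    perm <- sample(4)
    expect_equal(knn_probabilities(c(0, 0), train[perm, ], labels[perm],
                                   k = 2), p)
  }
})

test_that("class assignment breaks ties toward the least deleterious class", {
  expect_equal(classify_probabilities(c(NPDA = 0.5, NPDB = 0,
                                        Neutral = 0.5)), "Neutral")
  expect_equal(classify_probabilities(c(NPDA = 0.5, NPDB = 0.5,
                                        Neutral = 0)), "NPDB")
  expect_equal(classify_probabilities(c(NPDA = 1, NPDB = 0,
                                        Neutral = 0)), "NPDA")
  expect_equal(classify_probabilities(c(NPDA = 1, NPDB = 1,
                                        Neutral = 1) / 3), "Neutral")
})

test_that("genotype prediction averages allele probabilities", {
  hom_b <- genotype_predict(c(NPDA = 0, NPDB = 1, Neutral = 0),
                            c(NPDA = 0, NPDB = 1, Neutral = 0))
  expect_equal(hom_b$class, "NPDB")
  het_wt <- genotype_predict(c(NPDA = 1, NPDB = 0, Neutral = 0), NULL)
  expect_equal(unname(het_wt$probabilities), c(0.5, 0, 0.5))
  expect_equal(het_wt$class, "Neutral")
  compound <- genotype_predict(c(NPDA = 1, NPDB = 0, Neutral = 0),
                               c(NPDA = 0, NPDB = 1, Neutral = 0))
  expect_equal(unname(compound$probabilities), c(0.5, 0.5, 0))
  expect_equal(compound$class, "NPDB")
  # several variants on one allele are averaged within the allele first
  multi <- genotype_predict(rbind(c(NPDA = 1, NPDB = 0, Neutral = 0),
                                  c(NPDA = 0, NPDB = 0, Neutral = 1)),
                            NULL)
  expect_equal(unname(multi$allele1), c(0.5, 0, 0.5))
  expect_equal(unname(multi$probabilities), c(0.25, 0, 0.75))
})

test_that("a single mutated allele is always predicted Neutral", {
  probs <- random_probability_vectors(500, seed = 12)
  for (i in seq_len(nrow(probs))) {
    g <- genotype_predict(probs[i, ], NULL)
    expect_equal(g$class, "Neutral")
  }
})

test_that("position-level hold-out excludes every variant at the position", {
  tab <- data.frame(position = c(10L, 10L, 20L, 30L),
                    f1 = c(0, 0.1, 1, 2), f2 = c(0, 0, 1, 2),
                    PROVEAN = c(0, 0.1, 1, 2))
  labels <- c("A", "A", "B", "N")
  res <- loo_by_position(tab, labels, features = "PROVEAN", k = 2)
  # folds for the two position-10 variants saw only positions 20 and 30:
  # with k = 2 both neighbours (one B, one N) are used
  expect_equal(unname(unlist(res[1, c("NPDA", "NPDB", "Neutral")])),
               c(0, 0.5, 0.5))
  expect_equal(unname(unlist(res[2, c("NPDA", "NPDB", "Neutral")])),
               c(0, 0.5, 0.5))
  # a position holding everything is rejected
  tab_one <- data.frame(position = c(5L, 5L), PROVEAN = c(0, 1))
  expect_error(loo_by_position(tab_one, c("A", "B"), features = "PROVEAN"),
               "distinct positions")
})

test_that("position-level hold-out matches a retrain-per-query oracle", {
  tab <- make_feature_table(fixture_spec(n_per_class = c(N = 12L, B = 12L,
                                                         A = 12L)),
                            seed = 23)
  feats <- c("PROVEAN", "DEOGEN2", "Access", "EvolCI")
  k <- 5L
  res <- loo_by_position(tab, tab$label, features = feats, k = k)
  std <- standardize_features(tab[, feats])
  mat <- as.matrix(std)
  cls <- c(A = "NPDA", B = "NPDB", N = "Neutral")[tab$label]
  for (i in seq_len(nrow(tab))) {
    keep <- tab$position != tab$position[i]
    expected <- naive_knn(mat[i, ], mat[keep, , drop = FALSE], cls[keep],
                          min(k, sum(keep)))
    expect_equal(unname(unlist(res[i, c("NPDA", "NPDB", "Neutral")])),
                 unname(expected))
  }
})

test_that("unique positions reduce position-level hold-out to plain LOO", {
  set.seed(9)
  tab <- make_feature_table(fixture_spec(n_per_class = c(N = 8L, B = 8L,
                                                         A = 8L),
                                         position_pool_frac = 1),
                            seed = 31)
  tab$position <- sample(1000:2000, nrow(tab))   # force unique positions
  feats <- c("PROVEAN", "DEOGEN2")
  res <- loo_by_position(tab, tab$label, features = feats, k = 4)
  std <- as.matrix(standardize_features(tab[, feats]))
  cls <- c(A = "NPDA", B = "NPDB", N = "Neutral")[tab$label]
  for (i in seq_len(nrow(tab))) {
    expected <- naive_knn(std[i, ], std[-i, , drop = FALSE], cls[-i], 4)
    expect_equal(unname(unlist(res[i, c("NPDA", "NPDB", "Neutral")])),
                 unname(expected))
  }
})

test_that("k equal to the full training size returns the class prior", {
  tab <- make_feature_table(fixture_spec(n_per_class = c(N = 10L, B = 15L,
                                                         A = 5L)),
                            seed = 40)
  model <- zoom_train(tab, tab$label, k = 30L)
  p <- predict(model, tab[1:8, ])
  prior <- c(NPDA = 5, NPDB = 15, Neutral = 10) / 30
  for (i in 1:8) {
    expect_equal(unname(unlist(p[i, c("NPDA", "NPDB", "Neutral")])),
                 unname(prior))
  }
})

test_that("the default neighbour count is the square root of the training size", {
  tab <- make_feature_table(seed = 6)   # 129 training variants
  model <- zoom_train(tab, tab$label)
  expect_equal(model$k, round(sqrt(129)))
})

test_that("models survive plain-text serialization bit-for-bit", {
  tab <- make_feature_table(seed = 13)
  sel <- select_features(tab, tab$label)
  model <- zoom_train(tab, tab$label,
                      features = sel$feature[sel$selected])
  path <- withr::local_tempfile()
  write_zoom_model(model, path)
  back <- read_zoom_model(path)
  expect_equal(predict(back, tab), predict(model, tab))
})
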