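test_that("three-class metrics follow the class-averaged definitions", {
  truth <- rep(c("NPDA", "NPDB", "Neutral"), each = 10)
  perfect <- three_class_metrics(truth, truth)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$bacc, 100)
  # all-Neutral predictions on balanced truth: hand-derived confusion
  all_neut <- three_class_metrics(truth, rep("Neutral", 30))
  expect_equal(all_neut$sensitivity, 100 / 3, tolerance = 1e-10)
  expect_equal(all_neut$specificity, 200 / 3, tolerance = 1e-10)
  expect_equal(all_neut$bacc, 50, tolerance = 1e-10)
  # the BACC identity holds exactly
  set.seed(3)
  for (rep in 1:10) {
    pred <- sample(c("NPDA", "NPDB", "Neutral"), 30, replace = TRUE)
    m <- three_class_metrics(truth, pred)
    expect_identical(m$bacc, (m$sensitivity + m$specificity) / 2)
  }
  # an absent class degrades to a fewer-class mean with a warning
  expect_warning(
    m2 <- three_class_metrics(rep(c("NPDA", "NPDB"), 5),
                              rep("NPDA", 10)),
    "absent")
  expect_equal(m2$sensitivity, 50)
})

test_that("uniform random predictions approach the 33.3/66.7/50 baseline", {
  set.seed(2024)
  truth <- rep(c("NPDA", "NPDB", "Neutral"), each = 3000)
  pred <- sample(c("NPDA", "NPDB", "Neutral"), 9000, replace = TRUE)
  m <- three_class_metrics(truth, pred)
  expect_equal(m$sensitivity, 100 / 3, tolerance = 0.03)
  expect_equal(m$specificity, 200 / 3, tolerance = 0.015)
  expect_equal(m$bacc, 50, tolerance = 0.02)
})

test_that("rank-based AUROC equals exhaustive pair counting", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE,
                       prob = c(0.4, 0.6))
    if (!any(positive) || all(positive)) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # with ties
    expect_equal(auroc_binary(positive, scores),
                 pair_auroc(positive, scores))
  }
  # perfect ordering and chance level
  expect_equal(auroc_binary(c(rep(TRUE, 5), rep(FALSE, 5)),
                            c(6:10, 1:5)), 1)
  set.seed(8)
  truth <- sample(c("NPDA", "NPDB", "Neutral"), 2000, replace = TRUE)
  scores <- random_probability_vectors(2000, seed = 9)
  expect_equal(auroc_multiclass(truth, scores), 50, tolerance = 4)
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(10)
  positive <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  scores <- rnorm(50)
  base <- auroc_binary(positive, scores)
  expect_equal(auroc_binary(positive, exp(scores)), base)
  expect_equal(auroc_binary(positive, 3 * scores - 7), base)
  expect_equal(auroc_binary(positive, atan(scores)), base)
})

test_that("two-class collapse scores disease as the non-neutral probability", {
  p <- rbind(c(NPDA = 0.4, NPDB = 0.35, Neutral = 0.25),
             c(NPDA = 0.1, NPDB = 0.1, Neutral = 0.8))
  m <- collapse_to_two_classes(c("A", "N"), p)
  expect_equal(m$disease_score, c(0.75, 0.2))
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$bacc, 100)
  expect_equal(m$auroc, 100)
})

test_that("two-class collapse approaches the analytic optimum on Gaussian scores", {
  set.seed(77)
  n <- 4000
  truth <- rep(c("A", "N"), each = n / 2)
  mu <- ifelse(truth == "A", 0.7, 0.3)
  score <- pmin(pmax(rnorm(n, mu, 0.15), 0), 1)
  p <- cbind(NPDA = score / 2, NPDB = score / 2, Neutral = 1 - score)
  m <- collapse_to_two_classes(truth, p)
  analytic <- 100 * pnorm((0.7 - 0.5) / 0.15)
  expect_equal(m$sensitivity, analytic, tolerance = 1.5)
  expect_equal(m$specificity, analytic, tolerance = 1.5)
})

test_that("saturation scans keep per-domain fractions self-consistent", {
  tab <- make_feature_table(seed = 15)
  sel <- select_features(tab, tab$label)
  model <- zoom_train(tab, tab$label,
                      features = sel$feature[sel$selected])
  provider <- function(position, wt, mut) {
    set.seed(position * 131 + utf8ToInt(mut))
    as.data.frame(as.list(stats::setNames(
      rnorm(length(model$features)), model$features)))
  }
  scan <- saturation_scan(c(90, 120, 170, 300, 600),
                          c("A", "G", "P", "L", "S"), provider, model)
  expect_equal(nrow(scan$scan), 5 * 19)
  # fractions recomputed by independent counting of the emitted matrix
  for (d in scan$domain_fractions$domain) {
    sub <- scan$scan[scan$scan$domain == d, ]
    row <- scan$domain_fractions[scan$domain_fractions$domain == d, ]
    expect_equal(row$NPDA, sum(sub$class == "NPDA") / nrow(sub))
    expect_equal(row$NPDB + row$NPDA + row$Neutral, 1)
  }
  # identical feature vectors everywhere give an identical class
  flat_provider <- function(position, wt, mut) {
    as.data.frame(as.list(stats::setNames(
      rep(0.3, length(model$features)), model$features)))
  }
  flat <- saturation_scan(c(90, 300), c("A", "L"), flat_provider, model)
  expect_equal(length(unique(flat$scan$class)), 1L)
  # matrix writer emits one row per position
  path <- withr::local_tempfile()
  write_scan_matrix(scan, path)
  mat <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(mat), 5)
})

test_that("the pooled two-proportion z-test matches hand computation", {
  same <- proportion_ztest(30, 100, 30, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  strong <- proportion_ztest(80, 100, 20, 100)
  # pooled p = 0.5, se = sqrt(0.5^2 * 0.02), z = 0.6 / se
  expect_equal(strong$z, 0.6 / sqrt(0.25 * 0.02))
  expect_lt(strong$p_value, 1e-9)
  degenerate <- proportion_ztest(0, 50, 0, 70)
  expect_equal(degenerate$p_value, 1)
  expect_error(proportion_ztest(5, 4, 1, 10))
})

test_that("z-test significance calls agree with Fisher away from the boundary", {
  set.seed(55)
  for (rep in 1:40) {
    n1 <- sample(20:60, 1)
    n2 <- sample(20:60, 1)
    k1 <- rbinom(1, n1, runif(1, 0.1, 0.9))
    k2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    p_z <- proportion_ztest(k1, n1, k2, n2)$p_value
    p_f <- fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))$p.value
    # compare calls only when both tests are clearly away from 0.05
    if (min(p_z, p_f) > 0.1 || max(p_z, p_f) < 0.02) {
      expect_equal(p_z <= 0.05, p_f <= 0.05)
    }
  }
})

test_that("metrics reports serialize to JSON", {
  m <- three_class_metrics(rep(c("NPDA", "NPDB", "Neutral"), 4),
                           rep(c("NPDA", "NPDB", "Neutral"), 4))
  path <- withr::local_tempfile()
  write_metrics_json(m, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$bacc, 100)
})
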