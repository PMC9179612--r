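test_that("a hand-built stump routes vectors by threshold, <= going left", {
  tree <- stump("vebda", 1.05)
  expect_equal(predict(tree, tibble::tibble(vebda = 1.2)), "high")
  expect_equal(predict(tree, tibble::tibble(vebda = 0.9)), "low")
  expect_equal(predict(tree, tibble::tibble(vebda = 1.05)), "low") # boundary
  v <- tibble::tibble(vebda = c(1.2, 1.2))
  expect_equal(predict(tree, v)[1], predict(tree, v)[2]) # deterministic
})

test_that("prediction requires the model's features by name", {
  tree <- stump("vebda", 1.05)
  expect_error(predict(tree, tibble::tibble(obda = 1)), "vebda")
})

test_that("a linearly separable problem is learned perfectly", {
  set.seed(10)
  feats <- tibble::tibble(
    vebda = c(rnorm(30, 0.8, 0.05), rnorm(30, 1.3, 0.05)),
    obda = rnorm(60, 0.2, 0.05)
  )
  labels <- rep(c("2", "5"), each = 30)
  fit <- train_tree(feats, labels, "S1", feature_subset = c("vebda", "obda"))
  expect_equal(predict(fit, feats), labels)
})

test_that("training refuses degenerate label sets and incomplete features", {
  feats <- tibble::tibble(vebda = rnorm(20))
  expect_error(train_tree(feats, rep("2", 20), "S1"), "single class")
  feats$vebda[3] <- NA
  expect_error(
    train_tree(feats, rep(c("1", "2"), 10), "S1", feature_subset = "vebda"),
    "missing"
  )
})

test_that("tree models serialize to JSON and back without changing predictions", {
  study <- small_study()
  tree <- study$fit$bank$models$S1
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, path)
  back <- read_tree(path)
  expect_identical(predict(back, study$features), predict(tree, study$features))
  expect_identical(back$class_set, tree$class_set)
  expect_identical(back$features, tree$features)
})

test_that("the classifier bank round-trips through its JSON directory", {
  study <- small_study()
  bank <- study$fit$bank
  dir <- withr::local_tempdir()
  write_bank(bank, dir)
  back <- read_bank(dir)
  expect_equal(back$weights, bank$weights)
  expect_identical(
    predict_bank(back, study$features),
    predict_bank(bank, study$features)
  )
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(12)
  n <- 600
  feats <- tibble::tibble(vebda = rnorm(n), obda = rnorm(n))
  labels <- sample(rep(c("2", "5"), c(0.7 * n, 0.3 * n))) # no relation to features
  learn <- seq_len(0.75 * n)
  fit <- train_tree(feats[learn, ], labels[learn], "S1",
    feature_subset = c("vebda", "obda"),
    config = tree_config(minbucket = 25)
  )
  acc <- naive_accuracy(predict(fit, feats[-learn, ]), labels[-learn])
  expect_lt(abs(acc - 70), 5) # majority-class prevalence is 70%
})

test_that("unanimous containment votes elect the common class", {
  est <- tibble::tibble(s1 = "3", s2 = "34", s3 = "13", s4 = "1234", s5 = "33")
  out <- combine_estimates(est)
  expect_equal(out$w3, 5)
  expect_equal(out$s6, 3L)
})

test_that("the weighted vote follows the class-containment sums", {
  est <- tibble::tibble(s1 = "1", s2 = "12", s3 = "24", s4 = "1234", s5 = "22")
  out <- combine_estimates(est)
  expect_equal(out$w1, 3)
  expect_equal(out$w2, 4)
  expect_equal(out$s6, 2L)
})

test_that("zeroing all but one weight delegates the vote to that classifier", {
  est <- tibble::tibble(s1 = "1", s2 = "34", s3 = "24", s4 = "1234", s5 = "55")
  out <- combine_estimates(est, weights = c(0, 0, 0, 0, 1))
  expect_equal(out$s6, 5L) # only S5 membership counts
  expect_error(combine_estimates(est, weights = rep(0, 5)), "positive")
  expect_error(combine_estimates(est, weights = c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("the vote matches an exhaustive independent computation", {
  est <- random_estimates(2000, seed = 13)
  set.seed(14)
  weights <- runif(5, 0.2, 2)
  got <- combine_estimates(est, weights = weights)
  for (r in seq_len(nrow(est))) {
    want <- naive_combine(as.list(est[r, ]), weights)
    expect_equal(as.numeric(got[r, paste0("w", 1:8)]), want$W)
    expect_equal(got$s6[r], want$s6)
  }
})

test_that("when every classifier's group contains a class, it wins", {
  sets <- class_sets()
  set.seed(15)
  for (i in 1:50) {
    # drinking (6) and walking (7) belong to no lumped pair, so unanimity
    # can only be staged for the classes every set can express
    k <- sample(c(1:5, 8), 1)
    pick <- function(groups) {
      hits <- unlist(groups[vapply(groups, function(g) {
        k %in% herdsense:::group_members(g)
      }, logical(1))])
      hits[sample.int(length(hits), 1)]
    }
    est <- tibble::tibble(
      s1 = as.character(k), s2 = pick(sets$S2), s3 = pick(sets$S3),
      s4 = pick(sets$S4), s5 = pick(sets$S5)
    )
    expect_equal(combine_estimates(est)$s6, k)
  }
})
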