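test_that("behavior frequencies count, sort and tie-break correctly", {
  f <- behavior_frequencies(rep(4L, 100))
  expect_equal(f$behavior, 4)
  expect_equal(f$freq, 1)

  f <- behavior_frequencies(c(rep(5L, 9000), rep(1L, 6000)))
  expect_equal(f$behavior, c(5, 1))
  expect_equal(f$freq, c(0.6, 0.4))

  f <- behavior_frequencies(c(rep(1L, 5000), rep(2L, 5000), rep(3L, 5000)))
  expect_equal(f$behavior, c(1, 2, 3)) # ties broken by ascending code
  expect_equal(f$freq, rep(1 / 3, 3))

  expect_error(behavior_frequencies(integer(0)), "no labeled samples")
  expect_error(behavior_frequencies(c(1L, 9L)), "1..8")
})

test_that("the class-pair rule keeps a significant second class only", {
  f <- tibble::tibble(behavior = c(2L, 4L), freq = c(0.55, 0.45))
  expect_equal(assign_class_pair(f, fmin = 0.4)[, c("c1", "c2")],
    tibble::tibble(c1 = 2L, c2 = 4L))

  f <- tibble::tibble(behavior = c(5L, 1L), freq = c(0.9, 0.1))
  expect_equal(assign_class_pair(f, fmin = 0.4)[, c("c1", "c2")],
    tibble::tibble(c1 = 5L, c2 = 5L))

  f <- tibble::tibble(behavior = 1L, freq = 1)
  expect_equal(assign_class_pair(f, fmin = 0.7)[, c("c1", "c2")],
    tibble::tibble(c1 = 1L, c2 = 1L))

  # the rule is f2 >= fmin: the boundary keeps the second class
  f <- tibble::tibble(behavior = c(3L, 2L), freq = c(0.6, 0.4))
  expect_equal(assign_class_pair(f, fmin = 0.4)$c2, 2L)
})

test_that("class-pair assignment matches a brute-force recount", {
  set.seed(21)
  for (rep in 1:100) {
    labels <- sample.int(8L, 200, replace = TRUE, prob = runif(8))
    got <- assign_class_pair(behavior_frequencies(labels))
    want <- naive_class_pair(labels)
    expect_equal(c(got$c1, got$c2), unname(want))
  }
})

test_that("the unrestricted class-pair space enumerates to 64 pairs", {
  pairs <- list()
  for (a in 1:8) {
    for (b in setdiff(1:8, a)) {
      f <- tibble::tibble(behavior = c(a, b), freq = c(0.55, 0.45))
      p <- assign_class_pair(f, fmin = 0.4)
      pairs[[paste(p$c1, p$c2)]] <- TRUE
    }
    f <- tibble::tibble(behavior = a, freq = 1)
    p <- assign_class_pair(f)
    pairs[[paste(p$c1, p$c2)]] <- TRUE
  }
  expect_length(pairs, 64)
})

test_that("lumping follows the residual, rarity and pass-through branches", {
  pf <- tibble::tibble(
    c1 = c(7L, 2L, 5L), c2 = c(1L, 3L, 5L), freq = c(0.2, 0.005, 0.3)
  )
  out <- lump_class_pair(
    tibble::tibble(c1 = c(7L, 2L, 5L), c2 = c(1L, 3L, 5L)), pf, flow = 0.01
  )
  expect_equal(out$l1, c(8L, 2L, 5L))
  expect_equal(out$l2, c(8L, 8L, 5L))
  # a pair absent from the frequency table counts as rare
  out2 <- lump_class_pair(tibble::tibble(c1 = 3L, c2 = 1L), pf)
  expect_equal(c(out2$l1, out2$l2), c(3L, 8L))
})

test_that("lumping is idempotent over the whole pair space", {
  set.seed(9)
  grid <- tidyr::expand_grid(c1 = 1:8, c2 = 1:8)
  pf <- dplyr::mutate(grid, freq = as.numeric(stats::rmultinom(1, 1000, runif(64))[, 1] / 1000))
  once <- lump_class_pair(grid, pf)
  twice <- lump_class_pair(
    tibble::tibble(c1 = once$l1, c2 = once$l2), pf
  )
  expect_equal(twice$l1, once$l1)
  expect_equal(twice$l2, once$l2)
})

test_that("class-set projection matches the published groupings", {
  expect_equal(map_to_class_set(3, "S2"), "34") # ruminating
  expect_equal(map_to_class_set(3, "S3"), "13") # standing
  expect_equal(map_to_class_set(7, "S4"), "678") # residual group
  expect_equal(map_to_class_set(1:8, "S1"), as.character(1:8))
  # S1-S4 groups partition the eight codes exactly once
  for (id in c("S1", "S2", "S3", "S4")) {
    members <- unlist(lapply(class_sets()[[id]], herdsense:::group_members))
    expect_setequal(members, 1:8)
    expect_equal(length(members), 8)
  }
  expect_length(class_sets()$S5, 15)
  expect_equal(map_to_class_set("24", "S5"), "24")
  expect_error(map_to_class_set("13", "S5"), "not in class set")
  expect_error(map_to_class_set(9, "S2"), "1..8")
  expect_error(map_to_class_set(1, "S9"), "unknown class set")
})

test_that("window labeling chains pairs, lumping and class sets", {
  study <- small_study()
  labs <- study$labels
  expect_true(all(labs$s2 %in% class_sets()$S2))
  expect_true(all(nchar(labs$s5) == 2))
  expect_equal(labs$s1, as.character(labs$c1))
  # C1 is always the plurality behavior
  expect_true(all(labs$f1 >= labs$f2))
})
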