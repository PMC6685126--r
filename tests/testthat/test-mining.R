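# Equal-frequency discretization, Apriori, rule derivation and the
# question/behavior association analyses.

test_that("equal-frequency binning with nearest-rank edges and low-bin ties", {
  expect_identical(discretize_equal_frequency(1:9),
                   rep(c("low", "moderate", "high"), each = 3))
  # ties go to the lower bin, deterministically
  b <- discretize_equal_frequency(c(1, 1, 1, 1, 2, 3))
  expect_identical(b, c("low", "low", "low", "low", "moderate", "high"))
  expect_identical(discretize_equal_frequency(c(1, 1, 1, 1, 2, 3)), b)
  # constant (or too few distinct values): excluded
  expect_null(discretize_equal_frequency(rep(4, 10)))
  expect_null(discretize_equal_frequency(c(1, 1, 2, 2)))
  # NAs preserved
  expect_identical(discretize_equal_frequency(c(1:6, NA))[7], NA_character_)
})

test_that("Apriori matches the worked 4-transaction example exactly", {
  tr <- list(c("a", "b"), c("a", "b"), c("a", "c"), c("b", "c"))
  its <- apriori_frequent_itemsets(tr, 0.5)
  got <- setNames(its$support, vapply(its$items, itemset_key, character(1)))
  expect_equal(sort(names(got)), sort(c("a", "b", "c", "a|b")))
  expect_equal(unname(got[["a"]]), 0.75)
  expect_equal(unname(got[["b"]]), 0.75)
  expect_equal(unname(got[["c"]]), 0.5)
  expect_equal(unname(got[["a|b"]]), 0.5)

  # identical transactions at min_support 1: every non-empty subset
  tr2 <- rep(list(c("x", "y", "z")), 3)
  its2 <- apriori_frequent_itemsets(tr2, 1)
  expect_equal(nrow(its2), 7)
  expect_true(all(its2$support == 1))

  expect_equal(nrow(apriori_frequent_itemsets(tr, 0.9)), 0)
  expect_error(apriori_frequent_itemsets(list(), 0.5), "no transactions")

  # the size cap truncates the level-wise search without changing supports
  capped <- apriori_frequent_itemsets(tr2, 1, max_size = 2)
  expect_equal(max(capped$size), 2)
  expect_equal(nrow(capped), 6) # 3 singletons + 3 pairs of {x, y, z}
})

test_that("Apriori equals exhaustive enumeration on random transaction sets", {
  set.seed(55)
  items <- letters[1:10]
  for (rep in 1:15) {
    nt <- sample(6:20, 1)
    tr <- lapply(seq_len(nt), function(i)
      sample(items, sample(1:6, 1)))
    ms <- runif(1, 0.1, 0.5)
    got <- apriori_frequent_itemsets(tr, ms)
    want <- brute_frequent_itemsets(tr, ms)
    got_keys <- sort(vapply(got$items, itemset_key, character(1)))
    want_keys <- sort(vapply(want, function(w) itemset_key(w$items), character(1)))
    expect_identical(got_keys, want_keys)
    ws <- setNames(vapply(want, `[[`, numeric(1), "support"),
                   vapply(want, function(w) itemset_key(w$items), character(1)))
    gs <- setNames(got$support, vapply(got$items, itemset_key, character(1)))
    expect_equal(gs[want_keys], ws[want_keys], tolerance = 1e-12)
    # downward closure on the output
    for (i in which(got$size > 1)) {
      s <- got$items[[i]]
      for (d in seq_along(s))
        expect_true(itemset_key(s[-d]) %in% got_keys)
    }
  }
})

test_that("rule derivation computes confidence from itemset supports", {
  # 100 transactions: 46 {x, HL}, 4 {x}, 50 {z}
  tr <- c(rep(list(c("x", "HL")), 46), rep(list("x"), 4), rep(list("z"), 50))
  its <- apriori_frequent_itemsets(tr, 0.05)
  rules <- derive_rules(its, 0.9, "HL")
  expect_equal(nrow(rules), 1)
  expect_identical(rules$antecedent[[1]], "x")
  expect_equal(rules$support, 0.46)
  expect_equal(rules$confidence, 0.92, tolerance = 1e-12)

  # min_confidence 0: every frequent antecedent co-occurring with HL
  r0 <- derive_rules(its, 1e-9, "HL")
  expect_true(all(r0$consequent == "HL"))
  # behavior -> behavior rules are excluded by the consequent filter
  tr2 <- rep(list(c("f1", "f2")), 10)
  r2 <- derive_rules(apriori_frequent_itemsets(tr2, 0.5), 0.1, "HL")
  expect_equal(nrow(r2), 0)
  expect_error(derive_rules(its, 0.9, character(0)), "vocabulary")
  # confidence identity
  expect_equal(rules$confidence, rules$support / 0.5, tolerance = 1e-12)
})

test_that("question-level mining recovers a planted item association", {
  n <- 100
  resp <- matrix(1L, n, 20)
  lv <- rep("LL", n)
  hot <- 1:45
  resp[hot, 14] <- 4L # Q14 >= 3 for 45% of participants
  lv[hot] <- "HL"
  out <- mine_question_associations(resp, lv, min_support = 0.38,
                                    min_confidence = 0.90)
  r <- out$rules
  hit <- which(vapply(r$antecedent, function(a) identical(a, "Q14>=3"), logical(1)) &
               r$consequent == "level=HL")
  expect_length(hit, 1)
  expect_equal(r$support[hit], 0.45)
  expect_equal(r$confidence[hit], 1.0)

  # no item reaches support: empty
  out2 <- mine_question_associations(resp, lv, min_support = 0.99)
  expect_equal(nrow(out2$rules), 0)
})

test_that("raise-support search returns the largest support with rules", {
  n <- 100
  resp <- matrix(1L, n, 20)
  lv <- rep("LL", n)
  resp[1:41, 5] <- 3L
  lv[1:41] <- "HL"
  out <- mine_question_associations(resp, lv, min_support = 0.10,
                                    min_confidence = 0.90,
                                    search_optimal_support = TRUE, step = 0.01)
  expect_equal(out$optimal_support, 0.41, tolerance = 1e-9)
  expect_gt(nrow(out$rules), 0)
})

test_that("behavior-level mining recovers a planted low/low pattern", {
  set.seed(64)
  n <- 99 # terciles of exactly 33
  # the lowest tercile of each feature holds the 18 planted participants
  # plus 15 feature-specific others, so low AND low = the planted block
  f1 <- f2 <- runif(n, 5, 10)
  f1[c(1:18, 19:33)] <- runif(33, 0, 1)
  f2[c(1:18, 34:48)] <- runif(33, 0, 1)
  X <- cbind(`evening_offcampus [evening, weekends, semester]` = f1,
             `social_event_min [evening, weekdays, semester]` = f2)
  outcome <- c(rep("HL", 17), "LL", sample(c("HL", "LL"), 81, TRUE))
  out <- mine_behavior_associations(X, outcome, outcome_prefix = "postlevel",
                                    min_support = 0.10, min_confidence = 0.90)
  r <- out$rules
  pat <- which(vapply(r$antecedent, function(a)
    setequal(a, c("evening_offcampus [evening, weekends, semester]=low",
                  "social_event_min [evening, weekdays, semester]=low")),
    logical(1)) & r$consequent == "postlevel=HL")
  expect_length(pat, 1)
  # planted: 18 participants show the pattern, 17 of them are HL
  expect_equal(r$support[pat], 17 / 99, tolerance = 1e-9)
  expect_equal(r$confidence[pat], 17 / 18, tolerance = 1e-9)

  # constant features are excluded, empty selection gives no rules
  Xc <- cbind(const = rep(1, n))
  out2 <- mine_behavior_associations(Xc, outcome)
  expect_identical(out2$excluded_features, "const")
  expect_equal(nrow(out2$rules), 0)
  out3 <- mine_behavior_associations(X[, integer(0), drop = FALSE], outcome)
  expect_equal(nrow(out3$rules), 0)
})

test_that("null features: spurious rules are rare and unstable across seeds", {
  # with behavior unlinked to the outcome, any rule passing the thresholds
  # is a false discovery; such rules should be few per seed and no single
  # rule should recur across seeds
  rule_keys <- list()
  n_rules <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 60
    X <- matrix(runif(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    outcome <- sample(c("HL", "LL"), n, TRUE, prob = c(0.6, 0.4))
    out <- mine_behavior_associations(X, outcome, min_support = 0.10,
                                      min_confidence = 0.90)
    rule_keys[[s]] <<- unique(vapply(seq_len(nrow(out$rules)), function(i)
      paste(itemset_key(out$rules$antecedent[[i]]), out$rules$consequent[i]),
      character(1)))
    nrow(out$rules)
  }, numeric(1))
  # few false discoveries per seed relative to the thousands of candidate
  # antecedent combinations
  expect_lt(mean(n_rules), 3)
  # and no recurring rule: nothing shows up in more than a quarter of seeds
  all_keys <- unlist(rule_keys)
  if (length(all_keys) > 0) expect_lt(max(table(all_keys)), 5)
})
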