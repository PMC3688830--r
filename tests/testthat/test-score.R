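test_that("scoring counts involved sites and assigns the 3-tier group", {
  r <- sresc_score(c(1, 2, 4, 5))
  expect_equal(r$score, 4L)
  expect_equal(r$group, "medium")
  expect_equal(sresc_score(1:9)$score, 9L)
  expect_equal(sresc_score(1:9)$group, "high")
  expect_equal(sresc_score(1)$score, 1L)
  expect_equal(sresc_score(1)$group, "low")
})

test_that("scoring ignores listing order and duplicate sites", {
  expect_equal(sresc_score(c(5, 4, 2, 1))$score, sresc_score(c(1, 2, 4, 5))$score)
  expect_equal(sresc_score(c(1, 1, 1))$score, 1L)
  expect_equal(sresc_score("1;2;4;5")$score, 4L)
  expect_equal(sresc_score("5,2,1,4")$score, 4L)
})

test_that("invalid stone maps are rejected", {
  expect_error(sresc_score(integer(0)), "no stone")
  expect_error(sresc_score(""), "no stone")
  expect_error(sresc_score(c(0, 10)), "range")
  expect_error(sresc_score(2.5), "integers")
  expect_error(score_group(0), "1-9")
  expect_error(score_group(10), "1-9")
})

test_that("group rule partitions 1-9 as {1,2},{3,4},{5..9} exhaustively", {
  expect_equal(score_group(1:9),
               c("low", "low", "medium", "medium",
                 "high", "high", "high", "high", "high"))
  # every one of the 511 non-empty maps scores its cardinality and falls
  # in exactly one group
  for (mask in 1:511) {
    sites <- which(bitwAnd(mask, 2^(0:8)) > 0)
    r <- sresc_score(sites)
    expect_identical(r$score, length(sites))
    expect_true(r$group %in% group_levels())
    expect_equal(r$group, score_group(r$score))
  }
})

test_that("renometry classification follows the staghorn definitions", {
  expect_equal(classify_renometry(c(1, 2, 3, 4, 6, 8), 0.85),
               "complete staghorn")
  # all three calyceal regions but fill below 80% is only a partial staghorn
  expect_equal(classify_renometry(c(1, 2, 3, 4, 6, 8), 0.5),
               "partial staghorn")
  expect_equal(classify_renometry(c(1, 2, 8), 0.3), "partial staghorn")
  # two calyceal sites within one region: not a staghorn
  expect_equal(classify_renometry(c(1, 4, 5)), "pelvis+multiple calyces")
  expect_equal(classify_renometry(c(1, 4)), "pelvis+single calyx")
  expect_equal(classify_renometry(1), "pelvis only")
  expect_equal(classify_renometry(c(4, 8)), "multiple calyces")
  expect_equal(classify_renometry(6), "single calyx")
  expect_error(classify_renometry(integer(0)), "no stone")
  expect_error(classify_renometry(1, fill_fraction = 1.2), "0, 1")
})

test_that("every map yields exactly one category; complete implies partial", {
  for (mask in 1:511) {
    sites <- which(bitwAnd(mask, 2^(0:8)) > 0)
    for (fill in c(0.5, 0.9)) {
      cat_ <- classify_renometry(sites, fill)
      expect_true(cat_ %in% renometry_levels())
      if (cat_ == "complete staghorn") {
        # the partial predicate (pelvis + >= 2 calyceal regions) must hold
        expect_true(1 %in% sites)
        regions <- list(c(2, 4, 5), c(6, 7), c(3, 8, 9))
        expect_gte(sum(vapply(regions, function(r)
          any(r %in% sites), logical(1))), 2)
      }
    }
  }
})

test_that("stone volume follows the published formula", {
  expect_equal(stone_volume(10, 10, 10), 10 * 10 * 10 * pi * 0.52)
  expect_equal(round(stone_volume(10, 10, 10), 2), 1633.63)
  expect_equal(stone_volume(10, 0, 10), 0)
  expect_equal(stone_volume(20, 10, 10), 2 * stone_volume(10, 10, 10))
  expect_error(stone_volume(-1, 10, 10), "non-negative")
})

test_that("stone volume is monotone nondecreasing in each dimension", {
  set.seed(42)
  for (i in 1:50) {
    d <- runif(3, 0, 30)
    bump <- runif(1, 0, 5)
    base <- stone_volume(d[1], d[2], d[3])
    expect_gte(stone_volume(d[1] + bump, d[2], d[3]), base)
    expect_gte(stone_volume(d[1], d[2] + bump, d[3]), base)
    expect_gte(stone_volume(d[1], d[2], d[3] + bump), base)
  }
})

test_that("total stone volume sums per-stone volumes; empty set is 0", {
  expect_equal(total_stone_volume(data.frame(length_mm = numeric(0),
                                             width_mm = numeric(0),
                                             depth_mm = numeric(0))), 0)
  one <- data.frame(length_mm = 12, width_mm = 8, depth_mm = 5)
  expect_equal(total_stone_volume(one), stone_volume(12, 8, 5))
  two <- data.frame(length_mm = c(10, 10), width_mm = 10, depth_mm = 10)
  expect_equal(round(total_stone_volume(two), 2), 3267.26)
})
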