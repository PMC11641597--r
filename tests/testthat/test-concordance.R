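test_that("centroid distance matches direct arithmetic", {
  expect_equal(centroid_distance(rbind(c(50, 10), c(50, 10)), c(50, 10)), 0)
  expect_equal(centroid_distance(rbind(c(0, 0), c(2, 0)), c(1, 1)), 1)

  pairs <- rbind(c(64, 2), c(66, 4), c(70, 10), c(65, 3), c(68, 6))
  query <- c(61, 16)
  cen <- c(mean(pairs[, 1]), mean(pairs[, 2]))
  expect_equal(centroid_distance(pairs, query),
               sqrt(sum((query - cen)^2)))
})

test_that("centroid distance is order-invariant and translation-equivariant", {
  set.seed(5)
  for (rep in 1:10) {
    pairs <- matrix(round(runif(10, 0, 80)), 5, 2)
    q <- round(runif(2, 0, 80))
    d <- centroid_distance(pairs, q)
    expect_equal(centroid_distance(pairs[sample(5), ], q), d)
    shift <- round(runif(2, -20, 20))
    expect_equal(centroid_distance(sweep(pairs, 2, -shift), q + shift), d)
  }
})

test_that("strict 'below the maximum' rule gives the documented edge cases", {
  # everyone identical: both distances are 0, strictly-below fails -> 0%
  same <- data.frame(rater_id = paste0("R", 1:4), dapi = 50, marker = 10)
  res0 <- percentage_concordance(list(rater_count_set("img", same, c(50, 10))))
  expect_equal(res0$percentage, 0)
  expect_false(res0$per_image$within)

  # algorithm exactly at the centroid of spread raters -> 100%
  spread <- data.frame(rater_id = paste0("R", 1:4),
                       dapi = c(48, 52, 50, 50), marker = c(10, 10, 8, 12))
  res1 <- percentage_concordance(list(rater_count_set("img", spread, c(50, 10))))
  expect_equal(res1$percentage, 100)
})

test_that("concordance percentage matches the brute-force oracle exactly", {
  sets <- make_rater_sets(n_images = 10, n_raters = 5, seed = 42)
  got <- percentage_concordance(sets)
  expect_equal(got$percentage, oracle_concordance(sets))
  expect_gte(got$percentage, 0)
  expect_lte(got$percentage, 100)
})

test_that("leave-one-out scores a rater against the remaining raters only", {
  sets <- make_rater_sets(n_images = 6, n_raters = 5, seed = 8)
  r1 <- percentage_concordance(sets, leave_out = "R1")
  manual <- oracle_concordance(lapply(sets, function(s) {
    q <- as.numeric(s$raters[s$raters$rater_id == "R1", c("dapi", "marker")])
    s$raters <- s$raters[s$raters$rater_id != "R1", ]
    s$algorithm <- q
    s
  }))
  expect_equal(r1$percentage, manual)
  two <- list(rater_count_set("x", data.frame(rater_id = c("R1", "R2"),
                                              dapi = c(10, 12), marker = c(1, 2)),
                              c(11, 1)))
  expect_error(percentage_concordance(two, leave_out = "R1"), "fewer than 2")
})

test_that("the maximum rater distance is attained by a rater and is order-invariant", {
  sets <- make_rater_sets(n_images = 5, n_raters = 4, seed = 13)
  for (s in sets) {
    res <- percentage_concordance(list(s))$per_image
    pts <- as.matrix(s$raters[, c("dapi", "marker")])
    cen <- colMeans(pts)
    d <- apply(pts, 1, function(p) sqrt(sum((p - cen)^2)))
    expect_equal(res$max_rater_distance, max(d))
    shuf <- s
    shuf$raters <- shuf$raters[rev(seq_len(nrow(shuf$raters))), ]
    expect_equal(percentage_concordance(list(shuf))$per_image$max_rater_distance,
                 res$max_rater_distance)
  }
})

test_that("percent over range reproduces the published worked examples", {
  # image 8: algorithm 62 vs researcher counts spanning 39-55
  expect_equal(round(percent_over_range(62, c(55, 51, 54, 51, 39)), 1), 12.7)
  # image 10: algorithm 50 vs researcher counts 46,44,45,46,37
  expect_equal(round(percent_over_range(50, c(46, 44, 45, 46, 37)), 1), 8.7)
})

test_that("percent over range is signed by position relative to the range", {
  raters <- c(40, 45, 50)
  expect_gt(percent_over_range(55, raters), 0)
  expect_lt(percent_over_range(30, raters), 0)
  expect_equal(percent_over_range(45, raters), 0)
  expect_equal(percent_over_range(40, raters), 0)   # boundary is inside
  expect_equal(percent_over_range(30, raters), 100 * (30 - 40) / 40)
})

test_that("rater CSV reading and concordance writing round-trip", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "raters.csv")
  df <- expand.grid(image_name = c("a", "b"),
                    rater_id = c("R1", "R2", "R3", "FINS"),
                    channel = c("DAPI", "Ki67"), stringsAsFactors = FALSE)
  set.seed(2)
  df$count <- round(runif(nrow(df), 5, 60))
  write.csv(df, csv, row.names = FALSE)
  sets <- read_rater_counts(csv, marker_channel = "Ki67")
  expect_length(sets, 2)
  expect_equal(nrow(sets[[1]]$raters), 3)
  expect_length(sets[[1]]$algorithm, 2)
  res <- percentage_concordance(sets)
  out <- file.path(dir, "conc.csv")
  write_concordance_csv(res, out)
  back <- read.csv(out)
  expect_equal(nrow(back), 2)
  expect_equal(back$percentage[1], res$percentage)
})
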