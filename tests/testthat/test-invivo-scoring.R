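test_that("caliper volume follows the smaller-dimension ellipsoid rule", {
  expect_equal(tumor_volume(10, 8), 10 * 64 * pi / 6, tolerance = 1e-12)
  expect_equal(tumor_volume(8, 10), tumor_volume(10, 8))  # order invariance
  expect_equal(tumor_volume(2, 2), 8 * pi / 6, tolerance = 1e-12)
  expect_error(tumor_volume(-1, 5), "positive")
  expect_error(tumor_volume(0, 5), "positive")
})

test_that("caliper series are validated when converted to volumes", {
  cal <- tibble::tibble(
    patient = "PT1", group = "vehicle",
    mouse_id = rep("m1", 3), day = c(1, 4, 7),
    d1_mm = c(5, 6, 7), d2_mm = c(4, 5, 6)
  )
  vol <- caliper_volumes(cal)
  expect_equal(vol$volume_mm3, tumor_volume(cal$d1_mm, cal$d2_mm))

  dup <- cal; dup$day[2] <- 1
  expect_error(caliper_volumes(dup), "Duplicate")
  expect_error(caliper_volumes(cal[1:2, ]), "fewer than 3")
})

test_that("group allocation trims extremes and balances means", {
  # trimming oracle: 2/12 exclusion removes exactly the two extremes
  base <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12),
                         volume_mm3 = c(50, rep(100, 10), 400))
  alloc <- allocate_groups(base, n_groups = 2, exclusion_fraction = 2 / 12)
  expect_setequal(alloc$excluded$mouse_id, c("m01", "m12"))
  expect_equal(sort(alloc$excluded$volume_mm3), c(50, 400))
  expect_equal(alloc$group_summary$mean_mm3, c(100, 100))

  # serpentine on 1..12, 2 groups: means differ by at most 1
  seq12 <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12),
                          volume_mm3 = as.numeric(1:12))
  a2 <- allocate_groups(seq12, n_groups = 2)
  means <- a2$group_summary$mean_mm3
  expect_lte(abs(diff(means)), 1)
  sizes <- a2$group_summary$n
  expect_lte(max(sizes) - min(sizes), 1)

  # identical volumes: any assignment gives equal means
  same <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12), volume_mm3 = 100)
  a4 <- allocate_groups(same, n_groups = 4)
  expect_true(all(a4$group_summary$mean_mm3 == 100))

  expect_error(allocate_groups(seq12, n_groups = 5), "infeasible")
})

test_that("serpentine assignment matches a direct enumeration for small n", {
  # independent oracle: walk the groups back and forth, repeating at the
  # turn, exactly as cards are dealt in snake order
  snake_oracle <- function(n, k) {
    out <- integer(n); g <- 1L; dir <- 1L
    for (i in seq_len(n)) {
      out[i] <- g
      if (k == 1) next
      at_turn <- (g == k && dir == 1L) || (g == 1L && dir == -1L)
      if (at_turn) dir <- -dir else g <- g + dir
    }
    out
  }
  for (n in 3:8) {
    for (k in 1:min(3, n)) {
      vols <- tibble::tibble(mouse_id = sprintf("m%d", 1:n),
                             volume_mm3 = as.numeric(n:1))
      alloc <- allocate_groups(vols, n_groups = k, min_per_group = 1)
      sorted <- dplyr::arrange(alloc$assignments, volume_mm3)
      expect_identical(match(sorted$group, sprintf("group%d", 1:k)),
                       snake_oracle(n, k))
    }
  }
})

test_that("allocation balances means across random volume sets", {
  # enrollment protocol: 16 implanted mice, the 4 at the volume extremes
  # excluded, 12 allocated to 3 arms
  set.seed(202)
  worst <- vapply(1:100, function(i) {
    vols <- tibble::tibble(
      mouse_id = sprintf("m%02d", 1:16),
      volume_mm3 = 100 * exp(rnorm(16, 0, 0.15))
    )
    m <- allocate_groups(vols, n_groups = 3,
                         exclusion_fraction = 0.25)$group_summary$mean_mm3
    (max(m) - min(m)) / mean(m)
  }, numeric(1))
  expect_lt(max(worst), 0.10)  # all group means within 10% of each other

  # serpentine beats random assignment on mean balance at the median
  set.seed(203)
  spread <- function(groups, vols) {
    m <- tapply(vols, groups, mean)
    max(m) - min(m)
  }
  deltas <- vapply(1:100, function(i) {
    vols <- 100 * exp(rnorm(12, 0, 0.15))
    tb <- tibble::tibble(mouse_id = sprintf("m%02d", 1:12), volume_mm3 = vols)
    serp <- allocate_groups(tb, n_groups = 3)$assignments
    random <- sample(rep(1:3, 4))
    spread(serp$group, serp$volume_mm3) - spread(random, vols)
  }, numeric(1))
  expect_lt(median(deltas), 0)
})

test_that("vivo score matches the defining formula", {
  expect_equal(vivo_score_value(100, 100), 1)
  expect_equal(vivo_score_value(50, 25), 3)      # 0.5*2 + 0.5*4
  expect_equal(vivo_score_value(200, 200), 0.5)  # faster than control
})

test_that("vivo scores use the penultimate and last shared days", {
  mk_series <- function(group, mouse, vols, days = c(1, 4, 7, 10, 13)) {
    tibble::tibble(patient = "PT1", group = group, mouse_id = mouse,
                   day = days, volume_mm3 = vols)
  }
  ctrl <- dplyr::bind_rows(mk_series("vehicle", "c1", c(100, 120, 150, 200, 260)),
                           mk_series("vehicle", "c2", c(100, 140, 170, 200, 300)))
  # identical treatment arm scores exactly 1
  trt <- dplyr::bind_rows(mk_series("drugA", "t1", c(100, 120, 150, 200, 260)),
                          mk_series("drugA", "t2", c(100, 140, 170, 200, 300)))
  vs <- vivo_scores(dplyr::bind_rows(ctrl, trt), "vehicle")
  expect_equal(vs$vivo_f, 1)
  expect_equal(vs$day_penultimate, 10)
  expect_equal(vs$day_last, 13)

  # halved at day 10, quartered at day 13 -> vivoF 3
  trt2 <- dplyr::bind_rows(mk_series("drugB", "t3", c(100, 100, 100, 100, 70)),
                           mk_series("drugB", "t4", c(100, 100, 100, 100, 70)))
  vs2 <- vivo_scores(dplyr::bind_rows(ctrl, trt2), "vehicle")
  expect_equal(vs2$ttv_penultimate, 100 * 100 / 200)
  expect_equal(vs2$ttv_last, 100 * 70 / 280)
  expect_equal(vs2$vivo_f, 0.5 * 200 / 100 + 0.5 * 280 / 70)

  # a mouse missing the last day is dropped from that mean with a warning
  trt3 <- dplyr::bind_rows(mk_series("drugC", "t5", c(100, 100, 100, 100, 70)),
                           mk_series("drugC", "t6", c(100, 100, 100, 100),
                                     days = c(1, 4, 7, 10)))
  expect_warning(vs3 <- vivo_scores(dplyr::bind_rows(ctrl, trt3), "vehicle"),
                 "missing day")
  expect_equal(vs3$ttv_last, 100 * 70 / 280)

  expect_error(vivo_scores(dplyr::bind_rows(ctrl[ctrl$day == 1, ], trt), "vehicle"),
               "shared measurement days")
})

test_that("vivo scores recover the exponential closed form exactly", {
  r <- 0.08
  for (g in c(0.25, 0.5, 0.9)) {
    cfg <- exact_scenario(g = g)
    vol <- caliper_volumes(simulate_growth(cfg))
    vs <- vivo_scores(vol, "vehicle")
    expect_equal(vs$vivo_f, 0.5 * exp(r * g * 10) + 0.5 * exp(r * g * 13),
                 tolerance = 1e-9)
  }
})
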