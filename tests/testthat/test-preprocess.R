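test_that("composite scoring averages reverse-corrected items", {
  items <- data.frame(
    person = "p1", day = 1L, slot = "AM",
    variable = c("i1", "i2", "i3", "i4"),
    value = c(80, 60, 20, 60))
  panel <- ema_panel(items)
  spec <- composite_spec("sc", c("i1", "i2", "i3", "i4"), reverse = "i3")
  scored <- score_composites(panel, spec)
  expect_equal(scored$value[scored$variable == "sc"], 70)

  rum <- ema_panel(data.frame(person = "p1", day = 1L, slot = "PM",
                              variable = c("r1", "r2"), value = c(10, 30)))
  scored2 <- score_composites(rum, composite_spec("rumination",
                                                  c("r1", "r2")))
  expect_equal(scored2$value[scored2$variable == "rumination"], 20)
})

test_that("composites respect the minimum-items threshold", {
  items <- data.frame(person = "p1", day = 1L, slot = "AM",
                      variable = c("i1", "i2", "i3", "i4"),
                      value = c(40, NA, NA, NA))
  panel <- ema_panel(items)
  spec3 <- composite_spec("sc", paste0("i", 1:4), min_items = 3L)
  scored <- score_composites(panel, spec3)
  expect_true(is.na(scored$value[scored$variable == "sc"]))
  spec1 <- composite_spec("sc", paste0("i", 1:4), min_items = 1L)
  expect_equal(score_composites(panel, spec1)$value[5L], 40)

  expect_error(
    score_composites(panel, composite_spec("x", c("i1", "nope"))),
    "unknown item")
})

test_that("composite algebra: identical items and double reversal", {
  panel <- complete_panel(persons = 2L, days = 2L,
                          variables = c("j1", "j2"))
  # identical items: composite equals the item value
  dup <- as.data.frame(panel[panel$variable == "j1", ])
  dup$variable <- "j1b"
  p2 <- ema_panel(rbind(as.data.frame(panel), dup))
  sc <- score_composites(p2, composite_spec("cmp", c("j1", "j1b")))
  okey <- function(d) d[order(d$person, d$day, d$slot), "value"]
  cmp <- sc[sc$variable == "cmp", ]
  j1 <- sc[sc$variable == "j1", ]
  expect_equal(okey(cmp), okey(j1))

  # reversing twice is the identity
  rev_once <- as.data.frame(panel)
  rev_once$value[rev_once$variable == "j1"] <-
    100 - rev_once$value[rev_once$variable == "j1"]
  sc2 <- score_composites(ema_panel(rev_once),
                          composite_spec("cmp", "j1", reverse = "j1"))
  expect_equal(okey(sc2[sc2$variable == "cmp", ]), okey(j1))
})

test_that("compliance is completed over expected occasions", {
  full <- complete_panel(persons = 3L, days = 9L, variables = "anger")
  expect_equal(compliance(full, "anger", expected = 18)$overall, 100)

  half <- full[!(full$slot == "PM"), ]
  half <- ema_panel(as.data.frame(half))
  res <- compliance(half, "anger", expected = 18)
  expect_equal(res$overall, 50)
  expect_equal(res$per_person$rate, rep(50, 3L))

  expect_error(compliance(full, "anger", expected = 0), "positive")

  # Bernoulli(0.85) completion at study size lands near 85% (binomial
  # oracle: sd of the mean rate is ~1.1 points at 62 x 18)
  set.seed(11)
  grid <- expand.grid(person = sprintf("p%02d", 1:62), day = 1:9,
                      slot = c("AM", "PM"), variable = "anger",
                      stringsAsFactors = FALSE)
  grid$value <- 50
  keep <- runif(nrow(grid)) < 0.85
  panel <- ema_panel(grid[keep, ])
  rate <- compliance(panel, "anger", expected = 18)$overall
  expect_lt(abs(rate - 85), 3)
})

test_that("descriptives report slot means and a paired AM/PM comparison", {
  const <- complete_panel(persons = 4L, days = 3L, variables = "v")
  const$value <- 50
  const <- ema_panel(as.data.frame(const))
  d <- descriptives(const, "v")
  expect_equal(d$mean_all, 50)
  expect_equal(d$sd_all, 0)
  expect_false(d$p_am_vs_pm < 0.05)

  # forced separation: AM all 10, PM all 20 (with tiny person jitter so
  # the paired t-test is defined)
  set.seed(2)
  grid <- expand.grid(person = sprintf("p%02d", 1:12), day = 1:3,
                      slot = c("AM", "PM"), variable = "v",
                      stringsAsFactors = FALSE)
  grid$value <- ifelse(grid$slot == "AM", 10, 20) +
    rep(rnorm(12, 0, 0.1), times = 6)
  sep <- ema_panel(grid)
  ds <- descriptives(sep, "v")
  expect_equal(ds$mean_am, 10, tolerance = 0.05)
  expect_equal(ds$mean_pm, 20, tolerance = 0.05)
  expect_lt(ds$p_am_vs_pm, 0.05)

  expect_error(descriptives(const, "missing_var"), "absent")
})

test_that("generator defaults produce no morning/afternoon difference", {
  tm <- paper_preset()
  panel <- simulate_panel(tm, seed = 301)
  d <- descriptives(panel, tm$nodes)
  expect_true(all(d$p_am_vs_pm > 0.05))
})

test_that("lag pairs follow the within-day AM->PM design", {
  panel <- complete_panel(persons = 2L, days = 9L, variables = c("a", "b"))
  lags <- build_lag_pairs(panel, c("a", "b"))
  expect_equal(nrow(lags), 18L)  # 9 pairs per complete person
  expect_equal(sum(lags$person == "p01"), 9L)

  # AM-only person contributes no pairs
  am_only <- as.data.frame(panel)
  am_only <- am_only[!(am_only$person == "p02" & am_only$slot == "PM"), ]
  lags2 <- build_lag_pairs(ema_panel(am_only), c("a", "b"))
  expect_equal(unique(lags2$person), "p01")

  expect_error(build_lag_pairs(panel, c("a", "zzz")), "absent")
})

test_that("lag rows never cross days and centering uses all occasions", {
  # hand fixture: person p1, 3 days; day 2 has AM missing for variable a
  df <- expand.grid(person = "p1", day = 1:3, slot = c("AM", "PM"),
                    variable = "a", stringsAsFactors = FALSE)
  df$value <- c(10, 30, 50, 20, 40, 60)  # AM d1..d3, PM d1..d3
  df <- df[!(df$day == 2L & df$slot == "AM"), ]
  lags <- build_lag_pairs(ema_panel(df), "a")
  # person mean over ALL five observed occasions, PM of day 2 included
  m_hand <- mean(c(10, 50, 20, 40, 60))
  expect_equal(unique(lags$m_a), m_hand)
  # day 2 contributes no lag row (its morning is unobserved), but its
  # afternoon value entered the person mean above
  expect_setequal(lags$day, c(1L, 3L))
  expect_equal(lags$c_a[lags$day == 1L], 10 - m_hand)
  expect_equal(lags$y_a[lags$day == 1L], 20)
  expect_equal(lags$y_a[lags$day == 3L], 60)

  # property: on random gappy panels each row pairs AM and PM of the SAME
  # day, and complete persons have centered-predictor mean ~ 0
  set.seed(33)
  for (rep in 1:5) {
    panel <- complete_panel(persons = 3L, days = 6L,
                            variables = c("a", "b"), seed = rep)
    drop <- sample.int(nrow(panel), 10L)
    gappy <- ema_panel(as.data.frame(panel)[-drop, ])
    lg <- build_lag_pairs(gappy, c("a", "b"))
    wide <- as.data.frame(panel)[-drop, ]
    for (i in seq_len(nrow(lg))) {
      pm_val <- wide$value[wide$person == lg$person[i] &
                             wide$day == lg$day[i] & wide$slot == "PM" &
                             wide$variable == "a"]
      expect_equal(lg$y_a[i], if (length(pm_val)) pm_val else NA_real_)
    }
  }
  # exact centering: when AM and PM values coincide day by day, the
  # person mean equals the AM mean and centered predictors average to 0
  sym <- complete_panel(persons = 3L, days = 8L, variables = "a")
  sym <- as.data.frame(sym)
  sym$value <- ave(sym$value, sym$person, sym$day, FUN = mean)
  full <- build_lag_pairs(ema_panel(sym), "a")
  by_person <- tapply(full$c_a, full$person, mean)
  expect_equal(as.vector(by_person), rep(0, 3L), tolerance = 1e-12)
})

test_that("panels with an all-missing person are rejected", {
  df <- data.frame(person = c("p1", "p1", "p2"), day = 1L,
                   slot = c("AM", "PM", "AM"), variable = "a",
                   value = c(10, 20, NA))
  expect_error(build_lag_pairs(ema_panel(df), "a"), "zero observed")
})
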