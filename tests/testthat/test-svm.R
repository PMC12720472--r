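test_that("bootstrap-LOOCV accuracy separates what is separable", {
  tab <- simulate_feature_table(group_effect_spec(n_per_group = 6L,
                                                  n_parameters = 1L,
                                                  effect_size = 20,
                                                  rng_seed = 0))
  r <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 200, seed = 0)
  expect_gte(r$mean_accuracy_pct, 99)
  expect_true(r$ci_lo <= r$mean_accuracy_pct &
                r$mean_accuracy_pct <= r$ci_hi)
  expect_equal(r$n_animals, 12)
})

test_that("accuracy reports are deterministic and validate their inputs", {
  tab <- simulate_feature_table(group_effect_spec(n_per_group = 4L,
                                                  n_parameters = 2L,
                                                  effect_size = 1,
                                                  rng_seed = 1))
  a <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 50, seed = 9)
  b <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 50, seed = 9)
  expect_identical(a, b)
  expect_error(bootstrap_loocv_accuracy(tab, "nope", n_boot = 10, seed = 1),
               "not found")
  small <- tab[c(1, 5), ]
  expect_error(bootstrap_loocv_accuracy(small, "p01", n_boot = 10, seed = 1),
               "at least 2")
  # a zero-variance feature scores chance level with a flag
  tab$flat <- 1
  z <- bootstrap_loocv_accuracy(tab, "flat", n_boot = 20, seed = 1)
  expect_equal(z$mean_accuracy_pct, 50)
  expect_match(z$flag, "zero-variance")
})

test_that("accuracy is invariant to affine rescaling of a feature", {
  tab <- simulate_feature_table(group_effect_spec(n_per_group = 6L,
                                                  n_parameters = 1L,
                                                  effect_size = 1.5,
                                                  rng_seed = 3))
  a <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 100, seed = 4)
  tab$p01 <- 1000 * tab$p01 - 77
  b <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 100, seed = 4)
  expect_equal(a$mean_accuracy_pct, b$mean_accuracy_pct, tolerance = 1e-9)
})

test_that("parameter ranking orders by accuracy and carries categories", {
  spec <- group_effect_spec(n_per_group = 6L, n_parameters = 3L,
                            effect_size = c(0, 1, 4), rng_seed = 6)
  tab <- simulate_feature_table(spec)
  cats <- c(p01 = "vein", p02 = "artery", p03 = "microvasculature")
  rk <- rank_parameters(tab, n_boot = 100, seed = 2, categories = cats)
  expect_equal(nrow(rk), 3)
  expect_true(all(diff(rk$mean_accuracy_pct) <= 0))
  expect_identical(rk$parameter[1], "p03")     # strongest effect ranks first
  # duplicated parameter column reproduces identical reports at fixed seed
  tab2 <- tab; tab2$p04 <- tab2$p03
  rk2 <- rank_parameters(tab2, n_boot = 50, seed = 2,
                         categories = c(cats, p04 = "microvasculature"))
  expect_equal(rk2$mean_accuracy_pct[rk2$parameter == "p03"],
               rk2$mean_accuracy_pct[rk2$parameter == "p04"],
               tolerance = 1e-9)
  # single parameter still yields a one-row report
  one <- rank_parameters(tab[, c("animal_id", "group", "p02")],
                         n_boot = 20, seed = 1)
  expect_equal(nrow(one), 1)
  expect_error(rank_parameters(tab, n_boot = 10, seed = 1,
                               categories = cats[1:2]), "unmapped")
})

test_that("category summaries are means with SEM, order-invariant", {
  rep <- data.frame(parameter = c("a", "b", "c"),
                    mean_accuracy_pct = c(80, 90, 70))
  cats <- c(a = "micro", b = "micro", c = "vein")
  s <- group_category_summary(rep, cats)
  micro <- s[s$category == "micro", ]
  expect_equal(micro$mean_accuracy_pct, 85)
  expect_equal(micro$sem_pct, 5)
  vein <- s[s$category == "vein", ]
  expect_equal(vein$sem_pct, 0)
  expect_true(vein$sem_flag)
  s2 <- group_category_summary(rep[c(3, 1, 2), ], cats)
  expect_equal(s2[order(s2$category), ], s[order(s$category), ],
               ignore_attr = TRUE)
  expect_error(group_category_summary(rep, cats[1:2]), "unmapped")
})

test_that("null-effect confidence intervals usually cover chance level", {
  covers <- vapply(1:20, function(s) {
    tab <- simulate_feature_table(group_effect_spec(n_per_group = 6L,
                                                    n_parameters = 1L,
                                                    effect_size = 0,
                                                    rng_seed = 100 + s))
    r <- bootstrap_loocv_accuracy(tab, "p01", n_boot = 60, seed = s)
    r$ci_lo <= 50 && 50 <= r$ci_hi
  }, logical(1))
  expect_gte(mean(covers), 0.9)
})
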