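test_that("NMJ-grain aggregation averages within terminals first", {
  tab <- data.frame(nmj_id = c(1, 1, 1), type = "Ib", frequency_hz = 20,
                    max_dff = c(0.1, 0.2, 0.3))
  s <- aggregate_kinetics(tab)
  nmj <- s[s$grain == "NMJ", ]
  expect_equal(nmj$mean, 0.2)
  expect_equal(nmj$n, 3L)
  expect_equal(nmj$N, 1L)
  # two NMJs with unequal bouton counts: NMJ means weighted equally
  tab2 <- data.frame(nmj_id = c(1, 1, 1, 2), type = "Ib", frequency_hz = 20,
                     max_dff = c(0.2, 0.2, 0.2, 0.4))
  s2 <- aggregate_kinetics(tab2)
  expect_equal(s2$mean[s2$grain == "NMJ"], 0.3)
  expect_equal(s2$mean[s2$grain == "bouton"], 0.25)
})

test_that("aggregation matches a brute-force two-pass oracle on random tables", {
  set.seed(17)
  for (rep in 1:25) {
    tab <- data.frame(
      nmj_id = sample(1:4, 30, replace = TRUE),
      type = sample(c("Ib", "Is"), 30, replace = TRUE),
      frequency_hz = sample(c(10, 40), 30, replace = TRUE),
      max_dff = runif(30))
    s <- aggregate_kinetics(tab)
    for (i in which(s$grain == "NMJ")) {
      d <- tab[tab$type == s$type[i] & tab$frequency_hz == s$frequency_hz[i], ]
      per_nmj <- vapply(split(d$max_dff, d$nmj_id), mean, numeric(1))
      expect_equal(s$mean[i], mean(per_nmj))
      expect_equal(s$sd[i], sd(per_nmj))
      expect_equal(s$N[i], length(per_nmj))
      b <- s[s$grain == "bouton" & s$type == s$type[i] &
               s$frequency_hz == s$frequency_hz[i], ]
      expect_equal(b$mean, mean(d$max_dff))
      expect_equal(b$n, nrow(d))
    }
  }
})

test_that("Bonferroni arithmetic and stars are exact", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.3, 6), 1)
  expect_equal(signif_stars(c(0.0004, 0.004, 0.04, 0.4)),
               c("***", "**", "*", ""))
})

test_that("identical samples give adjusted p near 1 and no stars", {
  set.seed(4)
  x <- rnorm(20)
  d <- data.frame(value = c(x, x), group = rep(c("a", "b"), each = 20))
  res <- run_group_tests(d, list(c("a", "b")), "t_test_bonferroni")
  expect_gt(res$p_adjusted, 0.99)
  expect_equal(res$stars, "")
})

test_that("degenerate groups are skipped with a reason", {
  d <- data.frame(value = c(1, 2, 3, 4), group = c("a", "a", "a", "b"))
  res <- run_group_tests(d, list(c("a", "b")), "t_test")
  expect_true(is.na(res$p_raw))
  expect_match(res$skipped, "< 2 observations")
})

test_that("Fisher's LSD uses the pooled ANOVA variance", {
  set.seed(8)
  d <- data.frame(value = c(rnorm(15, 0), rnorm(15, 0.1), rnorm(15, 3)),
                  group = rep(c("a", "b", "c"), each = 15))
  res <- run_group_tests(d, list(c("a", "b"), c("a", "c"), c("b", "c")),
                         "anova_fisher_lsd")
  expect_lt(attr(res, "omnibus_p"), 0.001)
  expect_gt(res$p_raw[1], 0.05)   # a vs b: no real shift
  expect_lt(res$p_raw[2], 0.001)  # a vs c: 3-sigma shift
  # LSD is unadjusted: raw and reported p coincide
  expect_equal(res$p_raw, res$p_adjusted)
})

test_that("t-test rejection rate tracks a permutation oracle", {
  # shifted normals, d = 2 SD, n = 12/group
  set.seed(21)
  n <- 12; reps <- 120; nperm <- 150
  t_rej <- perm_rej <- logical(reps)
  for (r in seq_len(reps)) {
    a <- rnorm(n); b <- rnorm(n, 2)
    t_rej[r] <- stats::t.test(a, b)$p.value < 0.05
    obs <- mean(a) - mean(b)
    pool <- c(a, b)
    null <- replicate(nperm, {
      idx <- sample(2 * n, n)
      mean(pool[idx]) - mean(pool[-idx])
    })
    perm_rej[r] <- mean(abs(null) >= abs(obs)) < 0.05
  }
  expect_lt(abs(mean(t_rej) - mean(perm_rej)), 0.05)
})

test_that("table cells render as value +/- SD (n, N) with stars", {
  s <- data.frame(type = "Ib", grain = "bouton", mean = 0.16, sd = 0.11,
                  sem = 0.015, n = 53L, N = 9L)
  class(s) <- c("grouped_summary", "data.frame")
  out <- render_tables(s)
  expect_equal(out$cell, "0.16 ± 0.11 (53, 9)")
  tests <- data.frame(comparison = "Ib vs Is", p_raw = 2e-4,
                      p_adjusted = 4e-4, stars = "***", skipped = "")
  out2 <- render_tables(s, tests)
  expect_equal(out2$cell, "0.16 ± 0.11 (53, 9)***")
})
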