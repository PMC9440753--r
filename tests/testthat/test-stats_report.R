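test_that("spearman matches the exhaustive rank formula at n = 5", {
  x <- 1:5
  expect_equal(spearman(x, x)$statistic, 1)
  expect_equal(spearman(x, rev(x))$statistic, -1)

  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (y in perms(1:5)) {
    rho <- spearman(x, y)$statistic
    oracle <- 1 - 6 * sum((x - y)^2) / (5 * (5^2 - 1))
    expect_equal(rho, oracle, tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("mann-whitney U matches the brute-force pairwise count", {
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  res <- mann_whitney(a, b)
  # wilcox.test's W counts pairs where a beats b
  u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(unname(res$statistic), u_brute)
  expect_equal(unname(res$statistic), 0)

  # identical groups: no shift, p about 1
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gte(same$p_value, 0.99)

  # Bonferroni over 3 comparisons
  m3 <- mann_whitney(a, b, m_comparisons = 3)
  expect_equal(m3$p_adjusted, min(1, 3 * m3$p_value))
  expect_gte(m3$p_adjusted, m3$p_value)

  # rank test is invariant to monotone transforms of the pooled data
  mono <- mann_whitney(exp(a), exp(b))
  expect_equal(mono$p_value, res$p_value)
  expect_error(mann_whitney(numeric(0), b), "non-empty")
})

test_that("kruskal-wallis H matches the rank-sum formula with Dunn post hoc", {
  groups <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_dunn(groups)
  rk <- rank(unlist(groups))
  N <- 9
  H <- 12 / (N * (N + 1)) *
    sum(3 * (tapply(rk, rep(1:3, each = 3), mean) - (N + 1) / 2)^2)
  expect_equal(unname(res$statistic), H, tolerance = 1e-12)

  # permuting group order leaves H unchanged
  res2 <- kruskal_dunn(groups[c(3, 1, 2)])
  expect_equal(res2$statistic, res$statistic)

  # identical groups: H ~ 0, all pairwise adjusted p = 1
  same <- kruskal_dunn(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                            g3 = c(1, 2, 3)))
  expect_lt(same$statistic, 1e-9)
  expect_true(all(same$pairwise$p_adjusted == 1))

  # adjusted p-values never fall below raw ones and are capped at 1
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_value))
  expect_true(all(res$pairwise$p_adjusted <= 1))
  expect_error(kruskal_dunn(list(1:3, 4:6)), "at least 3")
})

test_that("pooled t-test matches the closed-form arithmetic", {
  same <- t_test_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)

  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  res <- t_test_unpaired(a, b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (4 + 4 - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(unname(res$statistic), t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 6)
  # sign follows mean(a) - mean(b)
  expect_lt(res$statistic, 0)
  expect_gt(t_test_unpaired(b, a)$statistic, 0)
  expect_error(t_test_unpaired(c(1, 1), c(1, 1)), "variance")
})

test_that("ordinal index summaries report rounded category percentages", {
  s <- summarize_index(c(rep(3L, 15), rep(2L, 3)))
  expect_equal(s$categories$percent[s$categories$score == 2], 17)
  expect_equal(s$n, 18)

  all3 <- summarize_index(rep(3L, 10))
  expect_equal(all3$mean, 3)
  expect_equal(all3$sd, 0)
  expect_equal(all3$categories$percent, c(0, 0, 100))

  expect_equal(summarize_index(1:3)$mean, 2)
  expect_error(summarize_index(integer(0)), "empty")
  expect_error(summarize_index(c(1, 5)), "1..3")
})

test_that("tukey box summaries place quartiles, whiskers and outliers", {
  s <- tukey_box_summary(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$whisker_high, 9)
  expect_length(s$outliers, 0)

  cs <- tukey_box_summary(rep(4.2, 6))
  expect_equal(unique(c(cs$median, cs$q1, cs$q3, cs$whisker_low,
                        cs$whisker_high)), 4.2)

  out <- tukey_box_summary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  # whiskers stay within 1.5 IQR of the quartiles
  iqr <- out$q3 - out$q1
  expect_lte(out$whisker_high, out$q3 + 1.5 * iqr)
  expect_gte(out$whisker_low, out$q1 - 1.5 * iqr)
})

test_that("tests are invariant to within-group ordering", {
  set.seed(31)
  a <- rnorm(8); b <- rnorm(8) + 1
  p1 <- t_test_unpaired(a, b)$p_value
  p2 <- t_test_unpaired(sample(a), sample(b))$p_value
  expect_equal(p1, p2)
  expect_equal(mann_whitney(a, b)$p_value,
               mann_whitney(sample(a), sample(b))$p_value)
  expect_equal(kruskal_dunn(list(a, b, a + b))$statistic,
               kruskal_dunn(list(sample(a), sample(b), sample(a + b)))$statistic)
})

test_that("condition comparison assembles the group report", {
  # identical condition tables: zero reductions, nothing significant
  tab <- data.frame(condition = rep(c("control", "treated"), each = 6),
                    total_length_um = rep(c(100, 110, 90, 105, 95, 100), 2))
  rep0 <- compare_conditions(tab, control = "control")
  expect_equal(unname(rep0$metrics$total_length_um$percent_reduction), 0)
  expect_gt(rep0$metrics$total_length_um$test$p_value, 0.9)

  # reported means 23,000 vs 7200 -> 69% reduction
  tab2 <- data.frame(condition = rep(c("control", "IM"), each = 4),
                     total_length_um = c(20000, 26000, 24000, 22000,
                                         7000, 7600, 7200, 7000))
  stopifnot(mean(tab2$total_length_um[tab2$condition == "control"]) == 23000,
            mean(tab2$total_length_um[tab2$condition == "IM"]) == 7200)
  rep2 <- compare_conditions(tab2, control = "control")
  expect_equal(unname(rep2$metrics$total_length_um$percent_reduction["IM"]), 69)

  expect_error(compare_conditions(tab[, "total_length_um", drop = FALSE]),
               "condition")
})

test_that("a three-condition study flags severe damage against control", {
  # generator-level study: measured-by-construction lengths under pruning
  lengths <- function(pf, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(volume_um = c(90, 90, 50), n_neurons = 3,
                        neurites_per_soma = 3, neurite_length_um = 40,
                        connect = FALSE, psf_sigma_um = c(0, 0, 0),
                        noise_gaussian_sd = 0, noise_poisson_scale = 0,
                        seed = s)
      tr <- generate_network(cfg)
      if (pf > 0)
        tr <- apply_damage(tr, damage_params(prune_fraction = pf),
                           seed = s + 500)
      total_length(tr$graph)
    }, numeric(1))
  }
  tab <- rbind(
    data.frame(condition = "control", total_length_um = lengths(0, 1:10)),
    data.frame(condition = "mild", total_length_um = lengths(0.3, 11:20)),
    data.frame(condition = "severe", total_length_um = lengths(0.85, 21:30)))
  rep3 <- compare_conditions(tab, control = "control")
  pw <- rep3$metrics$total_length_um$test$pairwise
  sev <- pw[(pw$group1 == "control" & pw$group2 == "severe") |
              (pw$group1 == "severe" & pw$group2 == "control"), ]
  expect_lt(sev$p_adjusted, 0.05)
  expect_gte(unname(rep3$metrics$total_length_um$percent_reduction["severe"]),
             80)
})
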