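# Longitudinal pairing, tercile stratification, and the nonparametric tests,
# checked against enumeration oracles at small n.

test_that("annualized rates are plain differences per year", {
  expect_equal(annualized_rate(2.1, 1.9, 0.5), -0.4)
  expect_equal(annualized_rate(4.3, 4.4, 0.5), 0.2)
  expect_error(annualized_rate(1, 2, 0), class = "invalid_interval")
  expect_error(annualized_rate(1, 2, -1), class = "invalid_interval")
})

test_that("tercile assignment uses closed-interval cutoffs and partitions", {
  expect_equal(as.character(assign_tercile(0.020)), "low")
  expect_equal(as.character(assign_tercile(0.030)), "intermediate")
  expect_equal(as.character(assign_tercile(0.0251)), "intermediate")
  expect_equal(as.character(assign_tercile(0.038)), "intermediate")
  expect_equal(as.character(assign_tercile(0.0381)), "high")
  v <- runif(200, 0, 0.08)
  lab <- assign_tercile(v)
  expect_false(anyNA(lab))                        # exhaustive
  expect_equal(nlevels(lab), 3L)                  # mutually exclusive levels
  expect_error(assign_tercile(-0.01), class = "domain_error")
  expect_error(tercile_config(0.04, 0.02), class = "invalid_config")
})

test_that("frequency cells round half away from zero to one decimal", {
  expect_equal(summarize_binary(26, 31), "26 (83.9)")
  expect_equal(summarize_binary(6, 21), "6 (28.6)")
  expect_equal(summarize_binary(0, 5), "0 (0.0)")
  expect_equal(summarize_binary(1, 8), "1 (12.5)")   # .5 rounds away from zero
  expect_error(summarize_binary(1, 0), class = "undefined_denominator")
  expect_error(summarize_binary(5, 3), class = "invalid_input")
})

test_that("continuous cells report median [Q1, Q3] with type-7 quartiles", {
  expect_equal(summarize_continuous(1:5, 0), "3 [2, 4]")
  expect_equal(summarize_continuous(7, 0), "7 [7, 7]")
  set.seed(2)
  x <- rnorm(37)
  got <- summarize_continuous(x, 3)
  s <- sort(x)   # sort-midpoint oracle for the median at odd n
  expect_match(got, sprintf("^%.3f ", s[19]))
  expect_error(summarize_continuous(numeric(0)), class = "invalid_input")
})

test_that("Kruskal-Wallis matches the permutation oracle and handles nulls", {
  same <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  kw <- kruskal_wallis_dunn(same)
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_null(kw$pairwise)

  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis_dunn(groups)
  # full enumeration of the 90 equal-size partitions of ranks 1..6
  Hstat <- function(g1, g2, g3) {
    rk <- rank(c(g1, g2, g3))
    n <- 6; H <- 12 / (n * (n + 1)) *
      (sum(rk[1:2])^2 / 2 + sum(rk[3:4])^2 / 2 + sum(rk[5:6])^2 / 2) -
      3 * (n + 1)
    H
  }
  x <- 1:6
  Hs <- c()
  for (i1 in utils::combn(6, 2, simplify = FALSE)) {
    rest <- setdiff(x, i1)
    for (i2 in utils::combn(rest, 2, simplify = FALSE)) {
      i3 <- setdiff(rest, i2)
      Hs <- c(Hs, Hstat(x[i1], x[i2], i3))
    }
  }
  p_perm <- mean(Hs >= kw$H - 1e-12)
  expect_equal(kw$p, p_perm, tolerance = 0.02)

  # significant case produces a Dunn table with Holm column
  g <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6), c = c(10, 11, 12, 13, 14))
  kw2 <- kruskal_wallis_dunn(g)
  expect_lt(kw2$p, 0.05)
  expect_s3_class(kw2$pairwise, "data.frame")
  expect_equal(nrow(kw2$pairwise), 3)
  expect_true(all(kw2$pairwise$p_holm >= kw2$pairwise$p_unadjusted - 1e-12))
  # Dunn z for the most separated pair is the largest in magnitude
  ab_c <- kw2$pairwise[kw2$pairwise$group1 == "a" & kw2$pairwise$group2 == "c", ]
  expect_equal(max(abs(kw2$pairwise$z)), abs(ab_c$z))
  expect_error(kruskal_wallis_dunn(list(c(1, 2), numeric(0))),
               class = "invalid_input")
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney chi-square form", {
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(4.4, 6.1, 7.0)
  kw <- kruskal_wallis_dunn(list(x, y))
  # z^2 of the normal-approximate MW statistic equals H for two groups
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  U <- unname(wt$statistic)
  mu <- length(x) * length(y) / 2
  sg <- sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)
  expect_equal(kw$H, ((U - mu) / sg)^2, tolerance = 1e-10)
})

test_that("Mann-Whitney is exact at small n and symmetric", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$U), 0)
  expect_equal(res$p, 0.1)   # 2 / choose(6, 3) = 2/20
  # enumeration oracle: all C(6,3) label assignments
  vals <- 1:6
  Us <- apply(utils::combn(6, 3), 2, function(ix) {
    x <- vals[ix]; y <- vals[-ix]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  p_oracle <- mean(abs(Us - 4.5) >= abs(0 - 4.5))
  expect_equal(res$p, p_oracle, tolerance = 1e-12)
  x <- c(2.3, 5.1, 0.4, 8.8)
  expect_equal(mann_whitney(x, x)$p, 1, tolerance = 1e-9)
  y <- c(1.1, 4.0, 6.2)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  expect_error(mann_whitney(numeric(0), 1:3), class = "invalid_input")
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(1, 20), c(0, 10))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5))), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(3, 7), c(3, 7))), 1)
  # enumeration oracle on a 2x2 with margins (7,5) x (6,6)
  tab <- rbind(c(5, 2), c(1, 4))
  a_all <- max(0, 6 - 5):min(7, 6)
  pr <- stats::dhyper(a_all, 7, 5, 6)
  p_oracle <- sum(pr[pr <= stats::dhyper(5, 7, 5, 6) * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(tab), p_oracle, tolerance = 1e-9)
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))),
               class = "invalid_input")
})

test_that("Spearman correlation uses mid-ranks and a t-approximate p", {
  expect_equal(spearman_rank(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rank(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 9, 7, 8)
  # brute-force mid-rank Pearson
  oracle <- stats::cor(rank(x), rank(y))
  got <- spearman_rank(x, y)
  expect_equal(got$rho, oracle)
  expect_true(got$p > 0 && got$p < 1)
  expect_error(spearman_rank(rep(1, 5), 1:5), class = "undefined_correlation")
  expect_error(spearman_rank(1:2, 1:2), class = "invalid_input")
})

test_that("Shapiro-Wilk gate flags heavy tails and passes normal quantiles", {
  set.seed(31)
  heavy <- c(rnorm(180), rnorm(20, sd = 8))
  expect_false(shapiro_wilk_gate(heavy)$normal)
  expect_true(shapiro_wilk_gate(stats::qnorm(stats::ppoints(20)))$normal)
  const <- shapiro_wilk_gate(rep(2, 10))
  expect_false(const$normal)
  expect_equal(const$p, 0)
  expect_error(shapiro_wilk_gate(c(1, 2)), class = "invalid_input")
})

test_that("visit pairing derives intervals, rates, terciles, and direction", {
  visits <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4"),
    visit_date = c("2015-01-01", "2015-07-02",   # 182 days
                   "2015-03-01", "2016-02-29",
                   "2015-05-01", "2015-11-01",
                   "2015-06-01"),
    diameter_cm = c(4.3, 4.4, 5.0, 5.4, 3.8, 3.8, 4.0),
    eps_pp = c(2.1, 1.9, 4.1, 2.6, 1.0, 1.3, 2.2),
    rupture = c(0, 0, 1, 1, 0, 0, 0)
  )
  paired <- pair_visits(visits)
  expect_equal(nrow(paired), 3)                   # p4 has no follow-up
  p1 <- paired[paired$patient_id == "p1", ]
  expect_equal(p1$interval_years, 182 / 365.25)
  expect_equal(p1$net_strain_change, -0.2)
  expect_equal(p1$strain_rate, -0.2 / (182 / 365.25))
  expect_equal(p1$growth_rate, 0.1 / (182 / 365.25), tolerance = 1e-9)
  expect_equal(as.character(p1$tercile), "low")    # 0.021 < 0.0251
  expect_equal(as.character(p1$direction), "decrease")
  p2 <- paired[paired$patient_id == "p2", ]
  expect_equal(as.character(p2$tercile), "high")   # 0.041 > 0.038
  p3 <- paired[paired$patient_id == "p3", ]
  expect_equal(as.character(p3$direction), "increase")
  expect_true("rupture" %in% names(paired))
  # zero net change counts as decrease by convention
  z <- pair_visits(data.frame(patient_id = "q", visit_date = c("2015-01-01", "2016-01-01"),
                              diameter_cm = c(4, 4.2), eps_pp = c(2, 2)))
  expect_equal(as.character(z$direction), "decrease")
})

test_that("the cohort report runs the tercile and direction analyses", {
  set.seed(5)
  n <- 30
  idx_strain <- c(runif(18, 0.5, 2.4), runif(6, 2.6, 3.7), runif(6, 4.0, 7.0))
  rate <- c(runif(18, -1.6, 0.9), runif(6, -1.0, -0.4), runif(6, -5.3, -4.2))
  iv <- runif(n, 0.4, 0.8)
  visits <- rbind(
    data.frame(patient_id = sprintf("p%02d", 1:n), visit_date = "2015-01-01",
               diameter_cm = runif(n, 3.5, 5.5), eps_pp = idx_strain,
               rupture = rbinom(n, 1, 0.05)),
    data.frame(patient_id = sprintf("p%02d", 1:n),
               visit_date = as.character(as.Date("2015-01-01") + round(iv * 365.25)),
               diameter_cm = runif(n, 3.6, 5.6), eps_pp = idx_strain + rate * iv,
               rupture = 0)
  )
  paired <- pair_visits(visits)
  expect_equal(sum(paired$tercile == "low"), 18)
  rep <- cohort_report(paired)
  expect_equal(sum(rep$tercile_n), 30)
  expect_lt(rep$tercile_tests$strain_rate$p, 0.05)
  expect_s3_class(rep$tercile_tests$strain_rate$pairwise, "data.frame")
  expect_true(abs(rep$spearman_rate_vs_index$rho) <= 1)
  expect_lt(rep$spearman_rate_vs_index$rho, 0)    # high index strain falls fastest
  expect_true(is.numeric(rep$direction_tests$growth_rate$p))
  expect_true(all(c("increase", "decrease") %in% names(rep$direction_summaries)))
})

test_that("direction-stratified outcome tables use the printed cell formats", {
  paired <- data.frame(
    direction = factor(rep(c("decrease", "increase"), c(21, 10)),
                       levels = c("increase", "decrease")),
    growth_rate = c(rep(0.21, 21), rep(0.17, 10)),
    rupture = c(1, rep(0, 20), rep(0, 10))
  )
  md <- direction_outcomes_markdown(paired, binary = c(Rupture = "rupture"))
  expect_match(md[1], "Decrease \\(n = 21\\)")
  expect_match(md[1], "Increase \\(n = 10\\)")
  rupture_row <- md[grepl("Rupture", md)]
  expect_match(rupture_row, "1 \\(4.8\\)", fixed = FALSE)
  expect_match(rupture_row, "0 \\(0.0\\)", fixed = FALSE)
  expect_match(rupture_row, "\\| 1 \\|$")   # Fisher p = 1
})
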