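test_that("the exact U null matches enumeration, sums to 1 and is symmetric", {
  expect_equal(unname(exact_u_distribution(1, 1)), c(0.5, 0.5))
  pmf55 <- exact_u_distribution(5, 5)
  u <- as.integer(names(pmf55))
  expect_equal(sum(pmf55) * choose(10, 5), 252)      # total arrangements
  expect_equal(sum(pmf55[u >= 21]), 12 / 252)
  for (nn in list(c(2, 3), c(4, 4), c(3, 6))) {
    pmf <- exact_u_distribution(nn[1], nn[2])
    expect_equal(sum(pmf), 1)
    expect_equal(unname(pmf), rev(unname(pmf)))      # reflection symmetry
    expect_equal(unname(pmf), u_pmf_enumerated(nn[1], nn[2]))
  }
  expect_error(exact_u_distribution(25, 25), "cap")
})

test_that("the exact Mann-Whitney test agrees with wilcox.test on tie-free data", {
  s <- samples_with_u(21, 5, 5)
  r <- mann_whitney_exact(s$x, s$y)
  expect_equal(r$statistic, 21)
  expect_true(r$exact)
  expect_false(r$tie_corrected)
  set.seed(7)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1000, n1); y <- sample(2000:5000, n2) / 2.7
    ours <- mann_whitney_exact(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value)
  }
  # degenerate 1 + 1 case exhausts both tails
  r11 <- mann_whitney_exact(1, 2)
  expect_equal(r11$statistic, 0)
  expect_equal(r11$p_value, 1)
})

test_that("tied samples get an exact permutation p over the observed values", {
  x <- c(1, 2, 2, 5)
  y <- c(2, 3, 5, 7)
  r <- mann_whitney_exact(x, y)
  expect_true(r$tie_corrected)
  expect_true(r$exact)
  # independent oracle: literal enumeration of all C(8,4) relabelings
  pooled <- c(x, y)
  rk <- rank(pooled)
  combos <- utils::combn(8, 4)
  u_all <- apply(combos, 2, function(ix) sum(rk[ix]) - 4 * 5 / 2)
  W <- sum(rk[1:4]) - 4 * 5 / 2
  p_oracle <- min(1, 2 * min(mean(u_all <= W + 1e-9), mean(u_all >= W - 1e-9)))
  expect_equal(r$p_value, p_oracle)
  # huge tied designs fall back to flagged Monte-Carlo
  big <- mann_whitney_exact(rep(1:15, 2), rep(2:16, 2), perm_cap = 1e3,
                            mc_perms = 2e3)
  expect_false(big$exact)
})

test_that("Kruskal-Wallis is tie-corrected, rank-invariant and formula-exact", {
  # exchangeable groups give H = 0
  r0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$statistic, 0)
  # all-identical values are a defined degenerate case
  rc <- kruskal_wallis(rep(4, 9), rep(letters[1:3], 3))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)
  set.seed(11)
  vals <- c(rnorm(8), rnorm(6, 1), rnorm(7, 2), round(rnorm(5)))
  grp <- rep(c("a", "b", "c", "d"), c(8, 6, 7, 5))
  r <- kruskal_wallis(vals, grp)
  expect_equal(r$df, 3)
  # invariance under a strictly monotone transform
  expect_equal(kruskal_wallis(exp(vals / 4), grp)$statistic, r$statistic)
  # literal midrank formula with tie-correction divisor
  N <- length(vals)
  rk <- rank(vals)
  Rg <- tapply(rk, grp, sum); ng <- tapply(rk, grp, length)
  h_raw <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  tie <- table(vals)
  h_corr <- h_raw / (1 - sum(tie^3 - tie) / (N^3 - N))
  expect_equal(r$statistic, h_corr)
  expect_equal(r$p_value, stats::pchisq(h_corr, 3, lower.tail = FALSE))
})

test_that("Dunn's comparisons are symmetric, null-calibrated and well-powered", {
  d0 <- dunn_posthoc(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(d0$comparisons$z == 0))
  expect_true(all(d0$comparisons$p_value == 1))
  expect_equal(unname(d0$letters), rep("a", 3))
  # pair significance does not depend on group order
  set.seed(3)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), 10)
  d1 <- dunn_posthoc(v, g)
  d2 <- dunn_posthoc(v, factor(g, levels = c("c", "b", "a")))
  key <- function(d) {
    cc <- d$comparisons
    stats::setNames(cc$significant,
                    paste(pmin(cc$group1, cc$group2), pmax(cc$group1, cc$group2)))
  }
  expect_equal(key(d1), key(d2)[names(key(d1))])
  expect_equal(abs(d1$comparisons$z), abs(d2$comparisons$z)[c(3, 2, 1)])
  # two well-separated pairs: exactly the four cross-pair flags (Holm, alpha 0.05)
  set.seed(29)
  hits <- 0L
  for (i in 1:200) {
    vals <- c(rnorm(10), rnorm(10), rnorm(10, 10), rnorm(10, 10))
    grp <- rep(c("A", "B", "C", "D"), each = 10)
    dd <- dunn_posthoc(vals, grp, adjust = "holm")
    cc <- dd$comparisons
    cross <- (cc$group1 %in% c("A", "B")) != (cc$group2 %in% c("A", "B"))
    if (all(cc$significant == cross)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("compact letter display realises the published letter patterns", {
  # no significant pair: everyone shares one letter
  comp <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                     significant = FALSE)
  expect_equal(unname(compact_letter_display(comp, c("A", "B", "C"))),
               c("a", "a", "a"))
  # all pairs significant: distinct letters in group order
  comp$significant <- TRUE
  expect_equal(unname(compact_letter_display(comp, c("A", "B", "C"))),
               c("a", "b", "c"))
  # four groups, only the extreme pair differs: a / ab / ab / b
  comp4 <- data.frame(group1 = c("A", "A", "A", "B", "B", "C"),
                      group2 = c("B", "C", "D", "C", "D", "D"),
                      significant = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(compact_letter_display(comp4, c("A", "B", "C", "D"))),
               c("a", "ab", "ab", "b"))
  expect_error(compact_letter_display(comp4[-2, ], c("A", "B", "C", "D")),
               "incomplete")
})

test_that("Bonferroni and Holm adjustments follow the step-down arithmetic", {
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "bonferroni"),
               c(0.03, 0.12, 0.09))
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:8, 1))
    h <- adjust_pvalues(p, "holm")
    expect_true(all(h >= p))                       # never smaller than raw
    expect_true(all(diff(h[order(p)]) >= -1e-12))  # monotone in sorted order
    expect_true(all(h <= 1))
  }
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")
})

test_that("chi-square contingency tests use Pearson's statistic without correction", {
  prop <- matrix(c(10, 20, 30, 60), 2)      # proportional rows
  expect_equal(chisq_contingency(prop)$statistic, 0)
  r <- chisq_contingency(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  expect_equal(r$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
  # a 2 x 6 design (six mating classes, two outcomes) has df = 5
  set.seed(2)
  tab26 <- matrix(rpois(12, 30) + 1, 2, 6)
  expect_equal(chisq_contingency(tab26)$df, 5)
  expect_error(chisq_contingency(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margins")
  expect_error(chisq_contingency(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})
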