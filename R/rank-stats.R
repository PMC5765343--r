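#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Probability mass of U over `0..n1*n2` under the null of no ties, computed
#' by the standard count recursion (subset rank-sum dynamic programme). The
#' pmf sums to 1 and is symmetric about `n1*n2 / 2`.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @param cap Largest allowed `n1 * n2`; beyond it the asymptotic normal
#'   approximation should be used instead.
#' @return A numeric vector of probabilities named `"0"..as.character(n1*n2)`.
#' @examples
#' pmf <- exact_u_distribution(5, 5)
#' 2 * sum(pmf[as.integer(names(pmf)) >= 21])  # two-sided p at U = 21
#' @export
exact_u_distribution <- function(n1, n2, cap = 400) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 1L || n2 < 1L)
    stop("n1 and n2 must be positive integers")
  if (n1 * n2 > cap)
    stop("n1 * n2 = ", n1 * n2, " exceeds the exact cap (", cap,
         "); use the asymptotic approximation")
  N <- n1 + n2
  smax <- n1 * N
  # dp[k + 1, s + 1]: number of size-k subsets of {1..el} with rank sum s
  dp <- matrix(0, n1 + 1L, smax + 1L)
  dp[1L, 1L] <- 1
  for (el in seq_len(N)) {
    for (k in min(el, n1):1L) {
      idx <- (el + 1L):(smax + 1L)
      dp[k + 1L, idx] <- dp[k + 1L, idx] + dp[k, idx - el]
    }
  }
  counts <- dp[n1 + 1L, ]
  smin <- n1 * (n1 + 1L) / 2                       # minimal rank sum
  u_counts <- counts[(smin + 1L):(smin + n1 * n2 + 1L)]
  pmf <- u_counts / choose(N, n1)
  names(pmf) <- 0:(n1 * n2)
  pmf
}

# two-sided p as twice the smaller tail, capped at 1
.two_sided_from_tails <- function(p_le, p_ge) min(1, 2 * min(p_le, p_ge))

#' Exact Wilcoxon-Mann-Whitney test
#'
#' Reports the first-group U statistic `W` (rank sum of `x` using midranks,
#' minus `n1 (n1 + 1) / 2`) and a two-sided p-value equal to twice the
#' smaller tail probability, capped at 1. Without ties the null distribution
#' comes from [exact_u_distribution()]; with ties the exact p is obtained by
#' complete enumeration over all `choose(N, n1)` relabelings of the pooled
#' values when that count is at most `perm_cap`, otherwise by seeded
#' Monte-Carlo permutation (flagged non-exact).
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_cap Passed to [exact_u_distribution()].
#' @param perm_cap Largest enumeration size for the tied exact path.
#' @param mc_perms Monte-Carlo permutation count for the fallback.
#' @param mc_seed Seed for the Monte-Carlo fallback.
#' @return An object of class `rank_test` with fields `statistic_name`
#'   (`"W"`), `statistic`, `p_value`, `exact`, `tie_corrected`, `n1`, `n2`,
#'   `method`.
#' @examples
#' mann_whitney_exact(c(8, 9, 11, 14, 20), c(1, 2, 3, 4, 10))
#' @export
mann_whitney_exact <- function(x, y, exact_cap = 400, perm_cap = 2e6,
                               mc_perms = 1e5, mc_seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  eps <- 1e-9
  if (!ties && n1 * n2 <= exact_cap) {
    pmf <- exact_u_distribution(n1, n2, cap = exact_cap)
    u <- as.integer(names(pmf))
    p <- .two_sided_from_tails(sum(pmf[u <= W + eps]), sum(pmf[u >= W - eps]))
    exact <- TRUE
    method <- "exact (no ties, count recursion)"
  } else if (choose(N, n1) <= perm_cap) {
    idx <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- .two_sided_from_tails(mean(u_all <= W + eps), mean(u_all >= W - eps))
    exact <- TRUE
    method <- "exact (complete enumeration over relabelings)"
  } else {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(mc_seed)
    u_mc <- replicate(mc_perms, {
      rr <- sample(r)
      sum(rr[seq_len(n1)]) - n1 * (n1 + 1) / 2
    })
    p <- .two_sided_from_tails(mean(u_mc <= W + eps), mean(u_mc >= W - eps))
    exact <- FALSE
    method <- sprintf("Monte-Carlo permutation (%d draws)", as.integer(mc_perms))
  }
  structure(list(statistic_name = "W", statistic = W, df = NA_real_,
                 p_value = p, exact = exact, tie_corrected = ties,
                 n1 = n1, n2 = n2, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s = %g", x$statistic_name, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", p = %.5g%s\n", x$p_value, if (isTRUE(x$exact)) " (exact)" else ""))
  if (!is.null(x$method)) cat("method:", x$method, "\n")
  invisible(x)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Midrank-based H with the tie-correction divisor
#' `1 - sum(t^3 - t) / (N^3 - N)`; `df = k - 1`, p from the chi-square upper
#' tail (via [stats::kruskal.test()]). A degenerate input in which every
#' value is identical returns `H = 0, p = 1`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values` (>= 2 non-empty
#'   groups, total N >= 3).
#' @return A `rank_test` with `statistic_name = "H"`.
#' @export
kruskal_wallis <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(values) != length(groups)) stop("values and groups differ in length")
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (length(values) < 3L) stop("total N must be >= 3")
  k <- nlevels(groups)
  ties <- anyDuplicated(values) > 0
  if (length(unique(values)) == 1L) {
    h <- 0; p <- 1
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic); p <- kt$p.value
  }
  structure(list(statistic_name = "H", statistic = h, df = k - 1,
                 p_value = p, exact = FALSE, tie_corrected = ties,
                 method = "Kruskal-Wallis rank sum test (chi-square approximation)"),
            class = "rank_test")
}

#' Dunn's post hoc pairwise comparisons after Kruskal-Wallis
#'
#' For every group pair the z statistic is the difference in mean midranks
#' divided by
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_a + 1/n_b))`,
#' with a two-sided normal p-value, optional multiplicity adjustment, and a
#' compact letter display in which groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the letter display.
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return An object of class `pairwise_comparisons`: a list with
#'   `comparisons` (data frame: `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`, `significant`), `letters` (named character), `alpha`,
#'   `adjust`.
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05,
                         adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  values <- as.numeric(values)
  groups <- droplevels(factor(groups))
  if (length(values) != length(groups)) stop("values and groups differ in length")
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")
  N <- length(values)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  tie_tab <- table(values)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  lev <- levels(groups)
  pr <- utils::combn(length(lev), 2)
  z <- p_raw <- numeric(ncol(pr))
  for (j in seq_len(ncol(pr))) {
    a <- pr[1, j]; b <- pr[2, j]
    se <- sqrt(var_term * (1 / n_g[a] + 1 / n_g[b]))
    z[j] <- if (se > 0) (mean_rank[a] - mean_rank[b]) / se else 0
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- if (adjust == "none") p_raw else adjust_pvalues(p_raw, adjust)
  comp <- data.frame(group1 = lev[pr[1, ]], group2 = lev[pr[2, ]],
                     z = z, p_value = p_raw, p_adjusted = p_adj,
                     significant = p_adj < alpha,
                     stringsAsFactors = FALSE)
  out <- structure(list(comparisons = comp, letters = NULL,
                        alpha = alpha, adjust = adjust, groups = lev),
                   class = "pairwise_comparisons")
  out$letters <- compact_letter_display(out)
  out
}

#' @export
print.pairwise_comparisons <- function(x, digits = 4, ...) {
  cat(sprintf("Dunn's pairwise comparisons (alpha = %g, adjust = %s)\n",
              x$alpha, x$adjust))
  print(x$comparisons, digits = digits, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = ": ",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb assignment: starting from one letter covering all
#' groups, every significant pair splits each letter containing both; letter
#' groups that become subsets of others are absorbed. Two groups share a
#' letter if and only if their comparison is non-significant; letters are
#' assigned `a, b, c, ...` in group order.
#'
#' @param comparisons A [dunn_posthoc()] result, or a data frame with
#'   columns `group1`, `group2`, `significant`.
#' @param groups Optional character vector fixing the group order (required
#'   when `comparisons` is a bare data frame and the order matters).
#' @return A named character vector of letter strings, one per group.
#' @export
compact_letter_display <- function(comparisons, groups = NULL) {
  if (inherits(comparisons, "pairwise_comparisons")) {
    groups <- comparisons$groups
    comp <- comparisons$comparisons
  } else comp <- as.data.frame(comparisons)
  if (is.null(groups))
    groups <- unique(c(comp$group1, comp$group2))
  k <- length(groups)
  need <- utils::combn(k, 2)
  have <- paste(comp$group1, comp$group2)
  for (j in seq_len(ncol(need))) {
    g1 <- groups[need[1, j]]; g2 <- groups[need[2, j]]
    if (!(paste(g1, g2) %in% have || paste(g2, g1) %in% have))
      stop("comparisons are incomplete: missing pair ", g1, " vs ", g2)
  }
  cols <- list(rep(TRUE, k))
  sig <- comp[comp$significant, , drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    i1 <- match(sig$group1[j], groups); i2 <- match(sig$group2[j], groups)
    new_cols <- list()
    for (cc in cols) {
      if (cc[i1] && cc[i2]) {
        c1 <- cc; c1[i1] <- FALSE
        c2 <- cc; c2[i2] <- FALSE
        new_cols <- c(new_cols, list(c1, c2))
      } else new_cols <- c(new_cols, list(cc))
    }
    # absorb: drop duplicates and strict subsets
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) for (b in seq_along(new_cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_cols[[a]] | !new_cols[[b]]) ) {
        # b is a subset of a
        if (all(new_cols[[a]] == new_cols[[b]]) && a < b) keep[b] <- FALSE
        else if (!all(new_cols[[a]] == new_cols[[b]])) keep[b] <- FALSE
      }
    }
    cols <- new_cols[keep]
  }
  ord <- order(vapply(cols, function(cc) which(cc)[1], numeric(1)))
  cols <- cols[ord]
  lets <- vapply(seq_len(k), function(i)
    paste0(letters[which(vapply(cols, function(cc) cc[i], logical(1)))],
           collapse = ""), character(1))
  names(lets) <- groups
  lets
}

#' Multiple-testing adjustment of p-values
#'
#' `"bonferroni"` multiplies by the family size and caps at 1;
#' `"holm"` is the sequential (step-down) Bonferroni with monotonicity
#' enforcement. Input order is preserved.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Pearson chi-square test for a contingency table
#'
#' No continuity correction; `df = (r - 1)(c - 1)`, p from the chi-square
#' upper tail (via [stats::chisq.test()]).
#'
#' @param table A matrix (or table) of non-negative integer counts with no
#'   all-zero row or column.
#' @return A `rank_test` with `statistic_name = "chisq"`.
#' @export
chisq_contingency <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: all-zero row or column")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic_name = "chisq", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 exact = FALSE, tie_corrected = FALSE,
                 method = "Pearson chi-square test (no continuity correction)"),
            class = "rank_test")
}
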