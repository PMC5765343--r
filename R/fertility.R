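#' Round half up
#'
#' Decimal rounding with ties away from zero (the convention used for the
#' displayed percentages), unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Format a percentage for display
#'
#' Round-half-up to `digits` decimals with trailing zeros trimmed, so 88.0
#' prints as `"88"` and 37.06 as `"37.1"`.
#'
#' @param x Percentage value(s).
#' @param digits Decimal places (default 1).
#' @return Character vector.
#' @export
format_percent <- function(x, digits = 1) {
  out <- formatC(round_half_up(x, digits), format = "f", digits = digits)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' Percentage decrease between two mean counts
#'
#' `100 * (1 - mean_late / mean_early)`: the share of the early count no
#' longer present at the later timepoint (e.g. stored sperm used between 1 h
#' and 24 h after copulation). Full precision is returned; use
#' [format_percent()] for the one-decimal display convention.
#'
#' @param mean_early Baseline mean (> 0).
#' @param mean_late Later mean (>= 0).
#' @return Percentage decrease (full precision).
#' @seealso [percent_retained()]
#' @examples
#' percent_decrease(437.1, 275.1)  # 37.06...
#' @export
percent_decrease <- function(mean_early, mean_late) {
  if (any(mean_early <= 0)) stop("mean_early must be positive (undefined baseline)")
  if (any(mean_late < 0)) stop("mean_late must be non-negative")
  100 * (1 - mean_late / mean_early)
}

#' @rdname percent_decrease
#' @export
percent_retained <- function(mean_early, mean_late) {
  if (any(mean_early <= 0)) stop("mean_early must be positive (undefined baseline)")
  if (any(mean_late < 0)) stop("mean_late must be non-negative")
  100 * mean_late / mean_early
}

#' Binomial proportion with a confidence interval
#'
#' Point estimate `100 * successes / total` with a Wilson score interval
#' (default) or Clopper-Pearson exact interval, both on the percentage
#' scale.
#'
#' @param successes,total Non-negative integer counts, `successes <= total`,
#'   `total >= 1`.
#' @param ci_level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return An object of class `proportion_result` with fields `successes`,
#'   `total`, `percentage`, `ci_lower`, `ci_upper`, `ci_level`, `method`.
#' @examples
#' proportion(64, 358)   # 17.9% of eggs fertilised
#' @export
proportion <- function(successes, total, ci_level = 0.95,
                       method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  successes <- as.integer(successes); total <- as.integer(total)
  if (is.na(successes) || is.na(total) || total < 1L ||
      successes < 0L || successes > total)
    stop("need 0 <= successes <= total with total >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must lie in (0, 1)")
  phat <- successes / total
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    den <- 1 + z^2 / total
    centre <- (phat + z^2 / (2 * total)) / den
    half <- z * sqrt(phat * (1 - phat) / total + z^2 / (4 * total^2)) / den
    lo <- max(0, centre - half); hi <- min(1, centre + half)
  } else {
    ci <- stats::binom.test(successes, total, conf.level = ci_level)$conf.int
    lo <- ci[1]; hi <- ci[2]
  }
  structure(list(successes = successes, total = total,
                 percentage = 100 * phat,
                 ci_lower = 100 * lo, ci_upper = 100 * hi,
                 ci_level = ci_level, method = method),
            class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(sprintf("%s%% (%d/%d), %g%% CI [%s, %s] (%s)\n",
              format_percent(x$percentage), x$successes, x$total,
              100 * x$ci_level, format_percent(x$ci_lower),
              format_percent(x$ci_upper), x$method))
  invisible(x)
}

#' Sperm-storage summary table with retention arithmetic
#'
#' Builds a wide genotype-by-timepoint table of `mean +- SE (N)` cells per
#' organ from per-record summaries, and appends the percentage decrease
#' between the first and second timepoint for every genotype-organ pair
#' observed at exactly two timepoints. The result is a pure function of the
#' record set: input order is irrelevant (genotypes, organs and timepoints
#' are ordered by factor level, or lexicographically for plain characters),
#' and duplicated `(genotype, organ, timepoint)` records are an error.
#'
#' @param records A data frame with columns `genotype`, `organ`,
#'   `timepoint`, `mean`, `se`, `n`.
#' @return An object of class `storage_table`: a list with `cells` (wide
#'   data frame of formatted cells), `summaries` (the sorted input) and
#'   `decreases` (data frame: `genotype`, `organ`, `timepoint_early`,
#'   `timepoint_late`, `mean_early`, `mean_late`, `pct_decrease`).
#' @export
storage_table <- function(records) {
  req <- c("genotype", "organ", "timepoint", "mean", "se", "n")
  if (!all(req %in% names(records)))
    stop("records must have columns ", paste(req, collapse = ", "))
  rec <- as.data.frame(records)[req]
  if (any(rec$mean < 0) || any(rec$se < 0) || any(rec$n < 1))
    stop("means and SEs must be non-negative and n >= 1")
  key <- interaction(rec$genotype, rec$organ, rec$timepoint, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (genotype, organ, timepoint) record: ",
         as.character(key[duplicated(key)][1]))
  fac <- function(x) if (is.factor(x)) x else factor(x, levels = sort(unique(as.character(x))))
  rec$genotype <- fac(rec$genotype)
  rec$organ <- fac(rec$organ)
  rec$timepoint <- fac(rec$timepoint)
  rec <- rec[order(rec$genotype, rec$timepoint, rec$organ), , drop = FALSE]
  rownames(rec) <- NULL

  gt <- unique(rec[c("genotype", "timepoint")])
  cells <- gt
  for (org in levels(rec$organ)) {
    col <- character(nrow(gt))
    for (i in seq_len(nrow(gt))) {
      m <- rec[rec$genotype == gt$genotype[i] & rec$timepoint == gt$timepoint[i] &
                 rec$organ == org, , drop = FALSE]
      col[i] <- if (nrow(m) == 1L)
        sprintf("%s ± %s (%d)", format_percent(m$mean), format_percent(m$se),
                as.integer(m$n)) else ""
    }
    cells[[org]] <- col
  }

  dec <- NULL
  for (g in levels(rec$genotype)) for (org in levels(rec$organ)) {
    m <- rec[rec$genotype == g & rec$organ == org, , drop = FALSE]
    if (nrow(m) == 2L) {
      dec <- rbind(dec, data.frame(
        genotype = g, organ = org,
        timepoint_early = as.character(m$timepoint[1]),
        timepoint_late = as.character(m$timepoint[2]),
        mean_early = m$mean[1], mean_late = m$mean[2],
        pct_decrease = percent_decrease(m$mean[1], m$mean[2]),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(cells = cells, summaries = rec,
                 decreases = dec %||% data.frame()),
            class = "storage_table")
}

#' @export
print.storage_table <- function(x, ...) {
  cat("Sperm storage summary (mean ± SE (N))\n")
  print(x$cells, row.names = FALSE)
  if (nrow(x$decreases)) {
    cat("\nDecrease between timepoints\n")
    d <- x$decreases
    d$pct_decrease <- format_percent(d$pct_decrease)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two groups of per-female sperm counts
#'
#' An exact Wilcoxon-Mann-Whitney test ([mann_whitney_exact()]) with a
#' Bonferroni correction over `k_tests` comparisons, reporting the
#' significance tier used in the storage figures: `"**"` below 1%, `"*"`
#' below 5% (after correction), otherwise `"NS"`.
#'
#' @param group_a,group_b Non-empty vectors of per-female counts.
#' @param k_tests Size of the comparison family for the Bonferroni
#'   correction (default 1 = no correction).
#' @param ... Passed to [mann_whitney_exact()].
#' @return A `rank_test` with extra fields `p_adjusted`, `k_tests`, `tier`.
#' @export
compare_counts <- function(group_a, group_b, k_tests = 1L, ...) {
  k_tests <- as.integer(k_tests)
  if (is.na(k_tests) || k_tests < 1L) stop("k_tests must be >= 1")
  res <- mann_whitney_exact(group_a, group_b, ...)
  res$p_adjusted <- min(1, res$p_value * k_tests)
  res$k_tests <- k_tests
  res$tier <- if (res$p_adjusted < 0.01) "**"
    else if (res$p_adjusted < 0.05) "*" else "NS"
  res
}
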