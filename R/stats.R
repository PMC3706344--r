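#' Mann-Whitney U comparison of two AUC groups
#'
#' Two-sample rank test used to compare groups of AUC(CV_T) scores. The U
#' statistic is computed from midranks. The two-tailed p-value is exact
#' whenever feasible: via the exact null distribution of U when there are no
#' ties and `n1 * n2 <= 400`, or by full enumeration of all group
#' assignments when ties are present but `choose(n1 + n2, n1)` is small
#' (<= 2e5; e.g. two groups of five, even with tied values). Otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return A `group_comparison` list: `n1`, `n2`, `U` (for `group_a`),
#'   `p_value` (two-tailed), `method`, and per-group `summary` (see
#'   [group_summary()]).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))

  u_of <- function(first_idx) {
    sum(r[first_idx]) - n1 * (n1 + 1) / 2
  }
  if (!ties && n1 * n2 <= 400) {
    # exact null distribution of U (no ties)
    p <- min(1, 2 * min(pwilcox(U, n1, n2),
                        1 - pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else if (ties && choose(n1 + n2, n1) <= 2e5) {
    # full enumeration of assignments, midranks fixed by the pooled sample
    centre <- n1 * n2 / 2
    dev_obs <- abs(U - centre)
    combos <- combn(n1 + n2, n1)
    devs <- abs(apply(combos, 2, u_of) - centre)
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact enumeration (ties)"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- if (ties) "normal approximation (tie-corrected)" else
      "normal approximation"
  }
  structure(list(n1 = n1, n2 = n2, U = U, p_value = p, method = method,
                 summary = list(a = group_summary(group_a),
                                b = group_summary(group_b))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (two-tailed, %s)\n", x$method))
  cat(sprintf("  n1 = %d, n2 = %d, U = %.1f, p = %.4g\n",
              x$n1, x$n2, x$U, x$p_value))
  for (g in c("a", "b")) {
    s <- x$summary[[g]]
    cat(sprintf("  group %s: mean %.1f, SD %.2f, 95%% CI half-width %s\n",
                g, s$mean, s$sd,
                if (is.na(s$ci_halfwidth)) "NA" else
                  sprintf("%.2f", s$ci_halfwidth)))
  }
  invisible(x)
}

#' Group mean, SD and 95% confidence interval
#'
#' Student-t confidence interval on the mean:
#' `half-width = t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param values numeric vector.
#' @return A list with `n`, `mean`, `sd` (sample SD) and `ci_halfwidth`
#'   (`NA` when `n < 2`).
#' @export
group_summary <- function(values) {
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2) sd(values) else NA_real_
  hw <- if (n >= 2) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
  list(n = n, mean = m, sd = s, ci_halfwidth = hw)
}

#' Reference human cohort AUC scores
#'
#' AUC(CV_T) values (percent) from the clinical evaluation of the method:
#' five healthy, life-long non-smoking volunteers and five patients with
#' advanced (grade 3-4) COPD, analysed with a CV threshold of 22% taken from
#' the healthy group's mean CV frequency function. Useful as fixture data
#' for the group statistics.
#'
#' @return A data frame with columns `subject`, `group` (`"healthy"` /
#'   `"copd"`) and `auc` (percent).
#' @export
reference_cohort <- function() {
  data.frame(
    subject = c(paste0("H", 1:5), paste0("P", 1:5)),
    group = rep(c("healthy", "copd"), each = 5L),
    auc = c(52, 75, 57, 72, 71, 99, 100, 100, 100, 100))
}
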