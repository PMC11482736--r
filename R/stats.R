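#' 2x2 agreement table between two binary raters
#'
#' Cell layout follows the agreement tables of the adherence analysis:
#' rows are the self-report label, columns the objective (accelerometer)
#' label; `a` counts participants both call "Adhered", `d` both call
#' "Did not adhere", `b` self-Adhered / objective-Not, `c` the reverse.
#'
#' @param a,b,c,d Non-negative integer cell counts; `a + b + c + d > 0`.
#' @return A `contingency_2x2` object.
#' @export
#' @examples
#' contingency_2x2(16, 36, 8, 24)
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty contingency table", call. = FALSE)
  structure(as.list(cells), n = sum(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(self = c("Adhered", "Did not adhere"),
                              objective = c("Adhered", "Did not adhere")))
  print(m)
  invisible(x)
}

#' Observed agreement fraction
#'
#' @param table A [contingency_2x2()].
#' @return `(a + d) / n`.
#' @export
#' @examples
#' percent_agreement(contingency_2x2(16, 36, 8, 24))  # 40/84
percent_agreement <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  (table$a + table$d) / attr(table, "n")
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with
#' observed agreement `po = (a + d) / n` and chance agreement `pe`
#' computed from the margins.  The confidence interval uses the
#' large-sample standard error of the kappa estimate
#' (Fleiss--Cohen--Everitt), and the p-value is the two-sided
#' large-sample z test of kappa = 0 using the null-hypothesis standard
#' error.
#'
#' @param table A [contingency_2x2()].
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `kappa_result` list: `kappa`, `po`, `pe`, `se`, `se0`,
#'   `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
#' @examples
#' cohens_kappa(contingency_2x2(16, 36, 8, 24))$kappa  # 4/81
cohens_kappa <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  n <- attr(table, "n")
  p <- matrix(c(table$a, table$b, table$c, table$d), 2, byrow = TRUE) / n
  row_m <- rowSums(p)
  col_m <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(row_m * col_m)
  if (pe >= 1) stop("kappa undefined: degenerate margins (pe = 1)",
                    call. = FALSE)
  kappa <- (po - pe) / (1 - pe)

  # large-sample variance of kappa-hat (Fleiss, Cohen & Everitt)
  A <- sum(diag(p) * (1 - (row_m + col_m) * (1 - kappa))^2)
  off <- !diag(TRUE, 2)
  sum_off <- 0
  for (i in 1:2) for (j in 1:2) {
    if (i != j) sum_off <- sum_off + p[i, j] * (col_m[i] + row_m[j])^2
  }
  B <- (1 - kappa)^2 * sum_off
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(A + B - C, 0) / n) / (1 - pe)

  # null-hypothesis standard error for the z test of kappa = 0
  se0 <- sqrt(max(pe + pe^2 - sum(row_m * col_m * (row_m + col_m)), 0) / n) /
    (1 - pe)
  z <- if (se0 > 0) kappa / se0 else NA_real_
  p_value <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kappa, po = po, pe = pe, se = se, se0 = se0,
                 ci_low = kappa - crit * se, ci_high = kappa + crit * se,
                 p_value = p_value, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "Cohen's kappa: %.4f (po = %.4f, pe = %.4f)\n95%% CI [%.4f, %.4f], z-test of kappa = 0: p = %.4f, n = %d\n",
    x$kappa, x$po, x$pe, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

mw_u_from_ranks <- function(ranks, idx_a, n_a) {
  sum(ranks[idx_a]) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test for two independent groups
#'
#' Computes U from rank sums with midranks for ties.  In exact mode the
#' two-sided p-value is obtained by full enumeration of all assignments
#' of the pooled values to the two group sizes: p = 2 x min(P(U <= u),
#' P(U >= u)), capped at 1 (so a tie-heavy sample is handled exactly,
#' where closed forms diverge).  In approximate mode the normal
#' approximation with tie correction and continuity correction is used.
#' `mode = "auto"` (default) enumerates when `n_a + n_b <= 12`.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `group_comparison` list: `u_statistic` (U for group A),
#'   `p_value`, `method`, `median_a`, `median_b`, `mean_rank_a`,
#'   `mean_rank_b`, `n_a`, `n_b`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), mode = "exact")$p_value  # 1/3
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  n <- n_a + n_b
  ranks <- rank(pooled)                      # midranks for ties
  u_obs <- mw_u_from_ranks(ranks, seq_len(n_a), n_a)
  exact <- switch(mode, exact = TRUE, approx = FALSE, auto = n <= 12)

  if (exact) {
    combos <- utils::combn(n, n_a)
    u_all <- apply(combos, 2, function(idx) mw_u_from_ranks(ranks, idx, n_a))
    eps <- 1e-9
    p_low <- mean(u_all <= u_obs + eps)
    p_high <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact enumeration"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity correction toward the mean
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(list(u_statistic = u_obs, p_value = p, method = method,
                 median_a = stats::median(group_a),
                 median_b = stats::median(group_b),
                 mean_rank_a = mean(ranks[seq_len(n_a)]),
                 mean_rank_b = mean(ranks[n_a + seq_len(n_b)]),
                 n_a = n_a, n_b = n_b),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %.2f (%s)\n  group A: n = %d, median = %g, mean rank = %.2f\n  group B: n = %d, median = %g, mean rank = %.2f\n  two-sided p = %.4g\n",
    x$u_statistic, x$method, x$n_a, x$median_a, x$mean_rank_a,
    x$n_b, x$median_b, x$mean_rank_b, x$p_value))
  invisible(x)
}

#' Simple rate
#'
#' @param numerator,denominator Counts; `denominator > 0`.
#' @return `numerator / denominator`.
#' @export
#' @examples
#' rate(3, 139)  # reinjury rate, about 0.0216
rate <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  numerator / denominator
}

#' Median and interquartile range
#'
#' Quartiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)` (so `1:5` gives quartiles 2 and 4).
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `median`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}
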