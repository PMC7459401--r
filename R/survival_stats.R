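#' Summarise desiccation-assay recovery rates
#'
#' Per condition: replicate recovery rates \eqn{r_i = recovered_i/total_i},
#' their mean and sample SD (denominator n - 1).
#'
#' @param assays survival tibble from [read_survival()] or
#'   [simulate_survival()] (columns `condition`, `replicate`, `recovered`,
#'   `total`).
#' @return list with `rates` (per-replicate tibble adding a `rate` column)
#'   and `summary` (per-condition tibble `condition`, `n`, `mean_rate`,
#'   `sd_rate`).
#' @examples
#' a <- tibble::tibble(condition = "vehicle", replicate = 1:3,
#'                     recovered = c(12, 13, 15), total = 15)
#' recovery_summary(a)$summary
#' @export
recovery_summary <- function(assays) {
  if (any(assays$total <= 0)) stop("survival total must be > 0", call. = FALSE)
  if (any(assays$recovered < 0 | assays$recovered > assays$total)) {
    stop("recovered count outside [0, total]", call. = FALSE)
  }
  rates <- dplyr::mutate(assays, rate = .data$recovered / .data$total)
  summary <- rates |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_rate = mean(.data$rate),
                     sd_rate = sd(.data$rate),
                     .groups = "drop")
  list(rates = rates, summary = summary)
}

# P(range of k iid standard normals <= w), by integration over the position
# of the minimum: k * Integral phi(z) [Phi(z+w) - Phi(z)]^(k-1) dz
normal_range_cdf <- function(w, k, rel_tol = 1e-9) {
  if (w <= 0) return(0)
  val <- stats::integrate(
    function(z) k * stats::dnorm(z) *
      (stats::pnorm(z + w) - stats::pnorm(z))^(k - 1),
    lower = -Inf, upper = Inf, rel.tol = rel_tol, abs.tol = 1e-12
  )$value
  min(max(val, 0), 1)
}

#' Upper tail of the studentized-range distribution
#'
#' Survival function \eqn{P(Q \ge q)} of the studentized range of k groups
#' with df error degrees of freedom, computed by direct numerical
#' integration: the range CDF of k standard normals (inner integral) is
#' mixed over the distribution of the pooled scale estimate
#' \eqn{s = \sqrt{\chi^2_{df}/df}} (outer integral). Accuracy is better
#' than 1e-4, sufficient for significance testing. `df = Inf` gives the
#' known-variance limit.
#'
#' @param q observed studentized-range statistic (q >= 0).
#' @param k number of groups (k >= 2).
#' @param df error degrees of freedom (df >= 1), or `Inf`.
#' @return upper tail probability in [0, 1].
#' @examples
#' studentized_range_sf(3.5, k = 3, df = 6)
#' @export
studentized_range_sf <- function(q, k, df) {
  stopifnot(length(q) == 1, length(k) == 1, length(df) == 1)
  if (is.na(q) || q < 0) stop("q must be a non-negative number", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 2) stop("k must be an integer >= 2", call. = FALSE)
  if (!(is.infinite(df) || df >= 1)) stop("df must be >= 1 (or Inf)", call. = FALSE)
  if (q == 0) return(1)
  if (is.infinite(df)) return(1 - normal_range_cdf(q, k))
  # density of s = sqrt(chi^2_df / df): f(s) = 2 s df dchisq(s^2 df, df)
  cdf <- stats::integrate(
    function(s) {
      vapply(s, function(si) {
        2 * si * df * stats::dchisq(si^2 * df, df) *
          normal_range_cdf(q * si, k, rel_tol = 1e-7)
      }, numeric(1))
    },
    lower = 0, upper = Inf, rel.tol = 1e-6, abs.tol = 1e-10
  )$value
  min(max(1 - cdf, 0), 1)
}

#' Tukey-Kramer all-pairs comparison
#'
#' One-way ANOVA pooled mean squared error, then for every pair (i, j) the
#' studentized statistic
#' \eqn{q_{ij} = |\bar{y}_i - \bar{y}_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}
#' (the Kramer adjustment for unequal group sizes) with p-values from the
#' studentized-range distribution with k groups and N - k degrees of
#' freedom. Controls the family-wise error rate across all pairwise
#' comparisons.
#'
#' @param groups named list of numeric vectors, one per group (k >= 2,
#'   each of length >= 2).
#' @return tibble with one row per unordered pair: `group1`, `group2`,
#'   `diff` (mean of group2 minus mean of group1), `q`, `p`.
#' @examples
#' tukey_kramer(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
#' @export
tukey_kramer <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2)) stop("each group needs at least 2 observations", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_len(k))
  }
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), numeric(1))) /
    (N - k)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[j] - means[i]
    se <- sqrt((mse / 2) * (1 / n[i] + 1 / n[j]))
    if (se == 0) {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    } else {
      q <- abs(d) / se
      p <- studentized_range_sf(q, k = k, df = N - k)
    }
    c(d, q, p)
  })
  tibble::tibble(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = res[1, ], q = res[2, ], p = res[3, ]
  )
}

#' Test recovery-rate differences between conditions
#'
#' The statistical treatment of the desiccation assay: replicate recovery
#' rates are compared with Student's t-test when there are exactly two
#' conditions and with the Tukey-Kramer test when there are three or more
#' (`test = "auto"`). Rates are analyzed untransformed by default; the
#' arcsine-square-root variance-stabilizing transform is available.
#'
#' @param assays survival count tibble (see [recovery_summary()]).
#' @param test `"auto"`, `"t"` or `"tukey"`.
#' @param arcsine apply `asin(sqrt(rate))` before testing.
#' @return list with `summary` (per-condition means/SDs) and `comparisons`
#'   (pairwise tibble `group1`, `group2`, `diff`, statistic, `p`).
#' @export
survival_test <- function(assays, test = c("auto", "t", "tukey"),
                          arcsine = FALSE) {
  test <- match.arg(test)
  rs <- recovery_summary(assays)
  rates <- rs$rates
  if (arcsine) rates$rate <- asin(sqrt(rates$rate))
  groups <- split(rates$rate, rates$condition)
  if (length(groups) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (test == "auto") test <- if (length(groups) == 2) "t" else "tukey"
  comparisons <- if (test == "t") {
    if (length(groups) != 2) stop("t-test requires exactly 2 conditions", call. = FALSE)
    tt <- student_t_test(groups[[2]], groups[[1]])
    tibble::tibble(group1 = names(groups)[1], group2 = names(groups)[2],
                   diff = mean(groups[[2]]) - mean(groups[[1]]),
                   statistic = tt$t, p = tt$p)
  } else {
    tk <- tukey_kramer(groups)
    tibble::tibble(group1 = tk$group1, group2 = tk$group2, diff = tk$diff,
                   statistic = tk$q, p = tk$p)
  }
  list(summary = rs$summary, comparisons = comparisons, test = test)
}
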