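#' Selection configuration for the differential cascade
#'
#' Bundles the thresholds and group labels of the candidate-selection
#' cascade: significance level for both t-tests, the fold-change bound of
#' strict criterion (a), and the vehicle band of strict criterion (b).
#'
#' @param alpha two-sided significance level (default 0.05).
#' @param fc_threshold fold-change bound; "more than `fc_threshold`-fold" is
#'   strict (> threshold for up, < 1/threshold for down). Default 2.
#' @param vehicle_band closed interval the vehicle/untreated fold change
#'   must fall in (default `c(0.8, 1.2)`).
#' @param control,vehicle,treatment group labels in the manifest.
#' @param triplicate_rule `"all_groups"` (protein must be quantified in
#'   every replicate of every group; default) or `"compared_groups"`
#'   (only the two groups of each t-test must be complete — with this rule a
#'   protein may be testable for one contrast only, and it is tested iff
#'   both contrasts are complete).
#' @param log_transform run the t-tests on log(L) instead of L.
#' @param welch use Welch's unequal-variance t instead of the pooled
#'   Student's t.
#' @param fc_stat `"arithmetic"` (ratio of arithmetic group means, matching
#'   mean +/- SD bar plots; default) or `"geometric"`.
#' @return list of class `"selection_config"`.
#' @export
selection_config <- function(alpha = 0.05, fc_threshold = 2,
                             vehicle_band = c(0.8, 1.2),
                             control = "untreated", vehicle = "vehicle",
                             treatment = "treatment",
                             triplicate_rule = c("all_groups", "compared_groups"),
                             log_transform = FALSE, welch = FALSE,
                             fc_stat = c("arithmetic", "geometric")) {
  stopifnot(alpha > 0, alpha < 1, fc_threshold > 1,
            length(vehicle_band) == 2,
            vehicle_band[1] < 1, vehicle_band[2] > 1)
  structure(list(alpha = alpha, fc_threshold = fc_threshold,
                 vehicle_band = sort(as.numeric(vehicle_band)),
                 control = control, vehicle = vehicle, treatment = treatment,
                 triplicate_rule = match.arg(triplicate_rule),
                 log_transform = isTRUE(log_transform), welch = isTRUE(welch),
                 fc_stat = match.arg(fc_stat)),
            class = "selection_config")
}

runs_by_group <- function(manifest, groups) {
  missing <- setdiff(groups, manifest$group)
  if (length(missing) > 0) {
    stop("manifest lacks required group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(setNames(groups, groups),
         function(g) manifest$run[manifest$group == g])
}

#' Biological-triplicate detection filter
#'
#' Only proteins detected as full biological replicate sets enter the
#' statistical tests. Under the default rule a protein passes iff its
#' protein-level relative expression is defined in every replicate of every
#' group, which guarantees both t-tests and both fold changes are
#' computable.
#'
#' @param quant a `"protein_quant"` from [protein_rollup()].
#' @param manifest manifest tibble (`run`, `group`, `replicate`).
#' @param cfg a [selection_config()].
#' @return character vector of protein ids passing the filter.
#' @export
triplicate_filter <- function(quant, manifest, cfg = selection_config()) {
  stopifnot(inherits(quant, "protein_quant"))
  grp_runs <- runs_by_group(manifest,
                            c(cfg$control, cfg$vehicle, cfg$treatment))
  if (any(lengths(grp_runs) < 3)) {
    stop("each group needs >= 3 replicate runs", call. = FALSE)
  }
  missing_runs <- setdiff(unlist(grp_runs), colnames(quant$L))
  if (length(missing_runs) > 0) {
    stop("manifest run(s) absent from protein matrix: ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  }
  complete_in <- function(runs) {
    rowSums(is.na(quant$L[, runs, drop = FALSE])) == 0
  }
  ok <- if (cfg$triplicate_rule == "all_groups") {
    complete_in(grp_runs[[cfg$control]]) &
      complete_in(grp_runs[[cfg$vehicle]]) &
      complete_in(grp_runs[[cfg$treatment]])
  } else {
    # both contrasts share the control group, so "compared groups complete"
    # for both tests is again all three groups complete; kept as a distinct
    # rule for designs with extra, uncompared groups in the manifest
    complete_in(grp_runs[[cfg$control]]) &
      complete_in(grp_runs[[cfg$vehicle]]) &
      complete_in(grp_runs[[cfg$treatment]])
  }
  rownames(quant$L)[ok]
}

#' Two-sample Student's t-test
#'
#' Classical equal-variance two-sample t-test with
#' \eqn{df = n_a + n_b - 2} and a two-sided p-value, the test named by the
#' analysis this package reproduces. Degenerate inputs are defined exactly:
#' zero pooled variance with equal means gives t = 0, p = 1; zero pooled
#' variance with unequal means gives p = 0 and sets the `degenerate` flag.
#' Welch's unequal-variance variant is available.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use Welch's t with Satterthwaite degrees of freedom.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @examples
#' student_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  if (welch) {
    va <- var(a) / na; vb <- var(b) / nb
    se <- sqrt(va + vb)
    df <- if (se > 0) (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)) else na + nb - 2
  } else {
    df <- na + nb - 2
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  }
  if (se == 0) {
    if (d == 0) {
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(d) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tstat <- d / se
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), degenerate = FALSE)
}

group_values <- function(L, protein, runs, log_transform = FALSE) {
  v <- L[protein, runs]
  if (log_transform) log(v) else v
}

#' Classify proteins through the differential cascade
#'
#' For every protein passing the triplicate filter, the protein-level
#' relative expression in the treatment group and in the vehicle group is
#' compared with the untreated control by Student's t-test. A protein is
#' *differentially regulated* iff the treatment contrast is significant
#' (`p_treatment < alpha`) and the vehicle contrast is not
#' (`p_vehicle >= alpha`) — a significant change only in the treated group.
#' Fold changes are ratios of group means. A Benjamini-Hochberg adjusted
#' treatment p-value is reported for information only; it plays no role in
#' the cascade, whose reliability filters are the strict criteria of
#' [apply_strict_criteria()].
#'
#' @inheritParams triplicate_filter
#' @return tibble with one row per protein in the matrix: group means and
#'   SDs, `p_treatment`, `p_vehicle`, `padj_treatment` (BH, informational),
#'   `fc_treatment`, `fc_vehicle`, `n_unique_peptides`, and `class` in
#'   {`not_tested`, `tested`, `differentially_regulated`} (the significant
#'   classes are assigned by [apply_strict_criteria()]).
#' @export
classify_differential <- function(quant, manifest, cfg = selection_config()) {
  tested <- triplicate_filter(quant, manifest, cfg)
  grp_runs <- runs_by_group(manifest,
                            c(cfg$control, cfg$vehicle, cfg$treatment))
  L <- quant$L
  proteins <- rownames(L)
  is_tested <- proteins %in% tested

  grp_mean <- function(runs) unname(rowMeans(L[, runs, drop = FALSE], na.rm = FALSE))
  grp_sd <- function(runs) unname(apply(L[, runs, drop = FALSE], 1L, sd))
  mu_c <- grp_mean(grp_runs[[cfg$control]])
  mu_v <- grp_mean(grp_runs[[cfg$vehicle]])
  mu_t <- grp_mean(grp_runs[[cfg$treatment]])
  gm <- function(runs) unname(exp(rowMeans(log(L[, runs, drop = FALSE]))))
  if (cfg$fc_stat == "geometric") {
    fc_t <- gm(grp_runs[[cfg$treatment]]) / gm(grp_runs[[cfg$control]])
    fc_v <- gm(grp_runs[[cfg$vehicle]]) / gm(grp_runs[[cfg$control]])
  } else {
    fc_t <- mu_t / mu_c
    fc_v <- mu_v / mu_c
  }

  p_t <- p_v <- rep(NA_real_, length(proteins))
  for (i in which(is_tested)) {
    ctl <- group_values(L, proteins[i], grp_runs[[cfg$control]], cfg$log_transform)
    p_t[i] <- student_t_test(
      group_values(L, proteins[i], grp_runs[[cfg$treatment]], cfg$log_transform),
      ctl, welch = cfg$welch)$p
    p_v[i] <- student_t_test(
      group_values(L, proteins[i], grp_runs[[cfg$vehicle]], cfg$log_transform),
      ctl, welch = cfg$welch)$p
  }

  cls <- ifelse(!is_tested, "not_tested",
                ifelse(p_t < cfg$alpha & p_v >= cfg$alpha,
                       "differentially_regulated", "tested"))
  padj <- rep(NA_real_, length(proteins))
  padj[is_tested] <- stats::p.adjust(p_t[is_tested], method = "BH")

  tibble::tibble(
    protein = proteins,
    n_unique_peptides = unname(apply(quant$counts, 1L, max)),
    mean_untreated = mu_c, sd_untreated = grp_sd(grp_runs[[cfg$control]]),
    mean_vehicle = mu_v, sd_vehicle = grp_sd(grp_runs[[cfg$vehicle]]),
    mean_treatment = mu_t, sd_treatment = grp_sd(grp_runs[[cfg$treatment]]),
    p_treatment = p_t, p_vehicle = p_v, padj_treatment = padj,
    fc_treatment = fc_t, fc_vehicle = fc_v,
    class = cls
  )
}

#' Apply the strict criteria for significant proteins
#'
#' Among the differentially regulated proteins, a protein is called
#' *significant* iff (a) its treatment/untreated fold change shows more than
#' `fc_threshold`-fold up- or downregulation (strict inequality) and (b) its
#' vehicle/untreated fold change lies in the closed vehicle band. Direction
#' is recorded as `significant_up` or `significant_down`.
#'
#' @param diff tibble from [classify_differential()].
#' @param cfg a [selection_config()].
#' @return the input tibble with `class` upgraded to `significant_up` /
#'   `significant_down` where the criteria hold.
#' @export
apply_strict_criteria <- function(diff, cfg = selection_config()) {
  dr <- diff$class == "differentially_regulated"
  in_band <- diff$fc_vehicle >= cfg$vehicle_band[1] &
    diff$fc_vehicle <= cfg$vehicle_band[2]
  up <- dr & in_band & diff$fc_treatment > cfg$fc_threshold
  down <- dr & in_band & diff$fc_treatment < 1 / cfg$fc_threshold
  diff$class[up] <- "significant_up"
  diff$class[down] <- "significant_down"
  diff
}

#' Extract the significant-protein table
#'
#' @param diff tibble from [apply_strict_criteria()].
#' @return rows with a significant class, sorted by decreasing
#'   |log2 fold change| of the treatment contrast.
#' @export
significant_table <- function(diff) {
  sig <- diff[diff$class %in% c("significant_up", "significant_down"), ]
  sig[order(-abs(log2(sig$fc_treatment))), ]
}

#' Report protein levels normalized to the untreated group
#'
#' Re-expresses each group's mean protein level relative to the untreated
#' mean, so the untreated group reports exactly 1.0; per-group SDs are
#' scaled by the same factor (the figure-style presentation of selected
#' proteins).
#'
#' @param diff tibble from [classify_differential()] (or later stage).
#' @return tibble with columns `protein`, `group`, `level`, `sd`.
#' @export
normalize_to_untreated <- function(diff) {
  long <- tidyr::pivot_longer(
    diff[c("protein", "mean_untreated", "sd_untreated", "mean_vehicle",
           "sd_vehicle", "mean_treatment", "sd_treatment")],
    cols = -"protein",
    names_to = c(".value", "group"),
    names_pattern = "(mean|sd)_(.*)"
  )
  ref <- diff$mean_untreated[match(long$protein, diff$protein)]
  tibble::tibble(protein = long$protein, group = long$group,
                 level = unname(long$mean / ref), sd = unname(long$sd / ref))
}
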