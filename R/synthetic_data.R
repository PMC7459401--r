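#' Simulation configuration
#'
#' Parameters of the synthetic LC-MS evidence generator and the survival
#' simulator. Defaults emulate the design of the study this package
#' reproduces: three groups (untreated, vehicle, treatment) in biological
#' triplicate, on the order of 1500 proteins carrying 1-10 tryptic peptides
#' each, log-normal peak areas with ~10% biological CV, per-run scale
#' factors spanning 0.5-2, 5% detection dropout, a small set of spiked
#' effects (treatment-only and vehicle-confounded, fold 4), and
#' desiccation assays of ~15 animals in triplicate per condition.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (min, max) of peptides per
#'   protein, drawn uniformly.
#' @param fraction_shared fraction of peptides embedded in a second parent
#'   protein (hence non-unique).
#' @param groups group labels; the first is the untreated control, the
#'   second the vehicle, the third the treatment.
#' @param n_replicates biological replicates per group.
#' @param median_area median raw peak area (arbitrary intensity units).
#' @param sdlog_protein log-scale SD of between-protein base abundance.
#' @param sdlog_peptide log-scale SD of per-peptide ionization efficiency.
#' @param cv_biological biological coefficient of variation of a peptide's
#'   peak area across replicate runs (log-normal noise).
#' @param scale_range per-run scale factors are drawn log-uniformly from
#'   this interval.
#' @param dropout probability that a (peptide, run) measurement is lost.
#' @param dropout_model `"uniform"` (independent of intensity, default) or
#'   `"intensity"` (logistic left-censoring: low areas drop out more).
#' @param dropout_exempt_spiked if `TRUE`, spiked (non-null) proteins are
#'   never subject to dropout; used when evaluating calling power in
#'   isolation from missingness.
#' @param frac_treatment_up,frac_treatment_down fractions of proteins
#'   spiked up/down in the treatment group only.
#' @param frac_confounded fraction spiked identically in vehicle and
#'   treatment (solvent-driven effects the cascade must reject).
#' @param fold_treatment,fold_confounded effect folds (> 0).
#' @param survival_p named vector of true per-condition recovery
#'   probabilities.
#' @param n_animals animals per survival replicate.
#' @param n_survival_replicates survival replicates per condition.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_proteins = 1500,
                       peptides_per_protein = c(1, 10),
                       fraction_shared = 0.1,
                       groups = c("untreated", "vehicle", "treatment"),
                       n_replicates = 3,
                       median_area = 1e7,
                       sdlog_protein = 1,
                       sdlog_peptide = 0.7,
                       cv_biological = 0.10,
                       scale_range = c(0.5, 2),
                       dropout = 0.05,
                       dropout_model = c("uniform", "intensity"),
                       dropout_exempt_spiked = FALSE,
                       frac_treatment_up = 0.01,
                       frac_treatment_down = 0.01,
                       frac_confounded = 0.01,
                       fold_treatment = 4,
                       fold_confounded = 4,
                       survival_p = c(vehicle = 0.35, treatment = 0.75),
                       n_animals = 15,
                       n_survival_replicates = 3) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    fraction_shared = fraction_shared,
    groups = groups, n_replicates = as.integer(n_replicates),
    median_area = median_area, sdlog_protein = sdlog_protein,
    sdlog_peptide = sdlog_peptide, cv_biological = cv_biological,
    scale_range = as.numeric(scale_range), dropout = dropout,
    dropout_model = match.arg(dropout_model),
    dropout_exempt_spiked = isTRUE(dropout_exempt_spiked),
    frac_treatment_up = frac_treatment_up,
    frac_treatment_down = frac_treatment_down,
    frac_confounded = frac_confounded,
    fold_treatment = fold_treatment, fold_confounded = fold_confounded,
    survival_p = survival_p, n_animals = as.integer(n_animals),
    n_survival_replicates = as.integer(n_survival_replicates)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c(cfg$fraction_shared, cfg$dropout, cfg$frac_treatment_up,
             cfg$frac_treatment_down, cfg$frac_confounded)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$frac_treatment_up + cfg$frac_treatment_down + cfg$frac_confounded > 1) {
    stop("effect fractions sum to more than 1", call. = FALSE)
  }
  if (cfg$fold_treatment <= 0 || cfg$fold_confounded <= 0) {
    stop("effect folds must be > 0", call. = FALSE)
  }
  if (cfg$cv_biological < 0 || cfg$sdlog_protein < 0 || cfg$sdlog_peptide < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (cfg$n_proteins < 1 || cfg$n_replicates < 1) {
    stop("n_proteins and n_replicates must be >= 1", call. = FALSE)
  }
  if (length(cfg$peptides_per_protein) != 2 ||
      cfg$peptides_per_protein[1] < 1 ||
      cfg$peptides_per_protein[1] > cfg$peptides_per_protein[2]) {
    stop("peptides_per_protein must be a valid integer range", call. = FALSE)
  }
  if (length(cfg$scale_range) != 2 || any(cfg$scale_range <= 0) ||
      cfg$scale_range[1] > cfg$scale_range[2]) {
    stop("scale_range must be a positive interval", call. = FALSE)
  }
  if (any(cfg$survival_p < 0 | cfg$survival_p > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$groups) < 3) stop("need three group labels", call. = FALSE)
  invisible(cfg)
}

# random tryptic-like peptides: body from an alphabet without K/R (cleavage
# residues) and without I (so I/L-collapsed uniqueness is exact by
# construction), terminated by K or R. Peptides are globally unique and no
# peptide is a suffix of another: K/R occur only at peptide ends, so a
# peptide can only occur inside a concatenated sequence where it was
# designed in, or as the suffix of a longer peptide -- which is excluded
# here. Substring matching therefore recovers the designed flags exactly.
random_peptides <- function(n, min_len = 7, max_len = 14) {
  alphabet <- strsplit("ACDEFGHLMNPQSTVWY", "")[[1]]
  draw <- function(m) {
    len <- sample(min_len:max_len, m, replace = TRUE) - 1L
    body <- vapply(len, function(l) {
      paste(sample(alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
    paste0(body, sample(c("K", "R"), m, replace = TRUE))
  }
  accepted <- new.env(parent = emptyenv())   # peptide -> TRUE
  suffixes <- new.env(parent = emptyenv())   # proper suffix of an accepted peptide
  out <- character(n)
  n_out <- 0L
  proper_suffixes <- function(p) {
    L <- nchar(p)
    ls <- seq(min_len, L - 1L)
    if (length(ls) == 0) return(character(0))
    substring(p, L - ls + 1L, L)
  }
  while (n_out < n) {
    for (p in draw(n - n_out)) {
      if (n_out >= n) break
      sufs <- proper_suffixes(p)
      clash <- !is.null(accepted[[p]]) || !is.null(suffixes[[p]]) ||
        any(vapply(sufs, function(s) !is.null(accepted[[s]]), logical(1)))
      if (!clash) {
        n_out <- n_out + 1L
        out[n_out] <- p
        accepted[[p]] <- TRUE
        for (s in sufs) suffixes[[s]] <- TRUE
      }
    }
  }
  out
}

#' Simulate an LC-MS proteomics experiment with ground truth
#'
#' Generates a peptide evidence table, the matching sample manifest, a
#' protein FASTA database, and the ground truth needed to score the
#' pipeline. The raw peak area of peptide p (parent protein q) in run r is
#'
#' \deqn{A_{p,r} = base_q \cdot ion_p \cdot effect(group_r, q) \cdot
#'   scale_r \cdot \varepsilon,\qquad
#'   \varepsilon \sim logNormal(0, \sigma),}
#'
#' with \eqn{\sigma = \sqrt{\log(1 + CV^2)}}, followed by detection
#' dropout. Protein sequences are synthesized by concatenating each
#' protein's tryptic peptides, so substring matching recovers the designed
#' unique/shared flags exactly; designed shared peptides are embedded in
#' two parent proteins. Fully reproducible from `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed for all randomness.
#' @return list with `evidence` (tibble `peptide`, `run`, `area`),
#'   `manifest`, `db` (named character vector, ready for
#'   [write_fasta_db()]), and `truth` (list of `proteins`, `peptides`,
#'   `scale` tibbles plus `survival_p`).
#' @export
simulate_proteome <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  set.seed(seed)
  np <- cfg$n_proteins
  protein_ids <- sprintf("PROT%05d", seq_len(np))

  # effect classes
  n_up <- round(cfg$frac_treatment_up * np)
  n_down <- round(cfg$frac_treatment_down * np)
  n_conf <- round(cfg$frac_confounded * np)
  cls <- rep("null", np)
  spiked_idx <- sample(np, n_up + n_down + n_conf)
  cls[spiked_idx[seq_len(n_up)]] <- "treatment_up"
  cls[spiked_idx[n_up + seq_len(n_down)]] <- "treatment_down"
  cls[spiked_idx[n_up + n_down + seq_len(n_conf)]] <- "confounded"
  # confounded effects alternate up/down so spiked mass stays directionally
  # balanced and the run totals used for normalization are barely disturbed
  conf_idx <- spiked_idx[n_up + n_down + seq_len(n_conf)]
  conf_dir <- rep_len(c(1, -1), length(conf_idx))
  true_fold <- dplyr::case_when(
    cls == "treatment_up" ~ cfg$fold_treatment,
    cls == "treatment_down" ~ 1 / cfg$fold_treatment,
    TRUE ~ 1
  )
  true_fold[conf_idx] <- ifelse(conf_dir > 0, cfg$fold_confounded,
                                1 / cfg$fold_confounded)

  base <- cfg$median_area * exp(rnorm(np, 0, cfg$sdlog_protein))

  # peptides: per-protein counts, then a shared subset gets a second parent
  n_pep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                  np, replace = TRUE)
  parent1 <- rep(seq_len(np), n_pep)
  total_pep <- length(parent1)
  pep_seq <- random_peptides(total_pep)
  shared <- runif(total_pep) < cfg$fraction_shared
  parent2 <- rep(NA_integer_, total_pep)
  if (np >= 2 && any(shared)) {
    parent2[shared] <- vapply(parent1[shared], function(q) {
      sample(setdiff(seq_len(np), q), 1L)
    }, integer(1))
  } else {
    shared[] <- FALSE
  }

  # sequences: concatenation of own peptides plus shared peptides adopted
  # from elsewhere (each peptide already ends in K/R)
  seq_parts <- split(pep_seq, factor(parent1, levels = seq_len(np)))
  adopt <- split(pep_seq[shared & !is.na(parent2)],
                 factor(parent2[shared & !is.na(parent2)], levels = seq_len(np)))
  db <- setNames(vapply(seq_len(np), function(q) {
    paste(c(seq_parts[[q]], adopt[[q]]), collapse = "")
  }, character(1)), protein_ids)

  # manifest
  manifest <- tidyr::expand_grid(group = cfg$groups,
                                 replicate = seq_len(cfg$n_replicates))
  manifest$run <- sprintf("run_%s_%d", manifest$group, manifest$replicate)
  manifest <- manifest[c("run", "group", "replicate")]
  nr <- nrow(manifest)
  true_scale <- exp(runif(nr, log(cfg$scale_range[1]), log(cfg$scale_range[2])))

  # effect multiplier per protein x run
  vehicle_grp <- cfg$groups[2]; treatment_grp <- cfg$groups[3]
  effect_of <- function(class, fold, group) {
    dplyr::case_when(
      class %in% c("treatment_up", "treatment_down") & group == treatment_grp ~ fold,
      class == "confounded" & group %in% c(vehicle_grp, treatment_grp) ~ fold,
      TRUE ~ 1
    )
  }

  ion <- exp(rnorm(total_pep, 0, cfg$sdlog_peptide))
  sigma <- sqrt(log(1 + cfg$cv_biological^2))

  grid <- tidyr::expand_grid(pep = seq_len(total_pep), run_i = seq_len(nr))
  grid$group <- manifest$group[grid$run_i]
  pclass <- cls[parent1[grid$pep]]
  mu <- base[parent1[grid$pep]] * ion[grid$pep] *
    effect_of(pclass, true_fold[parent1[grid$pep]], grid$group) *
    true_scale[grid$run_i]
  area <- mu * exp(rnorm(nrow(grid), 0, sigma))

  keep <- if (cfg$dropout <= 0) {
    rep(TRUE, nrow(grid))
  } else if (cfg$dropout_model == "uniform") {
    runif(nrow(grid)) >= cfg$dropout
  } else {
    # logistic left-censoring calibrated so the marginal dropout rate is
    # roughly cfg$dropout at the median log-area
    la <- log(area)
    p_drop <- stats::plogis(-(la - stats::quantile(la, cfg$dropout)) / 0.5) *
      (2 * cfg$dropout)
    runif(nrow(grid)) >= pmin(p_drop, 1)
  }
  if (cfg$dropout_exempt_spiked) keep <- keep | (pclass != "null")

  evidence <- tibble::tibble(
    peptide = pep_seq[grid$pep[keep]],
    run = manifest$run[grid$run_i[keep]],
    area = area[keep]
  )
  evidence <- evidence[order(evidence$peptide, evidence$run), ]

  truth <- list(
    proteins = tibble::tibble(protein = protein_ids, class = cls,
                              true_fold = true_fold, base_abundance = base),
    peptides = tibble::tibble(
      peptide = pep_seq,
      parent = protein_ids[parent1],
      second_parent = ifelse(is.na(parent2), NA_character_,
                             protein_ids[parent2]),
      shared = shared
    ),
    scale = tibble::tibble(run = manifest$run, true_scale = true_scale),
    survival_p = cfg$survival_p
  )
  list(evidence = evidence, manifest = manifest, db = db, truth = truth,
       config = cfg, seed = seed)
}

#' Simulate desiccation survival counts
#'
#' Per condition and replicate, the number of recovered animals is binomial
#' with the condition's true recovery probability.
#'
#' @param cfg a [sim_config()] (fields `survival_p`, `n_animals`,
#'   `n_survival_replicates`).
#' @param seed integer seed.
#' @return survival tibble (`condition`, `replicate`, `recovered`, `total`).
#' @export
simulate_survival <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  set.seed(seed)
  conds <- names(cfg$survival_p)
  if (is.null(conds)) stop("survival_p must be a named vector", call. = FALSE)
  out <- tidyr::expand_grid(condition = conds,
                            replicate = seq_len(cfg$n_survival_replicates))
  out$total <- cfg$n_animals
  out$recovered <- rbinom(nrow(out), out$total,
                          cfg$survival_p[out$condition])
  out[c("condition", "replicate", "recovered", "total")]
}

#' Score the significant-protein call against simulation truth
#'
#' Confusion summary of the cascade's significant calls versus the designed
#' effect classes. True positives are treatment-only spike-ins
#' (`treatment_up` / `treatment_down`); null and vehicle-confounded
#' proteins are negatives (a confounded protein called significant is a
#' false positive — the vehicle criteria exist to reject exactly those).
#' Proteins absent from the differential table (not detected or without
#' unique peptides) count as not-called.
#'
#' @param truth the `truth` element of [simulate_proteome()].
#' @param diff differential tibble from [apply_strict_criteria()].
#' @return list with `confusion` (TP/FP/TN/FN), `sensitivity`,
#'   `specificity`, and `confounded_excluded` (fraction of confounded
#'   spike-ins not called significant; `NA` if none simulated).
#' @export
recovery_report <- function(truth, diff) {
  tp_tbl <- truth$proteins
  unknown <- setdiff(diff$protein, tp_tbl$protein)
  if (length(unknown) > 0) {
    stop("differential table contains protein(s) unknown to the truth: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  called <- diff$protein[diff$class %in% c("significant_up", "significant_down")]
  positive <- tp_tbl$class %in% c("treatment_up", "treatment_down")
  is_called <- tp_tbl$protein %in% called
  tp <- sum(positive & is_called)
  fn <- sum(positive & !is_called)
  fp <- sum(!positive & is_called)
  tn <- sum(!positive & !is_called)
  conf <- tp_tbl$class == "confounded"
  list(
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    confounded_excluded = if (any(conf)) mean(!is_called[conf]) else NA_real_
  )
}
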