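#' Normalize peak areas across LC-MS runs
#'
#' Between-run normalization against the peak areas of all identified
#' peptides. With total-sum normalization (the default) each run r with raw
#' total \eqn{T_r = \sum_p A_{p,r}} is rescaled by
#' \eqn{s_r = \bar{T} / T_r}, where \eqn{\bar{T}} is the mean total over
#' runs, so that after scaling every run carries the same total signal.
#' A median-ratio alternative (scale by the mean of per-run median areas
#' over the run's median) is available for data with a few dominant
#' peptides.
#'
#' @param evidence evidence tibble from [read_evidence()] (columns
#'   `peptide`, `run`, `area`).
#' @param statistic `"total"` (sum of areas, default) or `"median"`.
#' @return list of class `"normalized_evidence"` with elements `evidence`
#'   (the input plus a `normalized_area` column) and `scale` (tibble `run`,
#'   `total`, `scale`).
#' @examples
#' ev <- tibble::tibble(peptide = c("AAK", "CCK", "AAK", "CCK"),
#'                      run = c("r1", "r1", "r2", "r2"),
#'                      area = c(100, 300, 300, 900))
#' normalize_runs(ev)$scale
#' @export
normalize_runs <- function(evidence, statistic = c("total", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(nrow(evidence) > 0)
  stat_fun <- if (statistic == "total") sum else median
  totals <- evidence |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(total = stat_fun(.data$area), .groups = "drop")
  if (any(totals$total <= 0)) {
    stop("run(s) with non-positive total signal: ",
         paste(totals$run[totals$total <= 0], collapse = ", "), call. = FALSE)
  }
  totals$scale <- mean(totals$total) / totals$total
  ev <- dplyr::left_join(evidence, totals[c("run", "scale")], by = "run")
  ev$normalized_area <- ev$area * ev$scale
  ev$scale <- NULL
  structure(list(evidence = ev, scale = totals, statistic = statistic),
            class = "normalized_evidence")
}

#' Peptide relative expression across runs
#'
#' For every peptide, each run's normalized peak area is divided by the mean
#' normalized area of that same sequence over the runs where it was
#' detected, giving the relative expression E. By construction the mean of
#' E over a peptide's detected runs is exactly 1; runs where the peptide was
#' not detected are masked (`NA`), never imputed.
#'
#' @param ne a `"normalized_evidence"` object from [normalize_runs()].
#' @param runs optional character vector fixing the column order; defaults
#'   to the sorted run ids present.
#' @return numeric matrix E (peptides x runs) with `NA` where not detected.
#' @export
peptide_relative_expression <- function(ne, runs = NULL) {
  stopifnot(inherits(ne, "normalized_evidence"))
  ev <- ne$evidence
  ev <- ev |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(rel = .data$normalized_area / mean(.data$normalized_area)) |>
    dplyr::ungroup()
  if (is.null(runs)) runs <- sort(unique(ev$run))
  peptides <- sort(unique(ev$peptide))
  E <- matrix(NA_real_, nrow = length(peptides), ncol = length(runs),
              dimnames = list(peptides, runs))
  E[cbind(match(ev$peptide, peptides), match(ev$run, runs))] <- ev$rel
  E
}

#' Roll peptide relative expression up to protein level
#'
#' The relative expression of a protein in a run is the median of the
#' relative expression of its *unique* peptides detected in that run; shared
#' peptides never contribute. Even-count medians are the arithmetic mean of
#' the two central values. A (protein, run) cell is defined iff at least one
#' unique peptide of that protein was detected in that run; proteins with no
#' unique peptide anywhere are excluded from the matrix and counted in the
#' `excluded_proteins` element.
#'
#' @param E peptide relative-expression matrix from
#'   [peptide_relative_expression()].
#' @param uniqueness tibble from [map_peptide_uniqueness()] covering every
#'   peptide in `E`.
#' @return list of class `"protein_quant"` with `L` (protein x run matrix of
#'   protein relative expression), `counts` (contributing unique peptides
#'   per cell), and `excluded_proteins` (ids whose peptides are all shared).
#' @export
protein_rollup <- function(E, uniqueness) {
  missing <- setdiff(rownames(E), uniqueness$peptide)
  if (length(missing) > 0) {
    stop("uniqueness not computed for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  umap <- uniqueness[uniqueness$unique & uniqueness$peptide %in% rownames(E), ]
  all_matched <- unique(unlist(uniqueness$proteins[
    uniqueness$peptide %in% rownames(E)]))
  prot_of <- setNames(vapply(umap$proteins, `[[`, character(1), 1L),
                      umap$peptide)
  excluded <- sort(setdiff(all_matched, unname(prot_of)))
  if (length(excluded) > 0) {
    message(length(excluded),
            " protein(s) without any unique peptide were excluded from the matrix")
  }
  if (nrow(umap) == 0) stop("no unique peptides; nothing to quantify", call. = FALSE)

  sub <- E[umap$peptide, , drop = FALSE]
  det <- which(!is.na(sub), arr.ind = TRUE)
  long <- tibble::tibble(
    protein = unname(prot_of[rownames(sub)[det[, 1L]]]),
    run = colnames(sub)[det[, 2L]],
    rel = sub[det]
  )
  agg <- long |>
    dplyr::group_by(.data$protein, .data$run) |>
    dplyr::summarise(L = median(.data$rel), n = dplyr::n(), .groups = "drop")
  proteins <- sort(unique(agg$protein))
  runs <- colnames(E)
  L <- matrix(NA_real_, length(proteins), length(runs),
              dimnames = list(proteins, runs))
  counts <- matrix(0L, length(proteins), length(runs),
                   dimnames = list(proteins, runs))
  idx <- cbind(match(agg$protein, proteins), match(agg$run, runs))
  L[idx] <- agg$L
  counts[idx] <- agg$n
  structure(list(L = L, counts = counts, excluded_proteins = excluded),
            class = "protein_quant")
}

#' One-call quantification: evidence to protein matrix
#'
#' Convenience wrapper chaining [normalize_runs()],
#' [peptide_relative_expression()], [map_peptide_uniqueness()] and
#' [protein_rollup()].
#'
#' @param evidence evidence tibble (columns `peptide`, `run`, `area`).
#' @param db named character vector of protein sequences.
#' @param il_equivalent treat I and L as equivalent in uniqueness matching.
#' @param statistic run-normalization statistic, see [normalize_runs()].
#' @return list with `quant` (a `"protein_quant"`), `scale` (per-run scale
#'   factors), `uniqueness` (peptide-to-protein map), and `E` (peptide
#'   relative-expression matrix).
#' @export
quantify_proteins <- function(evidence, db, il_equivalent = TRUE,
                              statistic = "total") {
  ne <- normalize_runs(evidence, statistic = statistic)
  E <- peptide_relative_expression(ne)
  uniq <- map_peptide_uniqueness(rownames(E), db, il_equivalent = il_equivalent)
  quant <- protein_rollup(E, uniq)
  list(quant = quant, scale = ne$scale, uniqueness = uniq, E = E)
}
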