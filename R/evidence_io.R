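#' @importFrom rlang .data
#' @importFrom stats median pt var rnorm runif rbinom setNames sd
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Strip modification annotations from peptide strings
#'
#' Search-engine peptide tables decorate sequences with modification
#' annotations such as `"AAC(ox)K"`, `"M[15.99]PEK"` or leading/trailing
#' underscores. Quantification aggregates by bare sequence, so annotations in
#' parentheses or square brackets and all non-letter characters are removed
#' and the result is uppercased. The operation is idempotent.
#'
#' @param x character vector of peptide strings.
#' @return character vector of bare uppercase sequences.
#' @examples
#' strip_modifications(c("_AAC(ox)K_", "M[15.99]PEK"))
#' @export
strip_modifications <- function(x) {
  x <- gsub("\\([^()]*\\)", "", x)
  x <- gsub("\\[[^][]*\\]", "", x)
  toupper(gsub("[^A-Za-z]", "", x))
}

check_peptide_alphabet <- function(peptides) {
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), peptides)
  if (any(bad)) {
    stop("peptide sequence(s) outside the 20 amino-acid alphabet: ",
         paste(utils::head(unique(peptides[bad]), 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(peptides))) {
    stop("empty peptide sequence after modification stripping", call. = FALSE)
  }
  invisible(peptides)
}

# Validate and canonicalize a long-form evidence tibble: bare sequences,
# strictly positive areas, one row per (peptide, run).
new_evidence <- function(df) {
  df$peptide <- as.character(df$peptide)
  df$run <- as.character(df$run)
  df$area <- as.numeric(df$area)
  neg <- which(!is.na(df$area) & df$area < 0)
  if (length(neg) > 0) {
    stop("negative peak area at row(s): ", paste(utils::head(neg, 5L), collapse = ", "),
         call. = FALSE)
  }
  df <- df[!is.na(df$area) & df$area > 0, , drop = FALSE]
  dup <- duplicated(df[c("peptide", "run")])
  if (any(dup)) {
    stop("duplicate (peptide, run) record(s), e.g. ",
         df$peptide[which(dup)[1]], " / ", df$run[which(dup)[1]], call. = FALSE)
  }
  df$peptide <- strip_modifications(df$peptide)
  # modified forms of the same bare sequence in one run are the same analyte:
  # their areas are summed
  df <- df |>
    dplyr::group_by(.data$peptide, .data$run) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
  check_peptide_alphabet(df$peptide)
  tibble::as_tibble(df[order(df$peptide, df$run), ])
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  name_repair = "minimal")
}

#' Read a peptide evidence table
#'
#' Loads one quantified peak area per (peptide, LC-MS run). Two dialects are
#' supported: `long` with columns `peptide`, `run`, `area` (the native
#' format), and `wide` with a `peptide` column followed by one intensity
#' column per run (the common search-engine peptide-table shape). Empty or
#' zero intensity cells mean the peptide was not detected in that run and are
#' dropped; modification annotations are stripped to the bare sequence and
#' areas of modified forms of the same sequence in the same run are summed.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect `"long"` or `"wide"`.
#' @return a tibble with columns `peptide`, `run`, `area` (all areas > 0,
#'   one row per detected (peptide, run) pair).
#' @seealso [read_manifest()], [read_fasta_db()], [normalize_runs()]
#' @export
read_evidence <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_quiet(path)
  if (dialect == "long") {
    require_columns(df, c("peptide", "run", "area"), "evidence table")
    new_evidence(df[c("peptide", "run", "area")])
  } else {
    require_columns(df, "peptide", "evidence table")
    runs <- setdiff(names(df), "peptide")
    if (length(runs) == 0) {
      stop("wide evidence table has no run columns", call. = FALSE)
    }
    long <- tidyr::pivot_longer(df, cols = dplyr::all_of(runs),
                                names_to = "run", values_to = "area")
    new_evidence(long)
  }
}

#' Read a protein sequence database from FASTA
#'
#' The header token up to the first whitespace is the protein identifier.
#' Sequences are uppercased; the alphabet is restricted to the 20 amino
#' acids plus `X`.
#'
#' @param path path to a FASTA file.
#' @return named character vector mapping protein id to amino-acid sequence.
#' @export
read_fasta_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # readAAStringSet silently drops invalid one-letter codes, so screen the
  # raw sequence lines first
  raw <- readLines(path, warn = FALSE)
  seq_lines <- raw[!startsWith(raw, ">")]
  bad_chr <- grepl(sprintf("[^%sX[:space:]]", paste(AA20, collapse = "")),
                   toupper(seq_lines))
  if (any(bad_chr)) {
    stop("non-amino-acid characters in FASTA sequence line(s): ",
         paste(utils::head(which(!startsWith(raw, ">"))[bad_chr], 3L),
               collapse = ", "), call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA", call. = FALSE)
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad)) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write a protein sequence database to FASTA
#'
#' @param db named character vector (protein id to sequence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path) {
  aa <- Biostrings::AAStringSet(db)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Map peptides to matching proteins and flag unique peptides
#'
#' Each peptide is matched as a contiguous substring against every protein
#' sequence in the database. A peptide is *unique* when it occurs in exactly
#' one protein; only unique peptides contribute to protein quantification.
#' Isoleucine and leucine are mass-indistinguishable on the instrument class
#' this pipeline targets and are treated as equivalent by default.
#'
#' Peptides matching no protein are retained with an empty match set (they
#' can never contribute to any protein); their count is reported in the
#' `n_unmatched` attribute and a warning.
#'
#' @param peptides character vector of bare peptide sequences.
#' @param db named character vector from [read_fasta_db()].
#' @param il_equivalent collapse I and L before matching (default `TRUE`).
#' @return tibble with columns `peptide`, `proteins` (list of matching
#'   protein ids), `n_proteins`, `unique`; attribute `n_unmatched`.
#' @export
map_peptide_uniqueness <- function(peptides, db, il_equivalent = TRUE) {
  stopifnot(length(peptides) > 0, length(db) > 0, !is.null(names(db)))
  peptides <- unique(as.character(peptides))
  seqs <- unname(db)
  pat <- peptides
  if (il_equivalent) {
    seqs <- chartr("I", "L", seqs)
    pat <- chartr("I", "L", pat)
  }
  # concatenate the database with a non-residue separator so matches cannot
  # span protein boundaries; map match offsets back to proteins
  big <- paste(seqs, collapse = "-")
  starts <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]
  loc <- stringi::stri_locate_all_fixed(big, pat, omit_no_match = TRUE)
  hits <- lapply(loc, function(m) {
    if (nrow(m) == 0) return(character(0))
    sort(unique(names(db)[findInterval(m[, 1L], starts)]))
  })
  n_hit <- lengths(hits)
  n_unmatched <- sum(n_hit == 0L)
  if (n_unmatched > 0) {
    warning(n_unmatched, " peptide(s) match no protein in the database",
            call. = FALSE)
  }
  out <- tibble::tibble(
    peptide = peptides,
    proteins = hits,
    n_proteins = n_hit,
    unique = n_hit == 1L
  )
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Read a sample manifest
#'
#' Maps each LC-MS run to its experimental group and biological replicate.
#' Columns: `run`, `group`, `replicate`.
#'
#' @param path path to a tab-separated manifest.
#' @return tibble with columns `run`, `group`, `replicate`.
#' @export
read_manifest <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("run", "group", "replicate"), "manifest")
  validate_manifest(tibble::tibble(
    run = as.character(df$run),
    group = as.character(df$group),
    replicate = as.integer(df$replicate)
  ))
}

validate_manifest <- function(m) {
  if (anyDuplicated(m$run)) {
    stop("duplicate run id(s) in manifest: ",
         paste(unique(m$run[duplicated(m$run)]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(m$replicate)) || any(m$replicate < 1)) {
    stop("manifest replicate labels must be integers >= 1", call. = FALSE)
  }
  dup <- duplicated(m[c("group", "replicate")])
  if (any(dup)) {
    stop("duplicate replicate label within group: ",
         m$group[which(dup)[1]], " / ", m$replicate[which(dup)[1]], call. = FALSE)
  }
  m
}

#' Read a desiccation survival-assay count table
#'
#' Columns: `condition`, `replicate`, `recovered`, `total` — the number of
#' animals judged recovered (spontaneous movement or touch response after
#' rehydration) out of the animals desiccated, per replicate.
#'
#' @param path path to a tab-separated count table.
#' @return tibble with columns `condition`, `replicate`, `recovered`, `total`.
#' @export
read_survival <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("condition", "replicate", "recovered", "total"),
                  "survival table")
  out <- tibble::tibble(
    condition = as.character(df$condition),
    replicate = as.integer(df$replicate),
    recovered = as.integer(df$recovered),
    total = as.integer(df$total)
  )
  if (any(out$total <= 0)) stop("survival total must be > 0", call. = FALSE)
  if (any(out$recovered < 0 | out$recovered > out$total)) {
    stop("recovered count outside [0, total]", call. = FALSE)
  }
  out
}

# full-precision TSV writer: doubles are rendered with 17 significant digits
# so that write -> read round-trips exactly
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- sprintf("%.17g", df[[j]])
      x[is.na(df[[j]])] <- NA_character_
      df[[j]] <- x
    }
  }
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

matrix_to_tibble <- function(m) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(protein = rownames(m)), out)
}

#' Write the pipeline report tables
#'
#' Emits the protein-level relative-expression matrix (masked cells as
#' `"NA"`), the companion per-cell unique-peptide count matrix, the full
#' differential table, the significant-protein table, and a JSON run-log.
#' Numeric values are written at full precision so that writing and
#' re-reading is lossless.
#'
#' @param tables named list with any of `protein_matrix` (numeric matrix,
#'   proteins x runs), `peptide_counts` (integer matrix, same shape),
#'   `differential` (tibble), `significant` (tibble), `run_log` (list).
#' @param out_dir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, writer) {
    if (!is.null(tables[[name]])) {
      path <- file.path(out_dir, paste0(name, if (name == "run_log") ".json" else ".tsv"))
      writer(tables[[name]], path)
      written[[name]] <<- path
    }
  }
  emit("protein_matrix", function(x, p) write_tsv_full(matrix_to_tibble(x), p))
  emit("peptide_counts", function(x, p) write_tsv_full(matrix_to_tibble(x), p))
  emit("differential", write_tsv_full)
  emit("significant", write_tsv_full)
  emit("run_log", function(x, p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(written)
}

#' Read back a protein matrix written by [write_report()]
#'
#' @param path path to a `protein_matrix.tsv` (or `peptide_counts.tsv`) file.
#' @return numeric matrix with protein rownames and run colnames.
#' @export
read_protein_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read.delim's strtod-based parser round-trips %.17g exactly
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  require_columns(df, "protein", "protein matrix")
  m <- as.matrix(df[setdiff(names(df), "protein")])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein
  m
}
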