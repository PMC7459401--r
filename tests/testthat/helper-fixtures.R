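# shared fixtures, built in code at test time

write_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

toy_evidence <- function() {
  tibble::tibble(
    peptide = c("ACDK", "ACDK", "WEFR", "WEFR"),
    run = c("run1", "run2", "run1", "run2"),
    area = c(100, 300, 300, 900)
  )
}

# small but complete simulated experiment for fast end-to-end tests
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(n_proteins = 80, ...)
  simulate_proteome(cfg, seed = seed)
}

# hand-built protein_quant with a fully controlled L matrix
manual_quant <- function(L) {
  counts <- ifelse(is.na(L), 0L, 1L)
  storage.mode(counts) <- "integer"
  structure(list(L = L, counts = counts, excluded_proteins = character(0)),
            class = "protein_quant")
}

manifest_3x3 <- function() {
  tibble::tibble(
    run = paste0("run_", rep(c("untreated", "vehicle", "treatment"), each = 3),
                 "_", rep(1:3, 3)),
    group = rep(c("untreated", "vehicle", "treatment"), each = 3),
    replicate = rep(1:3, 3)
  )
}

# an L matrix whose rows have designed group means/noise on the 3x3 design
make_L <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- manifest_3x3()$run
  m
}
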