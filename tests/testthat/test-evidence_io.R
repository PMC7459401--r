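test_that("long-dialect evidence parses, validates, and drops nothing valid", {
  path <- write_tmp_tsv(tibble::tibble(
    peptide = c("ACDK", "ACDK", "WEFR"),
    run = c("run1", "run2", "run1"),
    area = c(100, 300, 50)
  ))
  ev <- read_evidence(path, dialect = "long")
  expect_equal(nrow(ev), 3L)
  expect_setequal(ev$peptide, c("ACDK", "WEFR"))
  expect_true(all(ev$area > 0))
})

test_that("wide-dialect zero and empty cells mean not detected", {
  path <- write_tmp_tsv(tibble::tibble(
    peptide = c("ACDK", "WEFR"),
    run1 = c(100, 50),
    run2 = c(300, 0)
  ))
  ev <- read_evidence(path, dialect = "wide")
  expect_equal(nrow(ev), 3L)
  expect_false(any(ev$peptide == "WEFR" & ev$run == "run2"))
})

test_that("format and validation errors name the offending column or row", {
  no_run <- write_tmp_tsv(tibble::tibble(peptide = "ACDK", area = 1))
  expect_error(read_evidence(no_run, "long"), "run")
  neg <- write_tmp_tsv(tibble::tibble(peptide = "ACDK", run = "r1", area = -5))
  expect_error(read_evidence(neg, "long"), "negative")
  dup <- write_tmp_tsv(tibble::tibble(peptide = c("ACDK", "ACDK"),
                                      run = c("r1", "r1"), area = c(1, 2)))
  expect_error(read_evidence(dup, "long"), "duplicate")
  bad_aa <- write_tmp_tsv(tibble::tibble(peptide = "ACBJK", run = "r1", area = 1))
  expect_error(read_evidence(bad_aa, "long"), "alphabet")
})

test_that("modification stripping is idempotent and modified forms are summed", {
  raw <- c("_AAC(ox)K_", "M[15.99]PEK", "AACK")
  stripped <- strip_modifications(raw)
  expect_equal(stripped, c("AACK", "MPEK", "AACK"))
  expect_equal(strip_modifications(stripped), stripped)

  path <- write_tmp_tsv(tibble::tibble(
    peptide = c("AAC(ox)K", "AACK", "MPEK"),
    run = c("r1", "r1", "r1"),
    area = c(10, 30, 5)
  ))
  ev <- read_evidence(path, "long")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$area[ev$peptide == "AACK"], 40)
})

test_that("FASTA databases load with id/case normalization and strict errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">prot1 some description", "acdefgh", ">prot2", "WWKR"), fa)
  db <- read_fasta_db(fa)
  expect_equal(length(db), 2L)
  expect_equal(unname(db["prot1"]), "ACDEFGH")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDK", ">p1", "WEFR"), dup)
  expect_error(read_fasta_db(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "AC1DK"), bad)
  expect_error(read_fasta_db(bad))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta_db(empty))
})

test_that("peptide uniqueness flags match direct substring logic", {
  db <- c(X = "MMACDKWW", Y = "GGPEPTR", Z = "TTPEPTRAA")
  u <- suppressWarnings(map_peptide_uniqueness(c("ACDK", "PEPTR", "QQQQK"), db))
  expect_warning(map_peptide_uniqueness(c("QQQQK"), db), "no protein")
  row <- function(p) u[u$peptide == p, ]
  expect_true(row("ACDK")$unique)
  expect_equal(row("ACDK")$proteins[[1]], "X")
  expect_false(row("PEPTR")$unique)
  expect_setequal(row("PEPTR")$proteins[[1]], c("Y", "Z"))
  expect_equal(row("QQQQK")$n_proteins, 0L)
})

test_that("I/L equivalence in matching is on by default and can be disabled", {
  db <- c(A = "MMAIDKWW")
  u_on <- map_peptide_uniqueness("ALDK", db, il_equivalent = TRUE)
  expect_true(u_on$unique)
  expect_warning(
    u_off <- map_peptide_uniqueness("ALDK", db, il_equivalent = FALSE),
    "no protein"
  )
  expect_equal(u_off$n_proteins, 0L)
})

test_that("uniqueness agrees with a brute-force scan over random toy databases", {
  set.seed(404)
  for (rep in 1:5) {
    n_prot <- sample(5:50, 1)
    db <- setNames(vapply(seq_len(n_prot), function(i) {
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   sample(40:80, 1), replace = TRUE), collapse = "")
    }, character(1)), paste0("P", seq_len(n_prot)))
    # peptides drawn from the proteins themselves plus a few random ones
    peps <- unique(c(
      vapply(1:25, function(i) {
        s <- db[[sample(n_prot, 1)]]
        start <- sample(nchar(s) - 8, 1)
        substr(s, start, start + sample(5:8, 1))
      }, character(1)),
      vapply(1:5, function(i) {
        paste(sample(c("A", "C", "D", "W", "Y"), 9, TRUE), collapse = "")
      }, character(1))
    ))
    got <- suppressWarnings(map_peptide_uniqueness(peps, db))
    db_il <- chartr("I", "L", db)
    for (p in peps) {
      hits <- names(db)[vapply(db_il, function(s) {
        grepl(chartr("I", "L", p), s, fixed = TRUE)
      }, logical(1))]
      r <- got[got$peptide == p, ]
      expect_setequal(r$proteins[[1]], hits)
      expect_identical(r$unique, length(hits) == 1L)
    }
  }
})

test_that("manifest reading validates the three-group replicate design", {
  ok <- write_tmp_tsv(manifest_3x3())
  m <- read_manifest(ok)
  expect_equal(nrow(m), 9L)
  expect_setequal(unique(m$group), c("untreated", "vehicle", "treatment"))

  dup_run <- manifest_3x3()
  dup_run$run[2] <- dup_run$run[1]
  expect_error(read_manifest(write_tmp_tsv(dup_run)), "duplicate run")

  dup_rep <- manifest_3x3()
  dup_rep$replicate[2] <- 1L
  expect_error(read_manifest(write_tmp_tsv(dup_rep)), "replicate")
})

test_that("a manifest lacking the vehicle group fails when the cascade needs it", {
  sim <- small_sim()
  two_group <- sim$manifest[sim$manifest$group != "vehicle", ]
  q <- suppressMessages(quantify_proteins(sim$evidence, sim$db))
  expect_error(triplicate_filter(q$quant, two_group), "vehicle")
})

test_that("survival counts read and validate", {
  ok <- write_tmp_tsv(tibble::tibble(condition = c("a", "a", "b"),
                                     replicate = c(1, 2, 1),
                                     recovered = c(10, 0, 15),
                                     total = 15))
  sv <- read_survival(ok)
  expect_equal(nrow(sv), 3L)
  bad <- write_tmp_tsv(tibble::tibble(condition = "a", replicate = 1,
                                      recovered = 16, total = 15))
  expect_error(read_survival(bad), "outside")
  zero <- write_tmp_tsv(tibble::tibble(condition = "a", replicate = 1,
                                       recovered = 0, total = 0))
  expect_error(read_survival(zero), "> 0")
})

test_that("report writing round-trips the protein matrix at full precision", {
  sim <- small_sim()
  q <- suppressMessages(quantify_proteins(sim$evidence, sim$db))
  out <- withr::local_tempdir()
  write_report(list(protein_matrix = q$quant$L,
                    peptide_counts = q$quant$counts), out)
  back <- read_protein_matrix(file.path(out, "protein_matrix.tsv"))
  expect_identical(dimnames(back), dimnames(q$quant$L))
  expect_identical(back, q$quant$L)
})
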