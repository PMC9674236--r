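test_that("quant tables round-trip through TSV losslessly", {
  mat <- matrix(c(1.5, NA, 3, 10, 20, NA, 7, 8, 9, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                nrow = 3)
  qt <- make_qt(mat, sequences = c("ACDEF", "GHILM", "NQSTV"),
                modifications = c("", "amidated_C_term", "oxidation"))
  path <- tempfile(fileext = ".tsv")
  write_quant_table(qt, path)
  back <- read_quant_table(path)
  expect_equal(back$abundance, qt$abundance)
  expect_equal(back$peptides$sequence, qt$peptides$sequence)
  expect_equal(back$peptides$modifications, qt$peptides$modifications)
  expect_equal(back$samples, qt$samples)

  # negative abundance rejected on read
  tab <- read.delim(path, check.names = FALSE)
  tab[1, 6] <- -5
  bad <- tempfile(fileext = ".tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  file.copy(paste0(path, ".samples.tsv"), paste0(bad, ".samples.tsv"))
  expect_error(read_quant_table(bad), "nonnegative")

  # missing sidecar names the required columns
  lonely <- tempfile(fileext = ".tsv")
  file.copy(path, lonely)
  expect_error(read_quant_table(lonely), "clone_id, genotype, bmp")

  expect_error(quant_table(matrix(-1, 1, 1),
                           data.frame(sequence = "AC", modifications = ""),
                           qt$samples[1, ]), "nonnegative")
})

test_that("total-intensity normalization equalizes per-sample totals", {
  mat <- matrix(c(40, 60, 150, 50), nrow = 2)
  qt <- make_qt(mat, genotype = c("WT", "WT"), sequences = c("ACDEF", "GHILM"))
  out <- normalize_total(qt)
  expect_equal(unname(attr(out, "scale_factors")), c(1.5, 0.75))
  expect_equal(unname(colSums(out$abundance)), c(150, 150))

  # already-equal totals: unchanged
  eq <- make_qt(matrix(c(1, 2, 2, 1), nrow = 2), genotype = c("WT", "WT"),
                sequences = c("ACDEF", "GHILM"))
  expect_equal(normalize_total(eq)$abundance, eq$abundance)

  # single sample: unchanged
  one <- quant_table(matrix(c(3, 4), 2, 1),
                     data.frame(sequence = c("ACDEF", "GHILM"),
                                modifications = ""),
                     data.frame(sample_id = "s1", clone_id = "c1",
                                genotype = "WT", bmp = "minus", replicate = 1))
  expect_equal(normalize_total(one)$abundance, one$abundance)

  # property: equal totals with missing values, tight tolerance
  withr::with_seed(1, {
    m <- matrix(rlnorm(120, 10, 1), 20, 6)
    m[sample(120, 25)] <- NA
    qr <- make_qt(m)
    tot <- colSums(normalize_total(qr)$abundance, na.rm = TRUE)
    expect_lt(max(abs(tot / tot[1] - 1)), 1e-9)
  })

  m_allna <- matrix(1, 2, 6)
  m_allna[, 2] <- NA
  expect_error(normalize_total(make_qt(m_allna)), "no observed values")
})

test_that("the replicate-completeness filter keeps fully observed groups", {
  # peptide 1: 3/3 in clone WT-c1, 1/3 in KO-c1 -> kept
  # peptide 2: 2/3 in both clones -> dropped
  mat <- rbind(c(1, 2, 3, NA, NA, 5),
               c(1, 2, NA, 4, 5, NA))
  qt <- make_qt(mat, sequences = c("ACDEF", "GHILM"))
  out <- filter_replicate_complete(qt)
  expect_equal(out$peptides$sequence, "ACDEF")
  expect_equal(attr(out, "n_filtered"), 1L)

  # idempotent
  again <- filter_replicate_complete(out)
  expect_equal(again$abundance, out$abundance)

  # single-replicate design: equivalent to detected anywhere
  m1 <- matrix(c(NA, 1, NA, NA), 2, 2)
  q1 <- quant_table(m1, data.frame(sequence = c("ACDEF", "GHILM"),
                                   modifications = ""),
                    data.frame(sample_id = c("a", "b"),
                               clone_id = c("c1", "c2"),
                               genotype = "WT", bmp = "minus", replicate = 1))
  expect_equal(filter_replicate_complete(q1)$peptides$sequence, "GHILM")

  # monotone: observing one more value never removes a kept peptide
  withr::with_seed(4, {
    m <- matrix(rlnorm(60), 10, 6)
    m[sample(60, 30)] <- NA
    qa <- make_qt(m)
    kept_a <- filter_replicate_complete(qa)$peptides$sequence
    miss <- which(is.na(m), arr.ind = TRUE)
    pick <- miss[sample(nrow(miss), 1), ]
    m[pick[1], pick[2]] <- 1
    qb <- make_qt(m, sequences = qa$peptides$sequence)
    kept_b <- filter_replicate_complete(qb)$peptides$sequence
    expect_true(all(kept_a %in% kept_b))
  })
})

test_that("peptide mapping recovers simulator coordinates and applies the amide rule", {
  reg <- test_registry()
  wt <- simulate_peptidome(reg)
  mat <- matrix(1, nrow(wt), 6)
  qt <- make_qt(mat, sequences = wt$sequence,
                modifications = ifelse(wt$amidated, "amidated_C_term", ""))
  mapped <- map_peptides(qt, reg)
  expect_true(all(mapped$peptides$map_status == "unique"))
  expect_equal(mapped$peptides$accession, wt$accession)
  expect_equal(mapped$peptides$start, wt$start)
  expect_equal(mapped$peptides$end, wt$end)

  # absent sequence flagged unmapped
  q0 <- make_qt(matrix(1, 1, 6), sequences = "WWWWWWW")
  expect_equal(map_peptides(q0, reg)$peptides$map_status, "unmapped")

  # ambiguous: a sequence present in two precursors
  amb <- read_precursors(write_fasta(list("X1|A" = "MKAACDEFGHAA",
                                          "X2|B" = "MKWWCDEFGHWW")))
  qa <- make_qt(matrix(1, 1, 6), sequences = "CDEFGH")
  expect_equal(map_peptides(qa, amb)$peptides$map_status, "ambiguous")

  # amidated peptide requires the successor glycine
  glp <- substr(proglucagon_seq(), 92, 127)
  q_ok <- make_qt(matrix(1, 1, 6), sequences = glp,
                  modifications = "amidated_C_term")
  m_ok <- map_peptides(q_ok, reg)
  expect_equal(m_ok$peptides$map_status, "unique")
  expect_equal(m_ok$peptides$start, 92L)
  # oxyntomodulin region ends before K: an amidated observation cannot map
  oxm <- substr(proglucagon_seq(), 53, 89)
  q_bad <- make_qt(matrix(1, 1, 6), sequences = oxm,
                   modifications = "amidated_C_term")
  expect_equal(map_peptides(q_bad, reg)$peptides$map_status, "unmapped")
  # the same sequence without the amide maps fine
  q_plain <- make_qt(matrix(1, 1, 6), sequences = oxm)
  expect_equal(map_peptides(q_plain, reg)$peptides$map_status, "unique")
})

test_that("precursor aggregation sums non-missing values and preserves n.d.", {
  reg <- test_registry()
  mat <- rbind(c(3, NA, 1, 1, 1, 1),
               c(5, NA, 2, 2, 2, 2),
               c(7, 1, NA, 3, 3, 3))
  seqs <- c(substr(proglucagon_seq(), 53, 68),   # two proglucagon peptides
            substr(proglucagon_seq(), 92, 120),
            "TPNDFESHLIV")                       # synthetic SST-like peptide
  qt <- map_peptides(make_qt(mat, sequences = seqs), reg)
  agg <- aggregate_precursor(qt)
  expect_equal(agg["P01275", 1], 8)
  expect_true(is.na(agg["P01275", 2]))   # n.d. sample
  expect_equal(agg["SYNSST", 2], 1)
  # conservation: per-sample totals match the mapped peptide totals
  expect_equal(unname(colSums(agg, na.rm = TRUE)),
               unname(colSums(mat, na.rm = TRUE)))
})

test_that("bioactive labels require exact coordinates and amidation state", {
  reg <- test_registry()
  glu <- substr(proglucagon_seq(), 53, 81)
  short <- substr(proglucagon_seq(), 53, 80)
  glp1a <- substr(proglucagon_seq(), 98, 127)
  qt <- make_qt(matrix(1, 3, 6), sequences = c(glu, short, glp1a),
                modifications = c("", "", "amidated_C_term"))
  out <- match_bioactive(map_peptides(qt, reg), reg)
  expect_equal(out$peptides$bioactive, c("Glucagon", NA, "GLP-1(7-36)a"))
})
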