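test_that("dibasic endoproteolysis matches the pair-scan oracle", {
  expect_equal(digest_endo("AAKRGG")$sequence, c("AAKR", "GG"))
  expect_equal(digest_endo("ACDEFG")$sequence, "ACDEFG")
  expect_error(digest_endo(""), "non-empty")

  # dibasic pair at the very end: no empty trailing fragment
  expect_equal(digest_endo("AAKR")$sequence, "AAKR")

  # full proglucagon (signal removed), including the internal RR of the
  # glucagon region which the plain dibasic rule also cuts
  s <- substr(proglucagon_seq(), 21, 180)
  frags <- digest_endo(s, start_pos = 21L)
  expect_identical(frags$sequence, oracle_digest(s))
  expect_true("HSQGTFTSDYSKYLDSRR" %in% frags$sequence)
  expect_equal(frags$start[frags$sequence == "HSQGTFTSDYSKYLDSRR"], 53L)

  withr::with_seed(42, {
    for (i in 1:50) {
      x <- paste(sample(c("A", "C", "D", "G", "K", "R", "S", "T"), 30, TRUE),
                 collapse = "")
      fr <- digest_endo(x)
      expect_identical(fr$sequence, oracle_digest(x))
      expect_equal(paste(fr$sequence, collapse = ""), x)
      # every internal boundary is immediately preceded by a dibasic pair
      ends <- cumsum(nchar(fr$sequence))
      for (e in head(ends, -1))
        expect_match(substr(x, e - 1, e), "^[KR][KR]$")
      # fragment coordinates recover the fragments
      expect_identical(substring(x, fr$start, fr$end), fr$sequence)
    }
  })

  # partial efficiency only ever cuts at eligible boundaries
  withr::with_seed(7, {
    fr <- digest_endo("AAKRGGKKCCRRDD", efficiency = 0.5)
    expect_equal(paste(fr$sequence, collapse = ""), "AAKRGGKKCCRRDD")
    for (e in head(cumsum(nchar(fr$sequence)), -1))
      expect_match(substr("AAKRGGKKCCRRDD", e - 1, e), "^[KR][KR]$")
  })
})

test_that("carboxypeptidase trimming emits the full chain and stops correctly", {
  expect_equal(trim_carboxy("AKRRR"), c("AKRRR", "AKRR", "AKR", "AK", "A"))
  expect_equal(trim_carboxy("AQDFVQWLMNT"), "AQDFVQWLMNT")
  expect_equal(trim_carboxy("AAKR", active = FALSE), "AAKR")
  glu_kr <- paste0("HSQGTFTSDYSKYLDSRRAQDFVQWLMNT", "KR")
  chain <- trim_carboxy(glu_kr)
  expect_equal(chain[length(chain)], "HSQGTFTSDYSKYLDSRRAQDFVQWLMNT")
  expect_equal(length(chain), 3)

  # exhaustive comparison with the regex oracle over all 4-mers of {A,K,R}
  combos <- expand.grid(a = c("A", "K", "R"), b = c("A", "K", "R"),
                        c = c("A", "K", "R"), d = c("A", "K", "R"))
  for (i in seq_len(nrow(combos))) {
    pep <- paste(unlist(combos[i, ]), collapse = "")
    chain <- trim_carboxy(pep)
    expect_identical(chain, oracle_trim_chain(pep))
    # chain lengths strictly decrease by one residue per step
    expect_equal(nchar(chain), seq(nchar(pep), by = -1,
                                   length.out = length(chain)))
  }
})

test_that("DPP4 trimming requires P/A at position 2 and supports iteration", {
  expect_equal(trim_amino_dpp4("HAEGTFTSD"), c("HAEGTFTSD", "EGTFTSD"))
  expect_equal(trim_amino_dpp4("HGEGTFTSD"), "HGEGTFTSD")
  expect_equal(trim_amino_dpp4("HAEGTFTSD", active = FALSE), "HAEGTFTSD")
  expect_equal(trim_amino_dpp4("TPAPQRS", iterative = TRUE),
               c("TPAPQRS", "APQRS", "QRS"))
  expect_equal(trim_amino_dpp4("TPAPQRS", iterative = FALSE),
               c("TPAPQRS", "APQRS"))
  expect_error(trim_amino_dpp4("TP"), "length >= 3")
  # chain lengths decrease by two per step
  ch <- trim_amino_dpp4("APAPAPQ", iterative = TRUE)
  expect_identical(nchar(ch), seq(7L, by = -2L, length.out = length(ch)))
})

test_that("amidation consumes a C-terminal glycine", {
  glp1_737 <- substr(proglucagon_seq(), 92, 128)
  am <- amidate(glp1_737)
  expect_equal(am$sequence, substr(proglucagon_seq(), 92, 127))
  expect_true(am$amidated)
  expect_null(amidate("AQDFVQWLMNT"))
  expect_null(amidate("G"))
})

test_that("simulated peptidomes carry the expected genotype signatures", {
  reg <- test_registry()
  wt <- simulate_peptidome(reg)
  # complete processing leaves no free basic C terminus
  free_cterm <- wt$sequence[!wt$amidated]
  expect_false(any(grepl("[KR]$", free_cterm)))

  # carboxypeptidase knockout: accumulating species retain basic C termini
  for (ko in c("CPE", "CPB1")) {
    tr <- species_truth(reg, ko)
    acc <- tr[tr$label == "ko_accumulating", ]
    expect_gt(nrow(acc), 0)
    expect_true(all(grepl("[KR]$", acc$sequence)))
    # mature species lost in the knockout come only from precursors the
    # disabled enzyme is responsible for
    cmap <- cleavekit:::default_carboxy_map(reg)
    expect_true(all(cmap[tr$accession[tr$label != "constitutive"]] == ko))
  }

  # DPP4 knockout: accumulating species have P/A at position 2
  trd <- species_truth(reg, "DPP4")
  accd <- trd[trd$label == "ko_accumulating", ]
  expect_true(all(substr(accd$sequence, 2, 2) %in% c("P", "A")))
  # and the matching cleaved forms are wild-type-only
  matd <- trd[trd$label == "mature", ]
  expect_setequal(substring(accd$sequence, 3), matd$sequence)

  # double endoprotease knockout: no interior dibasic boundary is used -- every
  # species spans the whole post-signal chain up to exopeptidase edits (one
  # DPP4 dipeptide at the N terminus; C-terminal K/R trims plus the amide
  # glycine at the C terminus)
  dk <- simulate_peptidome(reg, c("PCSK1", "PCSK2"))
  for (i in seq_len(nrow(dk))) {
    rec <- reg[[dk$accession[i]]]
    sig <- max(rec$features$end[rec$features$kind == "signal"], 0)
    expect_true(dk$start[i] %in% c(sig + 1, sig + 3))
    expect_gte(dk$end[i], nchar(rec$sequence) - 4)
    # and no N terminus coincides with an interior dibasic cleavage product
    if (dk$start[i] > sig + 1) {
      pre <- substr(rec$sequence, dk$start[i] - 2, dk$start[i] - 1)
      expect_false(grepl("^[KR][KR]$", pre))
    }
  }

  # truth labels partition the union of the two peptidomes
  tr <- species_truth(reg, "CPE")
  expect_setequal(unique(tr$label), c("constitutive", "ko_accumulating", "mature"))
  wt_keys <- with(simulate_peptidome(reg),
                  paste(accession, sequence, start, end, amidated))
  ko_keys <- with(simulate_peptidome(reg, "CPE"),
                  paste(accession, sequence, start, end, amidated))
  tr_keys <- with(tr, paste(accession, sequence, start, end, amidated))
  expect_setequal(tr_keys, union(wt_keys, ko_keys))
  expect_setequal(tr_keys[tr$label == "ko_accumulating"],
                  setdiff(ko_keys, wt_keys))
  expect_setequal(tr_keys[tr$label == "mature"], setdiff(wt_keys, ko_keys))
})

test_that("generated abundance tables honour the effect, seed and censoring", {
  reg <- test_registry()
  tr <- species_truth(reg, "CPE")

  # noiseless limit: knockout-vs-wildtype log2 fold change is exactly the shift
  quiet <- noise_model(log2_sd_technical = 0, log2_sd_biological = 0,
                       ko_log2_shift = 4, censor_quantile = 0)
  g <- generate_quant_table(tr, sim_design("CPE"), quiet, seed = 3,
                            n_background = 0)
  lt <- log2(g$quant$abundance)
  ko_cols <- g$quant$samples$genotype == "CPE"
  fc <- rowMeans(lt[, ko_cols]) - rowMeans(lt[, !ko_cols])
  expect_equal(unname(fc[g$truth$label == "ko_accumulating"]),
               rep(4, sum(g$truth$label == "ko_accumulating")))
  expect_equal(unname(fc[g$truth$label == "mature"]),
               rep(-4, sum(g$truth$label == "mature")))
  expect_equal(unname(fc[g$truth$label == "constitutive"]),
               rep(0, sum(g$truth$label == "constitutive")))

  # determinism
  g1 <- generate_quant_table(tr, sim_design("CPE"), noise_model(), seed = 11)
  g2 <- generate_quant_table(tr, sim_design("CPE"), noise_model(), seed = 11)
  expect_identical(g1$quant$abundance, g2$quant$abundance)
  g3 <- generate_quant_table(tr, sim_design("CPE"), noise_model(), seed = 12)
  expect_false(identical(g1$quant$abundance, g3$quant$abundance))

  # left-censoring removes exactly the lowest quantile of the pre-censoring
  # matrix (same seed with censoring off reveals it)
  nm0 <- noise_model(censor_quantile = 0)
  nm2 <- noise_model(censor_quantile = 0.2)
  p0 <- generate_quant_table(tr, sim_design("CPE"), nm0, seed = 5,
                             n_background = 100)
  p2 <- generate_quant_table(tr, sim_design("CPE"), nm2, seed = 5,
                             n_background = 100)
  pre <- p0$quant$abundance
  thr <- quantile(pre, 0.2, names = FALSE)
  expected_na <- pre < thr
  kept <- rowSums(!expected_na) > 0
  expect_identical(unname(is.na(p2$quant$abundance)),
                   unname(expected_na[kept, , drop = FALSE]))
  expect_equal(mean(expected_na), 0.2, tolerance = 0.01)

  # all values observed in a sample group where the species is produced
  expect_true(all(table(p2$truth$label) > 0))
})
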