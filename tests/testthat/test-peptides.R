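# Peptide arithmetic: masses, fragmentation, hydrodynamic relations,
# oligomer inference.

NLS1_SEQ <- "AKKKSTGSSTWPLDPGVEVTLTMKVAS"   # residues 58-84 of the cargo
NLS2_EXT_SEQ <- "LLASPRSCYKLFQEQQNEGHGEALLFEGIKKKKQQKI"  # residues 490-526

test_that("average mass matches the elemental-composition oracle and known values", {
  expect_equal(average_mass(peptide_sequence(NLS1_SEQ, 58)), 2819.27,
               tolerance = 0.05 / 2819.27)
  expect_equal(average_mass(peptide_sequence(NLS1_SEQ, 58)),
               oracle_peptide_mass(NLS1_SEQ), tolerance = 1e-4)
  expect_equal(average_mass("G"), 75.07, tolerance = 1e-3)
  # random decapeptides agree with the oracle
  set.seed(11)
  for (i in 1:10) {
    s <- paste(sample(c("G","A","S","P","V","T","C","L","I","N","D","Q",
                        "K","E","M","H","F","R","Y","W"), 10, TRUE),
               collapse = "")
    expect_equal(average_mass(s), oracle_peptide_mass(s), tolerance = 1e-4)
  }
})

test_that("terminal caps adjust the mass by the documented deltas", {
  free <- average_mass(peptide_sequence(NLS1_SEQ))
  capped <- average_mass(peptide_sequence(NLS1_SEQ, n_term_cap = "acetyl",
                                          c_term_cap = "amide"))
  expect_equal(capped - free, 42.0367 - 0.9847, tolerance = 1e-9)
  methylated <- average_mass(peptide_sequence("GG", n_term_cap = "methyl",
                                              c_term_cap = "methyl"))
  expect_equal(methylated - average_mass("GG"), 2 * 14.0266,
               tolerance = 1e-9)
  # custom deltas are honored
  expect_equal(average_mass(peptide_sequence("G", n_term_cap = "acetyl"),
                            deltas = cap_mass_deltas(acetyl = 50)) -
                 average_mass("G"), 50)
})

test_that("mass is additive over concatenation for free termini", {
  set.seed(42)
  for (i in 1:5) {
    a <- paste(sample(names(bindlab:::AA_AVERAGE_MASS), 6, TRUE), collapse = "")
    b <- paste(sample(names(bindlab:::AA_AVERAGE_MASS), 9, TRUE), collapse = "")
    expect_equal(average_mass(paste0(a, b)),
                 average_mass(a) + average_mass(b) - 18.01528,
                 tolerance = 1e-9)
  }
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(peptide_sequence(""), "non-empty")
  expect_error(peptide_sequence("AKXK"), "position 3")
  expect_error(peptide_sequence("AK", start_number = 0), ">= 1")
})

test_that("seven-residue/two-step fragmentation reproduces the printed fragment sets", {
  nls1 <- peptide_sequence(NLS1_SEQ, 58, "acetyl", "amide")
  fr <- make_fragments(nls1, window = 7, step = 2)
  expect_equal(nrow(fr), 11L)
  expect_equal(fr$sequence[1], "AKKKSTG")
  expect_equal(fr$start_number[1], 58L)
  expect_equal(fr$end_number[1], 64L)
  expect_equal(fr$sequence[11], "LTMKVAS")
  expect_equal(fr$start_number[11], 78L)
  expect_equal(fr$end_number[11], 84L)
  # all methyl-capped except the last C-terminus, which keeps the parent cap
  expect_true(all(fr$nterm_cap == "methyl"))
  expect_true(all(fr$cterm_cap[-11] == "methyl"))
  expect_equal(fr$cterm_cap[11], "amide")

  ext <- peptide_sequence(NLS2_EXT_SEQ, 490, "free", "amide")
  fr2 <- make_fragments(ext)
  expect_equal(nrow(fr2), 16L)
  expect_equal(fr2$sequence[1], "LLASPRS")
  expect_equal(fr2$sequence[16], "KKKQQKI")
  expect_equal(fr2$start_number[16], 520L)
  expect_equal(fr2$end_number[16], 526L)
})

test_that("fragmentation handles degenerate and non-tiling cases", {
  p7 <- peptide_sequence("AKKKSTG", 58)
  fr <- make_fragments(p7)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$sequence, "AKKKSTG")
  expect_error(make_fragments(peptide_sequence("AKK"), window = 7),
               "exceeds")
  # (L - W) not divisible by step: warn, last window is the final full one
  p8 <- peptide_sequence("AKKKSTGS", 58)
  expect_warning(fr8 <- make_fragments(p8, window = 7, step = 2),
                 "not divisible")
  expect_equal(nrow(fr8), 1L)
  expect_equal(fr8$sequence, "AKKKSTG")
})

test_that("fragment counts and coverage match brute-force window enumeration", {
  set.seed(7)
  for (i in 1:20) {
    L <- sample(7:40, 1); W <- sample(3:7, 1); S <- sample(1:4, 1)
    if (W > L) next
    s <- paste(sample(names(bindlab:::AA_AVERAGE_MASS), L, TRUE),
               collapse = "")
    fr <- suppressWarnings(make_fragments(peptide_sequence(s), W, S))
    exp_win <- oracle_windows(L, W, S)
    expect_equal(nrow(fr), (L - W) %/% S + 1)
    expect_equal(fr$start_number, exp_win$start)
    expect_equal(fr$sequence,
                 substring(s, exp_win$start, exp_win$end))
    # coverage counts agree with enumeration
    cov_pkg <- vapply(seq_len(L), function(r)
      sum(fr$start_number <= r & fr$end_number >= r), numeric(1))
    cov_brute <- vapply(seq_len(L), function(r)
      sum(exp_win$start <= r & exp_win$end >= r), numeric(1))
    expect_equal(cov_pkg, cov_brute)
  }
})

test_that("random-coil radius and its inverse are exact mutual inverses", {
  expect_equal(random_coil_rh(2819.27), 14.3, tolerance = 0.05 / 14.3)
  expect_equal(random_coil_rh(0), 0)
  expect_equal(random_coil_rh((1 / 0.027)^2), 10.0, tolerance = 1e-9)
  expect_equal(mass_from_rh(14.3), (1.43 / 0.027)^2, tolerance = 1e-9)
  expect_equal(mass_from_rh(0), 0)
  expect_equal(mass_from_rh(34), (3.4 / 0.027)^2, tolerance = 1e-9)
  set.seed(3)
  m <- runif(20, 100, 5e5)
  expect_equal(mass_from_rh(random_coil_rh(m)), m, tolerance = 1e-9)
  expect_error(random_coil_rh(-1), ">= 0")
  expect_error(mass_from_rh(-1), ">= 0")
  # non-default exponent round-trips too
  hp <- hydro_params(coefficient = 0.05, exponent = 0.6)
  expect_equal(mass_from_rh(random_coil_rh(1000, hp), hp), 1000,
               tolerance = 1e-9)
})

test_that("oligomer order rounds the mass ratio half away from zero", {
  oo <- oligomer_order(16421.9, 2819.27)
  expect_equal(oo$ratio, 5.83, tolerance = 1e-3)
  expect_equal(oo$order, 6L)
  expect_equal(oligomer_order(2819.27, 2819.27)$order, 1L)
  expect_equal(oligomer_order(2.5, 1)$order, 3L)  # tie rounds up
  expect_error(oligomer_order(-1, 1), "> 0")
  expect_error(oligomer_order(1, 0), "> 0")
})

test_that("FASTA round trip preserves the sequence", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">nls1", NLS1_SEQ), f)
  pep <- read_fasta_peptide(f, start_number = 58)
  expect_equal(pep$residues, NLS1_SEQ)
  expect_equal(pep$start_number, 58L)
})
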