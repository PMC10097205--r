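test_that("composition-family vectors are frequencies summing to one", {
  comp <- aa_composition("GGGG")
  expect_equal(unname(comp[["G"]]), 1)
  expect_equal(sum(comp), 1)
  expect_equal(aa_composition("AG")[["A"]], 0.5)
  uniform <- aa_composition(paste(amino_acids(), collapse = ""))
  expect_equal(unname(uniform), rep(0.05, 20))
  set.seed(9)
  for (seq in replicate(20, random_protein(sample(1:80, 1)))) {
    expect_equal(sum(aa_composition(seq)), 1, tolerance = 1e-12)
    alb <- reduced_alphabet("charge")
    expect_equal(sum(reduced_alphabet_composition(seq, alb)), 1,
                 tolerance = 1e-12)
  }
})

test_that("entropy terms follow the closed form and its bounds", {
  expect_equal(residue_entropy("GGGG")[["G"]], 0)
  expect_equal(residue_entropy("AG")[["A"]], 0.5)
  expect_equal(residue_entropy("AG")[["G"]], 0.5)
  expect_equal(residue_entropy("AAAG")[["G"]], 0.5) # -0.25*log2(0.25)
  uniform <- residue_entropy(paste(amino_acids(), collapse = ""))
  expect_equal(sum(uniform), log2(20))
  set.seed(4)
  for (seq in replicate(10, random_protein(sample(1:60, 1)))) {
    e <- residue_entropy(seq)
    expect_true(all(e >= 0 & e <= log2(20)))
  }
})

test_that("GRAVY is the hydropathy mean and orders classes correctly", {
  kd <- property_scale("kyte_doolittle")
  expect_equal(gravy("AAAA"), kd[["A"]])
  expect_equal(gravy("AG"), (kd[["A"]] + kd[["G"]]) / 2)
  expect_gt(gravy("ILVF"), gravy("DEKR"))
})

test_that("physicochemical summary matches standard constants", {
  g <- physchem_summary("G")
  expect_equal(g$length, 1L)
  expect_equal(g$molecular_weight, 75.07, tolerance = 1e-3) # free glycine
  # defining property of the pI: net charge crosses zero there
  pk <- physchem_summary("MKVVDEKLHRATS")
  counts <- table(factor(strsplit("MKVVDEKLHRATS", "")[[1]],
                         levels = amino_acids()))
  charge_at <- function(pH) {
    pos <- c(1, counts[["K"]], counts[["R"]], counts[["H"]])
    pka_p <- c(8.6, 10.8, 12.5, 6.5)
    neg <- c(1, counts[["D"]], counts[["E"]], counts[["C"]], counts[["Y"]])
    pka_n <- c(3.6, 3.9, 4.1, 8.5, 10.1)
    sum(pos / (1 + 10^(pH - pka_p))) - sum(neg / (1 + 10^(pka_n - pH)))
  }
  expect_lt(abs(charge_at(pk$isoelectric_point)), 1e-4)
  expect_gt(physchem_summary(strrep("K", 12))$isoelectric_point,
            physchem_summary(strrep("D", 12))$isoelectric_point)
})

test_that("reduced alphabets generalise plain composition", {
  seq <- random_protein(50, seed = 2)
  ident <- reduced_alphabet_composition(seq, reduced_alphabet("identity"))
  expect_equal(unname(ident), unname(aa_composition(seq)))
  ch <- reduced_alphabet_composition("KRDE", reduced_alphabet("charge"))
  expect_equal(unname(ch[[1]]), 0.5) # K,R positive
  expect_equal(unname(ch[[3]]), 0.5) # D,E negative
  incomplete <- stats::setNames(rep(1L, 19), amino_acids()[1:19])
  expect_error(reduced_alphabet_composition(seq, incomplete), "cover")
})

test_that("CTD encodes composition, transitions and distribution", {
  # AAAA: single group, no transitions, distribution collapses
  v <- ctd_features("AAAA", "polarity") # A is group 2 (neutral/small)
  expect_equal(unname(v[["comp_g2"]]), 1)
  expect_equal(sum(v[paste0("comp_g", 1:3)]), 1)
  expect_true(all(v[c("trans_g1g2", "trans_g1g3", "trans_g2g3")] == 0))
  # alternating two-group sequence: that transition frequency is 1
  alt <- ctd_features("LPLPLP", "polarity") # L=g1, P=g2
  expect_equal(unname(alt[["trans_g1g2"]]), 1)
  # LLLPPP: exactly one transition event over n-1 = 5 positions
  blocks <- ctd_features("LLLPPP", "polarity")
  expect_equal(unname(blocks[["trans_g1g2"]]), 1 / 5)
  # distribution: first L at 1/6, last L at 3/6
  expect_equal(unname(blocks[["dist_g1_p1"]]), 1 / 6)
  expect_equal(unname(blocks[["dist_g1_p100"]]), 3 / 6)
  expect_equal(unname(blocks[["dist_g3_p50"]]), 0) # absent group
  # length-1 sequence: transitions defined as 0
  expect_true(all(ctd_features("A", "charge")[4:6] == 0))
})

test_that("windowed property summaries honour degenerate windows", {
  kd <- property_scale("kyte_doolittle")
  const <- windowed_property("AAAA", kd, 2)
  expect_equal(const$max, kd[["A"]])
  expect_equal(const$min, kd[["A"]])
  seq <- "MKVLDEW"
  whole <- windowed_property(seq, kd, nchar(seq))
  expect_equal(whole$max, gravy(seq))
  expect_equal(whole$min, gravy(seq))
  # longer window than sequence: whole-sequence mean is the sole window
  short <- windowed_property("AG", kd, 11)
  expect_equal(short$mean, gravy("AG"))
  # max window sits on the most hydrophobic block (I > G on this scale)
  w <- windowed_property("GGGIII", kd, 3)
  expect_equal(w$min, kd[["G"]])
  expect_equal(w$max, kd[["I"]])
})

test_that("autocorrelation matches a brute-force oracle and its symmetries", {
  kd <- property_scale("kyte_doolittle")
  expect_equal(autocorrelation("AAAA", kd, 1), 0) # zero variance
  expect_error(autocorrelation("AG", kd, 2), "lag")
  set.seed(31)
  for (i in 1:10) {
    seq <- random_protein(sample(10:60, 1))
    x <- unname(unclass(kd))[match(strsplit(seq, "")[[1]], amino_acids())]
    rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    for (lag in c(1, 2, 5)) {
      expect_equal(autocorrelation(seq, kd, lag), moran_oracle(x, lag))
      expect_equal(autocorrelation(seq, kd, lag),
                   autocorrelation(rev_seq, kd, lag))
    }
  }
})

test_that("the N-glycosylation sequon excludes proline at X", {
  expect_equal(unname(ptm_motif_counts("NAS")[["nglyc_sequon"]]), 1L)
  expect_equal(unname(ptm_motif_counts("NPS")[["nglyc_sequon"]]), 0L)
  expect_equal(unname(ptm_motif_counts("GGGG")[["nglyc_sequon"]]), 0L)
  expect_equal(unname(ptm_motif_counts("NNST")[["nglyc_sequon"]]), 2L)
})

test_that("feature extraction is deterministic, registry-complete and finite", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 166L)
  expect_false(anyDuplicated(reg$feature) > 0)
  set.seed(17)
  recs <- protein_records(
    c("one", "dup", "short1", "short2", sprintf("r%d", 1:5)),
    c(random_protein(120), random_protein(120, seed = 99), "M", "MK",
      replicate(5, random_protein(sample(30:200, 1))))
  )
  recs$sequence[2] <- recs$sequence[1] # exact duplicate sequence
  f <- extract_features(recs)
  expect_equal(names(f), c("protein_id", reg$feature))
  expect_true(all(vapply(f[-1], function(x) all(is.finite(x)), TRUE)))
  # duplicate sequences give identical rows
  expect_equal(unlist(f[2, -1]), unlist(f[1, -1]))
  # permuting records permutes rows only
  perm <- sample(nrow(recs))
  f2 <- extract_features(recs[perm, ])
  expect_equal(f2, f[perm, ], ignore_attr = TRUE)
  # identical input -> identical table
  expect_identical(extract_features(recs), f)
})

test_that("min-max scaling is fitted on one set and reapplied unchanged", {
  recs <- protein_records(sprintf("p%d", 1:6),
                          replicate(6, random_protein(80)))
  f <- extract_features(recs)
  sc <- fit_feature_scaling(f)
  scaled <- apply_feature_scaling(f, sc)
  rng <- vapply(scaled[-1], function(x) range(x), numeric(2))
  expect_true(all(rng >= -1e-9 & rng <= 1 + 1e-9))
  # constant columns map to zero
  const_cols <- sc$feature[sc$max == sc$min]
  for (cc in const_cols) expect_true(all(scaled[[cc]] == 0))
})
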