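# NG86 sites/differences, Jukes-Cantor correction, back-translation,
# sliding windows

test_that("site counts match the brute-force oracle on representative codons", {
  for (cod in c("TTT", "ATG", "TGG", "CTA", "GGG", "AGA", "ATA", "TAT")) {
    expect_equal(ng86_site_count(cod), oracle_site_count(cod), info = cod)
  }
})

test_that("S + N = 3 for every sense codon and stops are rejected", {
  for (cod in all_sense_codons()) {
    sn <- ng86_site_count(cod)
    expect_equal(unname(sn["S"] + sn["N"]), 3, info = cod)
  }
  expect_error(ng86_site_count("TAA"), class = "microsynteny_input_error")
  expect_error(ng86_site_count("NNN"), class = "microsynteny_input_error")
})

test_that("difference counts handle 0-3 differences with path averaging", {
  expect_equal(ng86_diff_count("TTT", "TTT"), c(Sd = 0, Nd = 0))
  expect_equal(ng86_diff_count("TTT", "TTC"), c(Sd = 1, Nd = 0))  # F->F
  expect_equal(ng86_diff_count("TTT", "TTA"), c(Sd = 0, Nd = 1))  # F->L
  # classic two-difference example, verified against the oracle
  expect_equal(ng86_diff_count("TTT", "GTA"), oracle_diff_count("TTT", "GTA"))
  # three differences: counts sum to 3
  d3 <- ng86_diff_count("TTT", "GAC")
  expect_equal(unname(d3["Sd"] + d3["Nd"]), 3)
  expect_equal(d3, oracle_diff_count("TTT", "GAC"))
  # symmetry
  expect_equal(ng86_diff_count("GTA", "TTT"), ng86_diff_count("TTT", "GTA"))
})

test_that("stop-passing paths are excluded from the averaging", {
  # TGG (W) <-> TGT (C) x TAT: some orderings pass TAG/TGA stops
  pair <- list(c("TGG", "TAT"), c("TCA", "AGA"), c("TGG", "CAT"))
  for (p in pair) {
    expect_equal(ng86_diff_count(p[1], p[2]), oracle_diff_count(p[1], p[2]),
                 info = paste(p, collapse = "-"))
  }
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
  jc <- microsynteny:::jc_correct
  expect_equal(jc(0), 0)
  expect_equal(jc(0.1), -0.75 * log(1 - 4 * 0.1 / 3))
  expect_identical(jc(0.75), Inf)
  expect_identical(jc(0.9), Inf)
})

test_that("identical sequences give Ks = Ka = 0 with an NA ratio", {
  cds <- fx_random_cds(50, seed = 5)
  est <- kaks_pair(cds, cds, source_pair = c("x", "x2"))
  expect_equal(est$Ks, 0)
  expect_equal(est$Ka, 0)
  expect_true(is.na(est$ratio))
  expect_false(est$saturated)
  expect_equal(est$S + est$N, 3 * est$n_codons)
})

test_that("a small hand-built codon alignment is scored exactly", {
  # ten CTT codons, one synonymous difference (CTT -> CTC)
  ca <- structure(list(codons_a = rep("CTT", 10),
                       codons_b = c(rep("CTT", 9), "CTC"),
                       source_pair = c("a", "b")), class = "codon_alignment")
  est <- ng86_kaks(ca)
  oS <- (10 * oracle_site_count("CTT")["S"] +
           9 * oracle_site_count("CTT")["S"] + oracle_site_count("CTC")["S"]) / 2
  expect_equal(est$S, unname(oS))
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 1 / unname(oS))
  expect_equal(est$Ks, -0.75 * log(1 - 4 * (1 / unname(oS)) / 3))
  expect_equal(est$Ka, 0)
})

test_that("kaks estimates are symmetric in argument order", {
  a <- fx_random_cds(60, seed = 21)
  b <- evolve_sequence(a, years = 30e6, seed = 22)
  e1 <- kaks_pair(a, b)
  e2 <- kaks_pair(b, a)
  expect_equal(e1$Ks, e2$Ks)
  expect_equal(e1$Ka, e2$Ka)
})

test_that("back_translate drops gap columns and checks consistency", {
  cds_a <- fx_cds_for("MKLVDE")
  cds_b <- fx_cds_for("MKVDE")
  al <- list(aligned_a = "MKLVDE", aligned_b = "MK-VDE")
  ca <- back_translate(al, cds_a, cds_b)
  expect_identical(length(ca$codons_a), 5L)
  expect_identical(paste(ca$codons_a, collapse = ""), fx_cds_for("MKVDE"))
  # translation mismatch is an error
  expect_error(back_translate(al, cds_a, fx_cds_for("MKWDE")),
               class = "microsynteny_consistency_error")
})

test_that("trailing stops are tolerated and stop columns dropped", {
  cds_a <- paste0(fx_cds_for("MKLV"), "TAA")
  cds_b <- paste0(fx_cds_for("MKLV"), "TGA")
  al <- list(aligned_a = "MKLV", aligned_b = "MKLV")
  ca <- back_translate(al, cds_a, cds_b)
  expect_identical(length(ca$codons_a), 4L)
})

test_that("saturation is flagged above Ks = 2", {
  # deeply diverged -> Ks well beyond 2 or uncorrectable
  a <- fx_random_cds(200, seed = 31)
  b <- evolve_sequence(a, years = 600e6, seed = 32)
  al <- list(aligned_a = translate_cds(a), aligned_b = translate_cds(b))
  est <- ng86_kaks(back_translate(al, a, b))
  expect_true(est$saturated)
})

test_that("sliding windows tile the alignment per the closed form", {
  a <- fx_random_cds(150, seed = 41)           # 450 bp
  b <- evolve_sequence(a, years = 40e6, seed = 42)
  ca <- microsynteny:::codon_alignment_from_cds(a, b)
  sw <- sliding_window(ca, window = 150L, step = 9L)
  expect_identical(nrow(sw), oracle_window_count(450L, 150L, 9L))
  expect_true(all(sw$end - sw$start + 1L == 150L))
  expect_identical(sw$start[2] - sw$start[1], 9L)
  expect_false(any(sw$short))
  # each window agrees with scoring its codons directly
  w <- sw[3, ]
  ci <- ((w$start - 1L) %/% 3L + 1L):(w$end %/% 3L)
  direct <- ng86_kaks(structure(list(codons_a = ca$codons_a[ci],
                                     codons_b = ca$codons_b[ci],
                                     source_pair = c(NA, NA)),
                                class = "codon_alignment"))
  expect_equal(w$Ks, direct$Ks)
  expect_equal(w$Ka, direct$Ka)
})

test_that("window/step divisibility by 3 is enforced; short alignments flag", {
  a <- fx_random_cds(20, seed = 51)
  ca <- microsynteny:::codon_alignment_from_cds(a, a)
  expect_error(sliding_window(ca, window = 100L, step = 9L),
               class = "microsynteny_input_error")
  expect_error(sliding_window(ca, window = 150L, step = 10L),
               class = "microsynteny_input_error")
  sw <- sliding_window(ca, window = 150L, step = 9L)   # 60 bp < window
  expect_identical(nrow(sw), 1L)
  expect_true(sw$short)
  expect_equal(sw$end, 60L)
})
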