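# Region extraction, pairing, block calling, orientation, quality

# fabricate an anchor_region without going through an annotation
fx_region <- function(anchor, genes, species_id = "spA", chromosome = "chr1",
                      window_start = 1, window_end = 1e6) {
  structure(list(anchor = anchor, species_id = species_id,
                 chromosome = chromosome, window_start = window_start,
                 window_end = window_end, flanking = tibble::as_tibble(genes)),
            class = "anchor_region")
}

# fabricate a matched-pairs tibble; positions index gene order on each side
fx_pairs <- function(gene_a, gene_b, pos_b, same_strand = TRUE,
                     anchor_pair = rep(FALSE, length(gene_a))) {
  n <- length(gene_a)
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    start_a = seq_len(n) * 1000, end_a = seq_len(n) * 1000 + 500,
    strand_a = "+",
    start_b = pos_b * 1000, end_b = pos_b * 1000 + 500,
    strand_b = ifelse(rep_len(same_strand, n), "+", "-"),
    same_strand = rep_len(same_strand, n),
    e_value = 1e-40, is_anchor_pair = anchor_pair
  )
}

test_that("extract_region clips the window and includes span-overlapping genes", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:5), chromosome = "chr1",
    protein = rep("MKLVDEWQRT", 5)
  ), gap_bp = 400)
  # genes at 1-30, 431-460, 861-890, 1291-1320, 1721-1750
  r <- extract_region(ann, "g3", window = 500)
  expect_identical(r$anchor, "g3")
  expect_equal(r$window_start, 861 - 500)
  expect_equal(r$window_end, 890 + 500)
  expect_setequal(r$flanking$gene_id, c("g2", "g3", "g4"))
  # clipped at chromosome start
  r1 <- extract_region(ann, "g1", window = 500)
  expect_equal(r1$window_start, 1)
  expect_error(extract_region(ann, "nope"),
               class = "microsynteny_lookup_error")
})

test_that("match_regions pairs one-to-one, greedily by E-value", {
  fa <- tibble::tibble(gene_id = c("a1", "a2"), start = c(100, 2000),
                       end = c(400, 2300), strand = "+")
  fb <- tibble::tibble(gene_id = c("b1", "b2"), start = c(50, 1500),
                       end = c(350, 1800), strand = c("+", "-"))
  ra <- fx_region("a1", fa)
  rb <- fx_region("b1", fb, species_id = "spB")
  hits <- tibble::tibble(
    query_id = c("a1", "a2", "a2"),
    subject_id = c("b1", "b1", "b2"),
    score = c(200, 150, 140),
    e_value = c(1e-60, 1e-40, 1e-35)
  )
  p <- match_regions(ra, rb, hits, threshold = 1e-20)
  # b1 is taken by a1 (better E-value); a2 falls through to b2
  expect_identical(nrow(p), 2L)
  expect_identical(p$gene_b[p$gene_a == "a1"], "b1")
  expect_identical(p$gene_b[p$gene_a == "a2"], "b2")
  expect_true(p$is_anchor_pair[p$gene_a == "a1"])
  expect_identical(p$same_strand[p$gene_a == "a2"], FALSE)
  # threshold filters
  p2 <- match_regions(ra, rb, hits, threshold = 1e-50)
  expect_identical(nrow(p2), 1L)
})

test_that("a shared physical gene never pairs with itself", {
  fa <- tibble::tibble(gene_id = "x1", start = 100, end = 400, strand = "+")
  ra <- fx_region("x1", fa)
  rb <- fx_region("x1", fa)
  hits <- tibble::tibble(query_id = "x1", subject_id = "x1",
                         score = 500, e_value = 0)
  expect_identical(nrow(match_regions(ra, rb, hits, 1e-10)), 0L)
})

test_that("call_block enforces the >= 3 flanking-pair rule", {
  ra <- fx_region("a0", tibble::tibble(gene_id = "a0", start = 1, end = 10,
                                       strand = "+"))
  rb <- fx_region("b0", tibble::tibble(gene_id = "b0", start = 1, end = 10,
                                       strand = "+"), species_id = "spB")
  p2 <- fx_pairs(c("a1", "a2", "a0"), c("b1", "b2", "b0"), pos_b = 1:3,
                 anchor_pair = c(FALSE, FALSE, TRUE))
  expect_null(call_block(ra, rb, p2))          # only 2 flanking pairs
  expect_s3_class(call_block(ra, rb, p2, count_anchor = TRUE),
                  "synteny_block")             # 3 with the anchor counted
  p3 <- fx_pairs(paste0("a", 1:3), paste0("b", 1:3), pos_b = 1:3)
  blk <- call_block(ra, rb, p3)
  expect_s3_class(blk, "synteny_block")
  expect_identical(blk$n_pairs, 3L)
  expect_identical(blk$scope, "between-species")
})

test_that("orientation classification covers same, opposite and mixed", {
  ra <- fx_region("a0", tibble::tibble(gene_id = "a0", start = 1, end = 10,
                                       strand = "+"))
  rb <- fx_region("b0", tibble::tibble(gene_id = "b0", start = 1, end = 10,
                                       strand = "+"), species_id = "spB")
  same <- call_block(ra, rb, fx_pairs(paste0("a", 1:4), paste0("b", 1:4),
                                      pos_b = 1:4))
  expect_identical(same$orientation, "same")
  opp <- call_block(ra, rb, fx_pairs(paste0("a", 1:4), paste0("b", 1:4),
                                     pos_b = 4:1, same_strand = FALSE))
  expect_identical(opp$orientation, "opposite")
  mix <- call_block(ra, rb, fx_pairs(paste0("a", 1:4), paste0("b", 1:4),
                                     pos_b = c(2, 1, 3, 4)))
  expect_identical(mix$orientation, "mixed")
})

test_that("longest monotone subsequence is found", {
  lmm <- microsynteny:::longest_monotone_members
  expect_identical(sum(lmm(c(1, 3, 2, 4, 6, 5))), 4L)
  expect_identical(lmm(5:1), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(sum(lmm(5:1, decreasing = TRUE)), 5L)
  expect_identical(lmm(numeric(0)), logical(0))
})

test_that("the 80% conserved-microsynteny rule is boundary inclusive", {
  ra <- fx_region("a0", tibble::tibble(gene_id = "a0", start = 1, end = 10,
                                       strand = "+"))
  rb <- fx_region("b0", tibble::tibble(gene_id = "b0", start = 1, end = 10,
                                       strand = "+"), species_id = "spB")
  # 4 of 5 in order and strand-concordant: exactly 0.80 -> TRUE
  blk80 <- call_block(ra, rb, fx_pairs(paste0("a", 1:5), paste0("b", 1:5),
                                       pos_b = c(1, 2, 3, 5, 4)))
  expect_true(conserved_microsynteny_flag(blk80))
  # 3 of 5: below threshold
  blk60 <- call_block(ra, rb, fx_pairs(paste0("a", 1:5), paste0("b", 1:5),
                                       pos_b = c(2, 1, 4, 3, 5)))
  expect_false(conserved_microsynteny_flag(blk60))
  # fully inverted run with opposite strands counts as conserved
  blkinv <- call_block(ra, rb, fx_pairs(paste0("a", 1:5), paste0("b", 1:5),
                                        pos_b = 5:1, same_strand = FALSE))
  expect_true(conserved_microsynteny_flag(blkinv))
})

test_that("syntenic quality is 2p/(nA+nB) with tandem arrays collapsed", {
  fa <- tibble::tibble(gene_id = paste0("a", 1:4),
                       start = (1:4) * 1000, end = (1:4) * 1000 + 500,
                       strand = "+")
  fb <- tibble::tibble(gene_id = paste0("b", 1:4),
                       start = (1:4) * 1000, end = (1:4) * 1000 + 500,
                       strand = "+")
  ra <- fx_region("a1", fa)
  rb <- fx_region("b1", fb, species_id = "spB")
  blk <- call_block(ra, rb, fx_pairs(paste0("a", 1:3), paste0("b", 1:3),
                                     pos_b = 1:3))
  expect_equal(syntenic_quality(blk), 2 * 3 / (4 + 4))
  # a3/a4 are a tandem array: a4 dropped from the denominator
  tp <- tibble::tibble(gene_a = "a3", gene_b = "a4")
  expect_equal(syntenic_quality(blk, tp), 2 * 3 / (3 + 4))
  expect_error(syntenic_quality(structure(list(
    region_a = fx_region("z", fa[0, ]), region_b = rb,
    pairs = blk$pairs), class = "synteny_block")),
    class = "microsynteny_contract_error")
})

test_that("scan_all finds a planted between-species block and is deterministic", {
  shared <- vapply(1:5, function(i) fx_protein(i, 70), character(1))
  mkgenes <- function(prefix) {
    tibble::tibble(gene_id = paste0(prefix, 1:5), chromosome = "chr1",
                   protein = shared)
  }
  annA <- fx_annotation(mkgenes("a"), species_id = "spA", gap_bp = 2000)
  annB <- fx_annotation(mkgenes("b"), species_id = "spB", gap_bp = 2000)
  run <- function() scan_all(list(annA, annB), anchors = c("a3", "b3"),
                             window = 2e4)
  blocks <- run()
  expect_identical(length(blocks), 1L)
  expect_identical(blocks[[1]]$scope, "between-species")
  expect_identical(blocks[[1]]$n_pairs, 4L)  # 5 pairs minus the anchor pair
  expect_identical(blocks[[1]]$orientation, "same")
  expect_true(blocks[[1]]$conserved_microsynteny)
  expect_identical(block_table(blocks), block_table(run()))
})

test_that("scan_all skips overlapping same-chromosome windows", {
  shared <- vapply(1:5, function(i) fx_protein(i, 70), character(1))
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:5), chromosome = "chr1", protein = shared
  ), gap_bp = 2000)
  blocks <- scan_all(list(ann), anchors = c("g2", "g4"), window = 2e4)
  expect_identical(length(blocks), 0L)
})

test_that("unrelated regions yield no block", {
  annA <- fx_annotation(tibble::tibble(
    gene_id = paste0("a", 1:4), chromosome = "chr1",
    protein = vapply(1:4, function(i) fx_protein(i, 70), character(1))
  ), species_id = "spA", gap_bp = 2000)
  annB <- fx_annotation(tibble::tibble(
    gene_id = paste0("b", 1:4), chromosome = "chr1",
    protein = vapply(11:14, function(i) fx_protein(i, 70), character(1))
  ), species_id = "spB", gap_bp = 2000)
  blocks <- scan_all(list(annA, annB), anchors = c("a2", "b2"), window = 2e4)
  expect_identical(length(blocks), 0L)
})
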