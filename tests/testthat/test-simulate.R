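# Genome-evolution simulator: configs, substitution process, structural
# events, planted truth

test_that("simulation_config validates its arguments", {
  expect_error(simulation_config(), class = "microsynteny_config_error")
  expect_error(simulation_config(seed = 1, t_deep = 10, t_shallow = 20),
               class = "microsynteny_config_error")
  expect_error(simulation_config(seed = 1, syn_rate = 0),
               class = "microsynteny_config_error")
  expect_error(simulation_config(seed = 1, omega = -1),
               class = "microsynteny_config_error")
  cfg <- simulation_config(seed = 5)
  expect_s3_class(cfg, "simulation_config")
  expect_identical(cfg$seed, 5L)
})

test_that("the same seed reproduces the scenario exactly", {
  cfg <- function() simulation_config(seed = 17, n_chromosomes = 1L,
                                      genes_per_chromosome = 10L,
                                      mean_gene_length = 80L, n_anchors = 1L)
  s1 <- simulate_scenario(cfg())
  s2 <- simulate_scenario(cfg())
  for (sp in names(s1$annotations)) {
    expect_identical(as.data.frame(s1$annotations[[sp]]),
                     as.data.frame(s2$annotations[[sp]]))
  }
  expect_identical(s1$genes, s2$genes)
})

test_that("evolve_sequence keeps sequences translatable and is length-preserving", {
  cds <- fx_random_cds(100, seed = 23)
  out <- evolve_sequence(cds, years = 50e6, seed = 24)
  expect_identical(nchar(out), nchar(cds))
  prot <- translate_cds(out)
  expect_false(grepl("\\*", prot))
  expect_identical(nchar(prot), 100L)
  expect_identical(evolve_sequence(cds, years = 0), cds)
})

test_that("substitution counts scale with branch length (statistical)", {
  cds <- fx_random_cds(400, seed = 30)
  count_diffs <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  short <- evolve_sequence(cds, years = 5e6, seed = 31)
  long <- evolve_sequence(cds, years = 100e6, seed = 31)
  expect_lt(count_diffs(cds, short), count_diffs(cds, long))
})

test_that("tandem duplication inserts an adjacent copy with recorded truth", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:5), chromosome = "chr1",
    protein = vapply(1:5, function(i) fx_protein(i, 40), character(1))
  ))
  res <- apply_events(ann, list(
    list(type = "tandem_duplication", lineage = "direct", time = 1,
         anchor = "g3", span = 1)
  ), seed = 4)
  out <- res$annotation
  expect_identical(nrow(out), 6L)
  copy <- setdiff(out$gene_id, ann$gene_id)
  expect_length(copy, 1L)
  expect_match(copy, "^g3x")
  g <- out[order(out$start), ]
  expect_identical(abs(which(g$gene_id == copy) - which(g$gene_id == "g3")), 1L)
  expect_identical(out$cds[out$gene_id == copy], out$cds[out$gene_id == "g3"])
})

test_that("inversion reverses gene order and flips strands", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:7), chromosome = "chr1",
    protein = vapply(1:7, function(i) fx_protein(i, 40), character(1))
  ))
  res <- apply_events(ann, list(
    list(type = "inversion", lineage = "direct", time = 1,
         anchor = "g4", span = 3)
  ), seed = 4)
  out <- res$annotation[order(res$annotation$start), ]
  # g3..g5 segment inverted
  expect_identical(out$gene_id, c("g1", "g2", "g5", "g4", "g3", "g6", "g7"))
  expect_identical(out$strand[3:5], c("-", "-", "-"))
  expect_identical(out$strand[c(1, 2, 6, 7)], rep("+", 4))
})

test_that("gene loss removes the requested genes", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:6), chromosome = "chr1",
    protein = vapply(1:6, function(i) fx_protein(i, 40), character(1))
  ))
  res <- apply_events(ann, list(
    list(type = "gene_loss", lineage = "direct", time = 1,
         genes = c("g2", "g5"))
  ), seed = 4)
  expect_setequal(res$annotation$gene_id, c("g1", "g3", "g4", "g6"))
})

test_that("translocation moves a segment to another chromosome", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:8),
    chromosome = rep(c("chr1", "chr2"), each = 4),
    protein = vapply(1:8, function(i) fx_protein(i, 40), character(1))
  ))
  res <- apply_events(ann, list(
    list(type = "translocation", lineage = "direct", time = 1,
         anchor = "g2", span = 2, dest_chromosome = "chr2")
  ), seed = 4)
  out <- res$annotation
  expect_identical(nrow(out), 8L)  # moved, not duplicated
  moved <- out[out$gene_id %in% c("g2", "g3"), ]
  expect_true(all(moved$chromosome == "chr2"))
})

test_that("segmental duplication copies a span with new ids and truth records", {
  ann <- fx_annotation(tibble::tibble(
    gene_id = paste0("g", 1:8),
    chromosome = rep(c("chr1", "chr2"), each = 4),
    protein = vapply(1:8, function(i) fx_protein(i, 60), character(1))
  ))
  res <- apply_events(ann, list(
    list(type = "segmental_duplication", lineage = "direct", time = 1,
         anchor = "g2", span = 3, dest_chromosome = "chr2")
  ), seed = 4)
  out <- res$annotation
  expect_identical(nrow(out), 11L)
  copies <- setdiff(out$gene_id, ann$gene_id)
  expect_length(copies, 3L)
  expect_true(all(out$chromosome[out$gene_id %in% copies] == "chr2"))
  expect_true(all(grepl("xe1$", copies)))
  expect_setequal(res$truth$source_gene[res$truth$event_id == "e1"],
                  c("g1", "g2", "g3"))
})

test_that("true divergence combines split times and duplication times", {
  sim <- simulate_scenario(paper_like_config(seed = 101))
  # orthologs of the deep split (osa vs sbi): 60 mya
  expect_equal(true_divergence(sim, "osa_g0030", "sbi_g0030"), 60)
  # shallow split (sbi vs zma): 15 mya
  expect_equal(true_divergence(sim, "sbi_g0030", "zma_g0030"), 15)
  # ancestral duplication e1 at 70 mya dominates any split
  expect_equal(true_divergence(sim, "osa_g0018", "sbi_g0018xe1"), 70)
  # within-species duplication: the event time
  expect_equal(true_divergence(sim, "sbi_g0078", "sbi_g0078xe4"), 10)
  # unrelated genes
  expect_true(is.na(true_divergence(sim, "osa_g0030", "sbi_g0042")))
  expect_error(true_divergence(sim, "osa_g0030", "nope"),
               class = "microsynteny_lookup_error")
})

test_that("expected Ks tracks 2 * rate * T for planted divergences", {
  # single 1500-codon pair at 15 mya; generous single-draw band
  cds <- fx_random_cds(1500, seed = 61)
  a <- evolve_sequence(cds, years = 15e6, seed = 62)
  b <- evolve_sequence(cds, years = 15e6, seed = 63)
  est <- kaks_pair(a, b)
  expect_gt(est$Ks, 0.195 * 0.7)
  expect_lt(est$Ks, 0.195 * 1.3)
  expect_lt(est$ratio, 1)
})

test_that("true_blocks requires >= 3 shared-ancestry flanking pairs", {
  sim <- simulate_scenario(paper_like_config(seed = 101))
  tb <- true_blocks(sim)
  expect_true(all(tb$expected_block == (tb$n_true_pairs >= 3L)))
  expect_gt(sum(tb$expected_block), 0L)
  # anchors sharing a planted duplication group are expected blocks
  expect_true(tb$expected_block[tb$anchor_a == "osa_g0102" &
                                  tb$anchor_b == "zma_g0102xe5"])
})
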