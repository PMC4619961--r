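# Small shared fixtures for the unit tests.

# deterministic reverse translation: first codon (alphabetically) per aa
.AA2CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc)) |> lapply(function(v) sort(v)[1])
})

fx_cds_for <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(x) .AA2CODON[[x]], character(1)), collapse = "")
}

# random stop-free CDS of n codons starting with ATG (independent RNG use)
fx_random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(all_sense_codons(), "ATG")
  paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)), collapse = "")
}

# a small annotation: genes laid out left to right on one or more chromosomes
# genes: tibble(gene_id, chromosome, protein [, strand])
fx_annotation <- function(genes, species_id = "spA", gene_bp = NULL,
                          gap_bp = 500) {
  genes <- tibble::as_tibble(genes)
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$cds <- vapply(genes$protein, fx_cds_for, character(1),
                      USE.NAMES = FALSE)
  rows <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, ]
    pos <- 1
    for (i in seq_len(nrow(g))) {
      len <- nchar(g$cds[i])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = g$gene_id[i], chromosome = chr,
        start = pos, end = pos + len - 1, strand = g$strand[i],
        cds = g$cds[i]
      )
      pos <- pos + len + gap_bp
    }
  }
  genome_annotation(dplyr::bind_rows(rows), species_id = species_id)
}

# distinct, unrelated 60-aa proteins (deterministic)
fx_protein <- function(seed, n_aa = 60L) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_aa,
               replace = TRUE), collapse = "")
}
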