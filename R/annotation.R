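#' Build a genome annotation table
#'
#' A genome annotation is a tibble of gene models — one row per protein-coding
#' gene with columns `gene_id`, `species_id`, `chromosome`, `start`, `end`,
#' `strand`, `cds`, `protein` — carrying the chromosome lengths as an
#' attribute. Coordinates are 1-based inclusive (GFF3 convention). Genes are
#' kept sorted by (chromosome, start).
#'
#' @param genes Data frame with the columns above (`protein` optional; it is
#'   derived from `cds` when missing).
#' @param chromosomes Named numeric vector of chromosome lengths in bp. When
#'   `NULL`, each chromosome length is taken as the largest gene end on it.
#' @param species_id Species label; defaults to the one value found in the
#'   `species_id` column.
#' @return A `genome_annotation` tibble.
#' @export
genome_annotation <- function(genes, chromosomes = NULL, species_id = NULL) {
  genes <- as_tibble(genes)
  needed <- c("gene_id", "chromosome", "start", "end", "strand", "cds")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "microsynteny_contract_error")
  }
  if (is.null(species_id)) {
    species_id <- if ("species_id" %in% names(genes)) unique(genes$species_id)[1] else "sp"
  }
  if (!"species_id" %in% names(genes)) genes$species_id <- species_id
  if (!"protein" %in% names(genes)) {
    genes$protein <- vapply(genes$cds, translate_cds, character(1), USE.NAMES = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene_id in annotation", class = "microsynteny_contract_error")
  }
  if (any(genes$start > genes$end)) {
    abort("gene with start > end", class = "microsynteny_contract_error")
  }
  if (any(nchar(genes$cds) %% 3L != 0L | nchar(genes$cds) < 9L)) {
    abort("every CDS must have length >= 9 and divisible by 3",
          class = "microsynteny_contract_error")
  }
  genes <- arrange(genes, .data$chromosome, .data$start, .data$gene_id)
  if (is.null(chromosomes)) {
    chromosomes <- tapply(genes$end, genes$chromosome, max)
    chromosomes <- setNames(as.numeric(chromosomes), names(chromosomes))
  }
  bad <- genes$end > chromosomes[genes$chromosome]
  if (any(is.na(bad)) || any(bad)) {
    abort("gene extends beyond its chromosome length (or chromosome missing)",
          class = "microsynteny_contract_error")
  }
  structure(genes,
            chromosomes = chromosomes,
            species_id = species_id,
            class = c("genome_annotation", class(genes)))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> species ", attr(x, "species_id"),
      ": ", nrow(x), " genes on ", length(attr(x, "chromosomes")),
      " chromosome(s)\n", sep = "")
  NextMethod()
}

#' Chromosome lengths of an annotation
#' @param annotation A `genome_annotation`.
#' @return Named numeric vector of lengths in bp.
#' @export
chromosome_lengths <- function(annotation) attr(annotation, "chromosomes")

#' Bundled CCCH IX reference tables
#'
#' `ccch_ix_family()` returns the published 27-member CCCH IX gene set of
#' rice, maize and sorghum (gene name and identifier, ORF length in aa,
#' molecular weight, pI, chromosome and coordinates). `ccch_ix_blocks()`
#' returns the 31 published anchor-pair microsynteny blocks with their
#' conserved flanking-pair counts, NG86 synonymous sites, mean +/- sd Ks and
#' clock dates in mya. These are reference values used as worked-example
#' inputs and in validation of the clock arithmetic.
#'
#' @return A tibble.
#' @export
ccch_ix_family <- function() {
  readr::read_tsv(system.file("extdata", "ccch_ix_family.tsv",
                              package = "microsynteny", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' @rdname ccch_ix_family
#' @export
ccch_ix_blocks <- function() {
  readr::read_tsv(system.file("extdata", "ccch_ix_blocks.tsv",
                              package = "microsynteny", mustWork = TRUE),
                  show_col_types = FALSE)
}
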