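# Readers and writers for the standard formats the pipeline touches:
# FASTA (Biostrings), GFF3 (rtracklayer), 12-column tabular hits, the
# block/dating report table, and Circos link files.

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased.
#'
#' @param path FASTA file.
#' @return Named character vector, id -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "microsynteny_io_error")
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) {
    abort("empty FASTA file", class = "microsynteny_format_error")
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]),
          class = "microsynteny_format_error")
  }
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a GFF3 annotation into a genome annotation table
#'
#' Gene features must carry an `ID`; CDS features must reference their mRNA
#' (or gene) via `Parent`. Coding sequences are looked up by transcript id
#' (falling back to gene id) in `cds_fasta`; when a gene has several
#' transcripts the one with the longest summed CDS span is kept. Genes
#' without any CDS feature are skipped with a warning.
#'
#' @param path GFF3 file.
#' @param cds_fasta Named character vector, transcript/gene id -> CDS, as
#'   returned by [read_fasta()].
#' @param species_id Species label; default the file name sans extension.
#' @return A [genome_annotation()] tibble.
#' @export
read_gff <- function(path, cds_fasta, species_id = NULL) {
  if (is.null(species_id)) {
    species_id <- sub("\\.gff3?$", "", basename(path))
  }
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)

  chrom_len <- NULL
  si <- GenomeInfoDb::seqlengths(gr)
  if (length(si) && !all(is.na(si))) chrom_len <- si[!is.na(si)]

  genes <- gr[typ == "gene"]
  mrnas <- gr[typ %in% c("mRNA", "transcript")]
  cdss <- gr[typ == "CDS"]
  if (length(genes) == 0L) {
    abort("GFF3 contains no gene features", class = "microsynteny_format_error")
  }

  first_parent <- function(x) {
    p <- S4Vectors::mcols(x)$Parent
    vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_, character(1))
  }
  mrna_parent <- first_parent(mrnas)
  mrna_id <- S4Vectors::mcols(mrnas)$ID
  cds_parent <- first_parent(cdss)

  # summed CDS length per transcript, for the longest-transcript rule
  cds_len <- tapply(GenomicRanges::width(cdss), cds_parent, sum)

  rows <- list()
  skipped <- character()
  for (i in seq_along(genes)) {
    gid <- S4Vectors::mcols(genes)$ID[i]
    tx <- mrna_id[mrna_parent == gid]
    tx <- tx[!is.na(tx)]
    cand <- c(tx, gid)                      # CDS may hang off the gene directly
    cand <- cand[cand %in% names(cds_len)]
    if (length(cand) == 0L) {
      skipped <- c(skipped, gid)
      next
    }
    best_tx <- cand[which.max(cds_len[cand])]
    seq_id <- if (best_tx %in% names(cds_fasta)) best_tx else gid
    if (!seq_id %in% names(cds_fasta)) {
      abort(paste0("no CDS sequence for transcript ", best_tx, " (gene ", gid, ")"),
            class = "microsynteny_consistency_error")
    }
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(genes))[i],
      start = GenomicRanges::start(genes)[i],
      end = GenomicRanges::end(genes)[i],
      strand = as.character(GenomicRanges::strand(genes))[i],
      cds = unname(cds_fasta[seq_id])
    )
  }
  if (length(skipped)) {
    warn(paste0("skipped ", length(skipped), " gene(s) without CDS: ",
                paste(head(skipped, 5), collapse = ", ")))
  }
  genome_annotation(bind_rows(rows), chromosomes = chrom_len,
                    species_id = species_id)
}

#' Write a genome annotation as GFF3
#'
#' Emits gene, mRNA and CDS features (one single-part CDS per gene, spanning
#' the gene) plus `##sequence-region` chromosome lengths.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  n <- nrow(annotation)
  mk <- function(type, id, parent) {
    GenomicRanges::GRanges(
      seqnames = annotation$chromosome,
      ranges = IRanges::IRanges(annotation$start, annotation$end),
      strand = annotation$strand,
      type = type, ID = id, Parent = parent,
      source = "microsynteny"
    )
  }
  gr <- c(
    mk("gene", annotation$gene_id, NA_character_),
    mk("mRNA", paste0(annotation$gene_id, ".t1"), annotation$gene_id),
    mk("CDS", paste0(annotation$gene_id, ".cds"), paste0(annotation$gene_id, ".t1"))
  )
  cl <- chromosome_lengths(annotation)
  GenomeInfoDb::seqlevels(gr) <- names(cl)
  GenomeInfoDb::seqlengths(gr) <- cl
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a 12-column tabular hit file
#'
#' Standard tabular hit format (query, subject, percent identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore). Self-hits are dropped; multiple hits for a (query, subject)
#' pair are reduced to the best one (lowest E-value, ties by highest score).
#'
#' @param path Tab-separated hit file without header.
#' @return Tibble with columns `query_id`, `subject_id`, `score`, `e_value`,
#'   `identity` (fraction in \[0, 1\]).
#' @export
read_hits_table <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                       col_types = readr::cols(
                         query_id = "c", subject_id = "c", pident = "d",
                         length = "d", mismatch = "d", gapopen = "d",
                         qstart = "d", qend = "d", sstart = "d", send = "d",
                         evalue = "c", bitscore = "d"
                       ))
  ev <- suppressWarnings(as.numeric(x$evalue))
  if (anyNA(ev)) {
    abort("non-numeric E-value in hits table", class = "microsynteny_format_error")
  }
  x %>%
    mutate(e_value = ev, identity = .data$pident / 100, score = .data$bitscore) %>%
    filter(.data$query_id != .data$subject_id) %>%
    select("query_id", "subject_id", "score", "e_value", "identity") %>%
    reduce_hits()
}

# best-hit reduction per directed (query, subject) pair; idempotent
reduce_hits <- function(hits) {
  hits %>%
    arrange(.data$query_id, .data$subject_id, .data$e_value, desc(.data$score)) %>%
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)
}

#' Write the block report table
#'
#' One row per microsynteny block: the anchor pair, number of conserved
#' flanking gene pairs, orientation, syntenic quality, mean +/- sd Ks and
#' clock date in mya (dating columns are `NA` when no dating is attached).
#'
#' @param blocks A block set from [scan_all()] / [call_block()], or the tidy
#'   tibble from [block_table()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  tab <- if (inherits(blocks, "data.frame")) as_tibble(blocks) else block_table(blocks)
  num4 <- function(v) ifelse(is.na(v), NA, sprintf("%.4f", v))
  out <- tab %>%
    mutate(
      mean_ks = num4(.data$mean_ks),
      sd_ks = num4(.data$sd_ks),
      date_mya = num4(.data$date_mya),
      quality = ifelse(is.na(.data$quality), NA, sprintf("%.4f", .data$quality))
    )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' Read a block report table written by [write_block_table()]
#' @param path TSV file.
#' @return Tibble.
#' @export
read_block_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    anchor_a = "c", anchor_b = "c", species_a = "c",
                    species_b = "c", scope = "c", orientation = "c",
                    .default = readr::col_double()
                  ))
}

#' Write a Circos links file for a set of blocks
#'
#' One line per conserved gene pair: `chrA startA endA chrB startB endB`,
#' coordinates 1-based inclusive, taken from the paired gene spans.
#'
#' @param blocks A block set (list of `synteny_block`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_circos_links <- function(blocks, path) {
  if (inherits(blocks, "synteny_block")) blocks <- list(blocks)
  lines <- character()
  for (b in blocks) {
    p <- b$pairs
    need <- c("start_a", "end_a", "start_b", "end_b")
    if (!all(need %in% names(p))) {
      abort("block pairs lack genomic coordinates", class = "microsynteny_contract_error")
    }
    if (nrow(p)) {
      lines <- c(lines, sprintf("%s %d %d %s %d %d",
                                b$region_a$chromosome, as.integer(p$start_a),
                                as.integer(p$end_a),
                                b$region_b$chromosome, as.integer(p$start_b),
                                as.integer(p$end_b)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Circos links file
#' @param path Links file written by [write_circos_links()].
#' @return Tibble with chrom/start/end columns for both sides.
#' @export
read_circos_links <- function(path) {
  x <- readr::read_delim(path, delim = " ",
                         col_names = c("chr_a", "start_a", "end_a",
                                       "chr_b", "start_b", "end_b"),
                         show_col_types = FALSE,
                         col_types = "ciicii")
  as_tibble(x)
}
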