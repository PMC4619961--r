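# End-to-end orchestration: simulate/load -> motif scan -> anchors ->
# synteny scan -> Ka/Ks + dating -> sliding windows -> tree, with every
# artifact written as TSV/Newick/links and every parameter echoed to a log.

#' Pipeline configuration
#'
#' @param species Named list; each element a list with `gff`, `cds` and
#'   optionally `proteins` paths, or an in-memory [genome_annotation()] under
#'   `annotation`.
#' @param anchors Either a character vector of anchor ids, a path to an id
#'   file (one id per line), or `NULL` to select by motif count.
#' @param min_domains Motif-count anchor rule when `anchors` is `NULL`.
#' @param hits Optional path to a 12-column tabular hit file.
#' @param within_evalue,between_evalue Synteny E-value thresholds (defaults
#'   `1e-10` / `1e-20`).
#' @param window Flank window in bp (default 100,000).
#' @param ks_max Saturation cutoff (default 2.0).
#' @param rate Clock rate (default `6.5e-9`).
#' @param sw_window,sw_step Sliding-window size/step in bp (defaults 150/9).
#' @param bootstrap Bootstrap replicates for the tree (default 1000).
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species, anchors = NULL, min_domains = 2L,
                            hits = NULL,
                            within_evalue = 1e-10, between_evalue = 1e-20,
                            window = 1e5, ks_max = 2.0, rate = 6.5e-9,
                            sw_window = 150L, sw_step = 9L,
                            bootstrap = 1000L, seed = 1L) {
  stopifnot(within_evalue > 0, between_evalue > 0, window > 0, ks_max > 0,
            rate > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

load_species <- function(spec, species_id) {
  if (!is.null(spec$annotation)) return(spec$annotation)
  for (f in c("gff", "cds")) {
    if (is.null(spec[[f]]) || !file.exists(spec[[f]])) {
      abort(paste0("species ", species_id, ": missing or nonexistent ", f,
                   " path"), class = "microsynteny_config_error")
    }
  }
  read_gff(spec$gff, read_fasta(spec$cds), species_id = species_id)
}

#' Run the full comparative pipeline
#'
#' Stages: load annotations, scan motifs, resolve anchors, scan all anchor
#' pairs for microsynteny, estimate per-pair NG86 Ka/Ks, date blocks by the
#' synonymous clock, profile each block's anchor pair with sliding windows,
#' and build the bootstrap NJ tree of the anchor proteins. Identical
#' config + seed gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for TSV/Newick/links artifacts and the
#'   run log.
#' @return List of class `pipeline_result`: `annotations`, `motifs`,
#'   `anchors`, `blocks` (dated), `block_table`, `pair_kaks`,
#'   `sliding_windows`, `tree`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  # validate every referenced path before any computation
  anns <- imap(config$species, load_species)

  motifs <- imap(anns, function(a, nm) {
    count_domains(a) %>% mutate(species = nm)
  }) %>% list_rbind()

  anchor_ids <- config$anchors
  if (is.character(anchor_ids) && length(anchor_ids) == 1L &&
      file.exists(anchor_ids)) {
    anchor_ids <- readLines(anchor_ids)
    anchor_ids <- anchor_ids[nzchar(anchor_ids)]
  }
  anchors <- unlist(map(anns, function(a) {
    if (is.null(anchor_ids)) {
      select_anchors(a, min_domains = config$min_domains)
    } else {
      select_anchors(a, id_list = intersect(anchor_ids, a$gene_id))
    }
  }), use.names = FALSE)
  if (!is.null(anchor_ids)) {
    lost <- setdiff(anchor_ids, anchors)
    if (length(lost)) {
      abort(paste0("anchor id(s) not found in any annotation: ",
                   paste(lost, collapse = ", ")),
            class = "microsynteny_lookup_error")
    }
  }

  hits <- if (!is.null(config$hits)) read_hits_table(config$hits) else NULL

  blocks <- scan_all(anns, anchors, hits = hits,
                     within_evalue = config$within_evalue,
                     between_evalue = config$between_evalue,
                     window = config$window)
  blocks <- date_blocks(blocks, anns, rate = config$rate)
  btab <- block_table(blocks)

  pair_kaks <- map(blocks, function(b) {
    b$pair_ks %>% mutate(anchor_a = b$region_a$anchor,
                         anchor_b = b$region_b$anchor)
  }) %>% list_rbind()

  lk <- gene_lookup(anns)
  sw <- map(blocks, function(b) {
    a <- b$region_a$anchor; bb <- b$region_b$anchor
    al <- align_global(translate_cds(lk[[a]]$cds), translate_cds(lk[[bb]]$cds))
    ca <- back_translate(al, lk[[a]]$cds, lk[[bb]]$cds, c(a, bb))
    sliding_window(ca, config$sw_window, config$sw_step) %>%
      mutate(anchor_a = a, anchor_b = bb)
  }) %>% list_rbind()

  # anchor protein tree; simulator proteins are unaligned only by indels,
  # which the simulator does not generate, so equal lengths align natively;
  # unequal-length sets are padded via global alignment to the longest
  prots <- setNames(map_chr(anchors, function(a) lk[[a]]$protein), anchors)
  tree <- NULL
  if (length(anchors) >= 4L) {
    if (length(unique(nchar(prots))) > 1L) {
      ref <- names(which.max(nchar(prots)))
      aligned <- map_chr(names(prots), function(nm) {
        if (nm == ref) return(prots[[nm]])
        al <- align_global(prots[[ref]], prots[[nm]])
        al$aligned_b
      })
      maxw <- max(nchar(aligned))
      prots <- setNames(stringr::str_pad(aligned, maxw, "right", "-"),
                        names(prots))
    }
    tree <- bootstrap_support(prots, replicates = config$bootstrap,
                              seed = config$seed)
  }

  res <- structure(
    list(annotations = anns, motifs = motifs, anchors = anchors,
         blocks = blocks, block_table = btab, pair_kaks = pair_kaks,
         sliding_windows = sw, tree = tree, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Write all pipeline artifacts
#' @param res A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(res$motifs, file.path(dir, "motifs.tsv"))
  writeLines(res$anchors, file.path(dir, "anchors.txt"))
  write_block_table(res$block_table, file.path(dir, "blocks.tsv"))
  write_circos_links(res$blocks, file.path(dir, "links.txt"))
  readr::write_tsv(res$pair_kaks, file.path(dir, "pair_kaks.tsv"))
  readr::write_tsv(res$sliding_windows, file.path(dir, "sliding_windows.tsv"))
  if (!is.null(res$tree)) write_tree(res$tree, file.path(dir, "tree.nwk"))
  cfg <- res$config
  cfg$species <- names(cfg$species)
  log <- c("# pipeline run log",
           paste0(names(cfg), ": ",
                  vapply(cfg, function(v) paste(format(v), collapse = ","),
                         character(1))))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$anchors), " anchors, ",
      length(x$blocks), " blocks\n", sep = "")
  invisible(x)
}

#' Family summary table
#'
#' Per-gene ORF length (aa), chromosome and coordinates for a set of family
#' members, with min/max/mean summary; the mean is truncated to an integer
#' (reporting convention for ORF lengths).
#'
#' @param genes Either a [genome_annotation()] plus `anchors` ids, or a
#'   tibble already holding an `orf_aa` column (e.g. [ccch_ix_family()]).
#' @param anchors Family gene ids when `genes` is an annotation.
#' @return List with `table` (per-gene tibble) and `summary` (one-row
#'   tibble: `n`, `min_aa`, `max_aa`, `mean_aa_trunc`).
#' @export
summarize_family <- function(genes, anchors = NULL) {
  if (inherits(genes, "genome_annotation")) {
    g <- genes %>%
      filter(.data$gene_id %in% (anchors %||% .data$gene_id)) %>%
      mutate(orf_aa = nchar(.data$protein)) %>%
      select("gene_id", "species_id", "chromosome", "start", "end", "orf_aa") %>%
      as_tibble()
  } else {
    g <- as_tibble(genes)
    if (!"orf_aa" %in% names(g)) {
      abort("need an orf_aa column or an annotation",
            class = "microsynteny_contract_error")
    }
  }
  list(
    table = g,
    summary = tibble(
      n = nrow(g),
      min_aa = min(g$orf_aa),
      max_aa = max(g$orf_aa),
      mean_aa_trunc = trunc(mean(g$orf_aa))
    )
  )
}
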