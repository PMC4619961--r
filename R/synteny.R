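# Anchor-centred microsynteny: extract 100-kb flanking windows around family
# anchors, pair their genes one-to-one by homology, call blocks with >= 3
# conserved flanking pairs, classify orientation, and score syntenic quality.

#' Extract the anchor-centred window around a gene
#'
#' The window spans `anchor_start - window .. anchor_end + window`, clipped
#' to the chromosome; the flanking set is every gene whose span overlaps the
#' window by at least 1 bp (the anchor is always included).
#'
#' @param annotation A [genome_annotation()].
#' @param anchor Anchor gene id.
#' @param window Flank size in bp on each side (default 100,000).
#' @return List of class `anchor_region`: `anchor`, `species_id`,
#'   `chromosome`, `window_start`, `window_end`, `flanking` (tibble of gene
#'   rows, sorted by start).
#' @export
extract_region <- function(annotation, anchor, window = 1e5) {
  i <- match(anchor, annotation$gene_id)
  if (is.na(i)) {
    abort(paste0("unknown anchor: ", anchor), class = "microsynteny_lookup_error")
  }
  chr <- annotation$chromosome[i]
  chr_len <- chromosome_lengths(annotation)[[chr]]
  ws <- max(1, annotation$start[i] - window)
  we <- min(chr_len, annotation$end[i] + window)
  flanking <- annotation %>%
    filter(.data$chromosome == chr, .data$end >= ws, .data$start <= we) %>%
    arrange(.data$start) %>%
    as_tibble()
  structure(
    list(anchor = anchor, species_id = attr(annotation, "species_id"),
         chromosome = chr, window_start = ws, window_end = we,
         flanking = flanking),
    class = "anchor_region"
  )
}

#' Pair the genes of two anchor regions one-to-one by homology
#'
#' Qualifying cross-region hits (E-value at or below the scope threshold) are
#' taken greedily in order of ascending E-value (ties: higher score, then
#' lexicographic ids); a pair is accepted only if neither gene is already
#' paired. Each pair is annotated with strand agreement and whether it is the
#' anchor-anchor pair.
#'
#' @param region_a,region_b [extract_region()] results.
#' @param hits Hit tibble.
#' @param threshold E-value cutoff (`1e-10` within species, `1e-20` between).
#' @return Tibble of conserved pairs ordered by position in region A:
#'   `gene_a`, `gene_b`, coordinates and strands of both, `same_strand`,
#'   `e_value`, `is_anchor_pair`.
#' @export
match_regions <- function(region_a, region_b, hits, threshold) {
  empty <- tibble(gene_a = character(), gene_b = character(),
                  start_a = double(), end_a = double(), strand_a = character(),
                  start_b = double(), end_b = double(), strand_b = character(),
                  same_strand = logical(), e_value = double(),
                  is_anchor_pair = logical())
  fa <- region_a$flanking
  fb <- region_b$flanking
  h <- hits %>%
    filter(.data$query_id %in% fa$gene_id,
           .data$subject_id %in% fb$gene_id,
           .data$e_value <= threshold) %>%
    arrange(.data$e_value, desc(.data$score), .data$query_id, .data$subject_id)
  if (nrow(h) == 0L) return(empty)
  used_a <- used_b <- character()
  keep <- logical(nrow(h))
  for (r in seq_len(nrow(h))) {
    qa <- h$query_id[r]; sb <- h$subject_id[r]
    if (qa %in% used_a || sb %in% used_b) next
    # the same physical gene can sit in both windows when regions overlap
    if (qa == sb) next
    keep[r] <- TRUE
    used_a <- c(used_a, qa); used_b <- c(used_b, sb)
  }
  h <- h[keep, ]
  if (nrow(h) == 0L) return(empty)
  ia <- match(h$query_id, fa$gene_id)
  ib <- match(h$subject_id, fb$gene_id)
  tibble(
    gene_a = h$query_id, gene_b = h$subject_id,
    start_a = fa$start[ia], end_a = fa$end[ia], strand_a = fa$strand[ia],
    start_b = fb$start[ib], end_b = fb$end[ib], strand_b = fb$strand[ib],
    same_strand = fa$strand[ia] == fb$strand[ib],
    e_value = h$e_value,
    is_anchor_pair = h$query_id == region_a$anchor & h$subject_id == region_b$anchor
  ) %>% arrange(.data$start_a)
}

#' Call a microsynteny block from matched regions
#'
#' A block is returned iff the number of conserved flanking pairs (anchor
#' pair excluded unless `count_anchor`) reaches `min_pairs` (default 3, the
#' large-scale-duplication rule).
#'
#' @param region_a,region_b [extract_region()] results.
#' @param pairs [match_regions()] result.
#' @param min_pairs Minimum conserved flanking pairs (default 3).
#' @param count_anchor Count the anchor pair itself towards `n_pairs`.
#' @return A `synteny_block`, or `NULL` below threshold.
#' @export
call_block <- function(region_a, region_b, pairs, min_pairs = 3L,
                       count_anchor = FALSE) {
  n_flank <- sum(!pairs$is_anchor_pair)
  n_pairs <- if (count_anchor) nrow(pairs) else n_flank
  if (n_pairs < min_pairs) return(NULL)
  block <- structure(
    list(region_a = region_a, region_b = region_b, pairs = pairs,
         n_pairs = n_pairs,
         scope = if (region_a$species_id == region_b$species_id)
           "within-species" else "between-species",
         orientation = NA_character_, quality = NA_real_,
         conserved_microsynteny = NA),
    class = "synteny_block"
  )
  block$orientation <- classify_orientation(block)
  block
}

#' @export
print.synteny_block <- function(x, ...) {
  cat("<synteny_block> ", x$region_a$anchor, " & ", x$region_b$anchor,
      " (", x$scope, "): ", x$n_pairs, " conserved flanking pairs, ",
      x$orientation, " orientation\n", sep = "")
  invisible(x)
}

# rank of each pair's partner along region B, taking pairs in region-A order
partner_ranks <- function(block) {
  p <- block$pairs %>% arrange(.data$start_a)
  rank(p$start_b, ties.method = "first")
}

#' Classify block orientation from gene-order concordance
#'
#' Kendall concordance of partner order along the two regions over all pairs
#' of conserved pairs: all concordant gives `same`, all discordant `opposite`
#' (an inversion), anything else `mixed`.
#'
#' @param block A `synteny_block` with >= 2 pairs.
#' @return `"same"`, `"opposite"` or `"mixed"`.
#' @export
classify_orientation <- function(block) {
  rb <- partner_ranks(block)
  n <- length(rb)
  if (n < 2L) return("same")
  conc <- disc <- 0L
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (rb[j] > rb[i]) conc <- conc + 1L else disc <- disc + 1L
  }
  if (disc == 0L) "same" else if (conc == 0L) "opposite" else "mixed"
}

# longest monotone subsequence membership (one maximal run, O(n^2) DP)
longest_monotone_members <- function(x, decreasing = FALSE) {
  if (decreasing) x <- -x
  n <- length(x)
  if (n == 0L) return(logical(0))
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (x[j] < x[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  members <- logical(n)
  i <- which.max(len)
  while (!is.na(i)) { members[i] <- TRUE; i <- prev[i] }
  members
}

#' Flag conserved microsynteny (80% rule)
#'
#' A block exhibits conserved microsynteny when at least 80% of its pairs are
#' simultaneously order-concordant and strand-concordant (boundary
#' inclusive). Order concordance is membership in the longest monotone run of
#' partner order in the dominant direction; strand concordance means strand
#' agreement matching that direction (same strands for a direct run, opposite
#' strands for an inverted one).
#'
#' @param block A `synteny_block`.
#' @return Logical flag.
#' @export
conserved_microsynteny_flag <- function(block) {
  p <- block$pairs %>% arrange(.data$start_a)
  rb <- partner_ranks(block)
  n <- length(rb)
  if (n == 0L) return(FALSE)
  inc <- longest_monotone_members(rb, decreasing = FALSE)
  dec <- longest_monotone_members(rb, decreasing = TRUE)
  if (sum(inc) >= sum(dec)) {
    order_ok <- inc; strand_ok <- p$same_strand
  } else {
    order_ok <- dec; strand_ok <- !p$same_strand
  }
  mean(order_ok & strand_ok) >= 0.80
}

# tandem pairs among the genes of one region: adjacent (<= max_intervening
# in between) genes of the region that are homologous at `threshold`
region_tandem_pairs <- function(region, hits, threshold, max_intervening = 1L) {
  g <- region$flanking
  out <- list()
  n <- nrow(g)
  if (n < 2L) return(tibble(gene_a = character(), gene_b = character()))
  hkey <- paste(hits$query_id, hits$subject_id)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):min(n, i + 1L + max_intervening)) {
      if (j - i - 1L > max_intervening) next
      r <- match(paste(g$gene_id[i], g$gene_id[j]), hkey)
      if (!is.na(r) && hits$e_value[r] <= threshold) {
        out[[length(out) + 1L]] <- tibble(gene_a = g$gene_id[i],
                                          gene_b = g$gene_id[j])
      }
    }
  }
  if (!length(out)) return(tibble(gene_a = character(), gene_b = character()))
  bind_rows(out)
}

#' Syntenic quality of a block
#'
#' `2 * n_pairs / (n_genes_a + n_genes_b)` after collapsing tandem arrays to
#' one representative per array (first by coordinate) in both the pairing and
#' the denominators; in (0, 1].
#'
#' @param block A `synteny_block`.
#' @param tandem_pairs Tibble of tandem gene pairs (`gene_a`, `gene_b`) to
#'   collapse, e.g. from [detect_tandem()] or the internal per-region scan.
#' @return Fraction in (0, 1].
#' @export
syntenic_quality <- function(block, tandem_pairs = NULL) {
  ga <- block$region_a$flanking
  gb <- block$region_b$flanking
  if (nrow(ga) == 0L || nrow(gb) == 0L) {
    abort("empty region in block", class = "microsynteny_contract_error")
  }
  drop <- character()
  if (!is.null(tandem_pairs) && nrow(tandem_pairs)) {
    # connected components of the tandem-pair graph; keep first by coordinate
    nodes <- unique(c(tandem_pairs$gene_a, tandem_pairs$gene_b))
    comp <- setNames(seq_along(nodes), nodes)
    for (r in seq_len(nrow(tandem_pairs))) {
      a <- comp[[tandem_pairs$gene_a[r]]]; b <- comp[[tandem_pairs$gene_b[r]]]
      comp[comp == b] <- a
    }
    coords <- bind_rows(ga, gb)
    for (cc in unique(comp)) {
      members <- names(comp)[comp == cc]
      pos <- coords$start[match(members, coords$gene_id)]
      rep_gene <- members[order(pos)][1]
      drop <- c(drop, setdiff(members, rep_gene))
    }
  }
  na <- sum(!ga$gene_id %in% drop)
  nb <- sum(!gb$gene_id %in% drop)
  p <- block$pairs %>%
    filter(!.data$gene_a %in% drop, !.data$gene_b %in% drop)
  2 * nrow(p) / (na + nb)
}

#' Scan all anchor pairs for microsynteny blocks
#'
#' Evaluates every unordered anchor pair, within and between species, with
#' the scope-appropriate E-value threshold. Anchor pairs whose windows
#' overlap on the same chromosome are skipped (a region is trivially
#' syntenic with itself). When `hits` is `NULL` a surrogate hit table is
#' computed internally from global alignments of the region genes.
#'
#' @param annotations Named list of [genome_annotation()]s (one per species).
#' @param anchors Anchor gene ids (drawn from any of the annotations).
#' @param hits Optional precomputed hit tibble.
#' @param within_evalue,between_evalue Scope thresholds (defaults `1e-10`,
#'   `1e-20`).
#' @param window Flank size in bp (default 100,000).
#' @param min_pairs Minimum conserved flanking pairs (default 3).
#' @param count_anchor Count the anchor pair towards `n_pairs`.
#' @param max_intervening Tandem-array adjacency used in quality scoring.
#' @return List of `synteny_block` (class `synteny_blocks`), in deterministic
#'   (species, chromosome, coordinate) order, each with orientation, quality
#'   and the conserved-microsynteny flag filled in.
#' @export
scan_all <- function(annotations, anchors, hits = NULL,
                     within_evalue = 1e-10, between_evalue = 1e-20,
                     window = 1e5, min_pairs = 3L, count_anchor = FALSE,
                     max_intervening = 1L) {
  if (inherits(annotations, "genome_annotation")) annotations <- list(annotations)
  anchor_species <- map_chr(anchors, function(a) {
    for (nm in seq_along(annotations)) {
      if (a %in% annotations[[nm]]$gene_id) {
        return(attr(annotations[[nm]], "species_id"))
      }
    }
    abort(paste0("anchor not found in any annotation: ", a),
          class = "microsynteny_lookup_error")
  })
  species_of <- setNames(anchor_species, anchors)
  ann_by_species <- setNames(annotations,
                             map_chr(annotations, attr, "species_id"))

  regions <- setNames(
    map(anchors, function(a) extract_region(ann_by_species[[species_of[[a]]]],
                                            a, window = window)),
    anchors)

  # deterministic anchor order: species, chromosome, window start
  ord <- order(map_chr(regions, "species_id"), map_chr(regions, "chromosome"),
               map_dbl(regions, "window_start"), anchors)
  anchors <- anchors[ord]
  regions <- regions[ord]

  if (is.null(hits)) {
    region_gene_ids <- unique(unlist(map(regions, function(r) r$flanking$gene_id)))
    proteins <- unlist(map(ann_by_species, function(ann) {
      setNames(ann$protein, ann$gene_id)[intersect(ann$gene_id, region_gene_ids)]
    }), use.names = FALSE)
    names(proteins) <- unlist(map(ann_by_species, function(ann) {
      intersect(ann$gene_id, region_gene_ids)
    }), use.names = FALSE)
    db_size <- sum(map_dbl(ann_by_species, function(ann) sum(nchar(ann$protein))))
    # only gene pairs that can ever be compared: cross-region for some
    # anchor pair, or within-region (tandem detection)
    need <- list()
    for (i in seq_along(anchors)) {
      for (j in i:length(anchors)) {
        ga <- regions[[i]]$flanking$gene_id
        gb <- regions[[j]]$flanking$gene_id
        need[[length(need) + 1L]] <-
          tibble(query_id = rep(ga, each = length(gb)),
                 subject_id = rep(gb, times = length(ga)))
      }
    }
    need <- bind_rows(need) %>%
      filter(.data$query_id != .data$subject_id) %>%
      distinct()
    hits <- compute_hits(proteins, pairs = need, db_size = db_size)
  }

  blocks <- list()
  if (length(anchors) < 2L) return(structure(blocks, class = "synteny_blocks"))
  for (i in seq_len(length(anchors) - 1L)) {
    for (j in (i + 1L):length(anchors)) {
      ra <- regions[[i]]; rb <- regions[[j]]
      same_species <- ra$species_id == rb$species_id
      if (same_species && ra$chromosome == rb$chromosome &&
          ra$window_start <= rb$window_end && rb$window_start <= ra$window_end) {
        next  # overlapping windows: the region vs itself is not a duplication
      }
      thr <- if (same_species) within_evalue else between_evalue
      pairs <- match_regions(ra, rb, hits, thr)
      blk <- call_block(ra, rb, pairs, min_pairs = min_pairs,
                        count_anchor = count_anchor)
      if (is.null(blk)) next
      tp <- bind_rows(
        region_tandem_pairs(ra, hits, within_evalue, max_intervening),
        region_tandem_pairs(rb, hits, within_evalue, max_intervening)
      )
      blk$quality <- syntenic_quality(blk, tp)
      blk$conserved_microsynteny <- conserved_microsynteny_flag(blk)
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  structure(blocks, class = "synteny_blocks")
}

#' Tidy table of a block set
#'
#' @param blocks A `synteny_blocks` list.
#' @return Tibble, one row per block: anchors, species, scope, `n_pairs`,
#'   `orientation`, `quality`, `conserved_microsynteny`, and dating columns
#'   (`NA` unless [date_blocks()] has been applied).
#' @export
block_table <- function(blocks) {
  if (inherits(blocks, "synteny_block")) blocks <- list(blocks)
  if (length(blocks) == 0L) {
    return(tibble(anchor_a = character(), anchor_b = character(),
                  species_a = character(), species_b = character(),
                  scope = character(), n_pairs = integer(),
                  orientation = character(), quality = double(),
                  conserved_microsynteny = logical(),
                  mean_ks = double(), sd_ks = double(), date_mya = double()))
  }
  map(blocks, function(b) {
    tibble(
      anchor_a = b$region_a$anchor, anchor_b = b$region_b$anchor,
      species_a = b$region_a$species_id, species_b = b$region_b$species_id,
      scope = b$scope, n_pairs = as.integer(b$n_pairs),
      orientation = b$orientation, quality = b$quality,
      conserved_microsynteny = b$conserved_microsynteny,
      mean_ks = b$mean_ks %||% NA_real_,
      sd_ks = b$sd_ks %||% NA_real_,
      date_mya = b$date_mya %||% NA_real_
    )
  }) %>% list_rbind()
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("<synteny_blocks> ", length(x), " block(s)\n", sep = "")
  if (length(x)) print(block_table(x))
  invisible(x)
}
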