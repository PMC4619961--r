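# Molecular-clock dating of duplication events from synonymous distances:
# T = Ks / (2 * rate) * 1e-6 mya, grass silent-site rate 6.5e-9
# substitutions per synonymous site per year.

#' Convert a synonymous distance to a divergence date
#'
#' `T = Ks / (2 * rate) * 1e-6` million years.
#'
#' @param ks Synonymous distance (substitutions per synonymous site), >= 0.
#' @param rate Silent-site substitution rate per site per year (default
#'   `6.5e-9`, the grass clock).
#' @return Date in mya (full precision; report tables round to 4 decimals).
#' @export
date_from_ks <- function(ks, rate = 6.5e-9) {
  if (any(ks < 0, na.rm = TRUE)) {
    abort("ks must be nonnegative", class = "microsynteny_input_error")
  }
  if (any(rate <= 0)) {
    abort("rate must be positive", class = "microsynteny_input_error")
  }
  ks / (2 * rate) * 1e-6
}

#' Date a microsynteny block from its per-pair Ks estimates
#'
#' Saturated pairs (`Ks > 2`, at risk of multiple-hit saturation) are
#' excluded; the date is the clock conversion of the mean Ks of the rest,
#' with the sample (n-1) standard deviation reported alongside. A block
#' whose pairs are all saturated is returned undatable (`NA` fields) rather
#' than raising an error; a single usable pair gives sd 0 with a degenerate
#' flag.
#'
#' @param block A `synteny_block`.
#' @param estimates Tibble of per-pair `kaks_estimate` rows for the block's
#'   conserved pairs (columns `Ks`, `saturated`).
#' @param rate Clock rate (default `6.5e-9`).
#' @return One-row tibble: `anchor_a`, `anchor_b`, `n_pairs_used`,
#'   `n_saturated`, `mean_ks`, `sd_ks`, `date_mya`, `degenerate`.
#' @export
date_block <- function(block, estimates, rate = 6.5e-9) {
  usable <- estimates$Ks[!estimates$saturated & is.finite(estimates$Ks)]
  n_sat <- sum(estimates$saturated | !is.finite(estimates$Ks))
  if (length(usable) == 0L) {
    warn(paste0("block ", block$region_a$anchor, " & ", block$region_b$anchor,
                ": all pairs saturated, undatable"))
    return(tibble(anchor_a = block$region_a$anchor,
                  anchor_b = block$region_b$anchor,
                  n_pairs_used = 0L, n_saturated = n_sat,
                  mean_ks = NA_real_, sd_ks = NA_real_, date_mya = NA_real_,
                  degenerate = NA))
  }
  degenerate <- length(usable) == 1L
  if (degenerate) {
    warn("single usable pair: sd reported as 0 from a degenerate sample")
  }
  m <- mean(usable)
  tibble(anchor_a = block$region_a$anchor, anchor_b = block$region_b$anchor,
         n_pairs_used = length(usable), n_saturated = n_sat,
         mean_ks = m, sd_ks = if (degenerate) 0 else sd(usable),
         date_mya = date_from_ks(m, rate), degenerate = degenerate)
}

# CDS/protein lookup across a list of annotations
gene_lookup <- function(annotations) {
  if (inherits(annotations, "genome_annotation")) annotations <- list(annotations)
  all <- bind_rows(lapply(annotations, as_tibble))
  setNames(split(all[, c("cds", "protein")], seq_len(nrow(all))), all$gene_id)
}

#' Ka/Ks estimates for every conserved pair of a block
#'
#' @param block A `synteny_block`.
#' @param annotations Named list of [genome_annotation()]s holding the genes.
#' @return Tibble of `kaks_estimate` rows (one per conserved pair, anchor
#'   pair included).
#' @export
block_kaks <- function(block, annotations) {
  lk <- gene_lookup(annotations)
  map(seq_len(nrow(block$pairs)), function(r) {
    a <- block$pairs$gene_a[r]; b <- block$pairs$gene_b[r]
    kaks_pair(lk[[a]]$cds, lk[[b]]$cds, lk[[a]]$protein, lk[[b]]$protein,
              source_pair = c(a, b))
  }) %>% list_rbind()
}

#' Date every block of a block set
#'
#' Runs [block_kaks()] and [date_block()] per block and attaches `mean_ks`,
#' `sd_ks` and `date_mya` to each block (visible in [block_table()]).
#'
#' @param blocks A `synteny_blocks` list from [scan_all()].
#' @param annotations Named list of [genome_annotation()]s.
#' @param rate Clock rate (default `6.5e-9`).
#' @param flanking_only Use only non-anchor pairs for dating (default `TRUE`,
#'   the flanking-conserved-genes convention).
#' @return The block set with dating attached; the tidy dating table is in
#'   `attr(result, "dating")`.
#' @export
date_blocks <- function(blocks, annotations, rate = 6.5e-9,
                        flanking_only = TRUE) {
  rows <- list()
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    est <- block_kaks(b, annotations)
    if (flanking_only && any(!b$pairs$is_anchor_pair)) {
      est <- est[!b$pairs$is_anchor_pair, ]
    }
    d <- date_block(b, est, rate = rate)
    b$mean_ks <- d$mean_ks
    b$sd_ks <- d$sd_ks
    b$date_mya <- d$date_mya
    b$pair_ks <- est
    blocks[[k]] <- b
    rows[[k]] <- d
  }
  attr(blocks, "dating") <- list_rbind(rows)
  blocks
}
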