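# Genome-evolution simulator: multi-species genomes descended from a common
# ancestor with segmental/tandem duplications, inversions, gene losses and
# translocations planted at known times, and coding sequences diverged under
# a per-site Poisson substitution model with NG86 site classification
# (synonymous rate `syn_rate` per synonymous site per year, nonsynonymous
# rate `omega * syn_rate` per nonsynonymous site). Every derived gene maps
# to one ancestral gene; the full event history is recorded as truth.

#' Simulation configuration
#'
#' Three-species layout `((C, B) t_shallow, A) t_deep`: species A splits off
#' at `t_deep` mya, B and C at `t_shallow` mya.
#'
#' @param seed Integer seed (mandatory).
#' @param species Three species labels.
#' @param t_deep,t_shallow Split times in mya (defaults 60 and 15, the
#'   grass-family layout).
#' @param n_chromosomes,genes_per_chromosome Ancestral genome size.
#' @param mean_gene_length Mean gene length in codons (default 300).
#' @param intergenic_mean Mean intergenic gap in bp (default 9000,
#'   grass-like density of roughly one gene per 10 kb).
#' @param syn_rate Synonymous substitution rate per site per year (default
#'   `6.5e-9`).
#' @param omega dN/dS of the generating model (default 0.2, purifying).
#' @param n_anchors Number of ancestral CCCH-motif-bearing family genes.
#' @param events List of planted events; each a list with fields `type`
#'   (`segmental_duplication`, `tandem_duplication`, `inversion`,
#'   `gene_loss`, `translocation`), `lineage` (`"ancestor"` or a species
#'   label), `time` (mya), `anchor` (ancestral gene id the segment is
#'   centred on) or `genes`, `span` (segment size in genes),
#'   `dest_chromosome` where relevant, `fraction` for random loss.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              species = c("osa", "sbi", "zma"),
                              t_deep = 60, t_shallow = 15,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 60L,
                              mean_gene_length = 300L,
                              intergenic_mean = 9000,
                              syn_rate = 6.5e-9,
                              omega = 0.2,
                              n_anchors = 5L,
                              events = list()) {
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory", class = "microsynteny_config_error")
  }
  if (t_deep <= t_shallow || t_shallow <= 0) {
    abort("need t_deep > t_shallow > 0", class = "microsynteny_config_error")
  }
  if (syn_rate <= 0 || omega < 0) {
    abort("rates must be positive (omega >= 0)", class = "microsynteny_config_error")
  }
  structure(list(seed = as.integer(seed), species = species,
                 t_deep = t_deep, t_shallow = t_shallow,
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 mean_gene_length = as.integer(mean_gene_length),
                 intergenic_mean = intergenic_mean,
                 syn_rate = syn_rate, omega = omega,
                 n_anchors = as.integer(n_anchors), events = events),
            class = "simulation_config")
}

# ---- sequence generation ----------------------------------------------------

random_sense_codons <- function(n) {
  tab <- codon_tables()
  pool <- setdiff(tab$sense, codon_index("ATG"))   # ATG only where placed
  sample(pool, n, replace = TRUE)
}

# random codon encoding a given amino acid
aa_codon <- function(aa) {
  tab <- codon_tables()
  opts <- which(tab$aa == aa & !tab$is_stop)
  if (!length(opts)) abort(paste0("no codon for ", aa))
  if (length(opts) == 1L) opts else sample(opts, 1)
}

# CDS (integer codons) for an anchor gene: two CCCH motifs embedded in a
# random backbone
anchor_codons <- function(n_codons) {
  motif <- function() {
    spacer <- function(k) sample(setdiff(LETTERS[1:26], c("C", "H", "B", "J",
                                                          "O", "U", "X", "Z")),
                                 k, replace = TRUE)
    c("C", spacer(4), "C", spacer(4), "C", spacer(3), "H")
  }
  body_len <- n_codons - 1L
  m1 <- motif(); m2 <- motif()
  pad1 <- max(5L, floor((body_len - 2L * length(m1)) / 3))
  aa <- c(m1, rep(NA, pad1), m2)
  cods <- integer(0)
  for (x in aa) {
    cods <- c(cods, if (is.na(x)) random_sense_codons(1) else aa_codon(x))
  }
  fill <- body_len - length(cods)
  if (fill > 0) cods <- c(cods, random_sense_codons(fill))
  c(codon_index("ATG"), cods)
}

# ---- substitution process ---------------------------------------------------

# mutate integer codon vector over `years` of one lineage
evolve_codons <- function(codons, years, syn_rate, omega) {
  if (years <= 0) return(codons)
  tab <- codon_tables()
  S_tot <- sum(tab$S[codons])
  N_tot <- sum(tab$N[codons])
  n_syn <- rpois(1, syn_rate * years * S_tot)
  n_non <- rpois(1, omega * syn_rate * years * N_tot)
  classes <- sample(c(rep(TRUE, n_syn), rep(FALSE, n_non)))
  L <- length(codons)
  for (want_syn in classes) {
    for (try in 1:2000) {
      i <- sample.int(L, 1L)
      k <- sample.int(9L, 1L)
      cc <- codons[i]
      if (tab$mut_stop[cc, k]) next
      is_syn <- tab$mut_syn[cc, k]
      if (is_syn == want_syn) {
        codons[i] <- tab$mutants[cc, k]
        break
      }
    }
  }
  codons
}

#' Evolve a coding sequence along a branch
#'
#' Substitution events are drawn so that the expected number of synonymous
#' substitutions per synonymous site over the branch is `syn_rate * years`,
#' and nonsynonymous per nonsynonymous site is `omega * syn_rate * years`.
#' Substitutions that would create a stop codon are rejected and resampled;
#' multiple hits at a site are allowed.
#'
#' @param cds Stop-free coding sequence.
#' @param years Branch length in years.
#' @param syn_rate Synonymous rate per site per year.
#' @param omega dN/dS.
#' @param seed Optional seed (default: use the current RNG stream).
#' @return Diverged CDS string.
#' @export
evolve_sequence <- function(cds, years, syn_rate = 6.5e-9, omega = 0.2,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  codons_to_cds(evolve_codons(cds_to_codons(cds), years, syn_rate, omega))
}

# ---- genome state -----------------------------------------------------------

# internal state: one tibble row per gene; `pos` orders genes on a chromosome
ancestor_state <- function(config) {
  n_genes <- config$n_chromosomes * config$genes_per_chromosome
  # spread anchors across chromosomes, central-ish slots
  slots <- split(seq_len(n_genes),
                 rep(seq_len(config$n_chromosomes),
                     each = config$genes_per_chromosome))
  anchor_idx <- integer(0)
  per_chr <- ceiling(config$n_anchors / config$n_chromosomes)
  k <- 0L
  for (chr in seq_len(config$n_chromosomes)) {
    take <- min(per_chr, config$n_anchors - k)
    if (take <= 0) break
    at <- round(seq(0.3, 0.7, length.out = take) * config$genes_per_chromosome)
    anchor_idx <- c(anchor_idx, slots[[chr]][at])
    k <- k + take
  }
  lens <- pmax(60L, round(rnorm(n_genes, config$mean_gene_length,
                                config$mean_gene_length / 5)))
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    cods <- if (i %in% anchor_idx) anchor_codons(lens[i]) else
      c(codon_index("ATG"), random_sense_codons(lens[i] - 1L))
    rows[[i]] <- tibble(
      gene_id = sprintf("g%04d", i),
      ancestor_id = sprintf("g%04d", i),
      chain = "",
      chromosome = paste0("chr", (i - 1L) %/% config$genes_per_chromosome + 1L),
      pos = as.numeric((i - 1L) %% config$genes_per_chromosome + 1L),
      strand = sample(c("+", "-"), 1),
      is_anchor = i %in% anchor_idx,
      codons = list(cods)
    )
  }
  bind_rows(rows)
}

renumber_pos <- function(state) {
  state %>%
    arrange(.data$chromosome, .data$pos) %>%
    group_by(.data$chromosome) %>%
    mutate(pos = as.numeric(row_number())) %>%
    ungroup()
}

evolve_state <- function(state, years_my, syn_rate, omega) {
  years <- years_my * 1e6
  state$codons <- lapply(state$codons, evolve_codons, years = years,
                         syn_rate = syn_rate, omega = omega)
  state
}

segment_rows <- function(state, anchor, span) {
  ai <- which(state$ancestor_id == anchor |
                state$gene_id == anchor)
  if (!length(ai)) {
    abort(paste0("event references unknown gene: ", anchor),
          class = "microsynteny_config_error")
  }
  ai <- ai[1]
  chr <- state$chromosome[ai]
  on_chr <- which(state$chromosome == chr)
  on_chr <- on_chr[order(state$pos[on_chr])]
  at <- match(ai, on_chr)
  lo <- max(1L, at - floor((span - 1) / 2))
  hi <- min(length(on_chr), lo + span - 1L)
  lo <- max(1L, hi - span + 1L)
  on_chr[lo:hi]
}

apply_one_event <- function(state, ev, event_id, lineage) {
  type <- ev$type
  truth <- NULL
  if (type %in% c("segmental_duplication", "tandem_duplication", "inversion",
                  "translocation")) {
    idx <- segment_rows(state, ev$anchor, ev$span %||% 5L)
    idx <- idx[order(state$pos[idx])]
  }
  if (type == "segmental_duplication" || type == "tandem_duplication") {
    copies <- state[idx, ]
    copies$gene_id <- paste0(copies$gene_id, "x", event_id)
    copies$chain <- paste0(copies$chain, "|", event_id)
    if (type == "tandem_duplication") {
      base <- max(state$pos[idx])
      copies$pos <- base + seq_along(idx) / (length(idx) + 1)
    } else {
      chrs <- unique(state$chromosome)
      dest <- ev$dest_chromosome %||% sample(chrs, 1)
      dp <- state$pos[state$chromosome == dest]
      at <- if (length(dp)) sample(c(0, dp), 1) else 0
      copies$chromosome <- dest
      copies$pos <- at + seq_along(idx) / (length(idx) + 1)
    }
    truth <- tibble(event_id = event_id, type = type, lineage = lineage,
                    time = ev$time,
                    source_gene = state$gene_id[idx],
                    derived_gene = copies$gene_id)
    state <- bind_rows(state, copies)
  } else if (type == "inversion") {
    state$pos[idx] <- rev(state$pos[idx])
    state$strand[idx] <- ifelse(state$strand[idx] == "+", "-", "+")
    truth <- tibble(event_id = event_id, type = type, lineage = lineage,
                    time = ev$time,
                    source_gene = state$gene_id[idx],
                    derived_gene = state$gene_id[idx])
  } else if (type == "gene_loss") {
    if (!is.null(ev$genes)) {
      drop <- which(state$gene_id %in% ev$genes | state$ancestor_id %in% ev$genes)
    } else {
      cand <- which(!state$is_anchor)
      n_drop <- round((ev$fraction %||% 0.2) * length(cand))
      drop <- sample(cand, n_drop)
    }
    truth <- tibble(event_id = event_id, type = type, lineage = lineage,
                    time = ev$time,
                    source_gene = state$gene_id[drop],
                    derived_gene = NA_character_)
    if (length(drop)) state <- state[-drop, ]
  } else if (type == "translocation") {
    chrs <- setdiff(unique(state$chromosome), state$chromosome[idx[1]])
    dest <- ev$dest_chromosome %||% sample(chrs, 1)
    dp <- state$pos[state$chromosome == dest]
    at <- if (length(dp)) sample(c(0, dp), 1) else 0
    state$chromosome[idx] <- dest
    state$pos[idx] <- at + seq_along(idx) / (length(idx) + 1)
    truth <- tibble(event_id = event_id, type = type, lineage = lineage,
                    time = ev$time,
                    source_gene = state$gene_id[idx],
                    derived_gene = state$gene_id[idx])
  } else {
    abort(paste0("unknown event type: ", type), class = "microsynteny_config_error")
  }
  list(state = renumber_pos(state), truth = truth)
}

#' Apply structural events to an annotation
#'
#' Applies planted events (duplication, inversion, loss, translocation) to a
#' genome without sequence divergence, returning the modified annotation and
#' the truth records. Used directly in tests; [simulate_scenario()] applies
#' events along lineage branches with divergence interleaved.
#'
#' @param annotation A [genome_annotation()].
#' @param events List of event lists (see [simulation_config()]).
#' @param seed Optional seed.
#' @param intergenic_mean Mean intergenic gap for the re-layout.
#' @return List with `annotation` and `truth` (tibble of per-gene event
#'   records).
#' @export
apply_events <- function(annotation, events, seed = NULL, intergenic_mean = 9000) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  state <- annotation %>%
    as_tibble() %>%
    mutate(ancestor_id = .data$gene_id, chain = "",
           pos = NA_real_,
           is_anchor = FALSE,
           codons = lapply(.data$cds, cds_to_codons)) %>%
    group_by(.data$chromosome) %>%
    mutate(pos = rank(.data$start)) %>%
    ungroup() %>%
    select("gene_id", "ancestor_id", "chain", "chromosome", "pos", "strand",
           "is_anchor", "codons")
  truths <- list()
  for (k in seq_along(events)) {
    res <- apply_one_event(state, events[[k]], paste0("e", k), "direct")
    state <- res$state
    truths[[k]] <- res$truth
  }
  list(annotation = state_to_annotation(state, attr(annotation, "species_id"),
                                        intergenic_mean),
       truth = bind_rows(truths))
}

state_to_annotation <- function(state, species_id, intergenic_mean) {
  state <- renumber_pos(state)
  state$len_bp <- 3L * vapply(state$codons, length, integer(1))
  out <- state %>%
    mutate(gap = 200 + rgeom(n(), 1 / intergenic_mean))
  # cumulative layout per chromosome: geometric gaps, genes never overlap
  starts <- numeric(nrow(out))
  for (chr in unique(out$chromosome)) {
    rows <- which(out$chromosome == chr)
    at <- 0
    for (r in rows) {
      at <- at + out$gap[r]
      starts[r] <- at
      at <- at + out$len_bp[r]
    }
  }
  out$start <- starts
  out$end <- starts + out$len_bp - 1
  chrom_len <- tapply(out$end + 1000, out$chromosome, max)
  genes <- out %>%
    mutate(cds = vapply(.data$codons, codons_to_cds, character(1)),
           species_id = species_id) %>%
    select("gene_id", "species_id", "chromosome", "start", "end", "strand",
           "cds")
  ann <- genome_annotation(genes,
                           chromosomes = setNames(as.numeric(chrom_len),
                                                  names(chrom_len)),
                           species_id = species_id)
  attr(ann, "state") <- out %>%
    select("gene_id", "ancestor_id", "chain", "is_anchor")
  ann
}

# ---- full scenario ----------------------------------------------------------

# evolve a lineage from `from` to `to` mya, applying its events on the way
run_lineage <- function(state, from, to, events, lineage, config, counter) {
  evs <- purrr::keep(events, function(e) {
    identical(e$lineage, lineage) && e$time <= from && e$time > to
  })
  times <- map_dbl(evs, "time")
  ord <- order(-times)
  evs <- evs[ord]
  t_now <- from
  truths <- list()
  for (e in evs) {
    state <- evolve_state(state, t_now - e$time, config$syn_rate, config$omega)
    counter$n <- counter$n + 1L
    res <- apply_one_event(state, e, paste0("e", counter$n), lineage)
    state <- res$state
    truths[[length(truths) + 1L]] <- res$truth
    t_now <- e$time
  }
  state <- evolve_state(state, t_now - to, config$syn_rate, config$omega)
  list(state = state, truth = bind_rows(truths))
}

#' Simulate a full multi-species scenario
#'
#' Builds the ancestral genome, applies ancestral events, splits lineages at
#' the configured times with per-lineage events, and returns per-species
#' annotations plus the complete truth. With `out_dir` set, writes per
#' species a CDS FASTA, a protein FASTA and a GFF3, plus TSV truth tables.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory.
#' @return List of class `synteny_simulation`: `annotations` (named list of
#'   [genome_annotation()]), `genes` (tibble mapping every simulated gene to
#'   its species, ancestral gene and duplication chain), `events` (truth
#'   records), `anchors` (named list of per-species anchor gene ids),
#'   `config`.
#' @export
simulate_scenario <- function(config, out_dir = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  sp <- config$species
  t_root <- max(c(config$t_deep + 10,
                  map_dbl(config$events, function(e) e$time %||% 0) + 1))

  anc <- ancestor_state(config)
  r0 <- run_lineage(anc, t_root, config$t_deep, config$events, "ancestor",
                    config, counter)
  rA <- run_lineage(r0$state, config$t_deep, 0, config$events, sp[1],
                    config, counter)
  rBC <- run_lineage(r0$state, config$t_deep, config$t_shallow, config$events,
                     "inner", config, counter)
  rB <- run_lineage(rBC$state, config$t_shallow, 0, config$events, sp[2],
                    config, counter)
  rC <- run_lineage(rBC$state, config$t_shallow, 0, config$events, sp[3],
                    config, counter)

  finalize <- function(res, species) {
    st <- res$state
    st$gene_id <- paste0(species, "_", st$gene_id)
    state_to_annotation(st, species, config$intergenic_mean)
  }
  anns <- list(finalize(rA, sp[1]), finalize(rB, sp[2]), finalize(rC, sp[3]))
  names(anns) <- sp

  genes <- bind_rows(lapply(anns, function(a) {
    s <- attr(a, "state")
    tibble(gene_id = s$gene_id, species = attr(a, "species_id"),
           ancestor_id = s$ancestor_id, chain = s$chain,
           is_anchor = s$is_anchor)
  }))
  anchors <- lapply(anns, function(a) {
    s <- attr(a, "state")
    s$gene_id[s$is_anchor]
  })
  events <- bind_rows(r0$truth, rA$truth, rBC$truth, rB$truth, rC$truth)

  sim <- structure(
    list(annotations = anns, genes = genes, events = events,
         anchors = anchors, config = config),
    class = "synteny_simulation"
  )
  if (!is.null(out_dir)) write_scenario(sim, out_dir)
  sim
}

#' @export
print.synteny_simulation <- function(x, ...) {
  cat("<synteny_simulation> ", length(x$annotations), " species, ",
      nrow(x$genes), " genes, ", nrow(x$events), " event record rows\n",
      sep = "")
  invisible(x)
}

#' Write a simulated scenario to disk
#'
#' @param sim A `synteny_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (species in names(sim$annotations)) {
    ann <- sim$annotations[[species]]
    write_fasta(setNames(ann$cds, ann$gene_id),
                file.path(dir, paste0(species, ".cds.fasta")))
    write_fasta(setNames(ann$protein, ann$gene_id),
                file.path(dir, paste0(species, ".protein.fasta")))
    write_gff(ann, file.path(dir, paste0(species, ".gff3")))
  }
  readr::write_tsv(sim$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$events, file.path(dir, "truth_events.tsv"))
  writeLines(unlist(sim$anchors), file.path(dir, "anchors.txt"))
  invisible(dir)
}

#' True divergence time between two simulated genes
#'
#' Two genes sharing an ancestral gene diverged at the species split time or
#' at the time of the first duplication event distinguishing their copy
#' chains, whichever is older. Expected Ks is `2 * rate * time`.
#'
#' @param sim A `synteny_simulation`.
#' @param gene_a,gene_b Simulated gene ids.
#' @return Divergence time in mya, or `NA` when the genes are unrelated.
#' @export
true_divergence <- function(sim, gene_a, gene_b) {
  g <- sim$genes
  ra <- g[g$gene_id == gene_a, ]; rb <- g[g$gene_id == gene_b, ]
  if (nrow(ra) == 0L || nrow(rb) == 0L) {
    abort("unknown gene id", class = "microsynteny_lookup_error")
  }
  if (ra$ancestor_id != rb$ancestor_id) return(NA_real_)
  split_time <- if (ra$species == rb$species) 0 else {
    two <- c(ra$species, rb$species)
    if (sim$config$species[1] %in% two) sim$config$t_deep else sim$config$t_shallow
  }
  ca <- strsplit(sub("^\\|", "", ra$chain), "\\|")[[1]]
  cb <- strsplit(sub("^\\|", "", rb$chain), "\\|")[[1]]
  ca <- ca[nzchar(ca)]; cb <- cb[nzchar(cb)]
  k <- 0L
  while (k < min(length(ca), length(cb)) && ca[k + 1L] == cb[k + 1L]) k <- k + 1L
  dup_time <- 0
  if (length(ca) > k || length(cb) > k) {
    evs <- c(if (length(ca) > k) ca[k + 1L], if (length(cb) > k) cb[k + 1L])
    times <- sim$events$time[match(evs, sim$events$event_id)]
    dup_time <- max(times, na.rm = TRUE)
  }
  max(split_time, dup_time)
}

#' Expected microsynteny blocks from the planted truth
#'
#' For every unordered anchor pair, counts the one-to-one gene pairs sharing
#' an ancestral gene between the two windows, excluding the anchor-anchor
#' pairing itself (anchors may still pair with non-anchor homologs, exactly
#' as in the scan's flanking-pair rule); pairs of regions with at least
#' `min_pairs` such pairs are the expected blocks. This is the
#' ancestry-based ground truth the sequence-based [scan_all()] is compared
#' against. Anchor pairs with overlapping windows are skipped, mirroring the
#' scan.
#'
#' @param sim A `synteny_simulation`.
#' @param window Flank size in bp (default 100,000).
#' @param min_pairs Minimum shared-ancestry flanking pairs (default 3).
#' @return Tibble: `anchor_a`, `anchor_b`, `n_true_pairs`, `expected_block`.
#' @export
true_blocks <- function(sim, window = 1e5, min_pairs = 3L) {
  all_anchors <- unlist(sim$anchors, use.names = FALSE)
  sp_of <- setNames(rep(names(sim$anchors),
                        lengths(sim$anchors)), all_anchors)
  regions <- lapply(all_anchors, function(a) {
    extract_region(sim$annotations[[sp_of[[a]]]], a, window = window)
  })
  names(regions) <- all_anchors
  amap <- setNames(sim$genes$ancestor_id, sim$genes$gene_id)
  rows <- list()
  n <- length(all_anchors)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ra <- regions[[i]]; rb <- regions[[j]]
      if (ra$species_id == rb$species_id && ra$chromosome == rb$chromosome &&
          ra$window_start <= rb$window_end && rb$window_start <= ra$window_end) {
        next
      }
      # one-to-one ancestor matching over the full windows (anchors may pair
      # with non-anchor homologs), minus the anchor-anchor pairing itself --
      # the same counting rule the scan applies
      ua <- table(amap[ra$flanking$gene_id])
      ub <- table(amap[rb$flanking$gene_id])
      shared <- intersect(names(ua), names(ub))
      n_true <- sum(pmin(ua[shared], ub[shared]))
      if (identical(amap[[ra$anchor]], amap[[rb$anchor]])) {
        n_true <- n_true - 1L
      }
      rows[[length(rows) + 1L]] <- tibble(
        anchor_a = all_anchors[i], anchor_b = all_anchors[j],
        n_true_pairs = n_true,
        expected_block = n_true >= min_pairs
      )
    }
  }
  bind_rows(rows)
}

#' Paper-like simulation preset
#'
#' Three grass-like species splitting at 60 and 15 mya, five planted
#' segmental-duplication groups (flanking segment sizes spanning the 5-17
#' gene range), a burst of recent within-species duplications, one
#' inversion and one translocation. `with_loss` adds 20% random gene loss
#' in every terminal lineage.
#'
#' @param seed Integer seed.
#' @param with_loss Add 20% random gene loss per terminal lineage.
#' @return A [simulation_config()].
#' @export
paper_like_config <- function(seed, with_loss = FALSE) {
  # anchors g0018, g0030, g0042 on chr1; g0078, g0102 on chr2
  events <- list(
    list(type = "segmental_duplication", lineage = "ancestor", time = 70,
         anchor = "g0018", span = 5, dest_chromosome = "chr2"),
    list(type = "segmental_duplication", lineage = "osa", time = 40,
         anchor = "g0030", span = 7, dest_chromosome = "chr2"),
    list(type = "segmental_duplication", lineage = "zma", time = 12,
         anchor = "g0042", span = 10, dest_chromosome = "chr2"),
    list(type = "segmental_duplication", lineage = "sbi", time = 10,
         anchor = "g0078", span = 13, dest_chromosome = "chr1"),
    list(type = "segmental_duplication", lineage = "zma", time = 14,
         anchor = "g0102", span = 17, dest_chromosome = "chr1"),
    list(type = "inversion", lineage = "zma", time = 8,
         anchor = "g0042", span = 6),
    list(type = "translocation", lineage = "osa", time = 20,
         anchor = "g0065", span = 4)
  )
  if (with_loss) {
    events <- c(events, list(
      list(type = "gene_loss", lineage = "osa", time = 5, fraction = 0.2),
      list(type = "gene_loss", lineage = "sbi", time = 5, fraction = 0.2),
      list(type = "gene_loss", lineage = "zma", time = 5, fraction = 0.2)
    ))
  }
  simulation_config(
    seed = seed, species = c("osa", "sbi", "zma"),
    t_deep = 60, t_shallow = 15,
    n_chromosomes = 2L, genes_per_chromosome = 60L,
    mean_gene_length = 300L, intergenic_mean = 9000,
    syn_rate = 6.5e-9, omega = 0.2, n_anchors = 5L,
    events = events
  )
}

#' Simulate the ancestral genome only
#'
#' @param config A [simulation_config()].
#' @return A [genome_annotation()] (CDS in the `cds` column); the anchor ids
#'   are in `attr(, "state")`.
#' @export
simulate_ancestor <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  state_to_annotation(ancestor_state(config), "ancestor",
                      config$intergenic_mean)
}
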