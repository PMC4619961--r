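# Pairwise protein similarity: exact global alignment (BLOSUM62, affine
# gaps) plus a Karlin-Altschul surrogate E-value, so that synthetic or
# desk-scale data can satisfy the same E-value thresholds as externally
# computed tabular hits. Also the match rules the synteny scan relies on:
# best nonself-match and tandem-duplicate detection.

#' Global protein alignment under BLOSUM62 with affine gaps
#'
#' Optimal Needleman-Wunsch alignment; a gap of length L costs
#' `gap_open + gap_extend * L`.
#'
#' @param a,b Protein sequences (no gaps).
#' @param gap_open,gap_extend Gap penalties (defaults 11 and 1).
#' @return List of class `alignment_result`: `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `score`, `identity` (fraction of identical
#'   columns among columns with no gap).
#' @export
align_global <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", class = "microsynteny_input_error")
  }
  ok <- "^[ACDEFGHIKLMNPQRSTVWYXBZ*]+$"
  if (!grepl(ok, toupper(a)) || !grepl(ok, toupper(b))) {
    abort("illegal residue character", class = "microsynteny_input_error")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  nongap <- ca != "-" & cb != "-"
  identity <- if (any(nongap)) mean(ca[nongap] == cb[nongap]) else 0
  structure(
    list(aligned_a = al_a, aligned_b = al_b,
         score = Biostrings::score(pa), identity = identity),
    class = "alignment_result"
  )
}

#' Karlin-Altschul surrogate E-value for an alignment score
#'
#' `E = K * m * n_db * exp(-lambda * S)` with fixed gapped-BLOSUM62 constants
#' (lambda = 0.267, K = 0.041). A documented surrogate that lets internal
#' alignments be filtered with the same thresholds as external hits; it is
#' not calibrated against any particular search tool.
#'
#' @param score Alignment score.
#' @param len_a Query length (aa).
#' @param len_b Subject length (aa); with `db_size` given, `len_b` is
#'   ignored in favour of the database size.
#' @param db_size Total database size in aa (default `len_b`).
#' @param lambda,K Karlin-Altschul constants.
#' @return Surrogate E-value (nonnegative, monotone decreasing in score).
#' @export
score_to_surrogate_evalue <- function(score, len_a, len_b,
                                      db_size = len_b,
                                      lambda = 0.267, K = 0.041) {
  if (any(len_a < 1) || any(len_b < 1)) {
    abort("sequence lengths must be >= 1", class = "microsynteny_input_error")
  }
  K * len_a * db_size * exp(-lambda * score)
}

#' Best nonself-match of a gene under an E-value threshold
#'
#' Among hits with the gene as query, a different subject, and
#' `e_value <= threshold`: the lowest E-value wins; ties broken by highest
#' score, then lexicographic subject id.
#'
#' @param gene Query gene id.
#' @param hits Hit tibble (`query_id`, `subject_id`, `score`, `e_value`, ...).
#' @param threshold E-value cutoff (e.g. `1e-10` within species, `1e-20`
#'   between species).
#' @return One-row tibble, or `NULL` when no hit qualifies.
#' @export
best_nonself_match <- function(gene, hits, threshold = 1e-10) {
  h <- hits %>%
    filter(.data$query_id == gene,
           .data$subject_id != gene,
           .data$e_value <= threshold)
  if (nrow(h) == 0L) return(NULL)
  h %>%
    arrange(.data$e_value, desc(.data$score), .data$subject_id) %>%
    slice(1)
}

#' Detect tandem-duplicate pairs in a gene family
#'
#' Two family members on the same chromosome separated by at most
#' `max_intervening` non-family genes form a tandem pair. Consecutive family
#' genes chain (three in a row give two pairs, not three).
#'
#' @param annotation A [genome_annotation()].
#' @param family Gene ids of the family.
#' @param max_intervening Maximum number of intervening non-family genes
#'   (default 1, operationalizing "same or neighbouring intergenic regions").
#' @return Tibble `gene_a`, `gene_b` (smaller coordinate first), `chromosome`,
#'   `n_intervening`.
#' @export
detect_tandem <- function(annotation, family, max_intervening = 1L) {
  missing_ids <- setdiff(family, annotation$gene_id)
  if (length(missing_ids)) {
    abort(paste0("family id(s) not in annotation: ",
                 paste(missing_ids, collapse = ", ")),
          class = "microsynteny_lookup_error")
  }
  out <- list()
  for (chr in unique(annotation$chromosome)) {
    g <- annotation[annotation$chromosome == chr, ]     # already sorted by start
    fam_pos <- which(g$gene_id %in% family)
    if (length(fam_pos) < 2L) next
    for (k in seq_len(length(fam_pos) - 1L)) {
      i <- fam_pos[k]; j <- fam_pos[k + 1L]
      if (j - i - 1L <= max_intervening) {
        out[[length(out) + 1L]] <- tibble(
          gene_a = g$gene_id[i], gene_b = g$gene_id[j],
          chromosome = chr, n_intervening = j - i - 1L
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  chromosome = character(), n_intervening = integer()))
  }
  bind_rows(out)
}

# ---- internal hit generation ------------------------------------------------

# shared 5-mer seeding: cheap prefilter so only plausibly homologous pairs
# reach the full dynamic-programming alignment
protein_kmers <- function(protein, k = 5L) {
  n <- nchar(protein)
  if (n < k) return(character())
  unique(substring(protein, 1:(n - k + 1L), k:n))
}

#' Compute pairwise protein hits internally
#'
#' All-vs-all (or query-set-vs-subject-set) surrogate hit table built from
#' exact global alignments. Pairs sharing fewer than `min_seed_kmers`
#' 5-mers are skipped without alignment (seeding, as in word-based search
#' tools); homologous proteins at the divergences this package targets share
#' dozens.
#'
#' @param proteins Named character vector of protein sequences.
#' @param pairs Optional two-column matrix/tibble of (query, subject) id
#'   pairs to evaluate; default all ordered nonself pairs.
#' @param db_size Database size in aa for the surrogate E-value (default sum
#'   of all protein lengths).
#' @param min_seed_kmers Seeding threshold (default 3).
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return Hit tibble (`query_id`, `subject_id`, `score`, `e_value`,
#'   `identity`), both directions included for evaluated pairs.
#' @export
compute_hits <- function(proteins, pairs = NULL, db_size = NULL,
                         min_seed_kmers = 3L, gap_open = 11, gap_extend = 1) {
  ids <- names(proteins)
  if (is.null(db_size)) db_size <- sum(nchar(proteins))
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
    pairs <- tibble(query_id = ids[idx[, 1]], subject_id = ids[idx[, 2]])
  } else {
    pairs <- as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("query_id", "subject_id")
    pairs <- pairs %>% filter(.data$query_id != .data$subject_id)
    # evaluate each unordered pair once
    key <- ifelse(pairs$query_id < pairs$subject_id,
                  paste(pairs$query_id, pairs$subject_id),
                  paste(pairs$subject_id, pairs$query_id))
    pairs <- pairs[!duplicated(key), ]
  }
  kmers <- lapply(proteins, protein_kmers)
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    qa <- pairs$query_id[r]; sb <- pairs$subject_id[r]
    shared <- sum(kmers[[qa]] %in% kmers[[sb]])
    if (shared < min_seed_kmers) next
    al <- align_global(proteins[[qa]], proteins[[sb]],
                       gap_open = gap_open, gap_extend = gap_extend)
    ev <- score_to_surrogate_evalue(al$score, nchar(proteins[[qa]]),
                                    nchar(proteins[[sb]]), db_size = db_size)
    rows[[r]] <- tibble(query_id = qa, subject_id = sb,
                        score = al$score, e_value = ev, identity = al$identity)
  }
  half <- bind_rows(compact(rows))
  if (nrow(half) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  score = double(), e_value = double(), identity = double()))
  }
  flipped <- half %>%
    select(query_id = "subject_id", subject_id = "query_id",
           "score", "e_value", "identity")
  bind_rows(half, flipped) %>% reduce_hits()
}
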