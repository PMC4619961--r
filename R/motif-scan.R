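# CCCH zinc-finger motif detection: C-X(4-15)-C-X(4-6)-C-X(3)-H.
# X (unknown residue) never matches the C/H positions but may fill spacers.

#' Find CCCH zinc-finger motifs in a protein
#'
#' Scans left to right for the motif C-X4-15-C-X4-6-C-X3-H. At each position
#' where at least one valid spacing exists, the match with the smallest total
#' span is reported (smallest first spacer, then smallest second); matches
#' are non-overlapping, taken greedily left to right.
#'
#' @param protein Amino-acid string (20-letter alphabet plus X).
#' @return Tibble with one row per motif: `start`, `end` (1-based inclusive
#'   aa positions), spacers `x1`, `x2`, `x3`.
#' @export
find_ccch_motifs <- function(protein) {
  empty <- tibble(start = integer(), end = integer(),
                  x1 = integer(), x2 = integer(), x3 = integer())
  if (is.na(protein) || nchar(protein) == 0L) return(empty)
  aa <- strsplit(toupper(protein), "")[[1]]
  n <- length(aa)
  is_c <- aa == "C"
  is_h <- aa == "H"
  hits <- list()
  i <- 1L
  while (i <= n) {
    if (!is_c[i]) { i <- i + 1L; next }
    cand <- list()
    for (x1 in 4:15) {
      p2 <- i + x1 + 1L
      if (p2 > n || !is_c[p2]) next
      for (x2 in 4:6) {
        p3 <- p2 + x2 + 1L
        p4 <- p3 + 4L                      # x3 fixed at 3
        if (p4 > n) next
        if (is_c[p3] && is_h[p4]) {
          cand[[length(cand) + 1L]] <- c(x1 = x1, x2 = x2, end = p4)
        }
      }
    }
    found <- NULL
    if (length(cand)) {
      m <- do.call(rbind, cand)
      # smallest total span, ties by smallest x1 then x2
      o <- order(m[, "x1"] + m[, "x2"], m[, "x1"], m[, "x2"])[1]
      found <- list(start = i, end = unname(m[o, "end"]),
                    x1 = unname(m[o, "x1"]), x2 = unname(m[o, "x2"]), x3 = 3L)
    }
    if (is.null(found)) {
      i <- i + 1L
    } else {
      hits[[length(hits) + 1L]] <- found
      i <- found$end + 1L                  # greedy non-overlap
    }
  }
  if (!length(hits)) return(empty)
  bind_rows(lapply(hits, as_tibble)) %>%
    mutate(across(c("start", "end", "x1", "x2", "x3"), as.integer))
}

#' Count CCCH motifs per gene
#'
#' @param annotation A [genome_annotation()] with a `protein` column.
#' @return Tibble `gene_id`, `n_motifs`.
#' @export
count_domains <- function(annotation) {
  tibble(
    gene_id = annotation$gene_id,
    n_motifs = vapply(annotation$protein,
                      function(p) nrow(find_ccch_motifs(p)), integer(1),
                      USE.NAMES = FALSE)
  )
}

#' Select anchor genes for synteny scanning
#'
#' Anchors seed the 100-kb microsynteny windows. Either pass an explicit id
#' list (e.g. a published subfamily membership), which is used verbatim, or a
#' minimum CCCH motif count.
#'
#' @param annotation A [genome_annotation()].
#' @param min_domains Minimum motif count (used when `id_list` is `NULL`).
#' @param id_list Optional explicit gene ids; wins over `min_domains`.
#' @return Character vector of anchor gene ids.
#' @export
select_anchors <- function(annotation, min_domains = 2L, id_list = NULL) {
  if (!is.null(id_list)) {
    missing_ids <- setdiff(id_list, annotation$gene_id)
    if (length(missing_ids)) {
      abort(paste0("anchor id(s) not in annotation: ",
                   paste(missing_ids, collapse = ", ")),
            class = "microsynteny_lookup_error")
    }
    return(id_list)
  }
  if (is.null(min_domains) || min_domains < 1L) {
    abort("min_domains must be >= 1 when no id_list is given",
          class = "microsynteny_input_error")
  }
  counts <- count_domains(annotation)
  counts$gene_id[counts$n_motifs >= min_domains]
}
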