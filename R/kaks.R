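# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, codon-alignment
# construction by back-translation of a protein alignment, and the
# sliding-window selection-pressure profile.

#' Back-translate a protein alignment to a codon alignment
#'
#' Each gapless aligned protein column is mapped to its codon in both coding
#' sequences; columns with a gap on either side, codons containing ambiguous
#' bases, and stop codons are dropped. The CDS translations must match the
#' ungapped aligned proteins.
#'
#' @param alignment An `alignment_result` from [align_global()], or a list
#'   with `aligned_a`/`aligned_b` gapped protein strings.
#' @param cds_a,cds_b Coding sequences of the two genes (a trailing stop is
#'   tolerated).
#' @param source_pair Optional `c(gene_a, gene_b)` labels.
#' @return List of class `codon_alignment`: `codons_a`, `codons_b` (equal
#'   length character vectors of sense codons), `source_pair`.
#' @export
back_translate <- function(alignment, cds_a, cds_b, source_pair = c(NA, NA)) {
  pa <- strsplit(alignment$aligned_a, "")[[1]]
  pb <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(pa) != length(pb)) {
    abort("aligned rows differ in length", class = "microsynteny_contract_error")
  }
  check_one <- function(aligned, cds, label) {
    prot <- paste(aligned[aligned != "-"], collapse = "")
    tr <- translate_cds(cds)
    if (tr != prot) {
      d <- which(strsplit(tr, "")[[1]] != strsplit(prot, "")[[1]])[1]
      abort(paste0("CDS ", label, " does not translate to its aligned protein",
                   " (first mismatch at aa ", d %||% NA, ")"),
            class = "microsynteny_consistency_error")
    }
  }
  check_one(pa, cds_a, "a")
  check_one(pb, cds_b, "b")
  tab <- codon_tables()
  ia <- ib <- 0L
  ka <- kb <- character()
  for (col in seq_along(pa)) {
    ga <- pa[col] == "-"; gb <- pb[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) next
    ca <- substr(cds_a, 3L * ia - 2L, 3L * ia)
    cb <- substr(cds_b, 3L * ib - 2L, 3L * ib)
    xa <- codon_index(ca); xb <- codon_index(cb)
    if (is.na(xa) || is.na(xb)) next            # ambiguous base
    if (tab$is_stop[xa] || tab$is_stop[xb]) next
    ka <- c(ka, ca); kb <- c(kb, cb)
  }
  structure(list(codons_a = ka, codons_b = kb, source_pair = source_pair),
            class = "codon_alignment")
}

# convenience: codon alignment straight from two equal-length gapless CDS
codon_alignment_from_cds <- function(cds_a, cds_b, source_pair = c(NA, NA)) {
  al <- list(aligned_a = translate_cds(cds_a), aligned_b = translate_cds(cds_b))
  back_translate(al, cds_a, cds_b, source_pair)
}

#' NG86 synonymous/nonsynonymous site counts of a codon
#'
#' Per position, the fraction of the single-nucleotide changes that are
#' synonymous, with changes to stop codons excluded from the denominator;
#' summed over the three positions. `S + N = 3` for every sense codon.
#'
#' @param codon 3-letter sense codon.
#' @return Named numeric `c(S = ..., N = ...)`.
#' @export
ng86_site_count <- function(codon) {
  tab <- codon_tables()
  i <- codon_index(codon)
  if (is.na(i) || tab$is_stop[i]) {
    abort(paste0("not a sense codon: ", codon), class = "microsynteny_input_error")
  }
  c(S = tab$S[i], N = tab$N[i])
}

#' NG86 synonymous/nonsynonymous difference counts between two codons
#'
#' Zero to three differing positions; with more than one difference the
#' classification is averaged over all orderings of single-step mutation
#' paths, excluding paths through stop codons (all paths are used if every
#' path is blocked by a stop). `syn + nonsyn` equals the number of differing
#' positions.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric `c(Sd = ..., Nd = ...)`.
#' @export
ng86_diff_count <- function(codon_a, codon_b) {
  tab <- codon_tables()
  ia <- codon_index(codon_a); ib <- codon_index(codon_b)
  if (is.na(ia) || tab$is_stop[ia] || is.na(ib) || tab$is_stop[ib]) {
    abort("inputs must be sense codons", class = "microsynteny_input_error")
  }
  a <- strsplit(toupper(codon_a), "")[[1]]
  b <- strsplit(toupper(codon_b), "")[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))

  paths <- if (k == 1L) list(diff_pos) else
    lapply(asplit(permutations_of(diff_pos), 1), as.integer)
  tot_s <- tot_n <- 0
  n_valid <- 0L
  for (ord in paths) {
    cur <- a
    s <- nn <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      i1 <- codon_index(paste(cur, collapse = ""))
      i2 <- codon_index(paste(nxt, collapse = ""))
      if (tab$is_stop[i2]) { ok <- FALSE; break }
      if (tab$aa[i1] == tab$aa[i2]) s <- s + 1 else nn <- nn + 1
      cur <- nxt
    }
    if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + nn; n_valid <- n_valid + 1L }
  }
  if (n_valid == 0L) {
    # degenerate: every path passes a stop; fall back to all paths
    for (ord in paths) {
      cur <- a
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        i1 <- codon_index(paste(cur, collapse = ""))
        i2 <- codon_index(paste(nxt, collapse = ""))
        if (tab$aa[i1] == tab$aa[i2]) tot_s <- tot_s + 1 else tot_n <- tot_n + 1
        cur <- nxt
      }
    }
    n_valid <- length(paths)
  }
  c(Sd = tot_s / n_valid, Nd = tot_n / n_valid)
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1, 1))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out[[i]] <- cbind(x[i], rest)
  }
  do.call(rbind, out)
}

# Jukes-Cantor multiple-hit correction; p >= 3/4 is uncorrectable (Inf)
jc_correct <- function(p) {
  ifelse(p >= 0.75, Inf, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Site counts are averaged between the two sequences; proportions
#' `pS = Sd/S`, `pN = Nd/N` receive the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`. Estimates with `Ks > 2` (or an
#' uncorrectable proportion) are flagged saturated; the ratio is `NA` when
#' `Ks` is 0.
#'
#' @param ca A `codon_alignment`.
#' @return A `kaks_estimate` (one-row tibble subclass) with columns `gene_a`,
#'   `gene_b`, `n_codons`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`,
#'   `ratio`, `saturated`.
#' @export
ng86_kaks <- function(ca) {
  tab <- codon_tables()
  if (length(ca$codons_a) < 1L) {
    abort("codon alignment is empty", class = "microsynteny_input_error")
  }
  ia <- vapply(ca$codons_a, codon_index, integer(1), USE.NAMES = FALSE)
  ib <- vapply(ca$codons_b, codon_index, integer(1), USE.NAMES = FALSE)
  S <- (sum(tab$S[ia]) + sum(tab$S[ib])) / 2
  N <- (sum(tab$N[ia]) + sum(tab$N[ib])) / 2
  d <- mapply(function(x, y) ng86_diff_count(x, y),
              ca$codons_a, ca$codons_b)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  saturated <- !is.finite(Ks) || Ks > 2.0
  ratio <- if (is.finite(Ks) && Ks > 0 && is.finite(Ka)) Ka / Ks else NA_real_
  out <- tibble(
    gene_a = as.character(ca$source_pair[1]),
    gene_b = as.character(ca$source_pair[2]),
    n_codons = length(ca$codons_a),
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    Ks = Ks, Ka = Ka, ratio = ratio, saturated = saturated
  )
  class(out) <- c("kaks_estimate", class(out))
  out
}

#' NG86 Ka/Ks straight from a gene pair
#'
#' Aligns the two proteins globally, back-translates to codons and runs
#' [ng86_kaks()].
#'
#' @param cds_a,cds_b Coding sequences.
#' @param protein_a,protein_b Optional proteins (derived from the CDS when
#'   missing).
#' @param source_pair Gene id labels.
#' @return A `kaks_estimate`.
#' @export
kaks_pair <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL,
                      source_pair = c(NA, NA)) {
  pa <- protein_a %||% translate_cds(cds_a)
  pb <- protein_b %||% translate_cds(cds_b)
  al <- align_global(pa, pb)
  ca <- back_translate(al, cds_a, cds_b, source_pair)
  ng86_kaks(ca)
}

#' Sliding-window Ka/Ks profile along a codon alignment
#'
#' Windows of `window` bp advanced by `step` bp (defaults 150/9, both must be
#' divisible by 3 to preserve codon integrity) on the ungapped codon
#' alignment; each window is scored with [ng86_kaks()]. Windows with `Ks` 0
#' carry an `NA` ratio. An alignment shorter than one window yields a single
#' whole-length window flagged short.
#'
#' @param ca A `codon_alignment`.
#' @param window Window size in bp (default 150).
#' @param step Step size in bp (default 9).
#' @return Tibble of class `kaks_profile`: `start`, `end` (bp on the ungapped
#'   alignment), `Ka`, `Ks`, `ratio`, `short`.
#' @export
sliding_window <- function(ca, window = 150L, step = 9L) {
  if (window %% 3L != 0L || step %% 3L != 0L) {
    abort("window and step must be divisible by 3",
          class = "microsynteny_input_error")
  }
  len_bp <- 3L * length(ca$codons_a)
  sub_est <- function(from_bp, to_bp) {
    ci <- ((from_bp - 1L) %/% 3L + 1L):(to_bp %/% 3L)
    est <- ng86_kaks(structure(list(codons_a = ca$codons_a[ci],
                                    codons_b = ca$codons_b[ci],
                                    source_pair = ca$source_pair),
                               class = "codon_alignment"))
    tibble(start = from_bp, end = to_bp, Ka = est$Ka, Ks = est$Ks,
           ratio = est$ratio)
  }
  if (len_bp < window) {
    out <- sub_est(1L, len_bp) %>% mutate(short = TRUE)
  } else {
    starts <- seq(1L, len_bp - window + 1L, by = step)
    out <- map(starts, function(s) sub_est(s, s + window - 1L)) %>%
      list_rbind() %>%
      mutate(short = FALSE)
  }
  class(out) <- c("kaks_profile", class(out))
  out
}
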