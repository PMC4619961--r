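# Codon machinery shared by the NG86 estimator and the sequence simulator.
#
# Codons are indexed 1..64 with base order A,C,G,T:
#   index = 16*(b1-1) + 4*(b2-1) + b3, bases coded A=1, C=2, G=3, T=4.
# All per-codon quantities (amino acid, NG86 site fractions, single-base
# mutant table) are precomputed once at load time.

.NUC <- c("A", "C", "G", "T")

codon_index <- function(codon) {
  b <- match(strsplit(codon, "")[[1]], .NUC)
  if (anyNA(b) || length(b) != 3L) return(NA_integer_)
  16L * (b[1] - 1L) + 4L * (b[2] - 1L) + b[3]
}

codon_string <- function(idx) {
  b1 <- (idx - 1L) %/% 16L
  b2 <- ((idx - 1L) %/% 4L) %% 4L
  b3 <- (idx - 1L) %% 4L
  paste0(.NUC[b1 + 1L], .NUC[b2 + 1L], .NUC[b3 + 1L])
}

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- vapply(1:64, codon_string, character(1))
  aa <- unname(gc[codons])           # "*" marks stops
  is_stop <- aa == "*"

  # mutants[i, k]: codon index after applying mutation k (k = 3*(pos-1)+alt,
  # alt in 1..3 enumerating the three non-identity bases at that position)
  mutants <- matrix(NA_integer_, 64, 9)
  for (i in 1:64) {
    b <- c((i - 1L) %/% 16L, ((i - 1L) %/% 4L) %% 4L, (i - 1L) %% 4L) + 1L
    k <- 0L
    for (pos in 1:3) {
      for (alt in setdiff(1:4, b[pos])) {
        k <- k + 1L
        nb <- b
        nb[pos] <- alt
        mutants[i, k] <- 16L * (nb[1] - 1L) + 4L * (nb[2] - 1L) + nb[3]
      }
    }
  }
  mut_aa <- matrix(aa[mutants], 64, 9)
  mut_stop <- matrix(is_stop[mutants], 64, 9)
  mut_syn <- mut_aa == matrix(aa, 64, 9) & !mut_stop
  mut_pos <- matrix(rep(rep(1:3, each = 3), each = 64), 64, 9)

  # NG86 fractional site counts: per position, fraction of non-stop
  # single-base changes that are synonymous; S + N = 3 per sense codon.
  S <- N <- rep(NA_real_, 64)
  for (i in which(!is_stop)) {
    s <- 0
    for (pos in 1:3) {
      k <- 3L * (pos - 1L) + 1:3
      valid <- !mut_stop[i, k]
      s <- s + if (any(valid)) sum(mut_syn[i, k][valid]) / sum(valid) else 0
    }
    S[i] <- s
    N[i] <- 3 - s
  }

  .codon_env$tab <- list(
    codons = codons, aa = aa, is_stop = is_stop,
    mutants = mutants, mut_syn = mut_syn, mut_stop = mut_stop,
    mut_pos = mut_pos, S = S, N = N,
    sense = which(!is_stop)
  )
  .codon_env$tab
}

#' Translate a coding sequence
#'
#' Standard genetic code; a single trailing stop codon is removed. Codons
#' containing ambiguous bases translate to `X`.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param strip_stop Drop a trailing stop codon (default `TRUE`).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, strip_stop = TRUE) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    abort("CDS length must be divisible by 3", class = "microsynteny_input_error")
  }
  tab <- codon_tables()
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  idx <- vapply(cods, codon_index, integer(1), USE.NAMES = FALSE)
  aa <- ifelse(is.na(idx), "X", tab$aa[idx])
  if (strip_stop && length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# integer codon vector <-> nucleotide string
cds_to_codons <- function(cds) {
  cds <- toupper(cds)
  cods <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  vapply(cods, codon_index, integer(1), USE.NAMES = FALSE)
}

codons_to_cds <- function(idx) paste(vapply(idx, codon_string, character(1)), collapse = "")

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
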