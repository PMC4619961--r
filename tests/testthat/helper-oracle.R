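# Independent brute-force oracles, built directly on Biostrings::GENETIC_CODE
# with plain string manipulation (no shared code with the package internals).

.ORACLE_GC <- as.list(Biostrings::GENETIC_CODE)
.ORACLE_BASES <- c("A", "C", "G", "T")

oracle_is_sense <- function(codon) {
  aa <- .ORACLE_GC[[codon]]
  !is.null(aa) && aa != "*"
}

all_sense_codons <- function() {
  cods <- names(.ORACLE_GC)
  cods[vapply(cods, function(cc) .ORACLE_GC[[cc]] != "*", logical(1))]
}

# NG86 fractional site counts: per position, the fraction of the three
# single-base changes that is synonymous, with stop-creating changes removed
# from the denominator; S + N = 3.
oracle_site_count <- function(codon) {
  cc <- strsplit(codon, "")[[1]]
  aa0 <- .ORACLE_GC[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    valid <- 0L
    for (b in setdiff(.ORACLE_BASES, cc[pos])) {
      alt <- cc
      alt[pos] <- b
      aa1 <- .ORACLE_GC[[paste(alt, collapse = "")]]
      if (aa1 == "*") next
      valid <- valid + 1L
      if (aa1 == aa0) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(S = s, N = 3 - s)
}

# NG86 difference counts: average over all orderings of the differing
# positions, dropping orderings that pass through a stop codon (all
# orderings are kept if every one is blocked).
oracle_diff_count <- function(codon_a, codon_b) {
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  dp <- which(a != b)
  if (length(dp) == 0L) return(c(Sd = 0, Nd = 0))
  orderings <- switch(
    as.character(length(dp)),
    "1" = list(dp),
    "2" = list(dp, rev(dp)),
    "3" = lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                 function(o) dp[o])
  )
  walk <- function(ord) {
    cur <- a
    s <- n <- 0L
    hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- .ORACLE_GC[[paste(cur, collapse = "")]]
      aa2 <- .ORACLE_GC[[paste(nxt, collapse = "")]]
      if (aa2 == "*") hit_stop <- TRUE
      if (aa1 == aa2) s <- s + 1L else n <- n + 1L
      cur <- nxt
    }
    c(s = s, n = n, stop = as.integer(hit_stop))
  }
  res <- t(vapply(orderings, walk, c(s = 0L, n = 0L, stop = 0L)))
  keep <- res[, "stop"] == 0L
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  c(Sd = mean(res[keep, "s"]), Nd = mean(res[keep, "n"]))
}

# closed-form sliding-window count
oracle_window_count <- function(len_bp, window, step) {
  if (len_bp < window) 1L else as.integer((len_bp - window) %/% step + 1L)
}
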