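# Protein phylogeny the classic way: Poisson-corrected distances with
# pairwise deletion, neighbor-joining, and nonparametric bootstrap support.

#' Poisson-corrected distance between two aligned protein rows
#'
#' Pairwise deletion drops columns where either row has a gap or X;
#' `p = mismatches / retained columns`, `d = -ln(1 - p)`.
#'
#' @param a,b Equal-length gapped amino-acid strings.
#' @return Distance (Inf, flagged by warning, when p = 1).
#' @export
poisson_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb)) {
    abort("aligned rows differ in length", class = "microsynteny_input_error")
  }
  valid <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  if (!any(valid)) {
    abort("no shared ungapped columns", class = "microsynteny_input_error")
  }
  p <- mean(ca[valid] != cb[valid])
  if (p >= 1) {
    warn("saturated pair (p = 1): distance is infinite")
    return(Inf)
  }
  -log(1 - p)
}

#' Poisson distance matrix for an alignment
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @return Symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
poisson_dist_matrix <- function(alignment) {
  n <- length(alignment)
  taxa <- names(alignment) %||% paste0("t", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- poisson_distance(alignment[[i]], alignment[[j]])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}); negative branch-length
#' estimates are clamped to 0 with a warning.
#'
#' @param dm Symmetric distance matrix (>= 3 taxa, finite entries) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3L) {
    abort("need at least 3 taxa", class = "microsynteny_input_error")
  }
  if (any(!is.finite(dm))) {
    abort("distance matrix has non-finite entries",
          class = "microsynteny_input_error")
  }
  tr <- ape::nj(stats::as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warn("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

# per-pair column equality/validity masks, reused across bootstrap replicates
pairwise_masks <- function(alignment) {
  A <- do.call(rbind, strsplit(toupper(alignment), ""))
  bad <- A == "-" | A == "X"
  n <- nrow(A)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  E <- matrix(FALSE, nrow(idx), ncol(A))
  V <- matrix(FALSE, nrow(idx), ncol(A))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    V[r, ] <- !bad[i, ] & !bad[j, ]
    E[r, ] <- V[r, ] & A[i, ] == A[j, ]
  }
  list(idx = idx, E = E, V = V, n = n)
}

dist_from_masks <- function(m, cols, taxa) {
  ret <- rowSums(m$V[, cols, drop = FALSE])
  mism <- ret - rowSums(m$E[, cols, drop = FALSE])
  p <- ifelse(ret > 0, mism / ret, 0)
  p <- pmin(p, 1 - 1e-9)                     # keep NJ input finite
  d <- matrix(0, m$n, m$n, dimnames = list(taxa, taxa))
  d[m$idx] <- -log(1 - p)
  d[m$idx[, c(2, 1)]] <- d[m$idx]
  d
}

#' NJ tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the
#' Poisson-distance NJ tree per replicate, and labels each internal node of
#' the original tree with the percentage of replicates containing its
#' bipartition. Reproducible for a fixed seed.
#'
#' @param alignment Named character vector of equal-length gapped rows.
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @return A `phylo` tree with `node.label` holding support in \[0, 100\].
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 42L) {
  taxa <- names(alignment) %||% paste0("t", seq_along(alignment))
  names(alignment) <- taxa
  m <- pairwise_masks(alignment)
  L <- ncol(m$E)
  main <- nj_tree(dist_from_masks(m, seq_len(L), taxa))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boots <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[r]] <- nj_tree(dist_from_masks(m, cols, taxa))
  }
  class(boots) <- "multiPhylo"
  counts <- suppressWarnings(ape::prop.clades(main, boots, rooted = FALSE))
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / replicates, 1)
  main
}

#' Bootstrap support of the bipartition separating a tip set
#'
#' @param tree A `phylo` with numeric `node.label` supports.
#' @param tips Tip labels on one side of the bipartition.
#' @return Support in \[0, 100\], or `NA` if the tree has no edge inducing
#'   that bipartition.
#' @export
bipartition_support <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  all_tips <- tree$tip.label
  want <- sort(match(tips, all_tips))
  comp <- sort(setdiff(seq_along(all_tips), want))
  for (k in seq_along(parts)) {
    got <- sort(parts[[k]])
    if (identical(got, want) || identical(got, comp)) {
      lbl <- tree$node.label[k]
      return(suppressWarnings(as.numeric(lbl)))
    }
  }
  NA_real_
}

#' Write a tree with support labels to Newick
#' @param tree A `phylo`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
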