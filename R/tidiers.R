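# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a block set
#' @param x A `synteny_blocks` list.
#' @param ... Unused.
#' @return One row per block (see [block_table()]).
#' @method tidy synteny_blocks
#' @export
tidy.synteny_blocks <- function(x, ...) block_table(x)

#' One-row summary of a block set
#' @param x A `synteny_blocks` list.
#' @param ... Unused.
#' @return Tibble with block counts by scope and dating coverage.
#' @method glance synteny_blocks
#' @export
glance.synteny_blocks <- function(x, ...) {
  tab <- block_table(x)
  tibble(
    n_blocks = nrow(tab),
    n_within = sum(tab$scope == "within-species"),
    n_between = sum(tab$scope == "between-species"),
    n_dated = sum(!is.na(tab$date_mya)),
    median_pairs = stats::median(tab$n_pairs)
  )
}

#' Tidy a single block
#' @param x A `synteny_block`.
#' @param ... Unused.
#' @return The conserved-pair tibble with anchors attached.
#' @method tidy synteny_block
#' @export
tidy.synteny_block <- function(x, ...) {
  x$pairs %>%
    mutate(anchor_a = x$region_a$anchor, anchor_b = x$region_b$anchor)
}

#' Tidy a Ka/Ks estimate
#' @param x A `kaks_estimate`.
#' @param ... Unused.
#' @return The estimate as a plain tibble.
#' @method tidy kaks_estimate
#' @export
tidy.kaks_estimate <- function(x, ...) as_tibble(x)

#' Tidy a sliding-window profile
#' @param x A `kaks_profile`.
#' @param ... Unused.
#' @return The window tibble.
#' @method tidy kaks_profile
#' @export
tidy.kaks_profile <- function(x, ...) as_tibble(x)

#' One-row summary of a sliding-window profile
#' @param x A `kaks_profile`.
#' @param ... Unused.
#' @return Window count and Ka/Ks range.
#' @method glance kaks_profile
#' @export
glance.kaks_profile <- function(x, ...) {
  tibble(
    n_windows = nrow(x),
    min_ratio = suppressWarnings(min(x$ratio, na.rm = TRUE)),
    max_ratio = suppressWarnings(max(x$ratio, na.rm = TRUE)),
    frac_purifying = mean(x$ratio < 1, na.rm = TRUE)
  )
}

#' Tidy a pipeline result
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The dated block table.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$block_table

#' One-row summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Counts of anchors, blocks, dated blocks and purifying pairs.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    n_species = length(x$annotations),
    n_anchors = length(x$anchors),
    n_blocks = length(x$blocks),
    n_dated = sum(!is.na(x$block_table$date_mya)),
    frac_pairs_purifying = mean(x$pair_kaks$ratio < 1, na.rm = TRUE)
  )
}
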