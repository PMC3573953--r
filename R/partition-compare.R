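#' Compare two partitions pair by pair
#'
#' All cross-partition logic in this package is pairwise: for every
#' unordered pair of specimens the two partitions either both split it,
#' both lump it, or conflict.  A pair is classified *no data* when
#' either member is in the no-data state in either partition.  The
#' adjusted Rand index is computed on the doubly-covered subset.
#'
#' @param p,q Partitions over the same specimen universe.
#' @return A list with `adjusted_rand`, `pairs_split_agree`,
#'   `pairs_lump_agree`, `pairs_conflict`, `pairs_nodata`.
#' @examples
#' p <- new_partition(c(a = "1", b = "1", c = "2"), "m1")
#' q <- new_partition(c(a = "x", b = "x", c = "y"), "m2")
#' compare_partitions(p, q)$adjusted_rand
#' @export
compare_partitions <- function(p, q) {
  ids <- names(p$assignment)
  if (!setequal(ids, names(q$assignment)))
    stop("partitions cover different specimen universes")
  ids <- sort(ids)
  pa <- p$assignment[ids]
  qa <- q$assignment[ids]
  n <- length(ids)
  if (n < 2L)
    return(list(adjusted_rand = NA_real_, pairs_split_agree = 0L,
                pairs_lump_agree = 0L, pairs_conflict = 0L,
                pairs_nodata = 0L))
  same_p <- outer(pa, pa, "==")
  same_q <- outer(qa, qa, "==")
  up <- upper.tri(same_p)
  nodata <- is.na(same_p) | is.na(same_q)
  lump <- !nodata & same_p & same_q
  splitb <- !nodata & !same_p & !same_q
  confl <- !nodata & (same_p != same_q)
  keep <- !is.na(pa) & !is.na(qa)
  ari <- if (sum(keep) >= 2L)
    mclust::adjustedRandIndex(pa[keep], qa[keep]) else NA_real_
  list(adjusted_rand = ari,
       pairs_split_agree = sum(splitb[up]),
       pairs_lump_agree = sum(lump[up]),
       pairs_conflict = sum(confl[up]),
       pairs_nodata = sum(nodata[up]))
}

#' Adjusted Rand index between two partitions
#'
#' Convenience wrapper around [compare_partitions()].
#' @param p,q Partitions over the same specimen universe.
#' @return Numeric ARI on the doubly-covered subset (1 means identical
#'   grouping).
#' @export
partition_ari <- function(p, q) compare_partitions(p, q)$adjusted_rand
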