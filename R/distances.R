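#' Distance model parameters
#'
#' Settings for pairwise distance computation.  `p` is the uncorrected
#' proportion of differing sites; `JC69` and `K80` apply the usual
#' one- and two-parameter corrections.  Site handling defaults to
#' pairwise deletion (each pair is compared on the sites where both
#' sequences are determined), which keeps per-pair information maximal;
#' ambiguity codes default to being excluded like missing data.
#'
#' @param model `"p"`, `"JC69"` or `"K80"`.
#' @param site_handling `"pairwise_deletion"` or `"complete_deletion"`.
#' @param ambiguity_policy `"exclude_site"` (IUPAC ambiguity codes are
#'   treated as missing) or `"mismatch"` (they are compared literally;
#'   a literal mismatch involving an ambiguity code counts as a
#'   transversion under K80).
#' @param saturation `"infinite"` (default): pairs whose corrected
#'   distance is undefined (e.g. p >= 0.75 under JC69) are reported as
#'   `Inf` with a warning, so threshold clustering still works;
#'   `"error"`: such a pair is an error naming the pair.
#' @return A list of class `dist_params`.
#' @export
dist_params <- function(model = c("p", "JC69", "K80"),
                        site_handling = c("pairwise_deletion",
                                          "complete_deletion"),
                        ambiguity_policy = c("exclude_site", "mismatch"),
                        saturation = c("infinite", "error")) {
  structure(list(model = match.arg(model),
                 site_handling = match.arg(site_handling),
                 ambiguity_policy = match.arg(ambiguity_policy),
                 saturation = match.arg(saturation)),
            class = "dist_params")
}

# internal constructor for the distance-matrix container
new_dist_matrix <- function(values, model, site_handling) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("distance matrix must carry specimen ids")
  fin <- values[is.finite(values)]
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("distance matrix is not symmetric")
  diag(values) <- 0
  if (any(fin < 0)) stop("negative distances")
  structure(list(specimen_ids = rownames(values), values = values,
                 model = model, site_handling = site_handling),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d specimens, model %s (%s)\n",
              length(x$specimen_ids), x$model, x$site_handling))
  invisible(x)
}

#' Pairwise distance matrix from an alignment
#'
#' For each pair, `p` = mismatches / comparable sites; `JC69` applies
#' d = -(3/4) log(1 - 4p/3); `K80` uses the transition/transversion
#' closed form d = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q)).  Saturated
#' pairs (undefined logarithm) are reported as `Inf` with a warning by
#' default (see [dist_params()]).
#'
#' @param aln A [marker_alignment()].
#' @param params A [dist_params()] object.
#' @return A `dist_matrix` object (symmetric, zero diagonal).
#' @examples
#' aln <- marker_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAACC"), "toy")
#' distance_matrix(aln, dist_params("p"))$values["a", "b"]   # 0.2
#' @export
distance_matrix <- function(aln, params = dist_params()) {
  m <- aln$seq
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  determined <- if (params$ambiguity_policy == "exclude_site")
    matrix(m %in% DETERMINED_BASES, n) else m != "-"
  if (params$site_handling == "complete_deletion") {
    keep <- colSums(determined) == n
    if (!any(keep)) stop("complete deletion removed every site")
    m <- m[, keep, drop = FALSE]
    determined <- determined[, keep, drop = FALSE]
  }
  D <- determined * 1
  shared <- tcrossprod(D)
  # matches: sites where both sequences carry the same determined state
  chars <- if (params$ambiguity_policy == "exclude_site")
    DETERMINED_BASES else setdiff(unique(as.vector(m)), "-")
  ind <- lapply(chars, function(b) (m == b & determined) * 1)
  names(ind) <- chars
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  off <- upper.tri(shared)
  if (any(shared[off] == 0)) {
    w <- which(shared == 0 & off, arr.ind = TRUE)[1L, ]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 rownames(m)[w[1L]], rownames(m)[w[2L]]))
  }
  mism <- shared - matches
  p <- mism / shared
  d <- p
  if (params$model == "JC69") {
    d <- ifelse(p < 0.75, -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.xmin)), Inf)
    d[p >= 0.75] <- Inf
  } else if (params$model == "K80") {
    has <- function(b) if (b %in% names(ind)) ind[[b]] else
      matrix(0, n, ncol(m))
    ts <- tcrossprod(has("A"), has("G")) + tcrossprod(has("G"), has("A")) +
      tcrossprod(has("C"), has("T")) + tcrossprod(has("T"), has("C"))
    P <- ts / shared
    Q <- (mism - ts) / shared
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    d <- ifelse(a1 > 0 & a2 > 0, -0.5 * log(a1 * sqrt(a2)), Inf)
  }
  diag(d) <- 0
  if (any(is.infinite(d[off]))) {
    if (params$saturation == "error") {
      w <- which(is.infinite(d) & off, arr.ind = TRUE)[1L, ]
      stop(sprintf("saturated pair under %s: '%s' vs '%s'", params$model,
                   rownames(m)[w[1L]], rownames(m)[w[2L]]))
    }
    warning(sprintf("%d pair(s) saturated under %s; reported as Inf",
                    sum(is.infinite(d[off])), params$model))
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  new_dist_matrix(d, params$model, params$site_handling)
}

#' Single-linkage threshold clustering
#'
#' Clusters are the connected components of the graph with an edge
#' wherever distance <= `threshold` (single linkage: chaining below the
#' cutoff).  Cluster labels are deterministic: each cluster is labelled
#' by its lexicographically smallest member id.
#'
#' @param dm A `dist_matrix`.
#' @param threshold Nonnegative distance cutoff (same scale as the
#'   matrix, i.e. a fraction such as 0.11 for 11%).
#' @return A [new_partition()] with method `"threshold"`.
#' @export
threshold_cluster <- function(dm, threshold, linkage = "single") {
  stopifnot(threshold >= 0, identical(linkage, "single"))
  comp <- components_below(dm$values, threshold, inclusive = TRUE)
  new_partition(label_components(comp), method = "threshold",
                parameters = list(threshold = threshold, linkage = "single",
                                  model = dm$model))
}

# connected components of the graph with edges d <= t (inclusive) or
# d < t (exclusive); returns integer membership named by specimen id
components_below <- function(values, t, inclusive = TRUE) {
  adj <- if (inclusive) values <= t else values < t
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  names(memb) <- rownames(values)
  memb
}

# deterministic labels: smallest member id per component
label_components <- function(memb) {
  ids <- names(memb)
  lab <- vapply(split(ids, memb), function(v) min(v), "")
  out <- lab[as.character(memb)]
  names(out) <- ids
  out
}

#' Intra- and inter-cluster distance summaries
#'
#' Given a partition, reports the largest intracluster distance per
#' cluster, and the smallest and mean intercluster distances, mirroring
#' the intra-/interspecific p-distance summaries used to diagnose a
#' barcoding gap.  Specimens in the no-data state are excluded.  Empty
#' categories (e.g. all clusters singletons) are reported as absent,
#' not zero.
#'
#' @param dm A `dist_matrix`.
#' @param part A partition covering the matrix specimens.
#' @return A list of class `distance_summary` with
#'   `per_cluster_max_intra` (named numeric), `overall_min_inter`,
#'   `overall_mean_inter`, `min_inter_pair` (the two cluster labels
#'   achieving the minimum), and `n_intra_pairs`/`n_inter_pairs`.
#' @export
distance_summary <- function(dm, part) {
  a <- part$assignment[dm$specimen_ids]
  if (anyNA(names(a)) || length(a) != length(dm$specimen_ids))
    stop("partition does not cover the matrix specimens")
  keep <- !is.na(a)
  ids <- dm$specimen_ids[keep]
  a <- a[keep]
  v <- dm$values[ids, ids, drop = FALSE]
  same <- outer(a, a, "==")
  up <- upper.tri(v)
  intra <- up & same
  inter <- up & !same
  per_cluster <- sapply(split(seq_along(ids), a), function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    max(v[idx, idx][upper.tri(v[idx, idx])])
  })
  per_cluster <- per_cluster[!is.na(per_cluster)]
  min_inter <- mean_inter <- NA_real_
  min_pair <- c(NA_character_, NA_character_)
  if (any(inter)) {
    min_inter <- min(v[inter])
    mean_inter <- mean(v[inter])
    w <- which(inter & v == min_inter, arr.ind = TRUE)[1L, ]
    min_pair <- sort(c(a[w[1L]], a[w[2L]]))
  }
  structure(list(per_cluster_max_intra = if (length(per_cluster))
                   per_cluster else NULL,
                 overall_min_inter = min_inter,
                 overall_mean_inter = mean_inter,
                 min_inter_pair = min_pair,
                 n_intra_pairs = sum(intra), n_inter_pairs = sum(inter)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary>\n")
  if (!is.null(x$per_cluster_max_intra))
    cat(sprintf("  max intra: %.4f (cluster %s)\n",
                max(x$per_cluster_max_intra),
                names(which.max(x$per_cluster_max_intra))))
  else cat("  no intracluster pairs (all clusters singletons)\n")
  if (!is.na(x$overall_min_inter))
    cat(sprintf("  min inter: %.4f (%s vs %s); mean inter: %.4f\n",
                x$overall_min_inter, x$min_inter_pair[1L],
                x$min_inter_pair[2L], x$overall_mean_inter))
  invisible(x)
}

#' Threshold agreement range of a partition
#'
#' The maximal interval of thresholds `t` for which single-linkage
#' clustering at `t` reproduces the given partition: the lower bound is
#' the largest within-cluster single-linkage merge height, the upper
#' bound the smallest between-cluster distance.  The interval is closed
#' at the lower end and open at the upper end; an empty result means no
#' threshold reproduces the partition.
#'
#' @param dm A `dist_matrix`.
#' @param part A partition over the matrix specimens (no-data specimens
#'   are ignored).
#' @return Numeric `c(lower, upper)`, or `numeric(0)` if empty.
#' @export
agreement_range <- function(dm, part) {
  a <- part$assignment[dm$specimen_ids]
  keep <- !is.na(a)
  ids <- dm$specimen_ids[keep]
  a <- a[keep]
  v <- dm$values[ids, ids, drop = FALSE]
  t_low <- 0
  for (idx in split(seq_along(ids), a)) {
    if (length(idx) < 2L) next
    sub <- v[idx, idx, drop = FALSE]
    h <- stats::hclust(stats::as.dist(sub), method = "single")
    t_low <- max(t_low, max(h$height))
  }
  same <- outer(a, a, "==")
  inter <- upper.tri(v) & !same
  if (!any(inter)) return(c(t_low, Inf))
  t_high <- min(v[inter])
  if (t_low >= t_high) return(numeric(0))
  c(t_low, t_high)
}
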