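#' ABGD scan settings
#'
#' Settings for automatic barcode gap discovery.  `P` is the prior
#' limit to intraspecific divergence: a candidate gap must end above
#' `P` (gaps lying entirely below `P` are intraspecific by assumption).
#' `X` is the relative gap width: a rank gap qualifies when its width
#' exceeds `X` times the mean gap width over the surrounding rank
#' window.
#'
#' @param P_min,P_max Bounds of the prior scan, `0 < P_min < P_max < 1`.
#' @param n_priors Number of log-spaced priors in the scan.
#' @param X Relative gap width (the study setting that recovers the
#'   published partitions is 1.2; the ABGD default is 1.5).
#' @param window Rank window half-width for the local mean gap; default
#'   `max(3, n_pairs/50)` is chosen at run time when `NULL`.
#' @return A list of class `abgd_settings`.
#' @export
abgd_settings <- function(P_min = 0.001, P_max = 0.20, n_priors = 20L,
                          X = 1.5, window = NULL) {
  stopifnot(P_min > 0, P_min < P_max, P_max < 1, X > 0, n_priors >= 1)
  structure(list(P_min = P_min, P_max = P_max, n_priors = as.integer(n_priors),
                 X = X, window = window),
            class = "abgd_settings")
}

#' Detect a barcoding gap in ranked pairwise distances
#'
#' Scores every consecutive rank gap of the ascending distance vector
#' by its width relative to the mean width of the other gaps in the
#' surrounding rank window.  A gap qualifies when (a) it ends above
#' the prior `P` (gaps entirely below `P` are intraspecific by
#' assumption) and (b) its width exceeds `X` times the local mean;
#' the midpoint of the *most* significant qualifying gap (largest
#' width-to-local-mean ratio) is returned, or `NULL` when no gap
#' qualifies (no barcoding gap).
#'
#' @param sorted_distances Ascending numeric vector of pairwise
#'   distances (at least 2).
#' @param P Prior limit to intraspecific divergence.
#' @param X Relative gap width factor.
#' @param window Rank window half-width; `NULL` for the default
#'   `max(3, length/50)`.
#' @return The gap midpoint (numeric) or `NULL`.
#' @examples
#' detect_gap(c(0.01, 0.02, 0.03, 0.30, 0.31), P = 0.05, X = 1.5)
#' @export
detect_gap <- function(sorted_distances, P, X, window = NULL) {
  d <- sorted_distances
  n <- length(d)
  if (n < 2L) stop("need at least 2 distances")
  if (is.unsorted(d)) stop("distances must be sorted ascending")
  if (is.null(window)) window <- max(3L, n %/% 50L)
  cand <- gap_candidates(d, P, X, window)
  if (!nrow(cand)) return(NULL)
  cand$mid[1L]
}

# all qualifying gaps, most significant first
gap_candidates <- function(d, P, X, window) {
  n <- length(d)
  g <- diff(d)
  mid <- ratio <- numeric(0)
  for (i in seq_len(n - 1L)) {
    if (d[i + 1L] <= P) next        # gap entirely below the prior
    if (g[i] <= 0) next
    idx <- setdiff(seq(max(1L, i - window), min(n - 1L, i + window)), i)
    mu <- if (length(idx)) mean(g[idx]) else 0
    # an all-tied window (quantised distances) carries no local scale;
    # fall back to the global mean gap so tie-edges do not dominate
    if (mu <= 0) mu <- mean(g)
    r <- if (mu > 0) g[i] / mu else Inf
    if (r > X) {
      mid <- c(mid, (d[i] + d[i + 1L]) / 2)
      ratio <- c(ratio, r)
    }
  }
  o <- order(-ratio, mid)
  data.frame(mid = mid[o], ratio = ratio[o])
}

#' ABGD partition at one prior
#'
#' The initial split takes the single-linkage components below the
#' detected gap; the same gap detection is then applied recursively
#' within each component on its sub-distances until no further gap is
#' found.  When no gap exists at the top level the result is a single
#' cluster (the "no barcoding gap" outcome).
#'
#' @param dm A `dist_matrix`.
#' @param P Prior limit to intraspecific divergence.
#' @param settings An [abgd_settings()] object (supplies `X` and the
#'   rank window).
#' @param max_depth Recursion safety cap.
#' @return A [new_partition()] with method `"abgd"`.
#' @export
abgd_partition <- function(dm, P = 0.01, settings = abgd_settings(),
                           max_depth = 20L) {
  ids <- dm$specimen_ids
  v <- dm$values
  assign_rec <- function(sub_ids, depth) {
    if (length(sub_ids) < 3L || depth > max_depth) {
      if (depth > max_depth)
        warning("ABGD recursion depth cap reached; component kept whole")
      return(list(sub_ids))
    }
    sub <- v[sub_ids, sub_ids, drop = FALSE]
    d <- sort(sub[upper.tri(sub)])
    d <- d[is.finite(d)]
    if (length(d) < 2L) return(list(sub_ids))
    window <- if (is.null(settings$window))
      max(3L, length(d) %/% 50L) else settings$window
    cand <- gap_candidates(d, P, settings$X, window)
    # single-linkage chaining can bridge a rank gap; take the most
    # significant gap that actually disconnects the component
    for (gap in cand$mid) {
      memb <- components_below(sub, gap, inclusive = FALSE)
      comps <- split(sub_ids, memb)
      if (length(comps) >= 2L)
        return(unlist(lapply(comps, assign_rec, depth = depth + 1L),
                      recursive = FALSE))
    }
    list(sub_ids)
  }
  groups <- assign_rec(ids, 1L)
  a <- rep(NA_character_, length(ids))
  names(a) <- ids
  for (grp in groups) a[grp] <- min(grp)
  new_partition(a, method = "abgd",
                parameters = list(P = P, X = settings$X, model = dm$model))
}

#' Scan ABGD over a range of priors
#'
#' Runs [abgd_partition()] at each of `n_priors` log-spaced priors
#' between `P_min` and `P_max`, groups identical partitions, and
#' reports the prior range over which each distinct partition is
#' stable.  Partitions are expected to coarsen (or stay equal) as the
#' prior grows; violations of that monotonicity are flagged, not
#' silently dropped.
#'
#' @param dm A `dist_matrix`.
#' @param settings An [abgd_settings()].
#' @return A list of class `abgd_scan`: `per_prior` (data.frame with
#'   `P`, `n_groups`, `partition_id`), `partitions` (one representative
#'   partition per distinct grouping), `stable_groups` (data.frame with
#'   `partition_id`, `n_groups`, `P_min`, `P_max`), and
#'   `monotone` (logical flag).
#' @export
prior_scan <- function(dm, settings = abgd_settings()) {
  priors <- exp(seq(log(settings$P_min), log(settings$P_max),
                    length.out = settings$n_priors))
  parts <- lapply(priors, function(P) abgd_partition(dm, P, settings))
  sigs <- vapply(parts, partition_signature, "")
  pid <- match(sigs, unique(sigs))
  per_prior <- data.frame(P = priors,
                          n_groups = vapply(parts, n_clusters, 0L),
                          partition_id = pid)
  reps <- parts[!duplicated(pid)]
  stable <- do.call(rbind, lapply(unique(pid), function(k) {
    data.frame(partition_id = k,
               n_groups = n_clusters(reps[[k]]),
               P_min = min(priors[pid == k]),
               P_max = max(priors[pid == k]))
  }))
  monotone <- TRUE
  for (i in seq_len(length(parts) - 1L)) {
    if (!is_refinement(parts[[i + 1L]], parts[[i]]) &&
        !is_refinement(parts[[i]], parts[[i + 1L]])) { monotone <- FALSE }
    if (n_clusters(parts[[i + 1L]]) > n_clusters(parts[[i]])) monotone <- FALSE
  }
  structure(list(per_prior = per_prior, partitions = reps,
                 stable_groups = stable, monotone = monotone),
            class = "abgd_scan")
}

#' @export
print.abgd_scan <- function(x, ...) {
  cat("<abgd_scan>\n")
  print(x$stable_groups, row.names = FALSE)
  if (!x$monotone) cat("  [flag] partitions do not coarsen monotonically\n")
  invisible(x)
}

# TRUE when every cluster of p is contained in a cluster of q
# (p refines q); compares on specimens with data in both
is_refinement <- function(p, q) {
  ids <- intersect(names(p$assignment), names(q$assignment))
  pa <- p$assignment[ids]; qa <- q$assignment[ids]
  keep <- !is.na(pa) & !is.na(qa)
  pa <- pa[keep]; qa <- qa[keep]
  all(vapply(split(qa, pa), function(v) length(unique(v)) == 1L, TRUE))
}
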