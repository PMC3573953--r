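# shared fixture builders; everything is generated in code

rand_alignment <- function(n = 6, L = 40, marker = "toy",
                           alphabet = c("A", "C", "G", "T")) {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  marker_alignment(m, marker)
}

rand_partition <- function(ids, k = 3, method = "rand", p_nodata = 0) {
  a <- sample(as.character(seq_len(k)), length(ids), replace = TRUE)
  if (p_nodata > 0) a[runif(length(ids)) < p_nodata] <- NA
  names(a) <- ids
  new_partition(a, method)
}

# brute-force pairwise comparison oracle for compare_partitions
brute_pair_counts <- function(p, q) {
  ids <- sort(names(p$assignment))
  out <- c(split = 0L, lump = 0L, conflict = 0L, nodata = 0L)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq(i + 1L, length(ids))) {
      pa <- p$assignment[c(ids[i], ids[j])]
      qa <- q$assignment[c(ids[i], ids[j])]
      if (anyNA(pa) || anyNA(qa)) { out["nodata"] <- out["nodata"] + 1L; next }
      sp <- pa[1L] == pa[2L]; sq <- qa[1L] == qa[2L]
      if (sp && sq) out["lump"] <- out["lump"] + 1L
      else if (!sp && !sq) out["split"] <- out["split"] + 1L
      else out["conflict"] <- out["conflict"] + 1L
    }
  }
  out
}

# two well-separated clusters with controllable intra/inter distances
two_cluster_matrix <- function(intra = 0.04, inter = 0.3, n1 = 3, n2 = 3) {
  n <- n1 + n2
  ids <- sprintf("s%02d", seq_len(n))
  v <- matrix(inter, n, n, dimnames = list(ids, ids))
  v[seq_len(n1), seq_len(n1)] <- intra
  v[seq(n1 + 1, n), seq(n1 + 1, n)] <- intra
  diag(v) <- 0
  structure(list(specimen_ids = ids, values = v, model = "p",
                 site_handling = "pairwise_deletion"),
            class = "dist_matrix")
}

dist_from_values <- function(v) {
  structure(list(specimen_ids = rownames(v), values = v, model = "p",
                 site_handling = "pairwise_deletion"),
            class = "dist_matrix")
}

small_benchmark <- function(seed = 1, n_species = 6, smax = 4,
                            lengths = c(200L, 150L, 200L)) {
  build_benchmark_dataset(msc_sim_settings(
    n_species = n_species, samples_per_species = c(1L, smax),
    markers = default_markers(lengths), seed = seed))
}

# independent naive UPGMA: repeated scan over a working copy of the matrix
naive_upgma_heights <- function(v) {
  groups <- as.list(rownames(v))
  sizes <- rep(1, nrow(v))
  heights <- c()
  while (nrow(v) > 1) {
    off <- which(upper.tri(v), arr.ind = TRUE)
    w <- off[which.min(v[off]), ]
    i <- min(w); j <- max(w)
    heights <- c(heights, v[i, j] / 2)
    new_row <- (v[i, ] * sizes[i] + v[j, ] * sizes[j]) / (sizes[i] + sizes[j])
    v[i, ] <- new_row; v[, i] <- new_row
    sizes[i] <- sizes[i] + sizes[j]
    v <- v[-j, -j, drop = FALSE]; sizes <- sizes[-j]
    diag(v) <- 0
  }
  sort(heights)
}

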