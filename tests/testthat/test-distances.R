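test_that("p, JC69 and K80 distances match closed forms on toy pairs", {
  aln <- marker_alignment(c(a = strrep("A", 100), b = strrep("A", 100)), "t")
  expect_equal(distance_matrix(aln, dist_params("p"))$values["a", "b"], 0)

  # 10 bp, 2 mismatches: p = 0.2, JC69 d = 0.2326
  aln2 <- marker_alignment(c(a = "AAAAAAAAAA", b = "AAAAAAAACC"), "t")
  expect_equal(distance_matrix(aln2, dist_params("p"))$values["a", "b"], 0.2)
  expect_equal(distance_matrix(aln2, dist_params("JC69"))$values["a", "b"],
               0.2326, tolerance = 1e-4 / 0.2326)

  # pairwise deletion: 5 aligned gap columns excluded from the denominator
  aln3 <- marker_alignment(c(a = "AAAAA-----CCCCC",
                             b = "AAAAT-----CCCCC"), "t")
  expect_equal(distance_matrix(aln3, dist_params("p"))$values["a", "b"],
               1 / 10)
})

test_that("distances agree with an established reference implementation", {
  set.seed(21)
  # a family of moderately diverged sequences (corrected distances defined)
  base <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  m <- t(replicate(8, {
    s <- base
    hit <- runif(300) < 0.12
    s[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    s
  }))
  rownames(m) <- sprintf("s%02d", 1:8)
  aln <- marker_alignment(m, "fam")
  dna <- ape::as.DNAbin(tolower(aln$seq))
  for (mod in c("p", "JC69", "K80")) {
    mine <- distance_matrix(aln, dist_params(mod))$values
    ref <- as.matrix(ape::dist.dna(dna, model = if (mod == "p") "raw" else mod,
                                   pairwise.deletion = TRUE))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  }
})

test_that("ambiguity and deletion policies change the comparable-site set", {
  aln <- marker_alignment(c(a = "ANGTACGTAC", b = "ACGTACGTAC",
                            c = "ACGTACGTAN"), "t")
  d_ex <- distance_matrix(aln, dist_params("p", ambiguity_policy = "exclude_site"))
  expect_equal(d_ex$values["a", "b"], 0)       # N site excluded
  d_mm <- distance_matrix(aln, dist_params("p", ambiguity_policy = "mismatch"))
  expect_equal(d_mm$values["a", "b"], 1 / 10)  # N vs C is a mismatch
  d_cd <- distance_matrix(aln, dist_params("p", site_handling = "complete_deletion"))
  # complete deletion drops both N columns for every pair
  expect_equal(d_cd$values["a", "b"], 0)
  expect_equal(d_cd$values["b", "c"], 0)
})

test_that("saturated corrected distances become Inf with a warning", {
  aln <- marker_alignment(c(a = "ACGTACGTACGT", b = "CATCATGACTGA"), "t")
  p <- distance_matrix(aln, dist_params("p"))$values["a", "b"]
  expect_gte(p, 0.75)
  expect_warning(d <- distance_matrix(aln, dist_params("JC69")), "saturated")
  expect_equal(d$values["a", "b"], Inf)
  expect_error(distance_matrix(aln, dist_params("JC69", saturation = "error")),
               "saturated pair")
})

test_that("corrected distances dominate p whenever defined", {
  set.seed(5)
  aln <- rand_alignment(6, 500)
  p <- distance_matrix(aln, dist_params("p"))$values
  suppressWarnings({
    jc <- distance_matrix(aln, dist_params("JC69"))$values
    k80 <- distance_matrix(aln, dist_params("K80"))$values
  })
  up <- upper.tri(p)
  expect_true(all(jc[up] >= p[up] - 1e-12))
  expect_true(all(k80[up] >= p[up] - 1e-12))
})

test_that("distance computation is permutation-equivariant", {
  set.seed(6)
  aln <- rand_alignment(7, 120)
  d1 <- distance_matrix(aln, dist_params("p"))$values
  perm <- sample(rownames(aln$seq))
  aln2 <- marker_alignment(aln$seq[perm, ], "t")
  d2 <- distance_matrix(aln2, dist_params("p"))$values
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("threshold clustering: extremes and monotone cluster counts", {
  set.seed(7)
  aln <- rand_alignment(6, 80)
  dm <- distance_matrix(aln, dist_params("p"))
  expect_equal(n_clusters(threshold_cluster(dm, 0)), 6)
  expect_equal(n_clusters(threshold_cluster(dm, max(dm$values))), 1)
  thr <- sort(runif(12))
  k <- vapply(thr, function(t) n_clusters(threshold_cluster(dm, t)), 0L)
  expect_true(all(diff(k) <= 0))
})

test_that("cluster labels are the smallest member id", {
  dm <- two_cluster_matrix()
  part <- threshold_cluster(dm, 0.1)
  expect_setequal(unique(part$assignment), c("s01", "s04"))
  expect_equal(unname(part$assignment["s02"]), "s01")
})

test_that("distance summaries match exhaustive pair enumeration", {
  dm <- two_cluster_matrix(intra = 0, inter = 0.3)
  part <- threshold_cluster(dm, 0.1)
  ds <- distance_summary(dm, part)
  expect_equal(max(ds$per_cluster_max_intra), 0)
  expect_equal(ds$overall_min_inter, 0.3)

  set.seed(8)
  for (r in 1:5) {
    aln <- rand_alignment(10, 60)
    dm <- distance_matrix(aln, dist_params("p"))
    part <- rand_partition(dm$specimen_ids, k = 3)
    ds <- distance_summary(dm, part)
    a <- part$assignment
    intra <- inter <- c()
    for (i in 1:9) for (j in (i + 1):10) {
      d <- dm$values[i, j]
      if (a[i] == a[j]) intra <- c(intra, d) else inter <- c(inter, d)
    }
    if (length(intra))
      expect_equal(max(ds$per_cluster_max_intra), max(intra))
    if (length(inter)) {
      expect_equal(ds$overall_min_inter, min(inter))
      expect_equal(ds$overall_mean_inter, mean(inter))
    }
  }
})

test_that("all-singleton partitions yield absent intra summaries, not zeros", {
  dm <- two_cluster_matrix()
  singles <- new_partition(stats::setNames(dm$specimen_ids, dm$specimen_ids),
                           "s")
  ds <- distance_summary(dm, singles)
  expect_null(ds$per_cluster_max_intra)
  expect_false(is.na(ds$overall_min_inter))
})

test_that("agreement range brackets exactly the reproducing thresholds", {
  dm <- two_cluster_matrix(intra = 0.05, inter = 0.2)
  part <- threshold_cluster(dm, 0.1)
  rng <- agreement_range(dm, part)
  expect_equal(rng, c(0.05, 0.2))

  set.seed(9)
  for (r in 1:4) {
    aln <- rand_alignment(9, 70)
    dm <- distance_matrix(aln, dist_params("p"))
    t0 <- runif(1, 0, max(dm$values))
    part <- threshold_cluster(dm, t0)
    rng <- agreement_range(dm, part)
    expect_true(length(rng) == 2 && rng[1] <= t0 && t0 < rng[2])
    for (t in seq(0, max(dm$values) * 1.01, length.out = 100)) {
      inside <- length(rng) == 2 && t >= rng[1] && t < rng[2]
      expect_equal(same_grouping(threshold_cluster(dm, t), part), inside)
    }
  }
})

test_that("agreement range is empty when no threshold reproduces the partition", {
  dm <- two_cluster_matrix(intra = 0.05, inter = 0.2)
  # group one member of each tight cluster together: unreachable by chaining
  bad <- new_partition(c(s01 = "A", s02 = "A", s03 = "A",
                         s04 = "A", s05 = "B", s06 = "B"), "bad")
  expect_length(agreement_range(dm, bad), 0)
})
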