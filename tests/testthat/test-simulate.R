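test_that("species trees are ultrametric, depth-scaled and deterministic", {
  t1 <- sim_species_tree(12, birth_rate = 1, tau_scale = 0.04, seed = 5,
                         min_depth_frac = 0.5)
  t2 <- sim_species_tree(12, birth_rate = 1, tau_scale = 0.04, seed = 5,
                         min_depth_frac = 0.5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(is_ultrametric(t1))
  expect_equal(t1$Nnode, 11)
  ages <- max(ape::node.depth.edgelength(t1)) -
    ape::node.depth.edgelength(t1)
  ia <- ages[13:23]
  expect_equal(max(ia), 0.04)
  expect_gte(min(ia), 0.5 * 0.04 - 1e-12)

  t3 <- sim_species_tree(2, tau_scale = 0.7, seed = 1)
  expect_equal(max(ape::node.depth.edgelength(t3)), 0.7)
})

test_that("relative branching times match an independent Yule sampler", {
  # naive forward pure-birth simulator, conditioned on n tips, root
  # rescaled to 1: the distribution of interior node ages must agree
  naive_yule_rel_ages <- function(n, lambda) {
    k <- 2
    t <- 0
    ages_abs <- c(0)
    while (k < n) {
      t <- t + rexp(1, k * lambda)
      ages_abs <- c(ages_abs, t)
      k <- k + 1
    }
    t_end <- t + rexp(1, n * lambda)
    1 - ages_abs / t_end   # ages measured from the present, root = 1st entry
  }
  set.seed(51)
  mine <- replicate(400, {
    tr <- sim_species_tree(8, birth_rate = 1, tau_scale = 1, seed = NULL)
    a <- max(ape::node.depth.edgelength(tr)) - ape::node.depth.edgelength(tr)
    sort(a[9:15] / max(a[9:15]))[1:6]  # non-root ages relative to root
  })
  ref <- replicate(400, {
    a <- naive_yule_rel_ages(8, 1)
    sort(a / a[1])[1:6]
  })
  expect_equal(rowMeans(mine), rowMeans(ref), tolerance = 0.06)
})

test_that("single-species coalescent TMRCA matches theta (1 - 1/k)", {
  sp2 <- sim_species_tree(2, tau_scale = 10, seed = 3)  # deep root
  set.seed(52)
  theta <- 0.01
  for (k in c(2L, 6L)) {
    tm <- replicate(2000, {
      gt <- sim_gene_trees(sp2, theta,
                           c(sp01 = k, sp02 = 1L), "g")[["g"]]
      sub <- ape::keep.tip(gt, grep("^sp01", gt$tip.label, value = TRUE))
      if (k == 2L && is.null(sub$Nnode)) NA else
        max(ape::node.depth.edgelength(sub))
    })
    expect_equal(mean(tm, na.rm = TRUE), theta * (1 - 1 / k),
                 tolerance = 0.05)
  }
})

test_that("gene trees follow the species tree when theta is tiny", {
  set.seed(53)
  hits <- 0
  for (r in 1:50) {
    sp <- sim_species_tree(6, tau_scale = 0.05, seed = NULL,
                           min_depth_frac = 0.3)
    gt <- sim_gene_trees(sp, theta = 0.05 * 1e-6,
                         stats::setNames(rep(1L, 6), sp$tip.label),
                         "g")[["g"]]
    gt$tip.label <- sub("_i1$", "", gt$tip.label)
    same <- suppressWarnings(ape::dist.topo(ape::unroot(sp),
                                            ape::unroot(gt)) == 0)
    if (all(same)) hits <- hits + 1
  }
  expect_gte(hits, 49)
})

test_that("independent linkage groups get distinct genealogies", {
  sp <- sim_species_tree(6, tau_scale = 0.04, seed = 9, min_depth_frac = 0.5)
  set.seed(54)
  gts <- sim_gene_trees(sp, theta = 0.01,
                        stats::setNames(rep(3L, 6), sp$tip.label),
                        c("mt", "nuc"))
  expect_false(identical(ape::write.tree(gts$mt), ape::write.tree(gts$nuc)))
})

test_that("sequence simulation matches substitution-model expectations", {
  two <- ape::read.tree(text = "(x:0.1,y:0.1);")  # total path 0.2
  set.seed(55)
  p_hat <- mean(replicate(60, {
    aln <- sim_alignment(two, 1000, model = "JC69")
    distance_matrix(aln, dist_params("p"))$values["x", "y"]
  }))
  p_exp <- 0.75 * (1 - exp(-4 * 0.2 / 3))
  expect_equal(p_hat, p_exp, tolerance = 0.02)

  short <- ape::read.tree(text = "(x:0.005,y:0.005);")
  p_hat2 <- mean(replicate(60, {
    aln <- sim_alignment(short, 10000, model = "JC69")
    distance_matrix(aln, dist_params("p"))$values["x", "y"]
  }))
  expect_equal(p_hat2, 0.75 * (1 - exp(-4 * 0.01 / 3)), tolerance = 0.02)

  # K80 kappa = 4: transition/transversion expectations at small t
  set.seed(56)
  tsv <- replicate(40, {
    aln <- sim_alignment(two, 2000, model = "K80", kappa = 4)
    m <- aln$seq
    purine <- m %in% c("A", "G")
    dim(purine) <- dim(m)
    diff <- m[1, ] != m[2, ]
    ts <- sum(diff & purine[1, ] == purine[2, ])
    c(ts = ts, tv = sum(diff) - ts)
  })
  ratio <- sum(tsv["ts", ]) / sum(tsv["tv", ])
  # K80 closed form at distance d = 0.2: P/Q
  d <- 0.2; kappa <- 4
  b <- 1 / (kappa + 2)
  P <- 0.25 - 0.5 * exp(-2 * b * d * (kappa + 1)) + 0.25 * exp(-4 * b * d)
  Q <- 0.5 - 0.5 * exp(-4 * b * d)
  expect_equal(ratio, P / Q, tolerance = 0.1)

  # zero-length branches give identical sequences
  zero <- ape::read.tree(text = "(x:0,y:0);")
  aln0 <- sim_alignment(zero, 200, seed = 5)
  expect_identical(aln0$seq["x", ], aln0$seq["y", ])
})

test_that("benchmark datasets are reproducible and carry their truth", {
  s <- msc_sim_settings(n_species = 5, samples_per_species = c(1, 3),
                        markers = default_markers(c(60L, 40L, 50L)),
                        seed = 77)
  b1 <- build_benchmark_dataset(s)
  b2 <- build_benchmark_dataset(s)
  expect_identical(b1$alignments$COI$seq, b2$alignments$COI$seq)
  expect_identical(b1$truth$assignment, b2$truth$assignment)
  expect_setequal(unique(b1$truth$assignment), sprintf("sp%02d", 1:5))

  d <- withr::local_tempdir()
  b3 <- build_benchmark_dataset(s, outdir = d)
  expect_true(all(file.exists(file.path(d, c("28S.fasta", "16S.fasta",
                                             "COI.fasta", "truth.tsv",
                                             "provenance.json")))))
  back <- read_partition(file.path(d, "truth.tsv"))[[1]]
  expect_identical(back$assignment, b3$truth$assignment)
})

test_that("marker dropout removes whole species from the marker", {
  s <- msc_sim_settings(n_species = 6, samples_per_species = c(2, 3),
                        markers = default_markers(c(60L, 40L, 50L)),
                        dropout = list(COI = list(n_species = 3L)),
                        seed = 8)
  b <- build_benchmark_dataset(s)
  dropped_sp <- unique(sub("_i\\d+$", "", b$dropped$COI))
  expect_length(dropped_sp, 3)
  expect_false(any(b$dropped$COI %in% alignment_specimens(b$alignments$COI)))
  # specimen table records the availability
  no_coi <- b$specimens$specimen_id[
    !vapply(b$specimens$markers, function(m) "COI" %in% m, TRUE)]
  expect_setequal(no_coi, b$dropped$COI)
})

test_that("recovery degrades as the separation ratio shrinks", {
  set.seed(57)
  mean_ari <- vapply(c(20, 5, 1), function(ratio) {
    aris <- vapply(1:6, function(sd) {
      s <- msc_sim_settings(n_species = 6, samples_per_species = c(2, 4),
                            theta = 0.002, tau_scale = 0.002 * ratio,
                            markers = default_markers(c(150L, 120L, 150L)),
                            dropout = list(), seed = 600 + sd)
      b <- build_benchmark_dataset(s)
      rep <- suppressWarnings(run_pipeline(b$alignments,
        pipeline_config(methods = c("abgd", "parsnet"))))
      partition_ari(rep$ssh, b$truth)
    }, 0)
    mean(aris)
  }, 0)
  expect_true(all(diff(mean_ari) <= 0.05))
  expect_gt(mean_ari[1], mean_ari[3])
})
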