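test_that("a split vetoed by one data-bearing method is lumped (ambiguous-MOTU case)", {
  ids <- c("a", "b")
  m1 <- new_partition(c(a = "1", b = "2"), "m1")
  m2 <- new_partition(c(a = "1", b = "2"), "m2")
  m3 <- new_partition(c(a = "1", b = "2"), "m3")
  m4 <- new_partition(c(a = "1", b = "1"), "m4")  # the lone lump
  rep <- minimum_consensus(list(m1, m2, m3, m4))
  expect_equal(n_clusters(rep$ssh), 1)
  expect_equal(nrow(rep$contested), 1)
  cor <- corroboration_report(rep, list(m1, m2, m3, m4))
  expect_equal(unname(unlist(cor$matrix[1, ])),
               c("split", "split", "split", "lump"))
})

test_that("identical inputs give back the same partition; single input is identity", {
  set.seed(41)
  ids <- sprintf("s%d", 1:9)
  p <- rand_partition(ids, 3, "m1")
  q <- new_partition(p$assignment, "m2")
  rep <- minimum_consensus(list(p, q))
  expect_true(same_grouping(rep$ssh, p))
  expect_equal(nrow(rep$contested), 0)
  solo <- minimum_consensus(list(p))
  expect_true(same_grouping(solo$ssh, p))
  expect_error(minimum_consensus(list()), "no partitions")
})

test_that("consensus equals brute-force components of the pairwise vote table", {
  set.seed(42)
  ids <- sprintf("s%d", 1:10)
  for (r in 1:8) {
    parts <- lapply(1:4, function(i)
      rand_partition(ids, sample(2:4, 1), paste0("m", i), p_nodata = 0.25))
    rep <- minimum_consensus(parts)
    # oracle: union-find over pairs where some covering method lumps,
    # or no method covers
    lump <- matrix(FALSE, 10, 10, dimnames = list(ids, ids))
    for (i in 1:9) for (j in (i + 1):10) {
      votes <- vapply(parts, function(p) {
        pa <- p$assignment[c(ids[i], ids[j])]
        if (anyNA(pa)) NA else pa[1] == pa[2]
      }, NA)
      lump[i, j] <- lump[j, i] <-
        if (all(is.na(votes))) TRUE else any(votes, na.rm = TRUE)
    }
    memb <- rep(0L, 10)
    lab <- 0L
    for (i in 1:10) {
      if (memb[i] == 0L) {
        lab <- lab + 1L
        queue <- i
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          if (memb[v] == 0L) {
            memb[v] <- lab
            queue <- c(queue, which(lump[v, ] & memb == 0L))
          }
        }
      }
    }
    oracle <- new_partition(stats::setNames(as.character(memb), ids), "o")
    expect_true(same_grouping(rep$ssh, oracle))
  }
})

test_that("consensus is order-invariant and idempotent", {
  set.seed(43)
  ids <- sprintf("s%d", 1:8)
  parts <- lapply(1:4, function(i)
    rand_partition(ids, 3, paste0("m", i), p_nodata = 0.2))
  rep1 <- minimum_consensus(parts)
  rep2 <- minimum_consensus(rev(parts))
  expect_true(same_grouping(rep1$ssh, rep2$ssh))
  rep3 <- minimum_consensus(c(parts, list(rep1$ssh)))
  expect_true(same_grouping(rep3$ssh, rep1$ssh))
})

test_that("the SSH never splits a pair lumped by a data-bearing method", {
  set.seed(44)
  ids <- sprintf("s%d", 1:9)
  for (r in 1:6) {
    parts <- lapply(1:3, function(i)
      rand_partition(ids, sample(2:5, 1), paste0("m", i), p_nodata = 0.3))
    ssh <- minimum_consensus(parts)$ssh
    for (p in parts) {
      a <- p$assignment[ids]
      for (i in 1:8) for (j in (i + 1):9) {
        if (!is.na(a[i]) && !is.na(a[j]) && a[i] == a[j])
          expect_true(ssh$assignment[ids[i]] == ssh$assignment[ids[j]])
      }
    }
  }
})

test_that("when every method refines Q, the SSH refines or equals Q", {
  set.seed(45)
  ids <- sprintf("s%d", 1:12)
  Q <- new_partition(stats::setNames(rep(c("A", "B", "C"), each = 4), ids), "Q")
  refine <- function(mname) {
    a <- Q$assignment
    # split each Q cluster randomly into 1-2 parts
    for (cl in unique(a)) {
      sub <- names(a)[a == cl]
      cut <- sample(0:1, length(sub), replace = TRUE)
      a[sub[cut == 1]] <- paste0(cl, "x")
    }
    new_partition(a, mname)
  }
  parts <- lapply(paste0("m", 1:3), refine)
  ssh <- minimum_consensus(parts)$ssh
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    if (ssh$assignment[ids[i]] == ssh$assignment[ids[j]])
      expect_true(Q$assignment[ids[i]] == Q$assignment[ids[j]])
  }
})

test_that("transitive chaining joins units through overlapping lump votes", {
  m1 <- new_partition(c(a = "1", b = "1", c = "2"), "m1")
  m2 <- new_partition(c(a = "1", b = "2", c = "2"), "m2")
  rep <- minimum_consensus(list(m1, m2))
  expect_equal(n_clusters(rep$ssh), 1)  # a~b (m1), b~c (m2) -> one unit
})

test_that("pairs with no doubly-covering method are lumped and counted", {
  m1 <- new_partition(c(a = "1", b = NA, c = "2"), "m1")
  m2 <- new_partition(c(a = NA, b = "1", c = NA), "m2")
  rep <- minimum_consensus(list(m1, m2))
  # a-b and b-c pairs are never doubly covered -> evidence-free lumps
  expect_equal(rep$evidence_free_pairs, 2)
  expect_equal(n_clusters(rep$ssh), 1)
})

test_that("BPP support aggregation: means, threshold, ambiguity flags", {
  rec <- data.frame(
    node_id = c(rep("n1", 4), rep("n2", 2), rep("n3", 2)),
    run_label = paste0("r", 1:8),
    prior_combo = c("a", "b", "c", "d", "a", "b", "a", "b"),
    pp = c(1, 1, 1, 1, 0.90, 0.96, 0.95, 0.95))
  agg <- aggregate_bpp_support(rec, threshold = 0.95)
  n1 <- agg$nodes[agg$nodes$node_id == "n1", ]
  expect_true(n1$supported); expect_equal(n1$mean_pp, 1)
  n2 <- agg$nodes[agg$nodes$node_id == "n2", ]
  expect_equal(n2$mean_pp, 0.93)
  expect_false(n2$supported)
  expect_true(n2$ambiguous)   # 0.96 combo supports, 0.90 combo does not
  n3 <- agg$nodes[agg$nodes$node_id == "n3", ]
  expect_true(n3$supported)   # threshold is inclusive
  expect_false(n3$ambiguous)

  bad <- rbind(rec, data.frame(node_id = "n1", run_label = "r9",
                               prior_combo = "a", pp = 1.2))
  expect_warning(agg2 <- aggregate_bpp_support(bad), "rejected")
  expect_equal(agg2$nodes[agg2$nodes$node_id == "n1", "n_runs"], 4)
})

test_that("a guide tree with unsupported nodes collapses into a partition", {
  guide <- ape::read.tree(text = "((u1:1,u2:1):1,(u3:1,u4:1):1);")
  rec <- data.frame(
    node_id = c("u1|u2", "u1|u2", "u3|u4", "u3|u4"),
    run_label = paste0("r", 1:4),
    prior_combo = c("a", "b", "a", "b"),
    pp = c(0.5, 0.6, 1, 1))
  agg <- aggregate_bpp_support(rec)
  part <- bpp_partition(guide, agg,
                        unit_map = list(u1 = c("x1", "x2"), u2 = "x3",
                                        u3 = "x4", u4 = c("x5", "x6")))
  # u1/u2 split unsupported -> lumped; u3/u4 supported -> split
  expect_equal(unname(part$assignment[c("x1", "x3")]), c("x1", "x1"))
  expect_false(part$assignment["x4"] == part$assignment["x5"])
  expect_equal(n_clusters(part), 3)
})
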