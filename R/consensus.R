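#' Minimum-consensus secondary species hypothesis
#'
#' Combines per-method partitions into a conservative secondary
#' species hypothesis (SSH), relying only on uncontradicted positive
#' splits: a pair of specimens is separated in the SSH only if *every*
#' method with data for both separates them.  Formally, the SSH is the
#' set of connected components of the graph with an edge between two
#' specimens whenever at least one data-bearing partition lumps them;
#' pairs covered by no method at all are lumped too (never split on
#' absence of evidence).  Methods enter unweighted.
#'
#' @param partitions List of [new_partition()] objects.  Specimens
#'   absent from a partition are treated as no-data for that method.
#' @return A list of class `consensus_report`: `ssh` (the consensus
#'   [new_partition()]), `atoms` (the finest units never split by any
#'   method), `boundaries` (data.frame of method votes per atom pair),
#'   `contested` (subset of boundaries split by some but not all
#'   data-bearing methods), `methods`, `evidence_free_pairs` (count of
#'   pairs lumped for lack of any doubly-covering method).
#' @examples
#' m1 <- new_partition(c(a = "1", b = "2", c = "3"), "m1")
#' m2 <- new_partition(c(a = "1", b = "1", c = "2"), "m2")
#' minimum_consensus(list(m1, m2))$ssh   # a,b lumped: m2 vetoes the split
#' @export
minimum_consensus <- function(partitions) {
  if (length(partitions) == 0L) stop("no partitions supplied")
  universe <- sort(unique(unlist(lapply(partitions, partition_specimens))))
  n <- length(universe)
  methods <- vapply(seq_along(partitions), function(i) {
    m <- partitions[[i]]$method
    if (is.null(m) || !nzchar(m)) paste0("method", i) else m
  }, "")
  if (anyDuplicated(methods))
    methods <- make.unique(methods, sep = ".")
  lump_any <- covered_any <- split_any <-
    matrix(FALSE, n, n, dimnames = list(universe, universe))
  votes <- array(NA_character_, c(n, n, length(partitions)),
                 dimnames = list(universe, universe, methods))
  for (i in seq_along(partitions)) {
    a <- partitions[[i]]$assignment[universe]
    same <- outer(a, a, "==")
    cov <- !is.na(same)
    lump_any <- lump_any | (cov & same)
    split_any <- split_any | (cov & !same)
    covered_any <- covered_any | cov
    v <- ifelse(cov, ifelse(same, "lump", "split"), "nodata")
    votes[, , i] <- v
  }
  edge_ssh <- lump_any | !covered_any
  ssh_memb <- components_of(edge_ssh, universe)
  ssh <- new_partition(label_components(ssh_memb), method = "ssh",
                       parameters = list(methods = methods))
  atom_memb <- components_of(!split_any, universe)
  atoms <- split(universe, atom_memb)
  atoms <- unname(atoms[order(vapply(atoms, min, ""))])
  boundaries <- atom_boundaries(atoms, ssh_memb, votes, methods, universe)
  contested <- boundaries[boundaries$same_ssh_unit &
                            boundaries$n_split > 0, , drop = FALSE]
  up <- upper.tri(covered_any)
  structure(list(ssh = ssh, atoms = atoms, boundaries = boundaries,
                 contested = contested, methods = methods,
                 evidence_free_pairs = sum(!covered_any[up])),
            class = "consensus_report")
}

# connected components from a logical adjacency matrix
components_of <- function(adj, ids) {
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  memb <- igraph::components(g)$membership
  names(memb) <- ids
  memb
}

# per-boundary method votes: for each pair of atoms, a method lumps
# the boundary if it lumps any covered cross pair (that is the veto),
# splits it if it covers some cross pair and lumps none, else no data
atom_boundaries <- function(atoms, ssh_memb, votes, methods, universe) {
  k <- length(atoms)
  if (k < 2L) {
    return(data.frame(atom_a = character(0), atom_b = character(0),
                      same_ssh_unit = logical(0), n_split = integer(0),
                      n_lump = integer(0), n_nodata = integer(0)))
  }
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      va <- vapply(seq_along(methods), function(m) {
        v <- votes[atoms[[i]], atoms[[j]], m, drop = FALSE]
        if (any(v == "lump")) "lump"
        else if (any(v == "split")) "split"
        else "nodata"
      }, "")
      rows[[length(rows) + 1L]] <- data.frame(
        atom_a = min(atoms[[i]]), atom_b = min(atoms[[j]]),
        same_ssh_unit = ssh_memb[atoms[[i]][1L]] ==
          ssh_memb[atoms[[j]][1L]],
        n_split = sum(va == "split"), n_lump = sum(va == "lump"),
        n_nodata = sum(va == "nodata"),
        t(stats::setNames(va, methods)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report> %d methods -> %d SSH units (%d atoms)\n",
              length(x$methods), n_clusters(x$ssh), length(x$atoms)))
  if (nrow(x$contested))
    cat(sprintf("  %d contested boundar%s (split by some methods, lumped by others)\n",
                nrow(x$contested), if (nrow(x$contested) == 1) "y" else "ies"))
  invisible(x)
}

#' Corroboration matrix behind a consensus report
#'
#' Renders the consensus as a units-by-methods table: for each SSH
#' unit, whether each method keeps it whole (`lump`), subdivides it
#' (`split`), or has no data, together with the number of method
#' entities intersecting the unit.  Boundary rows (between SSH units
#' and contested internal boundaries) are returned machine-readably.
#'
#' @param report A [minimum_consensus()] result.
#' @param partitions The partitions the report was built from (used to
#'   count method entities per unit); optional.
#' @return A list of class `corroboration`: `matrix` (data.frame unit x
#'   method), `boundaries` (as in the report), `contested`.
#' @export
corroboration_report <- function(report, partitions = NULL) {
  units <- partition_groups(report$ssh)
  units <- units[order(names(units))]
  methods <- report$methods
  cells <- matrix("nodata", length(units), length(methods),
                  dimnames = list(names(units), methods))
  counts <- matrix(NA_integer_, length(units), length(methods),
                   dimnames = list(names(units), methods))
  if (!is.null(partitions)) {
    for (m in seq_along(partitions)) {
      a <- partitions[[m]]$assignment
      for (u in seq_along(units)) {
        vals <- a[intersect(units[[u]], names(a))]
        vals <- vals[!is.na(vals)]
        if (!length(vals)) next
        counts[u, m] <- length(unique(vals))
        cells[u, m] <- if (length(unique(vals)) > 1L) "split" else "lump"
      }
    }
  }
  structure(list(matrix = as.data.frame(cells),
                 entity_counts = as.data.frame(counts),
                 boundaries = report$boundaries,
                 contested = report$contested),
            class = "corroboration")
}

#' Aggregate Bayesian species-delimitation support records
#'
#' Posterior speciation probabilities from repeated runs (different
#' prior combinations on ancestral population size theta and divergence
#' times tau, algorithms and seeds) are averaged per node; a node is
#' supported when its mean posterior probability meets the threshold
#' (inclusive).  Per-prior-combination ranges are retained, and a node
#' is flagged ambiguous when some prior combinations support it and
#' others do not.
#'
#' @param records Data frame with columns `node_id`, `run_label`,
#'   `prior_combo`, `pp` (posterior probability in `[0, 1]`; rows
#'   outside the unit interval are rejected with a warning).
#' @param threshold Support threshold, default 0.95.
#' @return A list of class `bpp_support`: `nodes` (data.frame with
#'   `node_id`, `mean_pp`, `n_runs`, `supported`, `ambiguous`),
#'   `by_prior` (data.frame `node_id`, `prior_combo`, `min_pp`,
#'   `max_pp`, `mean_pp`), `threshold`.
#' @export
aggregate_bpp_support <- function(records, threshold = 0.95) {
  need <- c("node_id", "run_label", "prior_combo", "pp")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  bad <- !is.finite(records$pp) | records$pp < 0 | records$pp > 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with pp outside [0,1] rejected")
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stop("no valid support records")
  by_node <- split(records, records$node_id)
  nodes <- do.call(rbind, lapply(by_node, function(d) {
    combo_means <- tapply(d$pp, d$prior_combo, mean)
    sup <- combo_means >= threshold
    data.frame(node_id = d$node_id[1L], mean_pp = mean(d$pp),
               n_runs = nrow(d), supported = mean(d$pp) >= threshold,
               ambiguous = length(unique(sup)) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(nodes) <- NULL
  by_prior <- do.call(rbind, lapply(by_node, function(d) {
    do.call(rbind, lapply(split(d, d$prior_combo), function(g) {
      data.frame(node_id = g$node_id[1L], prior_combo = g$prior_combo[1L],
                 min_pp = min(g$pp), max_pp = max(g$pp),
                 mean_pp = mean(g$pp), stringsAsFactors = FALSE)
    }))
  }))
  rownames(by_prior) <- NULL
  structure(list(nodes = nodes, by_prior = by_prior,
                 threshold = threshold),
            class = "bpp_support")
}

#' Partition from a guide tree and aggregated node support
#'
#' Converts Bayesian delimitation output into a specimen partition for
#' the consensus: internal splits of the rooted guide tree whose mean
#' posterior probability falls below the threshold are collapsed, so a
#' supported node contributes a split vote and an unsupported node a
#' lump vote.  Guide-tree tips are candidate units; `unit_map` expands
#' them to specimens.
#'
#' @param guide_tree Rooted `phylo` tree whose tips are unit labels.
#' @param support A [aggregate_bpp_support()] result; `node_id` must be
#'   the `|`-joined sorted tip labels of the clade the node subtends.
#' @param unit_map Named list mapping unit label to specimen ids;
#'   default maps each tip to itself.
#' @return A [new_partition()] with method `"bpp"`.
#' @export
bpp_partition <- function(guide_tree, support, unit_map = NULL) {
  tips <- guide_tree$tip.label
  if (is.null(unit_map)) unit_map <- stats::setNames(as.list(tips), tips)
  ntip <- length(tips)
  desc <- phangorn::Descendants(guide_tree, seq(ntip + 1L,
                                                ntip + guide_tree$Nnode),
                                "tips")
  node_ids <- vapply(desc, function(ix)
    paste(sort(tips[ix]), collapse = "|"), "")
  supported <- stats::setNames(support$nodes$supported,
                               support$nodes$node_id)
  # walk from the root: a tip group separates once every node on the
  # path that splits it is supported; collapse unsupported nodes by
  # unioning their descendant tips
  memb <- seq_len(ntip)
  for (i in seq_along(node_ids)) {
    sup <- supported[node_ids[i]]
    if (!is.na(sup) && !sup) {
      ix <- desc[[i]]
      memb[ix] <- min(memb[ix])
    }
  }
  a <- character(0)
  for (u in unique(memb)) {
    grp <- unlist(unit_map[tips[memb == u]])
    a[grp] <- min(grp)
  }
  new_partition(a, method = "bpp",
                parameters = list(threshold = support$threshold))
}
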