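#' Monophyly status of a specimen set on a rooted tree
#'
#' Evaluated on the members actually present in the tree; when fewer
#' than two members are present the tree carries no grouping
#' information for the set and the status is `insufficient_data`
#' (markers that failed to amplify leave MOTUs unrepresented in single
#' gene trees).
#'
#' @param tree Rooted `phylo` tree.
#' @param members Character vector of specimen ids.
#' @return One of `"monophyletic"`, `"violated"`,
#'   `"insufficient_data"`.
#' @export
monophyly_status <- function(tree, members) {
  if (!ape::is.rooted(tree)) stop("monophyly is undefined on unrooted trees")
  present <- intersect(members, tree$tip.label)
  if (length(present) < 2L) return("insufficient_data")
  if (length(present) == length(tree$tip.label)) return("monophyletic")
  if (ape::is.monophyletic(tree, present)) "monophyletic" else "violated"
}

#' Primary species hypothesis from concatenated and gene trees
#'
#' Enumerates candidate clades from the concatenated tree, largest
#' (deepest) first, and accepts a clade as a MOTU when (a) no gene
#' tree violates its monophyly (statuses `monophyletic` or
#' `insufficient_data` everywhere), (b) its support on the
#' concatenated tree meets `min_support` where supports are present,
#' and (c) it is not nested inside an already-accepted clade.  Every
#' ingroup leaf left unassigned becomes a singleton MOTU; the relative
#' terminal branch length of each singleton (against the median MOTU
#' stem length) is reported as a diagnostic, not used as a gate.
#'
#' @param concat_tree Rooted concatenated-data `phylo` tree.
#' @param gene_trees List of rooted single-marker `phylo` trees (each
#'   over a subset of the concatenated tree's leaves).
#' @param min_support Minimum node support for acceptance (default 75,
#'   a moderate bootstrap bar); ignored for nodes without a numeric
#'   support and disabled entirely when the tree carries no supports.
#'   Use `NULL` to disable.
#' @param ingroup Character vector of ingroup specimen ids (outgroup
#'   leaves are excluded from MOTU enumeration); default all leaves.
#' @return A list of class `motu_table`: `motus` (data.frame with
#'   label, size, support, type), `membership` (list of member ids per
#'   MOTU), `status` (matrix MOTU x gene tree), `singleton_diag`
#'   (data.frame with terminal branch lengths and length ratios) and
#'   `partition` (a [new_partition()] with method `"psh"`).
#' @export
psh_from_trees <- function(concat_tree, gene_trees = list(),
                           min_support = 75, ingroup = NULL) {
  if (!ape::is.rooted(concat_tree)) stop("concatenated tree must be rooted")
  tips <- concat_tree$tip.label
  for (g in gene_trees) {
    extra <- setdiff(g$tip.label, tips)
    if (length(extra))
      stop("gene tree leaf absent from concatenated tree: ",
           paste(extra, collapse = ", "))
  }
  if (is.null(ingroup)) ingroup <- tips
  ntip <- length(tips)
  supports <- tree_supports(concat_tree)
  has_supports <- any(!is.na(supports))
  ages <- node_ages(concat_tree)
  desc <- phangorn::Descendants(concat_tree, seq(ntip + 1L,
                                                 ntip + concat_tree$Nnode),
                                "tips")
  cl_members <- lapply(desc, function(ix) intersect(tips[ix], ingroup))
  ord <- order(-lengths(cl_members), -ages[seq(ntip + 1L,
                                               ntip + concat_tree$Nnode)])
  accepted <- list()
  acc_nodes <- integer(0)
  status_rows <- list()
  gt_names <- if (length(gene_trees))
    paste0("gene", seq_along(gene_trees)) else character(0)
  if (!is.null(names(gene_trees)) && all(nzchar(names(gene_trees))))
    gt_names <- names(gene_trees)
  for (i in ord) {
    node <- ntip + i
    members <- cl_members[[i]]
    # the full ingroup is not a candidate MOTU: delimitation starts
    # below the ingroup's most recent common ancestor
    if (length(members) < 2L || length(members) >= length(ingroup)) next
    if (any(vapply(accepted, function(a) all(members %in% a), TRUE))) next
    st <- vapply(gene_trees, monophyly_status, "", members = members)
    if (any(st == "violated")) next
    if (has_supports && !is.null(min_support) && node != ntip + 1L) {
      s <- supports[i]
      if (!is.na(s) && s < min_support) next
    }
    accepted[[length(accepted) + 1L]] <- members
    acc_nodes <- c(acc_nodes, node)
    status_rows[[length(status_rows) + 1L]] <- st
  }
  assigned <- unlist(accepted)
  singles <- setdiff(ingroup, assigned)
  a <- character(0)
  for (m in accepted) a[m] <- min(m)
  a[singles] <- singles
  part <- new_partition(a[sort(c(assigned, singles))], method = "psh",
                        parameters = list(min_support = min_support))
  # stem length of each accepted MOTU (edge subtending its node)
  stem_len <- vapply(acc_nodes, function(nd) {
    e <- which(concat_tree$edge[, 2L] == nd)
    if (length(e)) concat_tree$edge.length[e] else NA_real_
  }, 0)
  med_stem <- if (length(stem_len)) stats::median(stem_len, na.rm = TRUE)
              else NA_real_
  term_len <- vapply(singles, function(s) {
    e <- which(concat_tree$edge[, 2L] == match(s, tips))
    concat_tree$edge.length[e]
  }, 0)
  motus <- data.frame(
    label = c(vapply(accepted, min, ""), singles),
    size = c(lengths(accepted), rep(1L, length(singles))),
    support = c(supports[acc_nodes - ntip], rep(NA_real_, length(singles))),
    type = c(rep("clade", length(accepted)),
             rep("singleton", length(singles))),
    stringsAsFactors = FALSE)
  status <- if (length(gene_trees))
    rbind(if (length(status_rows)) do.call(rbind, status_rows),
          matrix("insufficient_data", length(singles), length(gene_trees)))
    else matrix(character(0), nrow(motus), 0)
  if (length(gene_trees)) colnames(status) <- gt_names
  structure(list(motus = motus,
                 membership = c(accepted, as.list(singles)),
                 status = status,
                 singleton_diag = data.frame(
                   specimen_id = singles,
                   terminal_length = unname(term_len),
                   length_ratio = unname(term_len) / med_stem,
                   stringsAsFactors = FALSE),
                 partition = part),
            class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  nc <- sum(x$motus$type == "clade")
  ns <- sum(x$motus$type == "singleton")
  cat(sprintf("<motu_table> %d MOTUs: %d reciprocally monophyletic clades + %d singletons\n",
              nrow(x$motus), nc, ns))
  invisible(x)
}
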