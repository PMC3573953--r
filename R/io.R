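#' Read a marker alignment from FASTA or NEXUS
#'
#' Sequences are upper-cased and `?` is normalised to the gap state
#' `-`.  All records must have the same aligned length; a ragged file
#' is an error naming the offending record.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"nexus"`; by default guessed from the
#'   file extension (`.nex`/`.nxs` are NEXUS, anything else FASTA).
#' @param marker_name Locus name stored in the object; defaults to the
#'   file name without extension.
#' @return A [marker_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus"),
                           marker_name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (is.null(marker_name))
    marker_name <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fasta") {
    if (length(readLines(path, n = 1L, warn = FALSE)) == 0L)
      stop("empty alignment file: ", path)
    dna <- ape::read.FASTA(path)
    if (length(dna) == 0L) stop("no sequences found in ", path)
    seqs <- vapply(as.character(dna), paste, "", collapse = "")
  } else {
    nx <- ape::read.nexus.data(path)
    if (length(nx) == 0L) stop("no sequences found in ", path)
    seqs <- vapply(nx, paste, "", collapse = "")
  }
  marker_alignment(seqs, marker_name)
}

#' Write a marker alignment to FASTA
#'
#' @param aln A [marker_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  m <- tolower(aln$seq)
  dna <- ape::as.DNAbin(m)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a rooted tree from Newick
#'
#' Internal node labels that parse as numbers are interpreted as
#' support values (bootstrap percentages or posterior probabilities).
#' Monophyly is undefined on unrooted trees, so unrooted input must be
#' rooted at a named outgroup leaf.
#'
#' @param path Path to a Newick file (or a Newick string when
#'   `text = TRUE` semantics are needed, use [ape::read.tree()]).
#' @param outgroup Optional leaf name: the tree is rooted on this leaf
#'   (required when the input is unrooted).
#' @param specimens Optional character vector of known specimen ids;
#'   any leaf outside this set is an error.
#' @return An [ape::read.tree()] `phylo` object; numeric node supports,
#'   if present, are kept in `node.label`.
#' @export
read_tree <- function(path, outgroup = NULL, specimens = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree: ", path)
  if (!is.null(specimens)) {
    unknown <- setdiff(tr$tip.label, specimens)
    if (length(unknown))
      stop("unknown specimen(s) in tree: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("outgroup leaf not in tree: ", outgroup)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else if (!ape::is.rooted(tr)) {
    stop("tree is unrooted; supply an outgroup leaf name")
  }
  tr
}

#' Node support values of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (NA where the label is
#'   absent or non-numeric), in node order.
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Check that a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within a relative tolerance.
#' @param tree A `phylo` object.
#' @param tol Relative tolerance on root-to-tip depth spread.
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(max(d), .Machine$double.eps)
}

#' Write partitions to a TSV partition table
#'
#' The table has columns `specimen_id`, `method`, `cluster_label`; the
#' no-data state is written as `NA`.  [read_partition()] is the
#' inverse.
#'
#' @param partitions A single partition or a list of
#'   [new_partition()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partitions, path) {
  if (inherits(partitions, "specimen_partition"))
    partitions <- list(partitions)
  rows <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(specimen_id = names(p$assignment),
               method = p$method,
               cluster_label = ifelse(is.na(p$assignment), "NA",
                                      p$assignment),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(rows[c("specimen_id", "method")]))
    stop("duplicate (specimen, method) rows; partitions must have distinct method names")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read partitions from a TSV partition table
#'
#' @param path Path written by [write_partition()].
#' @return A list of [new_partition()] objects, one per method, in
#'   file order.
#' @export
read_partition <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("specimen_id", "method", "cluster_label")
  if (!all(need %in% names(tab)))
    stop("partition table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[c("specimen_id", "method")]))
    stop("duplicate (specimen, method) rows in ", path)
  out <- lapply(split(tab, factor(tab$method, levels = unique(tab$method))),
                function(d) {
                  a <- d$cluster_label
                  a[a == "NA"] <- NA_character_
                  names(a) <- d$specimen_id
                  new_partition(a, method = d$method[1L])
                })
  names(out) <- NULL
  out
}
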