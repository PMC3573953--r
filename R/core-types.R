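#' motudelim: integrative molecular species delimitation
#'
#' Candidate-species partitions from several independent delimitation
#' methods (GMYC, ABGD, statistical parsimony, distance thresholds),
#' combined into a secondary species hypothesis by a conservative
#' minimum-consensus rule, plus a multispecies-coalescent benchmark
#' simulator.  See `vignette("delimitation-methods")` for the models.
#'
#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide codes accepted in alignments; '-' is the gap state.
IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")
DETERMINED_BASES <- c("A", "C", "G", "T")

#' Construct a marker alignment
#'
#' An equal-length nucleotide alignment for one locus, keyed by specimen
#' id.  Sequences are stored upper-cased with `?` normalised to the gap
#' state `-`; IUPAC ambiguity codes are retained verbatim (their
#' treatment is decided per analysis, see [dist_params()]).
#'
#' @param sequences Named character vector of aligned sequences (one
#'   string per specimen), or a character matrix with one row per
#'   specimen and one column per site.
#' @param marker_name Name of the locus (e.g. `"COI"`).
#' @return An object of class `marker_alignment`: a list with elements
#'   `marker_name`, `length` (number of columns) and `seq` (character
#'   matrix, rownames are specimen ids).
#' @examples
#' aln <- marker_alignment(c(a = "ACGT", b = "ACGA"), "COI")
#' aln$length
#' @export
marker_alignment <- function(sequences, marker_name) {
  if (is.matrix(sequences)) {
    m <- toupper(sequences)
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == ""))
      stop("sequences must be named by specimen id")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[lens != lens[1L]][1L]
      stop(sprintf("alignment '%s' is ragged: record '%s' has %d characters, expected %d",
                   marker_name, bad, nchar(sequences[[bad]]), lens[1L]))
    }
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(m) <- names(sequences)
  }
  m[m == "?"] <- "-"
  if (nrow(m) < 2L) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(rownames(m)))
    stop("duplicated specimen ids in alignment")
  bad <- setdiff(unique(as.vector(m)), IUPAC_CODES)
  if (length(bad))
    stop("unexpected characters in alignment: ", paste(bad, collapse = ", "))
  structure(list(marker_name = marker_name, length = ncol(m), seq = m),
            class = "marker_alignment")
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(sprintf("<marker_alignment> %s: %d sequences x %d sites\n",
              x$marker_name, nrow(x$seq), x$length))
  invisible(x)
}

#' Specimens present in an alignment
#' @param aln A [marker_alignment()].
#' @return Character vector of specimen ids.
#' @export
alignment_specimens <- function(aln) rownames(aln$seq)

#' Construct a specimen partition
#'
#' An assignment of specimens to candidate-species labels.  `NA` is the
#' explicit *no data* state: the method could not place the specimen
#' (e.g. the marker failed to amplify), which is distinct from the
#' method lumping it with others.  Cluster labels are opaque; identity
#' of labels carries no meaning across partitions.
#'
#' @param assignment Named character vector; names are specimen ids,
#'   values are cluster labels or `NA` for no data.
#' @param method Name of the method that produced the partition.
#' @param parameters List of settings that produced it.
#' @return An object of class `specimen_partition`.
#' @examples
#' new_partition(c(a = "1", b = "1", c = "2"), "toy")
#' @export
new_partition <- function(assignment, method = "unknown", parameters = list()) {
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("assignment must be named by specimen id")
  if (anyDuplicated(names(assignment)))
    stop("duplicated specimen ids in partition")
  nm <- names(assignment)
  assignment <- as.character(assignment)
  names(assignment) <- nm
  structure(list(assignment = assignment, method = method,
                 parameters = parameters),
            class = "specimen_partition")
}

# internal: keep names when coercing
#' @export
print.specimen_partition <- function(x, ...) {
  k <- n_clusters(x)
  nd <- sum(is.na(x$assignment))
  cat(sprintf("<specimen_partition> method '%s': %d specimens, %d clusters%s\n",
              x$method, length(x$assignment), k,
              if (nd) sprintf(" (%d no-data)", nd) else ""))
  invisible(x)
}

#' Number of clusters in a partition
#'
#' Counts distinct cluster labels among specimens with data (both
#' multi-member clusters and singletons count as one entity each).
#'
#' @param part A [new_partition()] object.
#' @return Integer count of entities.
#' @export
n_clusters <- function(part) {
  length(unique(part$assignment[!is.na(part$assignment)]))
}

#' Specimen universe of a partition
#' @param part A [new_partition()] object.
#' @return Character vector of specimen ids covered (including no-data).
#' @export
partition_specimens <- function(part) names(part$assignment)

# Canonical label-free signature of the grouping (used to test equality
# of partitions and to group identical ABGD scan results).  Labels are
# replaced by first-appearance indices over the sorted specimen ids;
# NA stays NA.
partition_signature <- function(part) {
  ids <- sort(names(part$assignment))
  a <- part$assignment[ids]
  lab <- match(a, unique(a[!is.na(a)]))
  paste(ifelse(is.na(a), ".", lab), collapse = "|")
}

#' Test whether two partitions group specimens identically
#'
#' Compares the grouping pattern only (labels are opaque), over the same
#' specimen universe; no-data states must coincide.
#' @param p,q Partitions.
#' @return Logical.
#' @export
same_grouping <- function(p, q) {
  if (!setequal(names(p$assignment), names(q$assignment))) return(FALSE)
  partition_signature(p) == partition_signature(q)
}

# internal: group membership as list label -> specimen ids (data only)
partition_groups <- function(part) {
  a <- part$assignment[!is.na(part$assignment)]
  split(names(a), a)
}

#' Build a specimen table
#'
#' One row per collected individual, with its locality label and the
#' set of markers for which a sequence is available.
#'
#' @param specimen_id Character vector of unique ids.
#' @param locality Character vector of locality labels (field codes).
#' @param markers_present List of character vectors, one per specimen.
#' @param marker_names Declared marker names of the dataset.
#' @return A data.frame of class `specimen_table` with a `markers`
#'   list-column.
#' @export
specimen_table <- function(specimen_id, locality, markers_present,
                           marker_names) {
  if (anyDuplicated(specimen_id)) stop("specimen ids must be unique")
  stopifnot(length(locality) == length(specimen_id),
            length(markers_present) == length(specimen_id))
  for (i in seq_along(markers_present)) {
    extra <- setdiff(markers_present[[i]], marker_names)
    if (length(extra))
      stop(sprintf("specimen '%s' lists unknown marker(s): %s",
                   specimen_id[i], paste(extra, collapse = ", ")))
  }
  out <- data.frame(specimen_id = specimen_id, locality = locality,
                    stringsAsFactors = FALSE)
  out$markers <- markers_present
  attr(out, "marker_names") <- marker_names
  class(out) <- c("specimen_table", class(out))
  out
}
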