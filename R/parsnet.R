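#' Statistical parsimony settings
#'
#' @param confidence Parsimony confidence level, strictly in (0, 1);
#'   the classical criterion is 0.95.
#' @param alignment_length Number of aligned sites (denoted L).
#' @param max_steps_cap Safety cap on the connection limit search.
#' @return A list of class `parsimony_settings`.
#' @export
parsimony_settings <- function(confidence = 0.95, alignment_length,
                               max_steps_cap = 1000L) {
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must be strictly between 0 and 1")
  stopifnot(alignment_length >= 1)
  structure(list(confidence = confidence,
                 alignment_length = as.integer(alignment_length),
                 max_steps_cap = as.integer(max_steps_cap)),
            class = "parsimony_settings")
}

# mutational steps between two aligned sequences: per-site mismatches
# over determined sites, plus gap handling.  A contiguous run of sites
# where exactly one sequence is gapped counts as one step under
# "fifth_run" (an indel is one event), or zero under "ignore".
hap_steps <- function(x, y, ambiguity_policy = "exclude_site",
                      gap_mode = "fifth_run") {
  detx <- x %in% DETERMINED_BASES
  dety <- y %in% DETERMINED_BASES
  if (ambiguity_policy == "exclude_site") {
    cmp <- detx & dety
  } else {
    cmp <- x != "-" & y != "-"
  }
  steps <- sum(x[cmp] != y[cmp])
  if (gap_mode == "fifth_run") {
    gp <- (x == "-") != (y == "-")
    if (any(gp)) {
      r <- rle(gp)
      steps <- steps + sum(r$values)
    }
  }
  steps
}

#' Collapse an alignment into haplotypes
#'
#' Sequences at mutational distance zero under the chosen policies
#' share a haplotype (an ambiguous site excluded from comparison cannot
#' separate two sequences, so collapsing can chain through ambiguous
#' intermediates).  The step matrix between haplotypes counts per-site
#' mismatches, with a contiguous gap run counted as a single step by
#' default (configurable to ignore gaps).
#'
#' @param aln A [marker_alignment()].
#' @param ambiguity_policy `"exclude_site"` or `"mismatch"` (see
#'   [dist_params()]).
#' @param gap_mode `"fifth_run"` (a gap run is one step) or `"ignore"`.
#' @return A list of class `haplotype_set`: `haplotypes` (character
#'   vector of representative sequences), `members` (list mapping
#'   haplotype index to specimen ids), `step_matrix` (integer matrix).
#' @export
collapse_haplotypes <- function(aln, ambiguity_policy = c("exclude_site",
                                                          "mismatch"),
                                gap_mode = c("fifth_run", "ignore")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  gap_mode <- match.arg(gap_mode)
  m <- aln$seq
  ids <- rownames(m)
  n <- nrow(m)
  steps <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      steps[i, j] <- steps[j, i] <-
        hap_steps(m[i, ], m[j, ], ambiguity_policy, gap_mode)
    }
  }
  memb <- components_below(steps, 0L, inclusive = TRUE)
  groups <- split(ids, memb)
  groups <- groups[order(vapply(groups, min, ""))]
  reps <- vapply(groups, function(g) g[[1L]], "")
  k <- length(groups)
  sm <- steps[reps, reps, drop = FALSE]
  dimnames(sm) <- NULL
  structure(list(haplotypes = vapply(reps, function(r)
                   paste(m[r, ], collapse = ""), ""),
                 members = unname(groups),
                 step_matrix = sm,
                 alignment_length = ncol(m),
                 ambiguity_policy = ambiguity_policy,
                 gap_mode = gap_mode),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes over %d specimens (L = %d)\n",
              length(x$members), sum(lengths(x$members)),
              x$alignment_length))
  invisible(x)
}

#' Probability that a j-step connection is parsimonious
#'
#' Probability that `j` observed differences between two sequences of
#' length `L` arose from exactly `j` substitutions at `j` distinct
#' sites, under the neutral model in which each substitution hits a
#' uniformly chosen site: P_j = L! / ((L - j)! L^j).  A superimposed
#' substitution (two hits at one site) is the event that can hide a
#' change and break parsimony.
#'
#' @param j Number of mutational steps.
#' @param L Alignment length.
#' @return Numeric probability in (0, 1].
#' @export
parsimony_probability <- function(j, L) {
  stopifnot(j >= 0, L >= 1)
  if (j > L) return(0)
  i <- seq_len(j) - 1
  prod(1 - i / L)
}

#' Parsimony connection limit
#'
#' The largest number of mutational steps `j*` such that the
#' probability of a parsimonious connection ([parsimony_probability()])
#' still meets the confidence level.  Haplotypes further apart than
#' `j*` steps are left unconnected; the unconnected networks are the
#' candidate entities.
#'
#' @param settings A [parsimony_settings()] object.
#' @return Integer `j*` (>= 1 at conventional lengths and confidence).
#' @examples
#' connection_limit(parsimony_settings(0.95, alignment_length = 440))
#' @export
connection_limit <- function(settings) {
  L <- settings$alignment_length
  C <- settings$confidence
  j <- 1L
  while (j < settings$max_steps_cap &&
         parsimony_probability(j + 1L, L) >= C) j <- j + 1L
  j
}

#' Partition specimens by statistical-parsimony networks
#'
#' Candidate entities are the connected components of the haplotype
#' graph with an edge wherever the step distance is at most `j_star`,
#' expanded back to specimens.  Network-internal topology (intermediate
#' haplotypes) is not computed; components suffice for delimitation.
#'
#' @param hs A [collapse_haplotypes()] result.
#' @param j_star Connection limit in mutational steps.
#' @return A [new_partition()] with method `"parsnet"`.
#' @export
parsimony_networks <- function(hs, j_star) {
  stopifnot(j_star >= 0)
  k <- length(hs$members)
  sm <- hs$step_matrix
  rn <- vapply(hs$members, function(g) min(g), "")
  dimnames(sm) <- list(rn, rn)
  memb <- components_below(sm, j_star, inclusive = TRUE)
  a <- character(0)
  for (h in seq_len(k)) {
    lab <- memb[h]
    a[hs$members[[h]]] <- lab
  }
  # deterministic labels by smallest specimen id per component
  new_partition(label_components(a[sort(names(a))]), method = "parsnet",
                parameters = list(j_star = j_star,
                                  alignment_length = hs$alignment_length))
}

#' One-call statistical parsimony delimitation
#'
#' Collapses haplotypes, computes the connection limit at the given
#' confidence, and returns the network partition.
#'
#' @param aln A [marker_alignment()].
#' @param confidence Parsimony confidence (default 0.95).
#' @param ... Passed to [collapse_haplotypes()].
#' @return A [new_partition()]; the fitted `j_star` is in
#'   `$parameters`.
#' @export
parsnet_partition <- function(aln, confidence = 0.95, ...) {
  hs <- collapse_haplotypes(aln, ...)
  j <- connection_limit(parsimony_settings(confidence, aln$length))
  p <- parsimony_networks(hs, j)
  p$parameters$confidence <- confidence
  p
}
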