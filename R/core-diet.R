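#' Core diet of a predator
#'
#' Restricts a detection matrix to one predator's samples and to the taxa
#' that predator consumed at least `min_occurrence` times (default: more
#' than once), the "core diet". Downstream POO and indices recomputed on
#' the restriction reflect the core diet only.
#'
#' @param x a [detection_matrix()].
#' @param predator predator label.
#' @param min_occurrence minimum incidence count across the predator's
#'   samples for a taxon to be core; `1` is the identity restriction.
#' @return a [detection_matrix()] of the predator's samples and core taxa.
#' @export
core_diet <- function(x, predator, min_occurrence = 2) {
  sub <- subset_predator(x, predator)
  keep <- colSums(sub$incidence) >= min_occurrence
  if (!any(keep)) stop("no core taxa for ", predator, call. = FALSE)
  detection_matrix(sub$incidence[, keep, drop = FALSE], sub$samples,
                   sub$taxa[keep, , drop = FALSE])
}

#' Per-rank overlap counts between two diets
#'
#' Rolls both taxon sets up to each requested rank and counts the unique
#' names private to each predator and shared between them (the numbers
#' behind a Venn diagram). An item resolved only to a coarser rank counts
#' at its own rank and coarser ranks, never at finer ones, so e.g. a
#' family-level detection contributes to the family and order tallies only.
#'
#' @param x_j,x_k [detection_matrix()] objects, typically core diets from
#'   [core_diet()] computed per predator independently.
#' @param ranks ranks to report, default species/genus/family/order.
#' @return a `data.frame` with columns `rank`, `only_j`, `shared`, `only_k`.
#' @export
overlap_sets <- function(x_j, x_k,
                         ranks = c("species", "genus", "family", "order")) {
  stopifnot(inherits(x_j, "detection_matrix"),
            inherits(x_k, "detection_matrix"))
  one_rank <- function(taxa, rank) {
    ri <- match(taxa$rank, RANKS)
    target <- match(rank, RANKS)
    eligible <- ri >= target  # own rank or finer
    nm <- name_at_rank(taxa[eligible, , drop = FALSE], rank)
    unique(nm[!is.na(nm)])
  }
  rows <- lapply(ranks, function(r) {
    sj <- one_rank(x_j$taxa, r)
    sk <- one_rank(x_k$taxa, r)
    data.frame(rank = r,
               only_j = length(setdiff(sj, sk)),
               shared = length(intersect(sj, sk)),
               only_k = length(setdiff(sk, sj)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Family-level partition table of core prey between two predators
#'
#' Counts per-taxon occurrences for each predator and reports, per prey
#' family, how the more important prey items are partitioned between the
#' two diets (the data behind a bipartite web plot). A taxon consumed only
#' once by one predator is still included when the other predator consumed
#' it more than once; taxa consumed at most once by both are dropped.
#' Taxa not resolved to family level are dropped with a message.
#'
#' @param x a [detection_matrix()] holding both predators' samples.
#' @param predator_j,predator_k the two predator labels.
#' @param min_occurrence core threshold, default 2 ("more than once").
#' @return a `data.frame` with columns `family`, `count_j`, `count_k`
#'   (summed occurrence counts per family) plus per-predator labels in
#'   attributes.
#' @export
partition_table <- function(x, predator_j, predator_k, min_occurrence = 2) {
  stopifnot(inherits(x, "detection_matrix"))
  cj <- colSums(x$incidence[x$samples$predator == predator_j, , drop = FALSE])
  ck <- colSums(x$incidence[x$samples$predator == predator_k, , drop = FALSE])
  keep <- pmax(cj, ck) >= min_occurrence & (cj + ck) > 0
  fam <- x$taxa$family
  no_family <- keep & is.na(fam)
  if (any(no_family)) {
    message("partition_table: dropping ", sum(no_family),
            " taxon/taxa not resolved to family level")
    keep <- keep & !is.na(fam)
  }
  if (!any(keep)) {
    return(structure(data.frame(family = character(), count_j = numeric(),
                                count_k = numeric(), stringsAsFactors = FALSE),
                     predators = c(predator_j, predator_k)))
  }
  fam <- fam[keep]
  tj <- tapply(cj[keep], fam, sum)
  tk <- tapply(ck[keep], fam, sum)
  fams <- sort(unique(fam))
  out <- data.frame(family = fams,
                    count_j = as.numeric(tj[fams]),
                    count_k = as.numeric(tk[fams]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "predators") <- c(predator_j, predator_k)
  out
}

#' Per-sample prey richness
#'
#' Number of distinct prey taxa detected in each of a predator's samples.
#'
#' @param x a [detection_matrix()].
#' @param predator predator label.
#' @return named integer vector, one entry per sample.
#' @export
per_sample_richness <- function(x, predator) {
  sub <- subset_predator(x, predator)
  rowSums(sub$incidence)
}

#' Unpaired two-sample Wilcoxon rank-sum test
#'
#' Compares per-sample prey counts (or any two samples) with the
#' Mann-Whitney form of the rank-sum test. `W` is the Mann-Whitney
#' statistic of the first group. The exact null distribution is used when
#' both groups are small and tie-free (`"auto"`: n1 + n2 <= 20 and no
#' ties); otherwise a tie-corrected normal approximation with 0.5
#' continuity correction. Two-sided p throughout.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return a list with `W`, `p`, and the `mode` actually used.
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) > 0L, length(y) > 0L)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups; p = 1")
    return(list(W = length(x) * length(y) / 2, p = 1, mode = "degenerate"))
  }
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (length(x) + length(y)) <= 20L && !ties)
  if (use_exact && ties) {
    warning("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(W = as.numeric(wt$statistic), p = wt$p.value,
       mode = if (use_exact) "exact" else "normal")
}
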