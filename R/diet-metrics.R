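#' Percentage-of-occurrence diet profile
#'
#' For one predator, counts each prey taxon's incidences across that
#' predator's samples and divides by the total number of prey occurrences,
#' so the profile sums to 1 (POO, percentage of occurrence).
#'
#' @param x a [detection_matrix()].
#' @param predator predator label.
#' @return an object of class `diet_profile`: a list with `predator`, `p`
#'   (named POO vector over detected taxa, sums to 1), `counts` (incidence
#'   counts), `n_samples`, `total_occurrences` and the `taxa` lineage table.
#' @export
poo <- function(x, predator) {
  stopifnot(inherits(x, "detection_matrix"))
  sub <- subset_predator(x, predator)
  counts <- colSums(sub$incidence)
  total <- sum(counts)
  if (total == 0) stop("empty diet: no detections for ", predator,
                       call. = FALSE)
  structure(list(predator = predator,
                 p = counts / total,
                 counts = counts,
                 n_samples = nrow(sub$incidence),
                 total_occurrences = total,
                 taxa = sub$taxa),
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat("<diet_profile> ", x$predator, ": ", length(x$p), " taxa, ",
      x$total_occurrences, " occurrences over ", x$n_samples, " samples\n",
      sep = "")
  top <- sort(x$p, decreasing = TRUE)[seq_len(min(5L, length(x$p)))]
  cat("  top POO: ", paste(sprintf("%s %.3f", names(top), top),
                           collapse = "; "), "\n", sep = "")
  invisible(x)
}

as_poo_vector <- function(x) {
  if (inherits(x, "diet_profile")) return(x$p)
  p <- as.numeric(x)
  if (any(p < 0) || sum(p) <= 0) stop("invalid proportion vector",
                                      call. = FALSE)
  names(p) <- names(x)
  p / sum(p)
}

#' Hill number (effective number of species) of order q
#'
#' Evaluates `(sum p_i^q)^(1/(1-q))` for `q != 1` and the continuous limit
#' `exp(-sum p_i log p_i)` at `q = 1`. `q = 0` counts taxa, `q = 2` is the
#' inverse Simpson concentration; larger q down-weights rare prey.
#'
#' @param x a `diet_profile` or a vector of proportions (normalised to
#'   sum 1 if needed).
#' @param q order of diversity, `q >= 0`.
#' @return the effective number of species, a value in `[1, S]`.
#' @export
hill_number <- function(x, q) {
  p <- as_poo_vector(x)
  p <- p[p > 0]
  stopifnot(length(q) == 1L, q >= 0)
  if (abs(q - 1) < 1e-9) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Shannon diversity index (natural log)
#'
#' `H' = -sum p_i log_e p_i` over a POO profile.
#'
#' @inheritParams hill_number
#' @return Shannon index in nats.
#' @export
shannon_index <- function(x) {
  p <- as_poo_vector(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Simpson diversity index, reported as 1 - D
#'
#' `D = sum p_i^2` is the Simpson concentration; the index returned is
#' `1 - D`, the probability that two random prey occurrences are different
#' taxa.
#'
#' @inheritParams hill_number
#' @return `1 - sum(p_i^2)`, in `[0, 1]`.
#' @export
simpson_index <- function(x) {
  p <- as_poo_vector(x)
  1 - sum(p^2)
}

#' Levins niche breadth with normalisation
#'
#' `B = 1 / sum p_i^2` ranges from 1 (single resource) to the number of
#' resource states. The normalised form `(B - 1) / (S - 1)` rescales to
#' `[0, 1]`, where 0 indicates a highly specialised diet and 1 an even use
#' of every resource state in the basis.
#'
#' @inheritParams hill_number
#' @param s_basis resource-state count used for normalisation; the default
#'   `"observed"` uses the predator's own observed consumed-taxon count.
#' @return a list with `B`, `B_normalized` and `S_basis`.
#' @export
levins_breadth <- function(x, s_basis = "observed") {
  p <- as_poo_vector(x)
  p <- p[p > 0]
  B <- 1 / sum(p^2)
  S <- if (identical(s_basis, "observed")) length(p) else as.numeric(s_basis)
  stopifnot(S >= 1)
  if (S == 1) {
    # degenerate single-resource diet: maximally specialised
    message("levins_breadth: single resource state; normalised breadth set to 0")
    Bn <- 0
  } else {
    Bn <- (B - 1) / (S - 1)
  }
  list(B = B, B_normalized = Bn, S_basis = S)
}

#' Pianka niche overlap between two diet profiles
#'
#' `O_jk = sum(p_ij p_ik) / sqrt(sum(p_ij^2) sum(p_ik^2))`, the symmetric
#' cosine-type similarity of two resource-use proportion vectors, 0 for
#' disjoint and 1 for proportional diets. Profiles are aligned on the union
#' of their taxa (absent taxa get p = 0). With `rank` given, each profile
#' is first aggregated to that rank by summing POO; an item resolved only
#' to a coarser rank keeps its own identity in the aggregation (it cannot
#' be split downward).
#'
#' @param profile_j,profile_k `diet_profile` objects (or named proportion
#'   vectors when `rank = "as-is"`).
#' @param rank `"as-is"` (default) or one of `"species"`, `"genus"`,
#'   `"family"`, `"order"`.
#' @return a list with `O_jk`, `rank` and the predator labels.
#' @export
pianka_overlap <- function(profile_j, profile_k, rank = "as-is") {
  pj <- aggregate_profile(profile_j, rank)
  pk <- aggregate_profile(profile_k, rank)
  if (length(pj) == 0L || length(pk) == 0L) {
    stop("cannot compute overlap on an empty profile", call. = FALSE)
  }
  taxa <- union(names(pj), names(pk))
  a <- b <- stats::setNames(numeric(length(taxa)), taxa)
  a[names(pj)] <- pj
  b[names(pk)] <- pk
  O <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  list(O_jk = as.numeric(O), rank = rank,
       predators = c(profile_label(profile_j), profile_label(profile_k)))
}

profile_label <- function(x) {
  if (inherits(x, "diet_profile")) x$predator else NA_character_
}

# sum POO within the requested rank; coarser-than-rank items keep their id
aggregate_profile <- function(x, rank) {
  p <- as_poo_vector(x)
  if (identical(rank, "as-is")) return(p)
  stopifnot(rank %in% RANKS)
  if (!inherits(x, "diet_profile")) {
    stop("rank aggregation needs a diet_profile with lineage information",
         call. = FALSE)
  }
  tx <- x$taxa[match(names(p), x$taxa$taxon_id), , drop = FALSE]
  label <- name_at_rank(tx, rank)
  label <- ifelse(is.na(label), names(p), taxon_label(rank, label))
  tapply(p, label, sum)[unique(label)]
}

#' Diversity profile of a diet
#'
#' Hill numbers over a grid of q values plus the classical Shannon and
#' Simpson indices and Levins breadth, in one table.
#'
#' @inheritParams hill_number
#' @param q q-value grid, default `c(0, 1, 2)`.
#' @param s_basis passed to [levins_breadth()].
#' @return a `data.frame` with one row per q (`q`, `qD`) and the scalar
#'   indices attached as attributes `shannon`, `simpson`, `levins`.
#' @export
diversity_profile <- function(x, q = c(0, 1, 2), s_basis = "observed") {
  qD <- vapply(q, function(qq) hill_number(x, qq), numeric(1))
  out <- data.frame(q = q, qD = qD)
  attr(out, "shannon") <- shannon_index(x)
  attr(out, "simpson") <- simpson_index(x)
  attr(out, "levins") <- levins_breadth(x, s_basis)
  out
}
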