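#' Incidence frequency counts Q_j
#'
#' From a binary incidence matrix, the number of taxa found in exactly j
#' sampling units, for j = 1..T. The input of the ICE estimator.
#'
#' @param x a [detection_matrix()] or a binary samples x taxa matrix.
#' @return a list with `T` (number of sampling units), `Q` (named vector,
#'   `Q[j]` = number of taxa found in exactly j units) and `m_inf_units`,
#'   a function giving the number of units holding at least one taxon from
#'   a supplied taxon subset.
#' @keywords internal
incidence_frequencies <- function(x) {
  inc <- if (inherits(x, "detection_matrix")) x$incidence else as.matrix(x)
  Tn <- nrow(inc)
  counts <- colSums(inc)
  Q <- tabulate(counts, nbins = Tn)
  names(Q) <- seq_len(Tn)
  list(T = Tn, Q = Q, counts = counts, incidence = inc)
}

#' Sample-based species accumulation curve
#'
#' Mean (and sd) cumulative prey richness over random permutations of
#' sample order, computed with `vegan::specaccum(method = "random")`.
#' Each permutation's curve is monotone non-decreasing and ends at the
#' observed richness.
#'
#' @param x a [detection_matrix()] or binary matrix.
#' @param n_perm number of permutations, default 100.
#' @param seed integer seed for the permutation generator.
#' @return a `data.frame` with columns `t`, `mean`, `sd`; the seed is
#'   recorded in the `"seed"` attribute.
#' @export
accumulation_curve <- function(x, n_perm = 100, seed = 1L) {
  inc <- if (inherits(x, "detection_matrix")) x$incidence else as.matrix(x)
  if (nrow(inc) == 1L) {
    out <- data.frame(t = 1L, mean = sum(inc > 0), sd = 0)
    attr(out, "seed") <- seed
    return(out)
  }
  set.seed(seed)
  sac <- vegan::specaccum(inc, method = "random", permutations = n_perm)
  out <- data.frame(t = sac$sites, mean = sac$richness, sd = sac$sd)
  attr(out, "seed") <- seed
  out
}

#' Roll incidence counts up to a coarser rank
#'
#' Sums the per-taxon incidence counts of all member taxa of each higher
#' taxon at the requested rank, producing abundance-style pseudo-counts
#' (e.g. a genus containing five once-detected species gets count 5) for
#' the abundance-based richness estimator. A taxon lacking the requested
#' ancestor rank is grouped under its finest available ancestor, with a
#' message.
#'
#' @param x a [detection_matrix()].
#' @param rank one of `"genus"`, `"family"`, `"order"` (or `"species"` for
#'   the identity roll-up).
#' @return named numeric vector of summed incidence counts per higher
#'   taxon.
#' @export
aggregate_rank_counts <- function(x, rank) {
  stopifnot(inherits(x, "detection_matrix"), rank %in% RANKS)
  counts <- colSums(x$incidence)
  taxa <- x$taxa
  label <- name_at_rank(taxa, rank)
  missing_rank <- is.na(label)
  if (any(missing_rank)) {
    # fall back to the finest ancestor that is resolved (coarsest first)
    for (r in rev(seq_len(match(rank, RANKS)))) {
      cand <- name_at_rank(taxa, RANKS[r])
      fill <- missing_rank & is.na(label) & !is.na(cand)
      label[fill] <- paste0(RANKS[r], ":", cand[fill])
    }
    still <- is.na(label)
    if (any(still)) label[still] <- taxa$taxon_id[still]
    message("aggregate_rank_counts: ", sum(missing_rank),
            " taxon/taxa lacked a ", rank,
            " ancestor; grouped under their finest available ancestor")
  }
  out <- tapply(counts, label, sum)
  out[sort(names(out))]
}

#' ICE incidence-based coverage estimator of species richness
#'
#' Classic Lee-Chao form. Taxa found in at most `k` sampling units are the
#' infrequent group; with `Q_j` the number of taxa found in exactly j
#' units, `N_inf = sum_{j<=k} j Q_j`, sample coverage
#' `C_ICE = 1 - Q_1 / N_inf`, and the coefficient of variation term
#' `gamma^2 = max((D_inf / C_ICE) (m_inf / (m_inf - 1))
#' sum_{j<=k} j (j-1) Q_j / N_inf^2 - 1, 0)` over the `m_inf` units that
#' contain at least one infrequent taxon,
#' `S_ICE = D_freq + D_inf / C_ICE + (Q_1 / C_ICE) gamma^2`.
#'
#' When every infrequent taxon is a unique (`C_ICE = 0`), the estimator is
#' undefined and the Chao2 estimator (bias-corrected when `Q_2 = 0`) is
#' returned instead, flagged via `fallback`.
#'
#' @param x a [detection_matrix()] or binary incidence matrix (at least two
#'   sampling units).
#' @param k infrequent-group cutoff, default 10 sampling units.
#' @return a list with `S_obs`, `S_est`, `coverage` (= S_obs / S_est),
#'   `fallback` (`NA` or `"chao2"`) and the intermediate quantities.
#' @export
ice <- function(x, k = 10) {
  fr <- incidence_frequencies(x)
  if (fr$T < 2L) stop("ICE needs at least two sampling units", call. = FALSE)
  counts <- fr$counts
  S_obs <- sum(counts > 0)
  infreq <- counts > 0 & counts <= k
  D_inf <- sum(infreq)
  D_freq <- S_obs - D_inf
  j <- seq_len(min(k, fr$T))
  Qj <- fr$Q[j]
  N_inf <- sum(j * Qj)
  Q1 <- if (fr$T >= 1) fr$Q[["1"]] else 0

  if (D_inf == 0L) {
    return(list(S_obs = S_obs, S_est = as.numeric(S_obs), coverage = 1,
                fallback = NA_character_, C_ice = 1, gamma2 = 0, k = k))
  }
  C_ice <- 1 - Q1 / N_inf
  if (C_ice <= 0) {
    est <- chao2(fr$Q, fr$T)
    return(list(S_obs = S_obs, S_est = est, coverage = S_obs / est,
                fallback = "chao2", C_ice = C_ice, gamma2 = NA_real_, k = k))
  }
  m_inf <- sum(rowSums(fr$incidence[, infreq, drop = FALSE]) > 0)
  gamma2 <- if (m_inf > 1) {
    max((D_inf / C_ice) * (m_inf / (m_inf - 1)) *
          sum(j * (j - 1) * Qj) / N_inf^2 - 1, 0)
  } else 0
  S_est <- D_freq + D_inf / C_ice + (Q1 / C_ice) * gamma2
  list(S_obs = S_obs, S_est = S_est, coverage = S_obs / S_est,
       fallback = NA_character_, C_ice = C_ice, gamma2 = gamma2, k = k)
}

chao2 <- function(Q, Tn) {
  Q1 <- Q[["1"]]
  Q2 <- if (Tn >= 2) Q[["2"]] else 0
  S_obs <- sum(Q)
  corr <- (Tn - 1) / Tn
  if (Q2 > 0) S_obs + corr * Q1^2 / (2 * Q2)
  else S_obs + corr * Q1 * (Q1 - 1) / 2
}

#' ACE abundance-based coverage estimator of species richness
#'
#' Taxa with total count at most `k` form the rare group; with `F_i` the
#' number of taxa with count exactly i, `N_rare = sum_{i<=k} i F_i`,
#' `C_ACE = 1 - F_1 / N_rare`,
#' `gamma^2 = max((S_rare / C_ACE) sum_{i<=k} i (i-1) F_i /
#' (N_rare (N_rare - 1)) - 1, 0)` and
#' `S_ACE = S_abund + S_rare / C_ACE + (F_1 / C_ACE) gamma^2`.
#' When `C_ACE = 0` the Chao1 estimator is returned instead (flagged).
#'
#' @param counts named vector of per-taxon counts (e.g. rank-aggregated
#'   incidence counts from [aggregate_rank_counts()]).
#' @param k rare-group cutoff, default 10.
#' @return a list with `S_obs`, `S_est`, `coverage`, `fallback` and the
#'   intermediate quantities.
#' @export
ace <- function(counts, k = 10) {
  counts <- counts[counts > 0]
  if (sum(counts) < 1) stop("ACE needs a positive total count", call. = FALSE)
  S_obs <- length(counts)
  rare <- counts <= k
  S_rare <- sum(rare)
  S_abund <- S_obs - S_rare
  if (S_rare == 0L) {
    return(list(S_obs = S_obs, S_est = as.numeric(S_obs), coverage = 1,
                fallback = NA_character_, C_ace = 1, gamma2 = 0, k = k))
  }
  F1 <- sum(counts == 1)
  N_rare <- sum(counts[rare])
  C_ace <- 1 - F1 / N_rare
  if (C_ace <= 0) {
    F2 <- sum(counts == 2)
    est <- if (F2 > 0) S_obs + F1^2 / (2 * F2)
           else S_obs + F1 * (F1 - 1) / 2
    return(list(S_obs = S_obs, S_est = est, coverage = S_obs / est,
                fallback = "chao1", C_ace = C_ace, gamma2 = NA_real_, k = k))
  }
  i <- seq_len(k)
  Fi <- vapply(i, function(v) sum(counts == v), numeric(1))
  gamma2 <- if (N_rare > 1) {
    max((S_rare / C_ace) * sum(i * (i - 1) * Fi) /
          (N_rare * (N_rare - 1)) - 1, 0)
  } else 0
  S_est <- S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2
  list(S_obs = S_obs, S_est = S_est, coverage = S_obs / S_est,
       fallback = NA_character_, C_ace = C_ace, gamma2 = gamma2, k = k)
}

#' Richness coverage summary per taxonomic level
#'
#' For one predator: observed richness, estimated total richness and
#' sampling coverage at the species level (ICE on the incidence matrix)
#' and at the genus, family and order levels (ACE on rank-aggregated
#' incidence counts, treated as pseudo-abundances).
#'
#' @param x a [detection_matrix()].
#' @param predator predator label.
#' @param k estimator cutoff, default 10.
#' @return a `data.frame` with columns `level`, `estimator`, `S_obs`,
#'   `S_est`, `coverage`, `fallback`.
#' @export
richness_summary <- function(x, predator, k = 10) {
  sub <- subset_predator(x, predator)
  rows <- list()
  sp <- ice(sub, k = k)
  rows[[1]] <- data.frame(level = "species", estimator = "ICE",
                          S_obs = sp$S_obs, S_est = sp$S_est,
                          coverage = sp$coverage,
                          fallback = sp$fallback %||% NA_character_,
                          stringsAsFactors = FALSE)
  for (lev in c("genus", "family", "order")) {
    counts <- suppressMessages(aggregate_rank_counts(sub, lev))
    est <- ace(counts, k = k)
    rows[[length(rows) + 1L]] <- data.frame(level = lev, estimator = "ACE",
                                            S_obs = est$S_obs,
                                            S_est = est$S_est,
                                            coverage = est$coverage,
                                            fallback = est$fallback %||%
                                              NA_character_,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$predator <- predator
  out[, c("predator", "level", "estimator", "S_obs", "S_est", "coverage",
          "fallback")]
}
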