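#' Configuration for the synthetic two-predator dataset generator
#'
#' Describes a study in which two predator species sample a partially
#' shared prey pool: per-sample prey counts, two-marker detection with
#' dropout, read-count magnitudes, assignment-identity mixtures spanning
#' the filtering thresholds, and prey trait labels. Defaults are sized to
#' a two-bat fecal metabarcoding study: 53 and 45 samples, a ~300-taxon
#' prey pool, mean 6 and 14 prey per sample, and gleanable-prey preference
#' mass of about 0.37 and 0.21.
#'
#' @param predators character vector of the two predator names.
#' @param n_samples samples per predator (length 2).
#' @param S_pool total prey taxa in the regional pool (>= 2).
#' @param frac_shared proportion of the pool available to both predators;
#'   the rest is split evenly into predator-exclusive taxa.
#' @param concentration symmetric Dirichlet concentration of each
#'   predator's prey-preference vector over its available taxa (smaller =
#'   more uneven diet).
#' @param prey_per_sample mean distinct prey per sample, per predator
#'   (length 2 or scalar); counts are Poisson (or negative binomial when
#'   `dispersion` is set), truncated to `[1, available taxa]`.
#' @param dispersion optional negative-binomial size parameter for the
#'   per-sample prey count; `NULL` = Poisson.
#' @param p_detect_coi,p_detect_s16 per-item detection probability of each
#'   marker.
#' @param marker_detect_cor Gaussian-copula correlation between the two
#'   markers' detection events (0 = independent).
#' @param read_meanlog,read_sdlog log-normal parameters of per-ZOTU read
#'   counts.
#' @param coi_band_weights probabilities that a COI assignment's identity
#'   falls in the species (>= 98), family (\[96, 98)), order (\[90, 96)) or
#'   failing (< 90) band.
#' @param s16_fail probability that a 16S assignment fails one of its
#'   identity / alignment-length / E-value thresholds.
#' @param frac_gleanable per-predator target proportion of the diet
#'   (preference mass) on gleanable prey (non-volant, or volant but
#'   diurnal). Shared taxa get the mean target as their label probability;
#'   each predator's exclusive taxa absorb the remainder, so differing
#'   targets create a genuine between-species capture-mode effect.
#' @param seed integer seed; a fixed seed makes the generated dataset
#'   fully reproducible.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(predators = c("Murina ussuriensis",
                                       "Myotis ikonnikovi"),
                         n_samples = c(53, 45),
                         S_pool = 300,
                         frac_shared = 0.5,
                         concentration = 1,
                         prey_per_sample = c(6, 14),
                         dispersion = NULL,
                         p_detect_coi = 0.8,
                         p_detect_s16 = 0.7,
                         marker_detect_cor = 0,
                         read_meanlog = log(150),
                         read_sdlog = 1.2,
                         coi_band_weights = c(species = 0.75, family = 0.12,
                                              order = 0.08, fail = 0.05),
                         s16_fail = 0.05,
                         frac_gleanable = c(0.37, 0.21),
                         seed = 1L) {
  stopifnot(length(predators) == 2L, S_pool >= 2, all(n_samples >= 1),
            frac_shared >= 0, frac_shared <= 1,
            p_detect_coi >= 0, p_detect_coi <= 1,
            p_detect_s16 >= 0, p_detect_s16 <= 1,
            marker_detect_cor >= 0, marker_detect_cor <= 1,
            all(frac_gleanable >= 0), all(frac_gleanable <= 1),
            concentration > 0, length(coi_band_weights) == 4L,
            abs(sum(coi_band_weights) - 1) < 1e-9,
            s16_fail >= 0, s16_fail <= 1)
  if (length(n_samples) == 1L) n_samples <- rep(n_samples, 2L)
  if (length(prey_per_sample) == 1L) prey_per_sample <- rep(prey_per_sample, 2L)
  if (length(frac_gleanable) == 1L) frac_gleanable <- rep(frac_gleanable, 2L)
  structure(list(predators = predators, n_samples = n_samples,
                 S_pool = S_pool, frac_shared = frac_shared,
                 concentration = concentration,
                 prey_per_sample = prey_per_sample, dispersion = dispersion,
                 p_detect_coi = p_detect_coi, p_detect_s16 = p_detect_s16,
                 marker_detect_cor = marker_detect_cor,
                 read_meanlog = read_meanlog, read_sdlog = read_sdlog,
                 coi_band_weights = coi_band_weights, s16_fail = s16_fail,
                 frac_gleanable = frac_gleanable, seed = as.integer(seed)),
            class = "synth_config")
}

#' Noise-free variant of a synthetic configuration
#'
#' Perfect detection by both markers, every COI identity in the species
#' band, no failing 16S assignments and read counts far above the
#' read-count screen, so the analysis pipeline should recover the
#' simulated consumed-prey incidence matrix exactly.
#'
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_config_perfect <- function(...) {
  args <- list(p_detect_coi = 1, p_detect_s16 = 1,
               coi_band_weights = c(species = 1, family = 0, order = 0,
                                    fail = 0),
               s16_fail = 0, read_meanlog = log(500), read_sdlog = 0.3)
  override <- list(...)
  args[names(override)] <- override
  do.call(synth_config, args)
}

#' Generate a synthetic two-predator metabarcoding dataset
#'
#' Builds a 4-rank taxonomy over the prey pool, draws each predator's prey
#' preference vector, simulates per-sample prey consumption (without
#' replacement, weighted by preference), marker-wise detection with
#' dropout, and per-detection read counts and assignment evidence whose
#' configured fraction fails the inclusion criteria. The returned ground
#' truth is computed from the configuration and the consumed (pre-noise)
#' data.
#'
#' @param cfg a [synth_config()].
#' @return a list with `hits` (list of COI and S16 hit tables in the
#'   format read by [read_hit_table()]), `samples` (metadata), `traits`
#'   (prey trait table), `truth` (list: `preferences`, `pianka`,
#'   `gleaning`, `gleanable`, `lineage`, `consumed` incidence matrix) and
#'   the `config`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  S <- cfg$S_pool

  lineage <- synth_taxonomy(S)

  # availability: shared block + one exclusive block per predator
  n_sh <- round(cfg$frac_shared * S)
  n_ex <- S - n_sh
  n_ex1 <- floor(n_ex / 2)
  idx_sh <- seq_len(n_sh)
  idx_ex1 <- if (n_ex1 > 0) n_sh + seq_len(n_ex1) else integer(0)
  idx_ex2 <- setdiff(seq_len(S), c(idx_sh, idx_ex1))
  avail <- list(c(idx_sh, idx_ex1), c(idx_sh, idx_ex2))

  pref <- matrix(0, nrow = 2, ncol = S,
                 dimnames = list(cfg$predators, lineage$species))
  for (g in 1:2) {
    gam <- stats::rgamma(length(avail[[g]]), shape = cfg$concentration)
    gam[gam <= 0] <- 1e-12
    pref[g, avail[[g]]] <- gam / sum(gam)
  }

  # gleanable labels target each predator's gleanable preference MASS
  # (frac_gleanable). Shared taxa carry one common label probability (the
  # mean target); each predator's exclusive taxa absorb the remainder so
  # that the expected preference mass on gleanable taxa hits the target
  # even though the predators share most of their prey pool.
  p_sh <- mean(cfg$frac_gleanable)
  p_glean <- numeric(S)
  p_glean[idx_sh] <- p_sh
  for (g in 1:2) {
    idx_ex <- if (g == 1) idx_ex1 else idx_ex2
    w_sh <- sum(pref[g, idx_sh])
    w_ex <- sum(pref[g, idx_ex])
    if (w_ex > 0) {
      p_glean[idx_ex] <- min(max((cfg$frac_gleanable[g] - w_sh * p_sh) /
                                   w_ex, 0.02), 0.98)
    }
  }
  gleanable <- stats::rbinom(S, 1, p_glean) == 1
  traits <- synth_traits(lineage, gleanable)

  truth <- list(
    preferences = pref,
    pianka = sum(pref[1, ] * pref[2, ]) /
      sqrt(sum(pref[1, ]^2) * sum(pref[2, ]^2)),
    gleaning = stats::setNames(as.numeric(pref %*% gleanable),
                               cfg$predators),
    gleanable = stats::setNames(gleanable, lineage$species),
    lineage = lineage
  )

  prefix <- toupper(substr(gsub("[^A-Za-z]", "", cfg$predators), 1, 3))
  sample_ids <- unlist(lapply(1:2, function(g)
    sprintf("%s%03d", prefix[g], seq_len(cfg$n_samples[g]))))
  predator_of <- rep(cfg$predators, cfg$n_samples)

  consumed <- matrix(0L, nrow = length(sample_ids), ncol = S,
                     dimnames = list(sample_ids,
                                     taxon_label("species", lineage$species)))
  coi_rows <- list()
  s16_rows <- list()
  zc <- c(COI = 0L, S16 = 0L)

  for (si in seq_along(sample_ids)) {
    g <- match(predator_of[si], cfg$predators)
    n_av <- length(avail[[g]])
    k <- if (is.null(cfg$dispersion)) {
      stats::rpois(1, cfg$prey_per_sample[g])
    } else {
      stats::rnbinom(1, size = cfg$dispersion, mu = cfg$prey_per_sample[g])
    }
    if (k > n_av) {
      warning("prey count ", k, " exceeds available taxa; truncated to ",
              n_av)
      k <- n_av
    }
    k <- max(1L, k)
    items <- sample(avail[[g]], k, prob = pref[g, avail[[g]]])
    consumed[si, items] <- 1L

    # marker detection via a Gaussian copula (independent by default)
    z0 <- stats::rnorm(k)
    r <- cfg$marker_detect_cor
    z1 <- sqrt(r) * z0 + sqrt(1 - r) * stats::rnorm(k)
    z2 <- sqrt(r) * z0 + sqrt(1 - r) * stats::rnorm(k)
    det_coi <- items[stats::pnorm(z1) < cfg$p_detect_coi]
    det_s16 <- items[stats::pnorm(z2) < cfg$p_detect_s16]

    if (length(det_coi) > 0) {
      rows <- synth_coi_hits(det_coi, sample_ids[si], lineage, cfg, zc["COI"])
      zc["COI"] <- zc["COI"] + nrow(rows)
      coi_rows[[length(coi_rows) + 1L]] <- rows
    }
    if (length(det_s16) > 0) {
      rows <- synth_s16_hits(det_s16, sample_ids[si], lineage, cfg, zc["S16"])
      zc["S16"] <- zc["S16"] + nrow(rows)
      s16_rows[[length(s16_rows) + 1L]] <- rows
    }
  }

  hits <- list(COI = do.call(rbind, c(coi_rows, list(empty_hit_table("COI")))),
               S16 = do.call(rbind, c(s16_rows, list(empty_hit_table("S16")))))
  rownames(hits$COI) <- NULL
  rownames(hits$S16) <- NULL

  host_reads <- function(n) round(stats::rlnorm(n, log(8000), 0.4))
  prey_reads <- function(tab) {
    v <- tapply(tab$read_count, tab$sample_id, sum)
    out <- stats::setNames(numeric(length(sample_ids)), sample_ids)
    out[names(v)] <- v
    out
  }
  samples <- data.frame(
    sample_id = sample_ids,
    predator = predator_of,
    sex = sample(c("f", "m"), length(sample_ids), replace = TRUE),
    age = sample(c("ad", "j"), length(sample_ids), replace = TRUE,
                 prob = c(0.85, 0.15)),
    year = sample(2015:2017, length(sample_ids), replace = TRUE),
    site = sample(1:20, length(sample_ids), replace = TRUE),
    total_reads_coi = prey_reads(hits$COI) + host_reads(length(sample_ids)),
    total_reads_s16 = prey_reads(hits$S16) + host_reads(length(sample_ids)),
    stringsAsFactors = FALSE
  )
  rownames(samples) <- NULL
  truth$consumed <- consumed

  list(hits = hits, samples = samples, traits = traits, truth = truth,
       config = cfg)
}

# nested 4-rank taxonomy: 12 orders, ~S/5 families, ~S/2.5 genera
synth_taxonomy <- function(S) {
  order_names <- c("Lepidoptera", "Diptera", "Coleoptera", "Hemiptera",
                   "Trichoptera", "Neuroptera", "Hymenoptera", "Orthoptera",
                   "Ephemeroptera", "Plecoptera", "Araneae", "Mecoptera")
  n_fam <- max(12L, round(S / 5))
  n_gen <- max(n_fam, round(S / 2.5))
  fam_order <- c(seq_along(order_names),
                 sample(seq_along(order_names), n_fam - length(order_names),
                        replace = TRUE))
  gen_fam <- c(seq_len(n_fam),
               sample(seq_len(n_fam), n_gen - n_fam, replace = TRUE))
  sp_gen <- c(seq_len(n_gen)[seq_len(min(n_gen, S))],
              sample(seq_len(n_gen), max(0L, S - n_gen), replace = TRUE))
  fam_names <- sprintf("Fam%03d", seq_len(n_fam))
  gen_names <- sprintf("Gen%03d", seq_len(n_gen))
  sp_names <- sprintf("%s sp%03d", gen_names[sp_gen], seq_len(S))
  data.frame(species = sp_names,
             genus = gen_names[sp_gen],
             family = fam_names[gen_fam[sp_gen]],
             order = order_names[fam_order[gen_fam[sp_gen]]],
             stringsAsFactors = FALSE)
}

# species-level trait rows; family-level rows added where the family is
# uniform, so detections demoted to family rank stay classifiable
synth_traits <- function(lineage, gleanable) {
  volant <- ifelse(gleanable,
                   ifelse(stats::runif(nrow(lineage)) < 0.5, "non_volant",
                          "volant"),
                   "volant")
  diel <- ifelse(volant == "non_volant", NA_character_,
                 ifelse(gleanable, "diurnal", "nocturnal"))
  sp <- data.frame(taxon = lineage$species, rank = "species",
                   volant = volant, diel = diel, stringsAsFactors = FALSE)
  fam_rows <- lapply(split(sp, lineage$family), function(d) {
    if (length(unique(d$volant)) == 1L &&
        length(unique(ifelse(is.na(d$diel), "-", d$diel))) == 1L) {
      data.frame(taxon = NA_character_, rank = "family",
                 volant = d$volant[1], diel = d$diel[1],
                 stringsAsFactors = FALSE)
    }
  })
  fams <- names(fam_rows)[!vapply(fam_rows, is.null, logical(1))]
  fam_df <- do.call(rbind, fam_rows[fams])
  if (!is.null(fam_df)) {
    fam_df$taxon <- fams
    sp <- rbind(sp, fam_df)
  }
  rownames(sp) <- NULL
  sp
}

synth_coi_hits <- function(items, sample_id, lineage, cfg, z0) {
  bands <- sample(names(cfg$coi_band_weights), length(items), replace = TRUE,
                  prob = cfg$coi_band_weights)
  rows <- list()
  for (i in seq_along(items)) {
    nz <- 1L + (stats::runif(1) < 0.15)
    ident <- switch(bands[i],
                    species = stats::runif(nz, 98, 100),
                    family = stats::runif(nz, 96, 97.99),
                    order = stats::runif(nz, 90, 95.99),
                    fail = stats::runif(nz, 80, 89.9))
    li <- lineage[items[i], ]
    rows[[i]] <- data.frame(
      sample_id = sample_id, marker = "COI", zotu_id = "tmp",
      read_count = pmax(1, round(stats::rlnorm(nz, cfg$read_meanlog,
                                               cfg$read_sdlog))),
      pct_identity = round(ident, 2),
      align_length = round(stats::runif(nz, 120, 160)),
      e_value = 10^stats::runif(nz, -45, -10),
      order = li$order, family = li$family, genus = li$genus,
      species = li$species, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$zotu_id <- sprintf("ZCOI%06d", z0 + seq_len(nrow(out)))
  out
}

synth_s16_hits <- function(items, sample_id, lineage, cfg, z0) {
  fails <- stats::runif(length(items)) < cfg$s16_fail
  rows <- list()
  for (i in seq_along(items)) {
    nz <- 1L + (stats::runif(1) < 0.15)
    ident <- stats::runif(nz, 90, 100)
    align <- round(stats::runif(nz, 100, 180))
    eval_ <- 10^stats::runif(nz, -40, -8)
    if (fails[i]) {
      mode <- sample(c("identity", "align", "evalue"), 1)
      if (mode == "identity") ident <- stats::runif(nz, 75, 89.9)
      if (mode == "align") align <- round(stats::runif(nz, 40, 99))
      if (mode == "evalue") eval_ <- 10^stats::runif(nz, -6.9, -2)
    }
    li <- lineage[items[i], ]
    rows[[i]] <- data.frame(
      sample_id = sample_id, marker = "S16", zotu_id = "tmp",
      read_count = pmax(1, round(stats::rlnorm(nz, cfg$read_meanlog,
                                               cfg$read_sdlog))),
      pct_identity = round(ident, 2),
      align_length = align,
      e_value = eval_,
      order = li$order, family = li$family, genus = li$genus,
      species = li$species, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$zotu_id <- sprintf("ZS16%06d", z0 + seq_len(nrow(out)))
  out
}

#' True Pianka overlap of a synthetic dataset
#'
#' The overlap of the two generating preference vectors, before any
#' sampling noise.
#'
#' @param truth the `truth` element of [generate_dataset()] output (or the
#'   full output list).
#' @return the true overlap in `[0, 1]`.
#' @export
true_pianka <- function(truth) {
  if (!is.null(truth$truth)) truth <- truth$truth
  truth$pianka
}

#' True gleanable-prey preference mass per predator
#'
#' @inheritParams true_pianka
#' @return named numeric vector, one proportion per predator.
#' @export
true_gleaning <- function(truth) {
  if (!is.null(truth$truth)) truth <- truth$truth
  truth$gleaning
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param ds output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(hits_coi = file.path(dir, "hits_coi.tsv"),
             hits_s16 = file.path(dir, "hits_s16.tsv"),
             samples = file.path(dir, "samples.tsv"),
             traits = file.path(dir, "traits.tsv"))
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(ds$hits$COI, paths["hits_coi"])
  wt(ds$hits$S16, paths["hits_s16"])
  wt(ds$samples, paths["samples"])
  wt(ds$traits, paths["traits"])
  invisible(paths)
}
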