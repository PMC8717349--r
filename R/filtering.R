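#' Inclusion-criteria configuration for assigned hits
#'
#' Bundles the thresholds used to turn raw marker-level assignments into
#' retained prey detections. Defaults follow common practice for
#' arthropod-diet metabarcoding with a COI barcode and a 16S marker:
#'
#' * a detection needs at least `min_reads` reads for the final assigned
#'   taxon (summed over ZOTUs mapping to that taxon within a
#'   sample x marker);
#' * COI assignments keep their species name at >= 98% identity, are demoted
#'   to the family at \[96, 98) and to the order at \[90, 96), and are
#'   rejected below 90%;
#' * 16S assignments are kept at their assigned rank only when identity
#'   >= 90%, alignment length >= 100 bp and E-value < 1e-7;
#' * samples with fewer than `sample_min_total_reads` total reads are
#'   excluded during QC.
#'
#' Band boundaries are closed on the lower bound and open on the upper.
#'
#' @param min_reads minimum summed read count per (sample, marker, taxon).
#' @param coi_species_identity minimum percent identity for a species-level
#'   COI assignment.
#' @param coi_family_band two-element identity interval \[lo, hi) demoted to
#'   family.
#' @param coi_order_band two-element identity interval \[lo, hi) demoted to
#'   order.
#' @param s16_min_identity minimum percent identity for a 16S assignment.
#' @param s16_min_align minimum 16S alignment length in bp.
#' @param s16_max_evalue 16S assignments need E-value strictly below this.
#' @param sample_min_total_reads sample QC read-depth threshold.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_reads = 10,
                          coi_species_identity = 98,
                          coi_family_band = c(96, 98),
                          coi_order_band = c(90, 96),
                          s16_min_identity = 90,
                          s16_min_align = 100,
                          s16_max_evalue = 1e-7,
                          sample_min_total_reads = 1000) {
  stopifnot(min_reads > 0, sample_min_total_reads > 0,
            length(coi_family_band) == 2L, length(coi_order_band) == 2L)
  if (!(coi_order_band[1] < coi_order_band[2] &&
        coi_order_band[2] <= coi_family_band[1] &&
        coi_family_band[1] < coi_family_band[2] &&
        coi_family_band[2] <= coi_species_identity)) {
    stop("identity bands must be ordered and non-overlapping: ",
         "order band < family band < species threshold", call. = FALSE)
  }
  structure(list(min_reads = min_reads,
                 coi_species_identity = coi_species_identity,
                 coi_family_band = coi_family_band,
                 coi_order_band = coi_order_band,
                 s16_min_identity = s16_min_identity,
                 s16_min_align = s16_min_align,
                 s16_max_evalue = s16_max_evalue,
                 sample_min_total_reads = sample_min_total_reads),
            class = "filter_config")
}

#' Apply rank-dependent identity thresholds to assigned hits
#'
#' For each hit, decides whether it is retained and at which taxonomic rank.
#' COI hits keep their species assignment at high identity and are demoted
#' to coarser ranks in the configured identity bands; 16S hits are retained
#' at their finest assigned rank only when identity, alignment length and
#' E-value all pass. A hit demoted to a rank its taxonomy does not resolve
#' is rejected with reason `"rank unavailable"`.
#'
#' @param hits a hit table as returned by [read_hit_table()].
#' @param cfg a [filter_config()].
#' @return `hits` with added columns `retained` (logical), `rank`
#'   (retained rank or `NA`), `taxon` (name at that rank) and `reason`
#'   (rejection reason for non-retained hits).
#' @export
apply_rank_thresholds <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  n <- nrow(hits)
  rank <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  is_coi <- hits$marker == "COI"
  id <- hits$pct_identity

  # COI: band-based rank demotion
  rank[is_coi & id >= cfg$coi_species_identity] <- "species"
  rank[is_coi & id >= cfg$coi_family_band[1] &
         id < cfg$coi_family_band[2]] <- "family"
  rank[is_coi & id >= cfg$coi_order_band[1] &
         id < cfg$coi_order_band[2]] <- "order"
  reason[is_coi & id < cfg$coi_order_band[1]] <- "below_identity"

  # 16S: retained at its assigned (finest) rank iff all evidence passes
  is_s16 <- hits$marker == "S16"
  s16_pass <- is_s16 & id >= cfg$s16_min_identity &
    hits$align_length >= cfg$s16_min_align &
    hits$e_value < cfg$s16_max_evalue
  rank[s16_pass] <- finest_rank(hits$order, hits$family, hits$genus,
                                hits$species)[s16_pass]
  reason[is_s16 & !s16_pass] <- "failed_16s_thresholds"
  reason[is_s16 & is.na(rank) & s16_pass] <- "rank unavailable"

  # name at the retained rank; missing name => rejection
  taxon <- rep(NA_character_, n)
  for (r in RANKS) {
    sel <- !is.na(rank) & rank == r
    if (any(sel)) taxon[sel] <- name_at_rank(hits[sel, , drop = FALSE], r)
  }
  unavailable <- !is.na(rank) & is.na(taxon)
  reason[unavailable] <- "rank unavailable"
  rank[unavailable | is.na(taxon)] <- NA_character_

  hits$retained <- !is.na(rank) & !is.na(taxon)
  hits$rank <- ifelse(hits$retained, rank, NA_character_)
  hits$taxon <- ifelse(hits$retained, taxon, NA_character_)
  hits$reason <- ifelse(hits$retained, NA_character_, reason)
  hits
}

#' Filter assigned hits into per-marker prey detections
#'
#' Runs the rank thresholds of [apply_rank_thresholds()], sums reads over
#' ZOTUs that map to the same final taxon within a sample and marker,
#' applies the read-count screen to those summed reads, and deduplicates to
#' one detection per (sample, marker, taxon).
#'
#' Lineage columns finer than the retained rank are blanked, so a hit
#' demoted to family rank carries no genus or species name downstream.
#'
#' @inheritParams apply_rank_thresholds
#' @return a `data.frame` of detections with columns `sample_id`, `marker`,
#'   `taxon_id` (rank-qualified, e.g. `"species:Ectropis obliqua"`), `rank`,
#'   `order`, `family`, `genus`, `species` and `reads` (summed).
#' @export
filter_hits <- function(hits, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (nrow(hits) == 0L) return(empty_detections())
  scored <- apply_rank_thresholds(hits, cfg)
  keep <- scored[scored$retained, , drop = FALSE]
  if (nrow(keep) == 0L) return(empty_detections())

  # truncate lineage below the retained rank
  ri <- match(keep$rank, RANKS)
  keep$species[ri < 4L] <- NA_character_
  keep$genus[ri < 3L] <- NA_character_
  keep$family[ri < 2L] <- NA_character_

  keep$taxon_id <- taxon_label(keep$rank, keep$taxon)
  key <- paste(keep$sample_id, keep$marker, keep$taxon_id, sep = "\r")
  reads <- tapply(keep$read_count, key, sum)
  first <- keep[!duplicated(key), , drop = FALSE]
  first$reads <- as.numeric(reads[paste(first$sample_id, first$marker,
                                        first$taxon_id, sep = "\r")])
  out <- first[first$reads >= cfg$min_reads,
               c("sample_id", "marker", "taxon_id", "rank",
                 "order", "family", "genus", "species", "reads"),
               drop = FALSE]
  out <- out[order(out$sample_id, out$marker, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(sample_id = character(), marker = character(),
             taxon_id = character(), rank = character(), order = character(),
             family = character(), genus = character(), species = character(),
             reads = numeric(), stringsAsFactors = FALSE)
}

#' Sample quality control
#'
#' Excludes samples whose sequencing depth is below the configured
#' threshold, and samples that are deep enough but yielded no retained prey
#' detection. In the default `"pooled"` mode the depth criterion applies to
#' the per-sample read total summed over both markers; in `"per_marker"`
#' mode each marker's total must individually reach the threshold.
#'
#' @param samples metadata `data.frame` as from [read_sample_metadata()].
#' @param detections retained detections from [filter_hits()] (both markers
#'   combined with `rbind`).
#' @param cfg a [filter_config()]; supplies the depth threshold.
#' @param mode `"pooled"` (default) or `"per_marker"`.
#' @return a list with `samples` (retained metadata rows) and `exclusions`
#'   (`data.frame` of `sample_id`, `reason` in `"low_reads"`, `"no_prey"`).
#' @export
qc_samples <- function(samples, detections, cfg = filter_config(),
                       mode = c("pooled", "per_marker")) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(detections$sample_id), samples$sample_id)
  if (length(unknown) > 0L) {
    stop("detections refer to sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  thr <- cfg$sample_min_total_reads
  depth_ok <- if (mode == "pooled") {
    (samples$total_reads_coi + samples$total_reads_s16) >= thr
  } else {
    samples$total_reads_coi >= thr & samples$total_reads_s16 >= thr
  }
  has_prey <- samples$sample_id %in% detections$sample_id

  reason <- rep(NA_character_, nrow(samples))
  reason[!depth_ok] <- "low_reads"
  reason[depth_ok & !has_prey] <- "no_prey"

  keep <- is.na(reason)
  list(samples = samples[keep, , drop = FALSE],
       exclusions = data.frame(sample_id = samples$sample_id[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}
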