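#' Construct a prey-incidence (detection) matrix
#'
#' The pivot of the pipeline: a binary samples x prey-taxa matrix with a
#' predator label per sample and a lineage sidecar per taxon. A taxon's
#' identity is its (rank, name) pair, so a detection retained at family
#' rank and a congeneric species-level detection occupy distinct columns.
#'
#' @param incidence integer matrix of 0/1, rows named by sample id, columns
#'   by rank-qualified taxon id.
#' @param samples `data.frame` with at least `sample_id` and `predator`,
#'   one row per matrix row.
#' @param taxa `data.frame` with `taxon_id`, `rank`, `order`, `family`,
#'   `genus`, `species`, one row per matrix column.
#' @return an object of class `detection_matrix`.
#' @export
detection_matrix <- function(incidence, samples, taxa) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "integer"
  if (!all(incidence %in% c(0L, 1L))) {
    stop("incidence cells must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(colnames(incidence)) || anyDuplicated(rownames(incidence))) {
    stop("duplicate sample or taxon ids in incidence matrix", call. = FALSE)
  }
  if (!identical(rownames(incidence), samples$sample_id)) {
    samples <- samples[match(rownames(incidence), samples$sample_id), ,
                       drop = FALSE]
  }
  if (anyNA(samples$sample_id)) {
    stop("every matrix row needs a metadata row", call. = FALSE)
  }
  if (!identical(colnames(incidence), taxa$taxon_id)) {
    taxa <- taxa[match(colnames(incidence), taxa$taxon_id), , drop = FALSE]
  }
  if (anyNA(taxa$taxon_id)) {
    stop("every matrix column needs a taxa sidecar row", call. = FALSE)
  }
  if (ncol(incidence) > 0L && any(colSums(incidence) == 0L)) {
    stop("every taxon must be detected in at least one sample", call. = FALSE)
  }
  rownames(samples) <- NULL
  rownames(taxa) <- NULL
  structure(list(incidence = incidence, samples = samples, taxa = taxa),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("<detection_matrix> ", nrow(x$incidence), " samples x ",
      ncol(x$incidence), " prey taxa\n", sep = "")
  tab <- table(x$samples$predator)
  cat("  predators: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  cat("  taxon ranks: ",
      paste(sprintf("%s %d", names(table(x$taxa$rank)),
                    as.integer(table(x$taxa$rank))), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Merge two-marker detections into a single incidence matrix
#'
#' Within each sample, a taxon detected by both the COI and the 16S marker
#' contributes exactly one incidence, so a prey item's presence is never
#' counted twice.
#'
#' @param detections combined detections from [filter_hits()] (both
#'   markers), typically after [qc_samples()].
#' @param samples retained sample metadata (`sample_id`, `predator`, ...).
#' @return a [detection_matrix()].
#' @export
merge_markers <- function(detections, samples) {
  detections <- detections[detections$sample_id %in% samples$sample_id, ,
                           drop = FALSE]
  sample_ids <- samples$sample_id
  taxa_ids <- sort(unique(detections$taxon_id))
  inc <- matrix(0L, nrow = length(sample_ids), ncol = length(taxa_ids),
                dimnames = list(sample_ids, taxa_ids))
  if (nrow(detections) > 0L) {
    inc[cbind(match(detections$sample_id, sample_ids),
              match(detections$taxon_id, taxa_ids))] <- 1L
  }
  taxa <- detections[!duplicated(detections$taxon_id),
                     c("taxon_id", "rank", "order", "family", "genus",
                       "species"), drop = FALSE]
  taxa <- taxa[match(taxa_ids, taxa$taxon_id), , drop = FALSE]
  detection_matrix(inc, samples, taxa)
}

#' Restrict a detection matrix to an allow-list of taxa
#'
#' Keeps a taxon when its own name, or the name of any of its resolved
#' ancestors, appears on the allow-list (e.g. a regional species checklist
#' given at order level retains all species of that order). Dropped taxa
#' are reported in a message and in the `"dropped_taxa"` attribute.
#'
#' @param x a [detection_matrix()].
#' @param allowed non-empty character vector of taxon names (any rank).
#' @return the restricted [detection_matrix()].
#' @export
restrict_to_checklist <- function(x, allowed) {
  stopifnot(inherits(x, "detection_matrix"))
  if (length(allowed) == 0L) stop("allow-list must be non-empty", call. = FALSE)
  lineage_names <- cbind(x$taxa$order, x$taxa$family, x$taxa$genus,
                         x$taxa$species)
  keep <- apply(lineage_names, 1L, function(v) any(v %in% allowed))
  dropped <- x$taxa$taxon_id[!keep]
  if (length(dropped) > 0L) {
    message("checklist restriction dropped ", length(dropped), " taxon/taxa: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  }
  inc <- x$incidence[, keep, drop = FALSE]
  out <- detection_matrix(inc, x$samples, x$taxa[keep, , drop = FALSE])
  attr(out, "dropped_taxa") <- dropped
  out
}

#' Subset a detection matrix to one predator's samples
#'
#' Taxa never detected in the remaining samples are dropped.
#'
#' @param x a [detection_matrix()].
#' @param predator predator label as in `x$samples$predator`.
#' @return a [detection_matrix()] of that predator's samples.
#' @export
subset_predator <- function(x, predator) {
  stopifnot(inherits(x, "detection_matrix"))
  rows <- x$samples$predator == predator
  if (!any(rows)) stop("no samples for predator: ", predator, call. = FALSE)
  inc <- x$incidence[rows, , drop = FALSE]
  cols <- colSums(inc) > 0L
  detection_matrix(inc[, cols, drop = FALSE],
                   x$samples[rows, , drop = FALSE],
                   x$taxa[cols, , drop = FALSE])
}

#' Write a detection matrix to TSV files
#'
#' Writes the binary incidence matrix (`<stem>_incidence.tsv`, samples x
#' taxa with a leading `sample_id` column) and the taxon lineage sidecar
#' (`<stem>_taxa.tsv`).
#'
#' @param x a [detection_matrix()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem, default `"detection"`.
#' @return invisibly, the paths written.
#' @export
write_detection_matrix <- function(x, dir, stem = "detection") {
  stopifnot(inherits(x, "detection_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(stem, "_incidence.tsv"))
  p2 <- file.path(dir, paste0(stem, "_taxa.tsv"))
  inc <- data.frame(sample_id = rownames(x$incidence), x$incidence,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(inc, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$taxa, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
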