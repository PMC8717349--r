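#' Read a prey trait table
#'
#' Tab- or comma-separated table mapping prey taxa (family or finer) to
#' flight capability and diel activity: columns `taxon`, `rank`, `volant`
#' (`volant` / `non_volant`) and `diel` (`nocturnal` / `diurnal`, may be
#' empty for non-volant taxa).
#'
#' @param path path to the trait table.
#' @return a `data.frame` with one row per classified taxon.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tr <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  names(tr) <- tolower(names(tr))
  missing_cols <- setdiff(c("taxon", "volant"), names(tr))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(tr$diel)) tr$diel <- NA_character_
  tr$volant <- tolower(trimws(tr$volant))
  tr$diel <- tolower(blank_to_na(tr$diel))
  bad <- !tr$volant %in% c("volant", "non_volant")
  if (any(bad)) stop("volant status must be 'volant' or 'non_volant'",
                     call. = FALSE)
  tr
}

#' Classify prey taxa into likely capture modes
#'
#' A prey item that is volant and nocturnal has a high probability of
#' being caught on the wing (aerial hawking); non-volant items and volant
#' but diurnal (hence resting at night) items are more likely gleaned from
#' surfaces. Lookup proceeds from the taxon's own name up through its
#' resolved ancestors (species, genus, family, order) and uses the first
#' classified match. A volant taxon without diel information, or a taxon
#' absent from the trait table altogether, is `undecided`.
#'
#' @param taxa a [detection_matrix()], its `$taxa` lineage table, or a
#'   character vector of taxon names.
#' @param traits trait table from [read_trait_table()] (or an equivalent
#'   `data.frame`).
#' @return character vector in `c("hawking", "gleaning", "undecided")`,
#'   named by taxon id.
#' @export
classify_mode <- function(taxa, traits) {
  if (inherits(taxa, "detection_matrix")) taxa <- taxa$taxa
  if (is.character(taxa)) {
    taxa <- data.frame(taxon_id = taxa, order = NA_character_,
                       family = NA_character_, genus = NA_character_,
                       species = taxa, stringsAsFactors = FALSE)
  }
  lookup_names <- cbind(taxa$species, taxa$genus, taxa$family, taxa$order)
  n <- nrow(taxa)
  mode <- rep("undecided", n)
  unmatched <- 0L
  for (i in seq_len(n)) {
    hit <- NA_integer_
    for (nm in lookup_names[i, ]) {
      if (!is.na(nm)) {
        j <- match(nm, traits$taxon)
        if (!is.na(j)) { hit <- j; break }
      }
    }
    if (is.na(hit)) { unmatched <- unmatched + 1L; next }
    volant <- traits$volant[hit]
    diel <- traits$diel[hit]
    mode[i] <- if (volant == "non_volant") "gleaning"
      else if (is.na(diel)) "undecided"
      else if (diel == "nocturnal") "hawking"
      else "gleaning"
  }
  if (unmatched > 0L) {
    warning(unmatched, " taxon/taxa absent from the trait table; ",
            "classified as undecided")
  }
  stats::setNames(mode, taxa$taxon_id)
}

#' Tally likely capture modes per sample
#'
#' Classifies every detected taxon with [classify_mode()] and counts, per
#' sample, the prey items likely caught by gleaning, by aerial hawking, and
#' the undecided ones. Undecided items are tracked but excluded from the
#' capture-mode model; samples whose classified count is zero are kept in
#' the tally (flagged by `model_input = FALSE`) and samples without any
#' detection are dropped with a warning.
#'
#' @param x a [detection_matrix()].
#' @param traits trait table (see [read_trait_table()]).
#' @return a `data.frame` with columns `sample_id`, `predator`,
#'   `n_gleaning`, `n_hawking`, `n_undecided`, `model_input`.
#' @export
tally_modes <- function(x, traits) {
  stopifnot(inherits(x, "detection_matrix"))
  mode <- classify_mode(x, traits)
  inc <- x$incidence
  empty <- rowSums(inc) == 0L
  if (any(empty)) {
    warning(sum(empty), " sample(s) without detections dropped from the tally")
    inc <- inc[!empty, , drop = FALSE]
  }
  tally <- data.frame(
    sample_id = rownames(inc),
    predator = x$samples$predator[match(rownames(inc), x$samples$sample_id)],
    n_gleaning = as.integer(inc %*% (mode == "gleaning")),
    n_hawking = as.integer(inc %*% (mode == "hawking")),
    n_undecided = as.integer(inc %*% (mode == "undecided")),
    stringsAsFactors = FALSE
  )
  tally$model_input <- (tally$n_gleaning + tally$n_hawking) > 0L
  tally
}
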