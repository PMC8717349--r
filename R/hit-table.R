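#' Read a marker-level taxonomic hit table
#'
#' Reads a delimited text table (tab- or comma-separated, auto-detected from
#' the header line) of taxonomically assigned amplicon hits: one row per
#' sample x ZOTU x best hit, with read counts and assignment evidence
#' (percent identity, alignment length, E-value) plus rank-resolved taxonomy
#' (order / family / genus / species; finer ranks may be empty).
#'
#' Required columns: `sample_id`, `zotu_id`, `read_count`, `pct_identity`,
#' `align_length`, `e_value`, `order`, `family`, `genus`, `species`.
#' A `marker` column is optional; the `marker` argument overrides it.
#' A trailing `%` on `pct_identity` values is stripped. Rows whose numeric
#' fields cannot be parsed, or that lack a sample id, are dropped with a
#' warning naming the offending row indices (also attached as the
#' `"rejected_rows"` attribute of the result).
#'
#' @param path path to the delimited text file.
#' @param marker marker code, `"COI"` or `"S16"` (the 16S marker; the
#'   spelling `"16S"` is accepted and normalised).
#' @return a `data.frame` of assigned hits, one row per retained input row.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   paste("sample_id", "zotu_id", "read_count", "pct_identity",
#'     "align_length", "e_value", "order", "family", "genus", "species",
#'     sep = "\t"),
#'   paste("s1", "z1", "120", "99.1", "155", "1e-40", "Lepidoptera",
#'     "Geometridae", "Ectropis", "Ectropis obliqua", sep = "\t")
#' ), tf)
#' read_hit_table(tf, marker = "COI")
#' @export
read_hit_table <- function(path, marker) {
  if (!file.exists(path)) {
    stop("hit table not found: ", path, call. = FALSE)
  }
  marker <- normalize_marker(marker)
  required <- c("sample_id", "zotu_id", "read_count", "pct_identity",
                "align_length", "e_value", "order", "family", "genus",
                "species")

  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    warning("empty hit table: ", path)
    return(empty_hit_table(marker))
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = TRUE)
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("hit table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("hit table has a header but no rows: ", path)
    return(empty_hit_table(marker))
  }

  hits <- data.frame(
    sample_id = blank_to_na(raw$sample_id),
    marker = marker,
    zotu_id = blank_to_na(raw$zotu_id),
    read_count = suppressWarnings(as.numeric(raw$read_count)),
    pct_identity = suppressWarnings(as.numeric(sub("%$", "",
                                                   trimws(raw$pct_identity)))),
    align_length = suppressWarnings(as.numeric(raw$align_length)),
    e_value = suppressWarnings(as.numeric(raw$e_value)),
    order = blank_to_na(raw$order),
    family = blank_to_na(raw$family),
    genus = blank_to_na(raw$genus),
    species = blank_to_na(raw$species),
    stringsAsFactors = FALSE
  )

  bad_numeric <- is.na(hits$read_count) | is.na(hits$pct_identity) |
    is.na(hits$align_length) | is.na(hits$e_value)
  bad_id <- is.na(hits$sample_id)
  bad <- bad_numeric | bad_id
  if (any(bad)) {
    warning(sum(bad), " row(s) rejected while reading ", basename(path),
            " (unparseable numerics or missing sample_id): rows ",
            paste(which(bad), collapse = ", "))
  }
  out <- hits[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- which(bad)
  out
}

normalize_marker <- function(marker) {
  m <- toupper(trimws(marker))
  m[m %in% c("16S", "S16", "X16S")] <- "S16"
  if (!all(m %in% c("COI", "S16"))) {
    stop("unknown marker code: ", paste(unique(m), collapse = ", "),
         " (expected COI or S16/16S)", call. = FALSE)
  }
  m
}

empty_hit_table <- function(marker) {
  data.frame(sample_id = character(), marker = character(),
             zotu_id = character(), read_count = numeric(),
             pct_identity = numeric(), align_length = numeric(),
             e_value = numeric(), order = character(), family = character(),
             genus = character(), species = character(),
             stringsAsFactors = FALSE)
}

#' Read a sample metadata table
#'
#' Tab- or comma-separated table with one row per fecal sample:
#' `sample_id`, `predator`, `sex` (f/m/NA), `age` (ad/j/NA), `year`, `site`,
#' and per-marker sequencing depth columns `total_reads_coi` and
#' `total_reads_s16`.
#'
#' @param path path to the metadata file.
#' @return a `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "")
  names(meta) <- tolower(names(meta))
  required <- c("sample_id", "predator", "total_reads_coi", "total_reads_s16")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  if (any(is.na(meta$predator) | !nzchar(meta$predator))) {
    stop("every sample needs a non-empty predator label", call. = FALSE)
  }
  meta
}
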