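`%||%` <- function(a, b) if (is.null(a)) b else a

RANKS <- c("order", "family", "genus", "species")

# name of a taxon at `rank`, given its lineage row; NA when not resolved
name_at_rank <- function(lineage, rank) {
  stopifnot(rank %in% RANKS)
  v <- lineage[[rank]]
  ifelse(is.na(v) | !nzchar(v), NA_character_, v)
}

# finest populated rank of a lineage row (order/family/genus/species)
finest_rank <- function(order, family, genus, species) {
  out <- rep(NA_character_, length(order))
  has <- function(x) !is.na(x) & nzchar(x)
  out[has(order)] <- "order"
  out[has(family)] <- "family"
  out[has(genus)] <- "genus"
  out[has(species)] <- "species"
  out
}

blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | x %in% c("NA", "na", ".")] <- NA_character_
  x
}

taxon_label <- function(rank, name) paste(rank, name, sep = ":")
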