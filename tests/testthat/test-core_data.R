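test_that("hit tables are parsed with delimiter detection and normalisation", {
  rows <- rbind(hit_row(zotu_id = "z1"), hit_row(zotu_id = "z2"),
                hit_row(zotu_id = "z3"))
  path <- write_hit_tsv(rows)
  hits <- read_hit_table(path, "COI")
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$marker, rep("COI", 3))

  # comma-separated variant with a trailing % on the identity
  rows$pct_identity <- "97.2%"
  pcsv <- tempfile(fileext = ".csv")
  write.table(rows, pcsv, sep = ",", quote = FALSE, row.names = FALSE)
  hits2 <- read_hit_table(pcsv, "16S")
  expect_equal(hits2$pct_identity, rep(97.2, 3))
  expect_equal(hits2$marker, rep("S16", 3))

  # row-level rejection: missing sample_id and unparseable read count
  bad <- rbind(hit_row(zotu_id = "z1"),
               hit_row(sample_id = "", zotu_id = "z2"),
               hit_row(zotu_id = "z3", read_count = "ten"))
  pbad <- write_hit_tsv(bad)
  expect_warning(hits3 <- read_hit_table(pbad, "COI"), "rejected")
  expect_equal(nrow(hits3), 1L)
  expect_equal(attr(hits3, "rejected_rows"), c(2L, 3L))

  # structural errors
  nocol <- rows[, setdiff(names(rows), "e_value")]
  expect_error(read_hit_table(write_hit_tsv(nocol), "COI"), "e_value")
  empty <- write_hit_tsv(rows[0, ])
  expect_warning(h0 <- read_hit_table(empty, "COI"), "no rows")
  expect_equal(nrow(h0), 0L)
})

test_that("rank thresholds retain, demote and reject at the documented boundaries", {
  cfg <- filter_config()
  coi <- function(id) hit_row(pct_identity = id)
  cases <- rbind(coi(99.1), coi(98), coi(97.9), coi(97), coi(96),
                 coi(95.9), coi(90), coi(89.9))
  out <- apply_rank_thresholds(cases, cfg)
  expect_equal(out$rank,
               c("species", "species", "family", "family", "family",
                 "order", "order", NA))
  expect_equal(out$taxon[1], "Ectropis obliqua")
  expect_equal(out$taxon[3], "Geometridae")
  expect_equal(out$taxon[6], "Lepidoptera")
  expect_equal(out$reason[8], "below_identity")

  # 16S: all three evidence thresholds must pass jointly
  s16 <- function(id, al, ev) hit_row(marker = "S16", pct_identity = id,
                                      align_length = al, e_value = ev)
  s16cases <- rbind(s16(95, 80, 1e-30),    # alignment too short
                    s16(89.9, 150, 1e-30), # identity too low
                    s16(95, 99, 1e-30),    # alignment boundary fails at 99
                    s16(95, 100, 1e-7),    # E-value must be strictly below
                    s16(95, 100, 9.9e-8),  # passes all three
                    s16(90, 100, 1e-30))   # identity boundary inclusive
  out16 <- apply_rank_thresholds(s16cases, cfg)
  expect_equal(out16$retained, c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out16$rank[5], "species")

  # demotion to an unresolved rank is a rejection
  nofam <- hit_row(pct_identity = 97, family = NA, genus = NA, species = NA)
  outna <- apply_rank_thresholds(nofam, cfg)
  expect_false(outna$retained)
  expect_equal(outna$reason, "rank unavailable")
})

test_that("the read-count screen applies to reads summed over ZOTUs per final taxon", {
  cfg <- filter_config()
  expect_equal(nrow(filter_hits(hit_row(read_count = 9), cfg)), 0L)

  ok <- filter_hits(hit_row(read_count = 10, pct_identity = 98), cfg)
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$rank, "species")

  # two ZOTUs of 6 + 5 reads mapping to one species pass jointly
  two <- rbind(hit_row(zotu_id = "z1", read_count = 6),
               hit_row(zotu_id = "z2", read_count = 5))
  agg <- filter_hits(two, cfg)
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$reads, 11)

  # duplicate detections collapse to one row
  dup <- rbind(hit_row(zotu_id = "z1"), hit_row(zotu_id = "z2"))
  expect_equal(nrow(filter_hits(dup, cfg)), 1L)

  # a demoted hit carries no lineage finer than its retained rank
  dem <- filter_hits(hit_row(pct_identity = 96.5), cfg)
  expect_equal(dem$rank, "family")
  expect_true(is.na(dem$species) && is.na(dem$genus))
  expect_equal(dem$taxon_id, "family:Geometridae")
})

test_that("sample QC excludes shallow and preyless samples with full accounting", {
  meta <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    predator = "Murina ussuriensis",
    total_reads_coi = c(500, 3000, 2500, 600),
    total_reads_s16 = c(300, 2000, 2500, 500),
    stringsAsFactors = FALSE)
  det <- filter_hits(rbind(hit_row(sample_id = "s3"),
                           hit_row(sample_id = "s4")), filter_config())
  qc <- qc_samples(meta, det)
  expect_equal(sort(qc$samples$sample_id), c("s3", "s4"))
  expect_equal(qc$exclusions$reason[qc$exclusions$sample_id == "s1"],
               "low_reads")
  expect_equal(qc$exclusions$reason[qc$exclusions$sample_id == "s2"],
               "no_prey")
  # accounting: exclusions + retained = input
  expect_equal(nrow(qc$samples) + nrow(qc$exclusions), nrow(meta))

  # s4 passes pooled (1100 >= 1000) but fails per-marker
  qc2 <- qc_samples(meta, det, mode = "per_marker")
  expect_equal(qc2$samples$sample_id, "s3")

  orphan <- filter_hits(hit_row(sample_id = "ghost"), filter_config())
  expect_error(qc_samples(meta, orphan), "absent from metadata")
})

test_that("marker merging counts a doubly-detected prey item once", {
  det <- filter_hits(rbind(hit_row(marker = "COI"),
                           hit_row(marker = "S16", zotu_id = "z9"),
                           hit_row(marker = "COI", zotu_id = "z2",
                                   species = "Alcis angulifera",
                                   genus = "Alcis")),
                     filter_config())
  samples <- data.frame(sample_id = "s1", predator = "Murina ussuriensis",
                        stringsAsFactors = FALSE)
  mat <- merge_markers(det, samples)
  expect_equal(dim(mat$incidence), c(1L, 2L))
  expect_equal(as.integer(mat$incidence["s1", "species:Ectropis obliqua"]), 1L)
  expect_equal(as.integer(mat$incidence["s1", "species:Alcis angulifera"]), 1L)
  expect_true(all(mat$incidence %in% 0:1))
})

test_that("checklist restriction matches taxa at their own rank or any ancestor", {
  inc <- matrix(1L, 1, 3,
                dimnames = list("s1", c("species:A a", "species:B b",
                                        "family:FamX")))
  taxa <- toy_taxa(colnames(inc), c("species", "species", "family"),
                   order = c("Lepidoptera", "Diptera", "Diptera"),
                   family = c("Geometridae", "Tipulidae", "FamX"),
                   species = c("A a", "B b", NA))
  mat <- toy_matrix(inc, "Murina ussuriensis", taxa)

  all_names <- unlist(taxa[, c("order", "family", "species")])
  expect_equal(ncol(restrict_to_checklist(mat, all_names)$incidence), 3L)

  # an order-level allow-list retains everything beneath that order
  dip <- suppressMessages(restrict_to_checklist(mat, "Diptera"))
  expect_equal(colnames(dip$incidence), c("species:B b", "family:FamX"))

  # excluding a family removes the taxa under it
  nofam <- suppressMessages(
    restrict_to_checklist(mat, c("Geometridae", "FamX")))
  expect_false("species:B b" %in% colnames(nofam$incidence))
})

test_that("filtering is idempotent and retained detections satisfy their marker's thresholds", {
  cfg <- filter_config()
  set.seed(11)
  for (rep in 1:20) {
    n <- 40
    hits <- hit_row()[rep(1, n), ]
    hits$sample_id <- sample(sprintf("s%d", 1:6), n, replace = TRUE)
    hits$marker <- sample(c("COI", "S16"), n, replace = TRUE)
    hits$zotu_id <- sprintf("z%02d", seq_len(n))
    hits$read_count <- sample(c(1, 5, 9, 10, 11, 200), n, replace = TRUE)
    hits$pct_identity <- round(runif(n, 85, 100), 2)
    hits$align_length <- sample(c(60, 99, 100, 150), n, replace = TRUE)
    hits$e_value <- 10^runif(n, -30, -4)
    sp <- sprintf("Sp %d", sample(1:8, n, replace = TRUE))
    hits$species <- sp
    hits$genus <- paste0("G", sp)
    hits$family <- sample(c("FamA", "FamB"), n, replace = TRUE)

    det <- filter_hits(hits, cfg)
    if (nrow(det) > 0) {
      # detections re-expressed as hits survive a second pass unchanged
      back <- det
      back$read_count <- back$reads
      back$zotu_id <- paste0("r", seq_len(nrow(back)))
      back$pct_identity <- ifelse(back$marker == "S16", 95,
                                  c(order = 91, family = 97,
                                    species = 99)[back$rank])
      back$align_length <- 150
      back$e_value <- 1e-30
      det2 <- filter_hits(back[, names(hits)], cfg)
      expect_equal(det2[, c("sample_id", "marker", "taxon_id", "reads")],
                   det[, c("sample_id", "marker", "taxon_id", "reads")])

      # every retained detection passes its marker's predicates
      expect_true(all(det$reads >= cfg$min_reads))
      scored <- apply_rank_thresholds(hits, cfg)
      keyd <- paste(det$sample_id, det$marker, det$taxon_id)
      keys <- paste(scored$sample_id, scored$marker,
                    ifelse(scored$retained,
                           paste(scored$rank, scored$taxon, sep = ":"), NA))
      expect_true(all(keyd %in% keys[scored$retained]))
    }
    # merging never exceeds the union of the two markers' taxon sets
    samples <- data.frame(sample_id = unique(hits$sample_id),
                          predator = "P", stringsAsFactors = FALSE)
    mat <- merge_markers(det, samples)
    for (s in samples$sample_id) {
      per_marker <- split(det$taxon_id[det$sample_id == s],
                          det$marker[det$sample_id == s])
      expect_lte(sum(mat$incidence[s, ]),
                 length(unique(unlist(per_marker))))
    }
  }
})
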