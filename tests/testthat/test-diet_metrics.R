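make_two_predator_matrix <- function() {
  # predator P1: taxon A in s1,s2; taxon B in s1 -> POO A 2/3, B 1/3
  # predator P2: taxa B, C in s3
  inc <- matrix(0L, 3, 3,
                dimnames = list(c("s1", "s2", "s3"),
                                c("species:A a", "species:B b",
                                  "species:C c")))
  inc["s1", ] <- c(1L, 1L, 0L)
  inc["s2", ] <- c(1L, 0L, 0L)
  inc["s3", ] <- c(0L, 1L, 1L)
  taxa <- toy_taxa(colnames(inc), "species",
                   order = c("Lepidoptera", "Lepidoptera", "Diptera"),
                   family = c("Geometridae", "Noctuidae", "Tipulidae"),
                   genus = c("Ga", "Gb", "Gc"),
                   species = c("A a", "B b", "C c"))
  toy_matrix(inc, c("P1", "P1", "P2"), taxa)
}

test_that("POO profiles are occurrence shares that sum to one", {
  mat <- make_two_predator_matrix()
  pf <- poo(mat, "P1")
  expect_equal(sum(pf$p), 1)
  expect_equal(as.numeric(pf$p["species:A a"]), 2 / 3)
  expect_equal(as.numeric(pf$p["species:B b"]), 1 / 3)
  expect_equal(pf$total_occurrences, 3)

  single <- toy_matrix(matrix(1L, 1, 1, dimnames = list("s1", "species:X x")),
                       "P", toy_taxa("species:X x", "species", "O",
                                     species = "X x"))
  expect_equal(as.numeric(poo(single, "P")$p), 1)
  expect_error(poo(mat, "nobody"), "no samples")
})

test_that("Hill numbers, Shannon, Simpson and Levins match hand-evaluated values", {
  p <- c(0.6, 0.3, 0.1)
  expect_equal(hill_number(p, 0), 3)
  expect_equal(hill_number(p, 1), 2.4545556, tolerance = 1e-6)
  expect_equal(hill_number(p, 2), 2.173913, tolerance = 1e-6)
  expect_equal(shannon_index(p), 0.8979457, tolerance = 1e-6)
  expect_equal(simpson_index(p), 0.54)
  lv <- levins_breadth(p, 3)
  expect_equal(lv$B, 2.173913, tolerance = 1e-6)
  expect_equal(lv$B_normalized, 0.5869565, tolerance = 1e-6)

  # degenerate and uniform cases
  expect_equal(shannon_index(1), 0)
  expect_equal(simpson_index(1), 0)
  expect_equal(hill_number(c(0.5, 0.5), 2), 2)
  expect_equal(hill_number(rep(1 / 7, 7), 1), 7)
  lv2 <- levins_breadth(c(0.5, 0.5), 2)
  expect_equal(lv2$B, 2)
  expect_equal(lv2$B_normalized, 1)
  expect_message(lv1 <- levins_breadth(1), "single resource")
  expect_equal(lv1$B, 1)
  expect_equal(lv1$B_normalized, 0)

  # independent oracle: vegan computes the same classical indices
  set.seed(3)
  q <- runif(9); q <- q / sum(q)
  expect_equal(shannon_index(q), unname(vegan::diversity(q, "shannon")))
  expect_equal(simpson_index(q), unname(vegan::diversity(q, "simpson")))
  expect_equal(levins_breadth(q)$B, unname(vegan::diversity(q, "invsimpson")))
})

test_that("diversity identities hold across random profiles and qD is monotone", {
  set.seed(101)
  qgrid <- seq(0, 5, by = 0.5)
  for (i in 1:200) {
    S <- sample(2:40, 1)
    p <- rgamma(S, shape = runif(1, 0.2, 2))
    p <- p / sum(p)
    expect_equal(hill_number(p, 1), exp(shannon_index(p)), tolerance = 1e-9)
    expect_equal(hill_number(p, 2), 1 / (1 - simpson_index(p)),
                 tolerance = 1e-9)
    expect_equal(hill_number(p, 2), levins_breadth(p)$B, tolerance = 1e-9)
    qD <- vapply(qgrid, function(qq) hill_number(p, qq), numeric(1))
    expect_true(all(diff(qD) <= 1e-9))
    expect_equal(qD[1], S)
  }
})

test_that("Pianka overlap is symmetric, bounded and matches hand-evaluated cases", {
  pj <- c(a = 0.5, b = 0.5, c = 0)
  pk <- c(a = 0, b = 0.5, c = 0.5)
  expect_equal(pianka_overlap(pj, pk)$O_jk, 0.5)
  expect_equal(pianka_overlap(pj, pj)$O_jk, 1)
  expect_equal(pianka_overlap(c(a = 1), c(b = 1))$O_jk, 0)
  expect_equal(pianka_overlap(pj, pk)$O_jk, pianka_overlap(pk, pj)$O_jk)
  # invariant to relabeling and to proportional rescaling
  set.seed(5)
  for (i in 1:20) {
    u <- setNames(rgamma(6, 1), letters[1:6])
    v <- setNames(rgamma(6, 1), letters[1:6])
    o1 <- pianka_overlap(u / sum(u), v / sum(v))$O_jk
    perm <- sample(letters[1:6])
    o2 <- pianka_overlap(setNames(u, perm)[letters[1:6]] / sum(u),
                         setNames(v, perm)[letters[1:6]] / sum(v))$O_jk
    expect_equal(o1, o2)
    expect_gte(o1, 0); expect_lte(o1, 1 + 1e-12)
  }
  expect_error(pianka_overlap(numeric(0), pj), "invalid proportion")
})

test_that("rank-aggregated overlap pools POO within higher taxa", {
  mat <- make_two_predator_matrix()
  p1 <- poo(mat, "P1"); p2 <- poo(mat, "P2")
  asis <- pianka_overlap(p1, p2)$O_jk
  # order level: P1 = (Lep 1), P2 = (Lep .5, Dip .5)
  o_order <- pianka_overlap(p1, p2, rank = "order")$O_jk
  expect_equal(o_order, 0.5 / sqrt(1 * 0.5), tolerance = 1e-12)
  expect_gt(o_order, asis)
})

test_that("core diet keeps taxa consumed at least min_occurrence times", {
  mat <- make_two_predator_matrix()
  core <- core_diet(mat, "P1", min_occurrence = 2)
  expect_equal(colnames(core$incidence), "species:A a")   # B seen once
  ident <- core_diet(mat, "P1", min_occurrence = 1)
  expect_equal(sort(colnames(ident$incidence)),
               c("species:A a", "species:B b"))
  expect_error(core_diet(mat, "P2", min_occurrence = 3), "no core taxa")
})

test_that("per-rank overlap counts roll items up without inventing fine-rank names", {
  # 3 species in 2 families vs 2 species in the same 2 families
  tj <- toy_taxa(paste0("species:j", 1:3), "species", "O1",
                 family = c("Fam1", "Fam1", "Fam2"),
                 genus = c("g1", "g2", "g3"),
                 species = paste0("j", 1:3))
  tk <- toy_taxa(paste0("species:k", 1:2), "species", "O1",
                 family = c("Fam1", "Fam2"), genus = c("g4", "g5"),
                 species = paste0("k", 1:2))
  mj <- toy_matrix(matrix(1L, 1, 3, dimnames = list("a", tj$taxon_id)),
                   "P1", tj)
  mk <- toy_matrix(matrix(1L, 1, 2, dimnames = list("b", tk$taxon_id)),
                   "P2", tk)
  ov <- overlap_sets(mj, mk)
  expect_equal(ov$shared[ov$rank == "family"], 2L)
  expect_equal(ov$only_j[ov$rank == "species"], 3L)
  expect_equal(ov$shared[ov$rank == "species"], 0L)
  expect_equal(ov$shared[ov$rank == "order"], 1L)

  # identical sets overlap completely
  ov2 <- overlap_sets(mj, mj)
  expect_equal(ov2$shared, c(3L, 3L, 2L, 1L))
  expect_equal(ov2$only_j, rep(0L, 4))

  # a family-level item counts at family and order, never at genus/species
  tmix <- toy_taxa(c("species:x1", "family:FamZ"), c("species", "family"),
                   "O2", family = c("FamY", "FamZ"),
                   genus = c("gx", NA), species = c("x1", NA))
  mmix <- toy_matrix(matrix(1L, 1, 2, dimnames = list("c", tmix$taxon_id)),
                     "P3", tmix)
  ovm <- overlap_sets(mmix, mj)
  expect_equal(ovm$only_j[ovm$rank == "species"], 1L)  # x1 only
  expect_equal(ovm$only_j[ovm$rank == "family"], 2L)   # FamY and FamZ
})

test_that("the partition table re-includes once-consumed prey shared with the other predator", {
  inc <- matrix(0L, 5, 3,
                dimnames = list(paste0("s", 1:5),
                                c("species:A a", "species:B b",
                                  "species:C c")))
  # A: once by P1 (s1), three times by P2 (s3,s4,s5) -> kept, counts (1, 3)
  # B: once by each -> dropped
  # C: twice by P1 only -> kept, counts (2, 0)
  inc["s1", "species:A a"] <- 1L
  inc["s3", "species:A a"] <- 1L; inc["s4", "species:A a"] <- 1L
  inc["s5", "species:A a"] <- 1L
  inc["s1", "species:B b"] <- 1L; inc["s3", "species:B b"] <- 1L
  inc["s1", "species:C c"] <- 1L; inc["s2", "species:C c"] <- 1L
  taxa <- toy_taxa(colnames(inc), "species", "O",
                   family = c("FamA", "FamB", "FamC"),
                   species = c("A a", "B b", "C c"))
  mat <- toy_matrix(inc, c("P1", "P1", "P2", "P2", "P2"), taxa)
  pt <- partition_table(mat, "P1", "P2")
  expect_equal(pt$family, c("FamA", "FamC"))
  expect_equal(pt$count_j, c(1, 2))
  expect_equal(pt$count_k, c(3, 0))
})

test_that("the rank-sum test matches brute-force enumeration and is symmetric", {
  out <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$W, 0)
  expect_equal(out$p, 0.1)
  expect_equal(out$mode, "exact")

  # oracle equivalence of the exact mode over random tie-free data
  set.seed(8)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(100, n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    ours <- rank_sum_test(x, y, mode = "exact")
    oracle <- brute_wilcox(x, y)
    expect_equal(ours$W, oracle$W)
    expect_equal(ours$p, oracle$p, tolerance = 1e-12)
    # swapping the groups flips W to n1*n2 - W at the same p
    swapped <- rank_sum_test(y, x, mode = "exact")
    expect_equal(swapped$W, n1 * n2 - ours$W)
    expect_equal(swapped$p, ours$p)
  }

  expect_warning(deg <- rank_sum_test(rep(2, 3), rep(2, 4)), "identical")
  expect_equal(deg$p, 1)
  expect_warning(tied <- rank_sum_test(c(1, 2, 2), c(2, 3, 4),
                                       mode = "exact"),
                 "ties")
  expect_equal(tied$mode, "normal")
})
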