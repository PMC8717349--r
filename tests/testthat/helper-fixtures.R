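# in-code fixtures shared across test files

hit_row <- function(sample_id = "s1", marker = "COI", zotu_id = "z1",
                    read_count = 50, pct_identity = 99, align_length = 150,
                    e_value = 1e-30, order = "Lepidoptera",
                    family = "Geometridae", genus = "Ectropis",
                    species = "Ectropis obliqua") {
  data.frame(sample_id = sample_id, marker = marker, zotu_id = zotu_id,
             read_count = read_count, pct_identity = pct_identity,
             align_length = align_length, e_value = e_value, order = order,
             family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

write_hit_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a detection matrix built directly from a samples x taxa 0/1 matrix plus
# a lineage table keyed by taxon_id
toy_matrix <- function(inc, predator, taxa) {
  samples <- data.frame(sample_id = rownames(inc), predator = predator,
                        stringsAsFactors = FALSE)
  detection_matrix(inc, samples, taxa)
}

toy_taxa <- function(taxon_id, rank, order, family = NA, genus = NA,
                     species = NA) {
  data.frame(taxon_id = taxon_id, rank = rank, order = order,
             family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

# brute-force enumeration oracle for the two-sided rank-sum test: all
# C(n1+n2, n1) group assignments of the pooled tie-free values
brute_wilcox <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  U_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  U_obs <- U_of(seq_len(n1))
  all_idx <- utils::combn(length(pooled), n1)
  U_all <- apply(all_idx, 2, U_of)
  p_low <- mean(U_all <= U_obs)
  p_high <- mean(U_all >= U_obs)
  list(W = U_obs, p = min(1, 2 * min(p_low, p_high)))
}

# simulate capture-mode counts from the model's own data-generating process
simulate_mode_counts <- function(n_per_group = 25, mean_prey = 8,
                                 beta0 = qlogis(0.25), beta1 = 0,
                                 sigma_u = 0.8) {
  n <- 2 * n_per_group
  pred <- rep(c("Myotis ikonnikovi", "Murina ussuriensis"),
              each = n_per_group)
  m <- stats::rpois(n, mean_prey) + 1L
  eta <- beta0 + beta1 * (pred == "Murina ussuriensis") +
    stats::rnorm(n, 0, sigma_u)
  y <- stats::rbinom(n, m, stats::plogis(eta))
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), predator = pred,
             n_gleaning = y, n_hawking = m - y, stringsAsFactors = FALSE)
}
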