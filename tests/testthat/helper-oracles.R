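# Fixture builders and independent oracles. Oracles deliberately use naive
# loop/enumeration code paths, never the package's vectorized routines.

random_count_table <- function(n_otus, n_samples, max_count = 50) {
  m <- matrix(sample(0:max_count, n_otus * n_samples, replace = TRUE),
              n_otus, n_samples)
  count_table(m,
              otu_ids = sprintf("OTU%02d", seq_len(n_otus)),
              sample_ids = sprintf("S%02d", seq_len(n_samples)))
}

random_binary_matrix <- function(n_rows, n_cols, p = 0.5) {
  matrix(rbinom(n_rows * n_cols, 1, p), n_rows, n_cols)
}

# staircase: column k present exactly in rows 1..(n_rows + 1 - k)
staircase_matrix <- function(n) {
  m <- matrix(0, n, n)
  for (k in seq_len(n)) m[seq_len(n + 1 - k), k] <- 1
  m
}

# brute-force NODF: literal pair enumeration with explicit row scans
nodf_oracle <- function(m) {
  pair_sum <- function(mat) {
    nc <- ncol(mat)
    total <- 0
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        if (i < j) {
          fi <- sum(mat[, i]); fj <- sum(mat[, j])
          hi <- max(fi, fj); lo <- min(fi, fj)
          if (hi > lo && lo > 0) {
            poorer <- if (fi < fj) i else j
            richer <- if (fi < fj) j else i
            shared <- 0
            for (r in seq_len(nrow(mat))) {
              if (mat[r, poorer] == 1 && mat[r, richer] == 1) {
                shared <- shared + 1
              }
            }
            total <- total + 100 * shared / lo
          }
        }
      }
    }
    total
  }
  cs <- pair_sum(m)
  rs <- pair_sum(t(m))
  list(nodf_columns = cs / choose(ncol(m), 2),
       nodf_rows = rs / choose(nrow(m), 2),
       nodf_total = (cs + rs) / (choose(ncol(m), 2) + choose(nrow(m), 2)))
}

# exhaustive permutations of 1..n (recursive, independent of the package)
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1)
  out <- NULL
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      row <- append(sub[i, ], n, after = pos - 1)
      out <- rbind(out, row)
    }
  }
  unname(out)
}

# exact Mantel p over the full permutation group (proportion of r >= r_obs)
mantel_exact_oracle <- function(a, b) {
  n <- nrow(a)
  ut <- upper.tri(a)
  r_obs <- cor(a[ut], b[ut])
  perms <- perms_oracle(n)
  r_all <- apply(perms, 1, function(idx) {
    bp <- b[idx, idx]
    cor(a[ut], bp[ut])
  })
  mean(r_all >= r_obs - 1e-12)
}

# classical one-way ANOVA F by the textbook sums-of-squares formulas
anova_f_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  a <- length(unique(groups))
  n <- length(values)
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# metadata fixture: n_pairs plants, two habitats, optional year split
toy_metadata <- function(n_pairs = 4, habitats = NULL, elevations = NULL) {
  plant <- sprintf("P%02d", seq_len(n_pairs))
  if (is.null(habitats)) {
    habitats <- rep(c("grassland", "slope"), length.out = n_pairs)
  }
  if (is.null(elevations)) elevations <- 630 + 10 * seq_len(n_pairs)
  sample_metadata(data.frame(
    sample_id = as.vector(rbind(paste0(plant, "_I"), paste0(plant, "_D"))),
    plant_id = rep(plant, each = 2),
    treatment = rep(c("intact", "disturbed"), n_pairs),
    habitat = rep(habitats, each = 2),
    elevation = rep(elevations, each = 2),
    collection_year = rep(rep(c(2015L, 2016L), length.out = n_pairs),
                          each = 2),
    stringsAsFactors = FALSE))
}
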