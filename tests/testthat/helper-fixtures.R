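# Shared fixtures and independent oracles. Oracles are deliberately written
# from first principles (enumeration, brute force, closed forms) and never
# call the package functions they check.

toy_counts <- function(pool = "DNA") {
  m <- matrix(c(5, 2, 0, 0, 7, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("a1", "a2")))
  asv_table(m, pool)
}

# paired survey over 2 stations x 3 depths used by the categorisation tests:
# depth indices 1, 3, 7 (station B misses the intermediate depth on purpose)
toy_meta <- function() {
  data.frame(
    sample_id = c("A1", "A3", "A7", "B1", "B3", "B7"),
    station = rep(c("A", "B"), each = 3),
    depth_m = rep(c(3, 430, 4000), 2),
    depth_index = rep(c(1L, 3L, 7L), 2),
    layer = rep(c("Surface", "Upper mesopelagic", "Bathypelagic"), 2),
    stringsAsFactors = FALSE)
}

toy_paired <- function() {
  asvs <- c("v1", "v2", "v3", "v4", "v5")
  samples <- toy_meta()$sample_id
  dna <- matrix(0, 6, 5, dimnames = list(samples, asvs))
  rna <- matrix(0, 6, 5, dimnames = list(samples, asvs))
  # v1: surface taxon surviving everywhere, active at depth at station A only
  dna[, "v1"] <- c(40, 10, 10, 40, 10, 10)
  rna[, "v1"] <- c(20, 5, 8, 20, 5, 0)
  # v2: first detected at depth 3 in DNA
  dna[c("A3", "A7", "B3", "B7"), "v2"] <- 5
  rna[c("A3", "B3"), "v2"] <- 2
  # v3: phantom at station A (RNA only); ordinary d1 taxon at station B
  rna[c("A1", "A7"), "v3"] <- 3
  dna[c("B1", "B3"), "v3"] <- 6
  rna["B1", "v3"] <- 1
  # v4: surface taxon lost below the surface
  dna[c("A1", "B1"), "v4"] <- 12
  rna[c("A1", "B1"), "v4"] <- 6
  # v5: bathypelagic-only taxon
  dna[c("A7", "B7"), "v5"] <- 30
  rna[c("A7", "B7"), "v5"] <- 15
  pair_tables(asv_table(dna, "DNA"), asv_table(rna, "RNA"))
}

# reference scenario scaled down to 4 stations for faster end-to-end tests;
# the ASV pool keeps its full size so the read-scale calibration of the
# planted structure (shifter threshold, rarity cutoffs) is preserved
small_cfg <- function(seed = 42) {
  scenario_config(seed = seed, n_stations = 4, n_stations_intermediate = 2,
                  n_stations_local = 1,
                  library_size_range = c(10000, 11000))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); k <- length(x)
  idx <- utils::combn(n, k)
  u_of <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - k * (k + 1) / 2
  }
  u_all <- apply(idx, 2, function(cols) {
    r <- rank(pooled)
    sum(r[cols]) - k * (k + 1) / 2
  })
  u_obs <- u_of(seq_len(k))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# brute-force rooted Faith PD: union of the edges on every root-to-tip path
pd_oracle <- function(tree, tips) {
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  for (tp in tips) {
    node <- which(tree$tip.label == tp)
    path <- ape::nodepath(tree, from = root, to = node)
    for (i in seq_len(length(path) - 1)) {
      e <- which(tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1])
      edges <- union(edges, e)
    }
  }
  sum(tree$edge.length[edges])
}

# PERMANOVA F and R2 from the squared-distance partition, by hand
permanova_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  ss_total <- sum(d[lower.tri(d)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(groups))
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# Jensen-Shannon divergence between two discrete distributions (nats)
jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  kl(p, m) / 2 + kl(q, m) / 2
}

write_tsv_tmp <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
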