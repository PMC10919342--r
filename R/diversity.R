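#' Per-sample alpha diversity
#'
#' Richness (number of detected ASVs), Shannon H in nats (via
#' [vegan::diversity()]) and Pielou's evenness `J = H / ln(richness)` from a
#' rarefied mean table. Detection is mean rarefied abundance > 0. `J` is
#' undefined (NA) for single-ASV samples.
#'
#' @param rarefied Rarefied mean count matrix (samples x ASVs); any
#'   equal-total abundance matrix works.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`.
#' @export
alpha_diversity <- function(rarefied) {
  m <- unclass(as.matrix(rarefied))
  if (any(rowSums(m) == 0)) stop("empty sample(s): ",
      paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  rich <- rowSums(is_detected(m))
  h <- vegan::diversity(m, index = "shannon")
  j <- ifelse(rich > 1, h / log(rich), NA_real_)
  data.frame(sample_id = rownames(m), richness = unname(rich),
             shannon = unname(h), pielou = unname(j),
             stringsAsFactors = FALSE)
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal rooted subtree connecting a
#' sample's detected ASVs to the root (rooted convention; set
#' `include_root = FALSE` for the unrooted variant). Computed with
#' [picante::pd()].
#'
#' @param rarefied Abundance matrix (samples x ASVs); detection is
#'   abundance > 0.
#' @param tree Rooted [ape::phylo] whose tips cover every detected ASV.
#' @param include_root Include the path to the root (default TRUE).
#' @return data.frame with columns `sample_id`, `faith_pd`, `richness`,
#'   `pd_over_richness`.
#' @export
faith_pd <- function(rarefied, tree, include_root = TRUE) {
  m <- unclass(as.matrix(rarefied))
  detected <- colnames(m)[colSums(is_detected(m)) > 0]
  miss <- setdiff(detected, tree$tip.label)
  if (length(miss))
    stop("detected ASVs absent from tree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pdres <- picante::pd(m[, intersect(colnames(m), tree$tip.label),
                         drop = FALSE],
                       tree, include.root = include_root)
  data.frame(sample_id = rownames(m), faith_pd = pdres$PD,
             richness = pdres$SR,
             pd_over_richness = ifelse(pdres$SR > 0, pdres$PD / pdres$SR,
                                       NA_real_),
             stringsAsFactors = FALSE)
}

#' Proportion of active taxa per sample
#'
#' For each sample, the number of ASVs detected in both the DNA and RNA pools
#' divided by the number detected in the DNA pool. RNA-only (phantom) taxa do
#' not enter the numerator or denominator.
#'
#' @param paired A [pair_tables()] object (typically of rarefied mean
#'   tables).
#' @return data.frame with columns `sample_id`, `n_dna`, `n_active`,
#'   `prop_active` (NA with a warning where no DNA detections exist).
#' @export
proportion_active <- function(paired) {
  dna <- is_detected(paired$dna)
  rna <- is_detected(paired$rna)
  n_dna <- rowSums(dna)
  n_act <- rowSums(dna & rna)
  if (any(n_dna == 0))
    warning("sample(s) with zero DNA detections: ",
            paste(rownames(paired$dna)[n_dna == 0], collapse = ", "))
  data.frame(sample_id = rownames(paired$dna), n_dna = unname(n_dna),
             n_active = unname(n_act),
             prop_active = unname(ifelse(n_dna > 0, n_act / n_dna, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Two-sample Mann-Whitney test
#'
#' Two-sided Wilcoxon rank-sum test via [stats::wilcox.test()]: exact by
#' enumeration when both groups have at most 8 values and there are no ties,
#' otherwise the normal approximation with tie correction.
#'
#' @param x,y Numeric vectors (each of length >= 1).
#' @return A list of class `"group_test"` with `statistic` (U for the first
#'   group), `p_value`, `method`, `groups`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups need at least one value")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("all values identical; p = 1")
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          method = "degenerate", groups = c("x", "y")),
                     class = "group_test"))
  }
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(pooled)
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 groups = c("x", "y")),
            class = "group_test")
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Kruskal-Wallis rank-sum test (tie-corrected H, chi-square p) via
#' [stats::kruskal.test()], followed by Dunn's pairwise z comparisons on the
#' joint ranks with tie correction. Dunn p values are unadjusted by default
#' (`p_adjust` accepts any [stats::p.adjust()] method).
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation; at least 3 groups, each of
#'   size >= 2.
#' @param p_adjust Multiplicity adjustment for the pairwise p values
#'   (default `"none"`).
#' @return A list of class `"group_test"` with `statistic` (H), `df`,
#'   `p_value`, `groups` and `posthoc` (data.frame: `group1`, `group2`, `z`,
#'   `p`, `p_adj`).
#' @export
kruskal_dunn <- function(values, groups, p_adjust = "none") {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 3) stop("need at least 3 groups")
  if (any(sizes < 2))
    stop("group(s) of size < 2: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  kw <- stats::kruskal.test(values, factor(groups))
  posthoc <- dunn_pairwise(values, groups, p_adjust)
  structure(list(statistic = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value,
                 groups = names(sizes), posthoc = posthoc),
            class = "group_test")
}

# Dunn's z on joint ranks: z_ij = (Rbar_i - Rbar_j) /
#   sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))
dunn_pairwise <- function(values, groups, p_adjust = "none") {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tiecor
  gl <- sort(unique(groups))
  rbar <- tapply(r, groups, mean)[gl]
  n <- tapply(r, groups, length)[gl]
  pairs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z[k] <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' @export
print.group_test <- function(x, ...) {
  cat("statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$posthoc)) {
    cat("post hoc (Dunn):\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

#' Joint diversity profile of a paired survey
#'
#' Convenience wrapper computing, per sample and pool, richness, Shannon,
#' Pielou, Faith's PD (when a tree is given), PD/richness, and the proportion
#' of active taxa.
#'
#' @param paired A [pair_tables()] object of rarefied mean tables.
#' @param tree Optional rooted phylogeny covering the detected ASVs.
#' @return Long data.frame, one row per (sample, pool).
#' @export
diversity_profile <- function(paired, tree = NULL) {
  per_pool <- function(m, pool) {
    a <- alpha_diversity(m)
    a$pool <- pool
    if (!is.null(tree)) {
      p <- faith_pd(m, tree)
      a$faith_pd <- p$faith_pd
      a$pd_over_richness <- p$pd_over_richness
    }
    a
  }
  out <- rbind(per_pool(paired$dna, "DNA"), per_pool(paired$rna, "RNA"))
  act <- proportion_active(paired)
  out$prop_active <- ifelse(out$pool == "DNA",
                            act$prop_active[match(out$sample_id,
                                                  act$sample_id)], NA)
  out
}
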