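#' Aitchison (CLR-Euclidean) distance matrix
#'
#' Pairwise Euclidean distances between the rows of a CLR-transformed table,
#' i.e. Aitchison distances between the underlying compositions.
#'
#' @param clr A [clr_transform()] matrix (or any numeric matrix of sample
#'   rows).
#' @return A symmetric `dist`-backed matrix with zero diagonal and sample
#'   labels.
#' @export
aitchison_distance <- function(clr) {
  m <- unclass(as.matrix(clr))
  if (anyNA(m) || any(!is.finite(m))) stop("CLR table contains missing values")
  if (nrow(m) < 2) stop("need at least 2 samples")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Within-group pairwise distances and grand mean
#'
#' For each group, the multiset of pairwise distances among its members (the
#' dispersion shown in within-layer box plots), together with the overall
#' mean pairwise distance across all samples.
#'
#' @param d Symmetric distance matrix with sample labels.
#' @param groups Group label per sample (in `rownames(d)` order).
#' @return A list with `groups` (named list of numeric distance vectors;
#'   singleton groups give empty vectors with a warning) and `grand_mean`.
#' @export
within_group_distances <- function(d, groups) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == length(groups))
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning("singleton group '", g, "': no within-group distances")
      out[[g]] <- numeric(0)
    } else {
      sub <- d[idx, idx]
      out[[g]] <- sub[lower.tri(sub)]
    }
  }
  list(groups = out, grand_mean = mean(d[lower.tri(d)]))
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix with
#' a single grouping factor and free permutation of sample labels, via
#' [vegan::adonis2()]. The pseudo-F comes from the partition of squared
#' distances (SS_total = sum d^2 / n; within-group SS from within-group
#' squared distances divided by group sizes); the p value is
#' `(number of permuted F >= observed F + 1) / (n_perm + 1)`.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param groups Group label per sample; at least 2 groups, none spanning the
#'   whole data set.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `"permanova_result"` with `df`, `F`, `R2`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 1000, seed = 1) {
  d <- stats::as.dist(d)
  groups <- as.character(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups must match the distance matrix")
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (max(table(groups)) == n) stop("a single group spans the whole data set")
  if (n < 4) stop("need at least 4 samples")
  g <- factor(groups)
  set.seed(as.integer(seed))
  fit <- vegan::adonis2(d ~ g, permutations = n_perm)
  structure(list(df = fit$Df[1], F = fit$F[1], R2 = fit$R2[1],
                 p = fit$`Pr(>F)`[1], n_permutations = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: df = %d, F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$df, x$F, x$R2, x$p, x$n_permutations))
  invisible(x)
}

#' Table-style PERMANOVA summary for a paired survey
#'
#' Depth layer tested separately within the DNA and the RNA distance
#' matrices (one row each). Combine with [permanova_pooled()] for the
#' two additional rows of the combined DNA + RNA design.
#'
#' @param d_dna,d_rna Distance matrices over the same samples.
#' @param layers Layer label per sample (in matrix order).
#' @param n_perm,seed As in [permanova()].
#' @return data.frame with columns `molecule`, `group`, `df`, `F`, `R2`, `p`.
#' @export
permanova_table <- function(d_dna, d_rna, layers, n_perm = 1000, seed = 1) {
  row_tests <- list(
    list(molecule = "DNA", group = "Depth layer",
         fit = permanova(d_dna, layers, n_perm, seed)),
    list(molecule = "RNA", group = "Depth layer",
         fit = permanova(d_rna, layers, n_perm, seed + 1L)))
  do.call(rbind, lapply(row_tests, function(r)
    data.frame(molecule = r$molecule, group = r$group, df = r$fit$df,
               F = r$fit$F, R2 = r$fit$R2, p = r$fit$p,
               stringsAsFactors = FALSE)))
}

#' PERMANOVA on a pooled DNA + RNA CLR table
#'
#' Stacks the DNA and RNA CLR tables (samples duplicated, one row per
#' molecule), computes the pooled Aitchison distance matrix and runs the two
#' one-factor tests of the combined design: depth layer, and molecule.
#'
#' @param clr_dna,clr_rna CLR matrices over identical samples and ASVs.
#' @param layers Layer label per sample.
#' @param n_perm,seed As in [permanova()].
#' @return data.frame with one row per factor (`group` is "Depth layer" or
#'   "molecule").
#' @export
permanova_pooled <- function(clr_dna, clr_rna, layers, n_perm = 1000,
                             seed = 1) {
  stopifnot(identical(dim(clr_dna), dim(clr_rna)))
  stacked <- rbind(unclass(clr_dna), unclass(clr_rna))
  rownames(stacked) <- c(paste0(rownames(clr_dna), "_DNA"),
                         paste0(rownames(clr_rna), "_RNA"))
  d <- aitchison_distance(stacked)
  lay2 <- c(layers, layers)
  mol <- rep(c("DNA", "RNA"), each = nrow(clr_dna))
  f1 <- permanova(d, lay2, n_perm, seed)
  f2 <- permanova(d, mol, n_perm, seed + 1L)
  data.frame(molecule = "DNA and RNA", group = c("Depth layer", "molecule"),
             df = c(f1$df, f2$df), F = c(f1$F, f2$F), R2 = c(f1$R2, f2$R2),
             p = c(f1$p, f2$p), stringsAsFactors = FALSE)
}

#' Nonmetric multidimensional scaling
#'
#' NMDS embedding of a distance matrix minimising Kruskal stress-1 by
#' iterative monotone regression from multiple random starts
#' ([vegan::metaMDS()] with `monoMDS` engine; no autotransform since the
#' input is already a distance matrix).
#'
#' @param d Symmetric distance matrix (or `dist`), finite entries.
#' @param k Embedding dimension (default 2), `1 <= k < n - 1`.
#' @param seed Integer seed for the random starts.
#' @param trymax Number of random starts (default 20).
#' @param maxit Maximum iterations per start (default 300).
#' @param tol Stress convergence tolerance (default 1e-7).
#' @return A list with `points` (n x k coordinates) and `stress`
#'   (Kruskal stress-1, fraction in [0, 1]).
#' @export
nmds <- function(d, k = 2, seed = 1, trymax = 20, maxit = 300, tol = 1e-7) {
  d <- stats::as.dist(d)
  if (any(!is.finite(d))) stop("distances must be finite")
  n <- attr(d, "Size")
  if (k < 1 || k >= n - 1) stop("k must satisfy 1 <= k < n - 1")
  set.seed(as.integer(seed))
  fit <- vegan::metaMDS(d, k = k, trymax = trymax, maxit = maxit,
                        sfgrmin = tol, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  list(points = fit$points, stress = fit$stress)
}
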