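#' 16S copy-number correction
#'
#' Divides each ASV's counts by the mean 16S rRNA gene copy number of its
#' lowest assigned taxonomic rank among order, family and genus (the deepest
#' available wins). ASVs whose lowest assigned rank is class or shallower are
#' left unchanged, because copy-number prediction at that resolution is too
#' inaccurate to help. Per-sample totals are then rescaled back to the
#' original totals so the correction redistributes reads rather than
#' shrinking libraries.
#'
#' @param table Count matrix (samples x ASVs); real-valued tables (e.g.
#'   rarefied means) are accepted.
#' @param tax Taxonomy data.frame (see [read_taxonomy()]) covering every ASV
#'   in `table`.
#' @param cn Copy-number lookup data.frame (see [read_copy_numbers()]).
#' @param rescale Rescale per-sample totals to the originals (default TRUE).
#' @return A matrix of the same shape; the `pool` attribute is preserved.
#' @export
correct_copy_number <- function(table, tax, cn, rescale = TRUE) {
  asvs <- colnames(table)
  miss <- setdiff(asvs, tax$asv_id)
  if (length(miss))
    stop("ASVs absent from taxonomy: ", paste(utils::head(miss, 5), collapse = ", "))
  tax <- tax[match(asvs, tax$asv_id), , drop = FALSE]
  use_ranks <- intersect(c("genus", "family", "order"), names(tax))
  if (!length(use_ranks))
    stop("taxonomy has none of the ranks order/family/genus")
  divisor <- rep(1, length(asvs))
  for (i in seq_along(asvs)) {
    for (rk in use_ranks) {            # deepest first
      taxon <- tax[[rk]][i]
      if (!is.na(taxon)) {
        hit <- which(cn$rank == rk & cn$taxon == taxon)
        if (!length(hit))
          stop("no copy number for ", rk, " '", taxon, "' (ASV ", asvs[i], ")")
        divisor[i] <- cn$copy_number[hit[1]]
        break                          # class or shallower: divisor stays 1
      }
    }
  }
  out <- sweep(unclass(table), 2, divisor, "/")
  if (rescale) {
    tot0 <- rowSums(unclass(table))
    tot1 <- rowSums(out)
    f <- ifelse(tot1 > 0, tot0 / tot1, 1)
    out <- out * f
  }
  dimnames(out) <- dimnames(table)
  attr(out, "pool") <- attr(table, "pool")
  out
}

#' Repeated rarefaction with averaging
#'
#' Subsamples each sample, without replacement, down to a fixed depth
#' (default 10 000 reads), repeats the subsampling `n` times (default 100)
#' and returns the per-cell mean. Samples whose total is below the depth are
#' excluded with a warning. Subsampling is delegated to [vegan::rrarefy()].
#'
#' @param table Integer count matrix (samples x ASVs). Non-integer counts are
#'   an error: rarefaction is defined on raw reads.
#' @param depth Reads per sample after rarefaction (default 10000).
#' @param n Number of rarefaction permutations to average (default 100).
#' @param seed Integer seed fixing all `n` subsamples.
#' @return A real-valued matrix of class `"rarefied_table"` whose rows each
#'   sum to `depth`, with attributes `depth`, `n_permutations` and `seed`.
#' @export
rarefy_repeated <- function(table, depth = 10000, n = 100, seed = 1) {
  if (depth <= 0 || n <= 0) stop("depth and n must be positive")
  m <- unclass(as.matrix(table))
  if (any(abs(m - round(m)) > 1e-8))
    stop("rarefaction requires integer counts; correct copy numbers after rarefying")
  m <- round(m)
  tot <- rowSums(m)
  drop <- tot < depth
  if (any(drop)) {
    warning("excluding ", sum(drop), " sample(s) below rarefaction depth: ",
            paste(rownames(m)[drop], collapse = ", "))
    m <- m[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  if (nrow(m) == 0) stop("no sample reaches the rarefaction depth")
  at_depth <- tot == depth            # subsampling N from N is the identity
  acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  if (all(at_depth)) {
    acc <- m
  } else {
    set.seed(as.integer(seed))
    work <- m[!at_depth, , drop = FALSE]
    sub <- matrix(0, nrow(work), ncol(work))
    # vegan warns about "observed counts" whenever a table lacks singletons;
    # integrality is already validated above, so that heuristic is muffled
    quiet_rrarefy <- function(x, d)
      withCallingHandlers(vegan::rrarefy(x, d), warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    for (i in seq_len(n)) sub <- sub + quiet_rrarefy(work, depth)
    acc[!at_depth, ] <- sub / n
    acc[at_depth, ] <- m[at_depth, , drop = FALSE]
  }
  storage.mode(acc) <- "double"
  structure(acc, depth = depth, n_permutations = n, seed = seed,
            pool = attr(table, "pool"),
            class = c("rarefied_table", "matrix", "array"))
}

#' Centred log-ratio (CLR) transform
#'
#' Per sample s and ASV i, `clr = ln(x_i + pc) - mean_j ln(x_j + pc)`. A
#' pseudocount of 1 on every cell is the default zero treatment, matching the
#' pseudocount convention used for the log2 RNA:DNA ratios; pass
#' `pseudocount = 0` only for strictly positive tables.
#'
#' @param table Count matrix (samples x ASVs), counts >= 0.
#' @param pseudocount Positive offset added to every cell (default 1);
#'   0 is allowed only when the table has no zeros.
#' @return A matrix of CLR values (rows sum to 0) with a `pseudocount`
#'   attribute, class `"clr_table"`.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  m <- unclass(as.matrix(table))
  if (any(m < 0)) stop("counts must be non-negative")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(m == 0))
    stop("pseudocount 0 requires a strictly positive table")
  lx <- log(m + pseudocount)
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(table)
  structure(out, pseudocount = pseudocount, pool = attr(table, "pool"),
            class = c("clr_table", "matrix", "array"))
}
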