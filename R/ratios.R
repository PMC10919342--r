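#' Per-ASV log2 RNA:DNA ratios
#'
#' Elementwise `log2((rna + 1) / (dna + 1))` over a paired table. The
#' pseudocount of 1 keeps the ratio finite for ASVs that are inactive
#' (RNA = 0) or undetected in the DNA pool, and both tables should share a
#' common scale (rarefied means at the same depth) so the pseudocount means
#' the same thing in both pools.
#'
#' @param paired A [pair_tables()] object (rarefied mean tables).
#' @return Matrix of ratios (samples x ASVs); 0 wherever RNA equals DNA.
#' @export
asv_ratios <- function(paired) {
  if (any(paired$dna < 0) || any(paired$rna < 0))
    stop("counts must be non-negative")
  log2((paired$rna + 1) / (paired$dna + 1))
}

#' Assign ASVs to mixed-rank reporting groups
#'
#' Resolves each ASV to one reporting group starting from a default rank
#' (phylum) and refining named groups to a deeper rank, the way community
#' composition is usually reported: e.g. split Proteobacteria at the class
#' level and Alphaproteobacteria/Gammaproteobacteria at the order level. The
#' most specific applicable rule wins. ASVs unassigned at the default rank
#' are labelled `"Unclassified"`.
#'
#' @param tax Taxonomy data.frame (see [read_taxonomy()]).
#' @param default_rank Rank used for every ASV unless refined
#'   (default `"phylum"`).
#' @param refine Named character vector: `group name -> deeper rank`,
#'   applied recursively (default splits Proteobacteria to class and its
#'   alpha/gamma classes to order).
#' @return Named character vector: `asv_id -> group`.
#' @export
assign_reporting_groups <- function(tax, default_rank = "phylum",
                                    refine = c(Proteobacteria = "class",
                                               Alphaproteobacteria = "order",
                                               Gammaproteobacteria = "order")) {
  if (!default_rank %in% names(tax)) stop("taxonomy lacks rank ", default_rank)
  grp <- tax[[default_rank]]
  grp[is.na(grp)] <- "Unclassified"
  for (i in seq_along(grp)) {
    seen <- character(0)
    while (grp[i] %in% names(refine) && !grp[i] %in% seen) {
      seen <- c(seen, grp[i])
      deeper <- tax[[refine[[grp[i]]]]][i]
      if (is.na(deeper)) break
      grp[i] <- deeper
    }
  }
  stats::setNames(grp, tax$asv_id)
}

#' Group-aggregated log2 RNA:DNA ratios
#'
#' Per sample and reporting group, `log2((sum rna + 1) / (sum dna + 1))` over
#' the member ASVs. Groups whose DNA total across the whole data set does not
#' exceed `min_dna_reads` (default 500 reads) are dropped, so ratios are only
#' reported for groups with enough DNA signal to anchor them.
#'
#' @param paired A [pair_tables()] object (rarefied mean tables).
#' @param groups Named character vector `asv_id -> group` (see
#'   [assign_reporting_groups()]); every ASV must map to exactly one group.
#' @param min_dna_reads Data-set-wide DNA read threshold (default 500; groups
#'   are kept only when strictly above it).
#' @return Long data.frame with columns `sample_id`, `group`, `ratio`.
#' @export
group_ratios <- function(paired, groups, min_dna_reads = 500) {
  asvs <- colnames(paired$dna)
  miss <- setdiff(asvs, names(groups))
  if (length(miss))
    stop("ASVs without a reporting group: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (anyDuplicated(names(groups)))
    stop("ASV mapped to more than one group: ",
         paste(unique(names(groups)[duplicated(names(groups))]), collapse = ", "))
  g <- factor(groups[asvs])
  agg <- function(m) {
    out <- t(rowsum(t(unclass(m)), g))          # samples x groups
    out
  }
  dna_g <- agg(paired$dna)
  rna_g <- agg(paired$rna)
  keep <- colSums(dna_g) > min_dna_reads
  if (!any(keep)) stop("no group exceeds min_dna_reads = ", min_dna_reads)
  dna_g <- dna_g[, keep, drop = FALSE]
  rna_g <- rna_g[, keep, drop = FALSE]
  ratio <- log2((rna_g + 1) / (dna_g + 1))
  data.frame(sample_id = rep(rownames(ratio), ncol(ratio)),
             group = rep(colnames(ratio), each = nrow(ratio)),
             ratio = as.vector(ratio), stringsAsFactors = FALSE)
}
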