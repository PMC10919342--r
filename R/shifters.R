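#' Detect RNA-abundance shifters
#'
#' For each ASV, the mean and maximum over all unordered sample pairs of the
#' absolute difference in rarefied RNA reads (the per-taxon "Euclidean
#' distance" between samples, which in one dimension is the absolute
#' difference). ASVs whose mean pairwise change exceeds the threshold
#' (default 10 reads on the 10 000-read rarefied scale) are flagged as
#' shifters. All samples are pooled: the statistic is global, not
#' per-station.
#'
#' The mean pairwise difference is computed from the sorted abundances:
#' `sum_{i<j} (x_(j) - x_(i)) = sum_i (2i - n - 1) x_(i)`.
#'
#' @param rna RNA rarefied mean matrix (samples x ASVs) over all samples.
#' @param threshold Mean-change threshold in reads (default 10; strictly
#'   greater flags a shifter).
#' @return data.frame with columns `asv_id`, `mean_change`, `max_change`,
#'   `is_shifter`.
#' @export
detect_shifters <- function(rna, threshold = 10) {
  m <- unclass(as.matrix(rna))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  w <- 2 * seq_len(n) - n - 1
  npairs <- n * (n - 1) / 2
  sorted <- apply(m, 2, sort)
  mean_change <- colSums(sorted * w) / npairs
  max_change <- sorted[n, ] - sorted[1, ]
  data.frame(asv_id = colnames(m), mean_change = unname(mean_change),
             max_change = unname(max_change),
             is_shifter = unname(mean_change > threshold),
             stringsAsFactors = FALSE)
}

#' Classify shifters by depth preference
#'
#' A shifter whose mean RNA abundance across surface (depth index 1) samples
#' exceeds its mean across bathypelagic (depth index 7) samples is a
#' "sunlit" shifter; the reverse is a "deep" shifter. Exact ties are left
#' unclassified (`"none"`) with a warning, as are non-shifters.
#'
#' @param records Output of [detect_shifters()].
#' @param rna RNA rarefied mean matrix used for the detection.
#' @param meta Sample metadata.
#' @return `records` with an added `depth_class` column
#'   (`"sunlit"`, `"deep"` or `"none"`).
#' @export
classify_shifters <- function(records, rna, meta) {
  meta <- match_meta(rna, meta)
  surf <- meta$sample_id[meta$depth_index == 1]
  bathy <- meta$sample_id[meta$depth_index == 7]
  if (!length(bathy)) stop("no bathypelagic (depth index 7) samples")
  if (!length(surf)) stop("no surface (depth index 1) samples")
  m <- unclass(as.matrix(rna))
  surf_mean <- colMeans(m[surf, , drop = FALSE])[records$asv_id]
  bathy_mean <- colMeans(m[bathy, , drop = FALSE])[records$asv_id]
  cls <- ifelse(surf_mean > bathy_mean, "sunlit",
                ifelse(bathy_mean > surf_mean, "deep", "none"))
  tied <- records$is_shifter & cls == "none"
  if (any(tied))
    warning("shifter(s) with tied surface/bathypelagic means left unclassified: ",
            paste(records$asv_id[tied], collapse = ", "))
  records$depth_class <- ifelse(records$is_shifter, cls, "none")
  records$surface_mean_rna <- unname(surf_mean)
  records$bathy_mean_rna <- unname(bathy_mean)
  records
}

#' Per-sample profiles of surface (d1) shifters
#'
#' Restricts the shifters to those categorised d1 (surface detected) at each
#' sample's station and reports, per sample and depth class, their summed
#' relative contribution to the RNA reads and their mean per-ASV
#' `log2((rna + 1) / (dna + 1))` ratio. These are the raw per-sample values
#' behind the depth-profile figures; any curve smoothing is presentation.
#'
#' @param records Classified shifter records (see [classify_shifters()]).
#' @param catmap Category map from [assign_depth_categories()].
#' @param paired A [pair_tables()] object of rarefied mean tables.
#' @param meta Sample metadata.
#' @return Long data.frame with columns `sample_id`, `station`,
#'   `depth_index`, `depth_class`, `n_asvs`, `rna_contribution` (fraction of
#'   the sample's RNA reads), `mean_ratio` (NA when no member ASV).
#' @export
d1_shifter_profiles <- function(records, catmap, paired, meta) {
  meta <- match_meta(paired, meta)
  ratios <- asv_ratios(paired)
  rna_rel <- unclass(paired$rna) / rowSums(paired$rna)
  out <- list()
  for (i in seq_len(nrow(meta))) {
    st <- meta$station[i]; sid <- meta$sample_id[i]
    d1_here <- catmap$asv_id[catmap$station == st & catmap$category == "d1"]
    for (cls in c("sunlit", "deep")) {
      members <- intersect(records$asv_id[records$is_shifter &
                                          records$depth_class == cls],
                           d1_here)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, station = st, depth_index = meta$depth_index[i],
        depth_class = cls, n_asvs = length(members),
        rna_contribution = sum(rna_rel[sid, members]),
        mean_ratio = if (length(members)) mean(ratios[sid, members])
                     else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
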