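#' First-detection depth categorisation of ASVs
#'
#' Per station, assigns every ASV the depth index at which it is first
#' detected in the DNA pool, assuming a directionality from the surface (d1)
#' to the bathypelagic (d7): an ASV DNA-detected at the station's surface is
#' a d1 ASV, one first DNA-detected at the next depth is a d2 ASV, and so
#' on. ASVs never DNA-detected at a station but RNA-detected there are
#' "phantom" taxa: too rare to be caught in the DNA pool yet active enough
#' to appear in the RNA pool. Stations are processed independently.
#'
#' Detection is abundance > 0 on the supplied tables (use rarefied means for
#' the standard analysis). Stations missing an intermediate depth keep their
#' native depth indices. A station without a surface (depth index 1) sample
#' is an error, since the directionality is undefined there.
#'
#' @param paired A [pair_tables()] object.
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @return data.frame with columns `station`, `asv_id`, `category`
#'   (`"d1"`..`"d7"` or `"phantom"`); ASVs undetected at a station in both
#'   pools carry no row.
#' @export
assign_depth_categories <- function(paired, meta) {
  meta <- match_meta(paired, meta)
  out <- list()
  for (st in unique(meta$station)) {
    sub <- meta[meta$station == st, , drop = FALSE]
    sub <- sub[order(sub$depth_index), , drop = FALSE]
    if (!1 %in% sub$depth_index)
      stop("station ", st, " has no surface (depth index 1) sample; ",
           "first-detection directionality is undefined")
    dna_det <- is_detected(paired$dna[sub$sample_id, , drop = FALSE])
    rna_det <- is_detected(paired$rna[sub$sample_id, , drop = FALSE])
    # collapse replicate samples at the same depth index, if any
    if (anyDuplicated(sub$depth_index)) {
      f <- factor(sub$depth_index)
      dna_det <- rowsum(dna_det + 0, f) > 0
      rna_det <- rowsum(rna_det + 0, f) > 0
      depths <- as.integer(levels(f))
    } else depths <- sub$depth_index
    any_dna <- colSums(dna_det) > 0
    any_rna <- colSums(rna_det) > 0
    first <- rep(NA_integer_, ncol(dna_det))
    first[any_dna] <- depths[max.col(t(dna_det[, any_dna, drop = FALSE]),
                                     ties.method = "first")]
    category <- ifelse(any_dna, paste0("d", first),
                       ifelse(any_rna, "phantom", NA))
    keep <- !is.na(category)
    out[[st]] <- data.frame(station = st,
                            asv_id = colnames(paired$dna)[keep],
                            category = category[keep],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

category_levels <- c(paste0("d", 1:7), "phantom")

#' Contribution of depth categories to DNA and RNA communities
#'
#' For every (station, depth, pool) sample, the fraction of reads carried by
#' ASVs of each first-detection category (d1..d7 and, for the RNA pool,
#' phantom). Pass copy-number-corrected rarefied tables to weight taxa by
#' cells rather than 16S copies.
#'
#' @param paired A [pair_tables()] object (abundances used as read weights).
#' @param catmap Category map from [assign_depth_categories()].
#' @param meta Sample metadata.
#' @param units `"reads"` (default) for read fractions or `"asvs"` for
#'   ASV-count fractions.
#' @return Long data.frame with columns `station`, `depth_index`,
#'   `sample_id`, `pool`, `category`, `fraction`; fractions over the
#'   categories sum to 1 per (sample, pool).
#' @export
category_contributions <- function(paired, catmap, meta,
                                   units = c("reads", "asvs")) {
  units <- match.arg(units)
  meta <- match_meta(paired, meta)
  out <- list()
  for (st in unique(meta$station)) {
    sub <- meta[meta$station == st, , drop = FALSE]
    cm <- catmap[catmap$station == st, , drop = FALSE]
    cats <- stats::setNames(cm$category, cm$asv_id)
    for (i in seq_len(nrow(sub))) {
      for (pool in c("dna", "rna")) {
        x <- paired[[pool]][sub$sample_id[i], ]
        if (units == "asvs") x <- is_detected(x) + 0
        x <- x[names(cats)]                      # uncategorised ASVs carry 0
        tot <- sum(x)
        frac <- if (tot > 0)
          tapply(x, factor(cats, levels = category_levels), sum,
                 default = 0) / tot
        else stats::setNames(rep(NA_real_, length(category_levels)),
                             category_levels)
        out[[length(out) + 1L]] <- data.frame(
          station = st, depth_index = sub$depth_index[i],
          sample_id = sub$sample_id[i], pool = toupper(pool),
          category = category_levels, fraction = as.numeric(frac),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Richness and activity of the surface-derived taxon pool by depth
#'
#' Per station and depth: the number of that station's d1-category (surface
#' derived) ASVs DNA-detected at that depth, the same number as a fraction
#' of the station's surface richness, and the proportion of those detected
#' taxa that are also RNA-detected (active) there.
#'
#' @param catmap Category map from [assign_depth_categories()].
#' @param paired A [pair_tables()] object.
#' @param meta Sample metadata.
#' @return data.frame with columns `station`, `depth_index`, `sample_id`,
#'   `richness_d1`, `frac_of_surface`, `prop_active`.
#' @export
surface_pool_richness <- function(catmap, paired, meta) {
  meta <- match_meta(paired, meta)
  out <- list()
  for (st in unique(meta$station)) {
    sub <- meta[meta$station == st, , drop = FALSE]
    sub <- sub[order(sub$depth_index), , drop = FALSE]
    d1_asvs <- catmap$asv_id[catmap$station == st & catmap$category == "d1"]
    dna <- is_detected(paired$dna[sub$sample_id, d1_asvs, drop = FALSE])
    rna <- is_detected(paired$rna[sub$sample_id, d1_asvs, drop = FALSE])
    rich <- rowSums(dna)
    act <- rowSums(dna & rna)
    surf <- rich[match(1, sub$depth_index)]
    out[[st]] <- data.frame(
      station = st, depth_index = sub$depth_index,
      sample_id = sub$sample_id, richness_d1 = unname(rich),
      frac_of_surface = unname(if (isTRUE(surf > 0)) rich / surf else NA_real_),
      prop_active = unname(ifelse(rich > 0, act / rich, NA_real_)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
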