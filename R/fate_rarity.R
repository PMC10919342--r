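#' Fate of surface-derived taxa in the bathypelagic
#'
#' Partitions each station's d1-category (surface derived) ASVs by their
#' status in that station's deepest (depth index 7) sample: `active`
#' (DNA- and RNA-detected), `inactive` (DNA-detected, RNA-undetected) or
#' `lost` (DNA-undetected). Stations without a depth-7 sample are skipped
#' with a warning.
#'
#' @param paired A [pair_tables()] object of rarefied mean tables.
#' @param catmap Category map from [assign_depth_categories()].
#' @param meta Sample metadata.
#' @return data.frame with columns `station`, `asv_id`, `fate`.
#' @export
classify_fate <- function(paired, catmap, meta) {
  meta <- match_meta(paired, meta)
  out <- list()
  for (st in unique(meta$station)) {
    sub <- meta[meta$station == st, , drop = FALSE]
    d7 <- sub$sample_id[sub$depth_index == 7]
    if (!length(d7)) {
      warning("station ", st, " has no depth-7 sample; skipped")
      next
    }
    d7 <- d7[1]
    d1_asvs <- catmap$asv_id[catmap$station == st & catmap$category == "d1"]
    dna <- is_detected(paired$dna[d7, d1_asvs])
    rna <- is_detected(paired$rna[d7, d1_asvs])
    out[[st]] <- data.frame(
      station = st, asv_id = d1_asvs,
      fate = ifelse(dna & rna, "active", ifelse(dna, "inactive", "lost")),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no station has a depth-7 sample")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Taxonomic composition of the fate classes
#'
#' Within each fate class, the fraction of ASV-by-station records belonging
#' to each reporting group (fractions sum to 1 within a class).
#'
#' @param fate Fate table from [classify_fate()].
#' @param groups Named character vector `asv_id -> group` (see
#'   [assign_reporting_groups()]).
#' @return data.frame with columns `fate`, `group`, `n`, `fraction`.
#' @export
fate_taxonomy_composition <- function(fate, groups) {
  miss <- setdiff(fate$asv_id, names(groups))
  if (length(miss))
    stop("ASVs without a reporting group: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- list()
  for (f in sort(unique(fate$fate))) {
    g <- groups[fate$asv_id[fate$fate == f]]
    tab <- table(g)
    out[[f]] <- data.frame(fate = f, group = names(tab),
                           n = as.integer(tab),
                           fraction = as.numeric(tab) / sum(tab),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Rarity and occurrence classification of surface-detected ASVs
#'
#' Abundance class from the maximum relative abundance across surface
#' (depth index 1) DNA samples: `abundant` (> 1 % in at least one surface
#' sample), `rare` (> 0.1 % and <= 1 %) or `very_rare` (<= 0.1 %).
#' Occurrence class from the fraction of stations whose surface DNA sample
#' detects the ASV: `ubiquitous` (> 70 %), `intermediate` (30-70 %) or
#' `local` (< 30 %). The boundary conventions make the classes exhaustive
#' and mutually exclusive; the cutpoints are configurable. Also reports, per
#' ASV, the number of distinct depth indices (any station) with DNA
#' detection, the water-column "cosmopolitanism".
#'
#' @param dna DNA rarefied mean matrix (samples x ASVs).
#' @param meta Sample metadata.
#' @param abundant_cut,rare_cut Relative-abundance cutpoints (defaults 0.01
#'   and 0.001).
#' @param ubiq_cut,local_cut Station-occupancy cutpoints (defaults 0.7 and
#'   0.3).
#' @return data.frame over surface-detected ASVs with columns `asv_id`,
#'   `max_surface_rel`, `abundance_class`, `n_stations`, `occupancy`,
#'   `occurrence_class`, `cosmopolitan_depths`.
#' @export
classify_rarity <- function(dna, meta, abundant_cut = 0.01, rare_cut = 0.001,
                            ubiq_cut = 0.7, local_cut = 0.3) {
  meta <- match_meta(dna, meta)
  surf <- meta$sample_id[meta$depth_index == 1]
  if (!length(surf)) stop("no surface (depth index 1) samples")
  m <- unclass(as.matrix(dna))
  rel <- m[surf, , drop = FALSE] / rowSums(m[surf, , drop = FALSE])
  max_rel <- apply(rel, 2, max)
  st_f <- factor(meta$station[match(surf, meta$sample_id)])
  det_station <- rowsum(is_detected(rel) + 0, st_f) > 0
  n_st <- colSums(det_station)
  keep <- n_st > 0
  occ <- n_st / nlevels(st_f)
  abundance_class <- ifelse(max_rel > abundant_cut, "abundant",
                            ifelse(max_rel > rare_cut, "rare", "very_rare"))
  occurrence_class <- ifelse(occ > ubiq_cut, "ubiquitous",
                             ifelse(occ >= local_cut, "intermediate",
                                    "local"))
  depth_det <- rowsum(is_detected(m) + 0, meta$depth_index) > 0
  data.frame(asv_id = colnames(m)[keep],
             max_surface_rel = unname(max_rel[keep]),
             abundance_class = unname(abundance_class[keep]),
             n_stations = unname(n_st[keep]), occupancy = unname(occ[keep]),
             occurrence_class = unname(occurrence_class[keep]),
             cosmopolitan_depths = unname(colSums(depth_det)[keep]),
             stringsAsFactors = FALSE)
}

#' Rarity/occurrence composition of the surface-derived active bathypelagic
#' RNA pool
#'
#' Across all stations with a depth-7 sample, sums the depth-7 RNA relative
#' abundance of the surface-derived ASVs that remained active there, split
#' by rarity and occurrence class, and normalises over all active
#' surface-derived ASVs. Also returns, for the active surface-derived ASVs
#' that become abundant in the bathypelagic active pool (> `abundant_cut`
#' RNA relative abundance in at least one depth-7 sample), their
#' water-column cosmopolitanism (number of depth indices with DNA
#' detection).
#'
#' @param rarity Rarity records from [classify_rarity()].
#' @param fate Fate table from [classify_fate()].
#' @param paired A [pair_tables()] object of rarefied mean tables.
#' @param meta Sample metadata.
#' @param abundant_cut RNA relative-abundance threshold for "abundant in the
#'   bathypelagic active pool" (default 0.01).
#' @return A list with `class_contributions` (data.frame: `abundance_class`,
#'   `occurrence_class`, `rna_weight`, `fraction`), `abundance_margin`
#'   (fractions by abundance class alone) and `abundant_bathy` (data.frame
#'   of the bathypelagic-abundant active ASVs with `cosmopolitan_depths`).
#' @export
bathy_active_rarity_breakdown <- function(rarity, fate, paired, meta,
                                          abundant_cut = 0.01) {
  meta <- match_meta(paired, meta)
  act <- fate[fate$fate == "active", , drop = FALSE]
  rna_rel <- unclass(paired$rna) / rowSums(paired$rna)
  weight <- stats::setNames(numeric(nrow(act)), NULL)
  max_bathy_rel <- stats::setNames(rep(0, length(unique(act$asv_id))),
                                   unique(act$asv_id))
  for (st in unique(act$station)) {
    sub <- meta[meta$station == st, , drop = FALSE]
    d7 <- sub$sample_id[sub$depth_index == 7][1]
    idx <- act$station == st
    w <- rna_rel[d7, act$asv_id[idx]]
    weight[idx] <- w
    mx <- pmax(max_bathy_rel[act$asv_id[idx]], w)
    max_bathy_rel[act$asv_id[idx]] <- mx
  }
  cls <- rarity[match(act$asv_id, rarity$asv_id),
                c("abundance_class", "occurrence_class")]
  if (anyNA(cls$abundance_class))
    stop("active surface-derived ASV(s) missing from the rarity records: ",
         paste(utils::head(act$asv_id[is.na(cls$abundance_class)], 5),
               collapse = ", "))
  agg <- stats::aggregate(weight,
                          by = list(abundance_class = cls$abundance_class,
                                    occurrence_class = cls$occurrence_class),
                          FUN = sum)
  names(agg)[3] <- "rna_weight"
  agg$fraction <- agg$rna_weight / sum(agg$rna_weight)
  marg <- stats::aggregate(agg$rna_weight,
                           by = list(abundance_class = agg$abundance_class),
                           FUN = sum)
  names(marg)[2] <- "rna_weight"
  marg$fraction <- marg$rna_weight / sum(marg$rna_weight)
  ab_ids <- names(max_bathy_rel)[max_bathy_rel > abundant_cut]
  abundant_bathy <- rarity[rarity$asv_id %in% ab_ids,
                           c("asv_id", "abundance_class", "occurrence_class",
                             "cosmopolitan_depths")]
  list(class_contributions = agg, abundance_margin = marg,
       abundant_bathy = abundant_bathy)
}
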