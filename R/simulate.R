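#' Scenario configuration for the paired-survey generator
#'
#' Builds the configuration of a synthetic paired DNA/RNA amplicon survey of
#' a stratified water column with fully known ground truth. The defaults
#' encode the reference scenario used for end-to-end validation: 13 stations
#' sampled at 7 depths (surface to bathypelagic), ~5000 ASVs, read libraries
#' on the 10 000-read scale, and planted structure at the bottom depth —
#' surface-derived taxa carrying 50 % of the bathypelagic RNA reads, a 15 %
#' per-station survival of surface taxa to the bottom, 70 % of the
#' surface-derived active bottom RNA mass on rare + very rare taxa, and
#' 25 sunlit + 25 deep shifter ASVs with a >= 100-read surface-vs-deep RNA
#' contrast against a low, near-constant RNA background.
#'
#' Surface (d1-origin) ASVs carry a planted surface-abundance class
#' (abundant / rare / very rare, via `*_w` expected-read ranges) and an
#' occurrence class; taxa that survive to the bottom are kept ubiquitous so
#' the planted bottom fractions are exact per station, and occurrence
#' variation is planted on the taxa that never reach the bottom. The
#' survivor count is solved from the occurrence mix so that the expected
#' per-station detected survival fraction equals `survival_to_bottom`.
#'
#' @param seed Master seed; fixes weights, masks and count sampling.
#' @param n_stations Number of stations.
#' @param depth_m Nominal depth (m) of depth indices 1..7.
#' @param layers Analysis-layer label per depth index.
#' @param library_size_range Inclusive integer range of per-sample library
#'   sizes (both pools).
#' @param n_abundant,n_rare,n_very_rare Surface-origin ASV counts per
#'   surface-abundance class.
#' @param abundant_w,rare_w,very_rare_w Expected surface DNA reads (uniform
#'   ranges) per class, on a 10 000-read sample scale.
#' @param survival_to_bottom Target per-station fraction of detected surface
#'   taxa that are still DNA-detected at depth index 7.
#' @param lost_depth_probs Distribution of the deepest depth index (1..6)
#'   reached by surface taxa that do not survive to the bottom.
#' @param n_sunlit,n_deep Planted shifter counts (sunlit decay below the
#'   photic zone; deep rise toward the bottom).
#' @param deep_shifter_classes Deep-shifter counts per surface-abundance
#'   class (named: abundant, rare, very_rare).
#' @param n_const_active Counts of bottom-active survivors with a flat RNA
#'   profile, per class (named: rare, very_rare).
#' @param occurrence_probs Mix of occurrence classes among non-surviving
#'   surface taxa (named: ubiquitous, intermediate, local).
#' @param n_stations_intermediate,n_stations_local Stations occupied by
#'   intermediate and local taxa.
#' @param d1_rna_share_bottom Planted fraction of bottom RNA reads carried
#'   by surface-derived taxa.
#' @param active_class_shares Split of that surface-derived bottom RNA mass
#'   over the surface-abundance classes (named; sums to 1).
#' @param deep_origin_counts ASV counts with origin depths 2..7.
#' @param n_phantom RNA-only (phantom) ASV count.
#' @param phantom_rna_w Expected RNA reads of a phantom taxon.
#' @param background_rna_cap Per-ASV cap (reads) on background RNA
#'   expectations, keeping non-planted taxa below the shifter threshold.
#' @param survivor_deep_w Expected sub-surface DNA reads (uniform range) of
#'   bottom survivors.
#' @param sunlit_profile Expected RNA reads of sunlit shifters at depths
#'   1..7.
#' @param deep_profile_shallow Expected RNA reads of deep shifters at depths
#'   1..6 (the depth-7 value is set by the class-share scaling).
#' @param deep_d7_w Pre-scaling depth-7 RNA reads of deep shifters per class.
#' @param const_active_w Flat RNA reads of the constant-profile active
#'   survivors.
#' @param inactive_shallow_w RNA reads of bottom-inactive survivors at
#'   depths 1..3 (0 below).
#' @param deep_origin_dna_lnorm Lognormal (meanlog, sdlog) of deep-origin
#'   DNA weights.
#' @param deep_origin_rna_mean Mean of the exponential base RNA weight of
#'   deep-origin taxa.
#' @param activity_identity If TRUE, RNA expectations are set equal to DNA
#'   expectations (log2 RNA:DNA ratios are 0 in the large-library limit).
#' @param rna_homogenize If TRUE, each ASV's RNA expectation is replaced by
#'   its across-depth mean (depth-homogeneous active community).
#' @return A validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1,
                            n_stations = 13,
                            depth_m = c(3, 106, 430, 700, 970, 2000, 4000),
                            layers = c("Surface", "DCM", "Upper mesopelagic",
                                       "Lower mesopelagic",
                                       "Lower mesopelagic", "Bathypelagic",
                                       "Bathypelagic"),
                            library_size_range = c(10000, 12000),
                            n_abundant = 20, n_rare = 120, n_very_rare = 900,
                            abundant_w = c(150, 250), rare_w = c(15, 60),
                            very_rare_w = c(2, 4),
                            survival_to_bottom = 0.15,
                            lost_depth_probs = c(0.40, 0.25, 0.12, 0.09,
                                                 0.07, 0.07),
                            n_sunlit = 25, n_deep = 25,
                            deep_shifter_classes = c(abundant = 8, rare = 10,
                                                     very_rare = 7),
                            n_const_active = c(rare = 30, very_rare = 14),
                            occurrence_probs = c(ubiquitous = 0.60,
                                                 intermediate = 0.25,
                                                 local = 0.15),
                            n_stations_intermediate = 6,
                            n_stations_local = 2,
                            d1_rna_share_bottom = 0.50,
                            active_class_shares = c(abundant = 0.30,
                                                    rare = 0.45,
                                                    very_rare = 0.25),
                            deep_origin_counts = c(800, 900, 600, 500, 400,
                                                   540),
                            n_phantom = 200, phantom_rna_w = 3,
                            background_rna_cap = 15,
                            survivor_deep_w = c(15, 40),
                            sunlit_profile = c(150, 40, 0, 0, 0, 0, 0),
                            deep_profile_shallow = c(5, 5, 5, 40, 60, 60),
                            deep_d7_w = c(abundant = 180, rare = 120,
                                          very_rare = 110),
                            const_active_w = 30, inactive_shallow_w = 8,
                            deep_origin_dna_lnorm = c(meanlog = 0.3,
                                                      sdlog = 1),
                            deep_origin_rna_mean = 1.2,
                            activity_identity = FALSE,
                            rna_homogenize = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  with(cfg, {
    if (n_stations < 1) stop("need at least one station")
    if (length(depth_m) != 7 || any(diff(depth_m) <= 0))
      stop("depth_m must be 7 strictly increasing depths")
    if (length(layers) != 7) stop("layers must label the 7 depth indices")
    if (abs(sum(occurrence_probs) - 1) > 1e-9)
      stop("occurrence_probs must sum to 1")
    if (abs(sum(lost_depth_probs) - 1) > 1e-9)
      stop("lost_depth_probs must sum to 1")
    if (abs(sum(active_class_shares) - 1) > 1e-9)
      stop("active_class_shares must sum to 1")
    if (survival_to_bottom < 0 || survival_to_bottom > 1 ||
        d1_rna_share_bottom < 0 || d1_rna_share_bottom >= 1)
      stop("planted fractions must lie in [0, 1)")
    if (n_stations_intermediate > n_stations ||
        n_stations_local > n_stations)
      stop("occupied-station counts exceed n_stations")
    if (library_size_range[1] < 1 ||
        library_size_range[2] < library_size_range[1])
      stop("invalid library_size_range")
    if (sum(deep_shifter_classes) != n_deep)
      stop("deep_shifter_classes must sum to n_deep")
  })
  roster <- roster_counts(cfg)
  if (roster$n_inactive < 0)
    stop("infeasible config: solved survivor count (", roster$n_survivors,
         ") is smaller than the planted active roster (", roster$n_active,
         ")")
  caps <- c(abundant = cfg$n_abundant, rare = cfg$n_rare,
            very_rare = cfg$n_very_rare)
  used <- roster$class_active + roster$class_inactive +
    c(abundant = 0, rare = cfg$n_sunlit, very_rare = 0)
  if (any(used > caps))
    stop("infeasible config: class ", names(caps)[which(used > caps)[1]],
         " cannot hold its planted roster")
  cfg
}

# survivor count solved so the expected per-station detected survival
# fraction equals the target, given the occurrence mix of non-survivors
roster_counts <- function(cfg) {
  n_d1 <- cfg$n_abundant + cfg$n_rare + cfg$n_very_rare
  q <- cfg$occurrence_probs[["ubiquitous"]] +
    cfg$occurrence_probs[["intermediate"]] *
      cfg$n_stations_intermediate / cfg$n_stations +
    cfg$occurrence_probs[["local"]] * cfg$n_stations_local / cfg$n_stations
  s <- cfg$survival_to_bottom
  n_surv <- round(s * (cfg$n_sunlit + q * (n_d1 - cfg$n_sunlit)) /
                    (1 - s + s * q))
  class_active <- c(abundant = cfg$deep_shifter_classes[["abundant"]],
                    rare = cfg$deep_shifter_classes[["rare"]] +
                      cfg$n_const_active[["rare"]],
                    very_rare = cfg$deep_shifter_classes[["very_rare"]] +
                      cfg$n_const_active[["very_rare"]])
  n_active <- sum(class_active)
  n_inactive <- n_surv - n_active
  # allocate inactive survivors across classes by remaining capacity
  remaining <- pmax(c(abundant = cfg$n_abundant,
                      rare = cfg$n_rare - cfg$n_sunlit,
                      very_rare = cfg$n_very_rare) - class_active, 0)
  class_inactive <- largest_remainder(n_inactive, remaining)
  list(n_d1 = n_d1, n_survivors = n_surv, n_active = n_active,
       n_inactive = n_inactive, class_active = class_active,
       class_inactive = class_inactive, presence_q = q)
}

# integer allocation of n proportional to weights (largest remainder)
largest_remainder <- function(n, weights) {
  if (n <= 0 || sum(weights) == 0)
    return(stats::setNames(rep(0L, length(weights)), names(weights)))
  raw <- n * weights / sum(weights)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# Deterministic construction of the scenario's expected-read weights, masks
# and per-ASV ground-truth attributes. Everything downstream (sampling and
# closed-form expectations) derives from this object.
build_scenario <- function(cfg) {
  set.seed(as.integer(cfg$seed))
  roster <- roster_counts(cfg)
  n_d1 <- roster$n_d1
  n_deep_origin <- sum(cfg$deep_origin_counts)
  n_asv <- n_d1 + n_deep_origin + cfg$n_phantom
  asv_id <- sprintf("asv%05d", seq_len(n_asv))

  origin <- c(rep(1L, n_d1),
              rep(2:7, cfg$deep_origin_counts),
              rep(NA_integer_, cfg$n_phantom))
  abundance_class <- rep(NA_character_, n_asv)
  abundance_class[seq_len(n_d1)] <-
    rep(c("abundant", "rare", "very_rare"),
        c(cfg$n_abundant, cfg$n_rare, cfg$n_very_rare))
  role <- rep("deep_origin", n_asv)
  role[is.na(origin)] <- "phantom"

  # within-class roles for surface taxa: shifters, const actives, sunlit,
  # inactive survivors, lost
  class_idx <- function(cl) which(abundance_class == cl)
  for (cl in c("abundant", "rare", "very_rare")) {
    idx <- class_idx(cl)
    k <- 0
    take <- function(n) {
      sel <- idx[k + seq_len(n)]; k <<- k + n; sel
    }
    role[take(cfg$deep_shifter_classes[[cl]])] <- "deep_shifter"
    nca <- if (cl %in% names(cfg$n_const_active)) cfg$n_const_active[[cl]] else 0
    role[take(nca)] <- "const_active"
    if (cl == "rare") role[take(cfg$n_sunlit)] <- "sunlit_shifter"
    role[take(roster$class_inactive[[cl]])] <- "inactive_survivor"
    if (k < length(idx)) role[idx[(k + 1):length(idx)]] <- "lost"
  }

  survivor <- role %in% c("deep_shifter", "const_active", "inactive_survivor")
  active_bottom <- role %in% c("deep_shifter", "const_active")

  # deepest depth reached (DNA presence), per ASV
  max_depth <- rep(7L, n_asv)
  lost <- which(role == "lost")
  max_depth[lost] <- sample(1:6, length(lost), replace = TRUE,
                            prob = cfg$lost_depth_probs)
  max_depth[role == "sunlit_shifter"] <- 2L
  max_depth[role == "phantom"] <- NA_integer_

  # occurrence: survivors, sunlit, deep-origin and phantoms are ubiquitous;
  # occurrence variation is planted on the remaining surface taxa
  occurrence <- rep("ubiquitous", n_asv)
  varying <- which(role %in% c("lost", "inactive_survivor") & !survivor)
  occurrence[varying] <- sample(names(cfg$occurrence_probs), length(varying),
                                replace = TRUE, prob = cfg$occurrence_probs)
  presence <- matrix(TRUE, n_asv, cfg$n_stations)
  for (i in which(occurrence == "intermediate")) {
    presence[i, ] <- FALSE
    presence[i, sample.int(cfg$n_stations, cfg$n_stations_intermediate)] <- TRUE
  }
  for (i in which(occurrence == "local")) {
    presence[i, ] <- FALSE
    presence[i, sample.int(cfg$n_stations, cfg$n_stations_local)] <- TRUE
  }

  # DNA weights (expected reads on a 10 000-read scale), ASV x depth
  base_w <- numeric(n_asv)
  rng <- list(abundant = cfg$abundant_w, rare = cfg$rare_w,
              very_rare = cfg$very_rare_w)
  for (cl in names(rng)) {
    idx <- class_idx(cl)
    base_w[idx] <- stats::runif(length(idx), rng[[cl]][1], rng[[cl]][2])
  }
  deep_idx <- which(role == "deep_origin")
  base_w[deep_idx] <- stats::rlnorm(length(deep_idx),
                                    cfg$deep_origin_dna_lnorm[["meanlog"]],
                                    cfg$deep_origin_dna_lnorm[["sdlog"]])
  sub_w <- stats::runif(n_asv, cfg$survivor_deep_w[1], cfg$survivor_deep_w[2])
  dna_w <- matrix(0, n_asv, 7)
  for (d in 1:7) {
    here <- !is.na(origin) & origin <= d & max_depth >= d
    dna_w[here, d] <- ifelse(survivor[here] & d > 1, sub_w[here],
                             base_w[here])
  }

  # RNA weights: planted profiles for shifters / actives, capped background
  # fill elsewhere so every column totals ~10 000 expected reads
  rna_w <- matrix(0, n_asv, 7)
  sun <- which(role == "sunlit_shifter")
  for (d in 1:7) rna_w[sun, d] <- cfg$sunlit_profile[d]
  dsh <- which(role == "deep_shifter")
  for (d in 1:6) rna_w[dsh, d] <- cfg$deep_profile_shallow[d]
  rna_w[dsh, 7] <- cfg$deep_d7_w[abundance_class[dsh]]
  cact <- which(role == "const_active")
  rna_w[cact, ] <- cfg$const_active_w
  inact <- which(role == "inactive_survivor")
  rna_w[inact, 1:3] <- cfg$inactive_shallow_w
  bg_base <- numeric(n_asv)
  bg_base[lost] <- pmin(base_w[lost], cfg$background_rna_cap)
  bg_base[deep_idx] <- stats::rexp(length(deep_idx),
                                   1 / cfg$deep_origin_rna_mean)
  ph <- which(role == "phantom")
  bg_base[ph] <- cfg$phantom_rna_w
  planted <- role %in% c("sunlit_shifter", "deep_shifter", "const_active",
                         "inactive_survivor")
  for (d in 1:7) {
    bg_here <- !planted &
      ((role == "phantom") |
         (!is.na(origin) & origin <= d & max_depth >= d))
    fixed <- sum(rna_w[planted, d])
    target <- if (d == 7) 10000 * (1 - cfg$d1_rna_share_bottom) else
      10000 - fixed
    fill <- rep(0, n_asv)
    open <- bg_here & bg_base > 0
    remaining <- target
    for (it in 1:4) {                      # cap-and-redistribute
      if (!any(open) || remaining <= 0) break
      alpha <- remaining / sum(bg_base[open])
      add <- pmin(alpha * bg_base, cfg$background_rna_cap - fill)
      add[!open] <- 0
      fill <- fill + add
      remaining <- remaining - sum(add)
      open <- open & fill < cfg$background_rna_cap - 1e-9
      if (remaining < 1e-6) break
    }
    rna_w[, d] <- rna_w[, d] + fill
  }
  # depth 7: scale the surface-derived active block so its class masses hit
  # the planted shares of the planted surface-derived total exactly
  bottom_bg <- sum(rna_w[!planted, 7])
  d1_total <- bottom_bg * cfg$d1_rna_share_bottom /
    (1 - cfg$d1_rna_share_bottom)
  for (cl in names(cfg$active_class_shares)) {
    blk <- which(active_bottom & abundance_class == cl)
    mass <- sum(rna_w[blk, 7])
    if (length(blk) && mass > 0)
      rna_w[blk, 7] <- rna_w[blk, 7] *
        (d1_total * cfg$active_class_shares[[cl]] / mass)
    else if (cfg$active_class_shares[[cl]] > 0 && d1_total > 0 &&
             !length(blk))
      stop("infeasible config: no active survivor carries class ", cl)
  }

  if (cfg$activity_identity) rna_w <- dna_w
  if (cfg$rna_homogenize) rna_w <- matrix(rowMeans(rna_w), n_asv, 7)

  shifter_class <- ifelse(role == "sunlit_shifter", "sunlit",
                          ifelse(role == "deep_shifter", "deep", "none"))
  fate <- ifelse(is.na(origin) | origin > 1, NA_character_,
                 ifelse(active_bottom, "active",
                        ifelse(survivor, "inactive", "lost")))
  truth_asv <- data.frame(
    asv_id = asv_id, origin_depth = origin, role = role,
    abundance_class = abundance_class, occurrence_class = occurrence,
    max_depth = max_depth, survivor = survivor,
    active_at_bottom = active_bottom,
    is_shifter = shifter_class != "none", shifter_class = shifter_class,
    fate = fate, stringsAsFactors = FALSE)

  list(config = cfg, asv_id = asv_id, dna_w = dna_w, rna_w = rna_w,
       presence = presence, truth_asv = truth_asv, roster = roster)
}

#' Generate a synthetic paired survey
#'
#' Samples DNA and RNA read counts for every (station, depth) sample by
#' multinomial draws from the scenario's expected-read weights, and returns
#' the paired tables together with sample metadata, a random taxonomy, a
#' random rooted phylogeny, a copy-number lookup and the full ground truth.
#'
#' @param cfg A [scenario_config()].
#' @return A list with elements `paired` ([pair_tables()] of raw counts),
#'   `meta`, `taxonomy`, `copy_numbers`, `tree` ([ape::phylo]) and `truth`
#'   (list: `asv` per-ASV attributes, `planted` the planted fractions,
#'   `weights` the expected-read matrices, `presence`, `library_sizes`).
#' @export
simulate_survey <- function(cfg) {
  scen <- build_scenario(cfg)
  n_asv <- length(scen$asv_id)
  S <- cfg$n_stations
  samples <- expand.grid(depth_index = 1:7, station = seq_len(S))
  sample_id <- sprintf("st%02d_d%d", samples$station, samples$depth_index)
  lib_vals <- seq(cfg$library_size_range[1], cfg$library_size_range[2])
  lib <- matrix(if (length(lib_vals) == 1) rep(lib_vals, 2 * nrow(samples))
                else sample(lib_vals, 2 * nrow(samples), replace = TRUE),
                ncol = 2, dimnames = list(sample_id, c("DNA", "RNA")))
  dna <- rna <- matrix(0L, nrow(samples), n_asv,
                       dimnames = list(sample_id, scen$asv_id))
  for (i in seq_len(nrow(samples))) {
    st <- samples$station[i]; d <- samples$depth_index[i]
    pd <- scen$dna_w[, d] * scen$presence[, st]
    pr <- scen$rna_w[, d] * scen$presence[, st]
    if (sum(pd) <= 0 || sum(pr) <= 0)
      stop("sample ", sample_id[i], " has no expected reads in a pool")
    dna[i, ] <- stats::rmultinom(1, lib[i, "DNA"], pd)
    rna[i, ] <- stats::rmultinom(1, lib[i, "RNA"], pr)
  }
  meta <- data.frame(sample_id = sample_id,
                     station = sprintf("st%02d", samples$station),
                     depth_m = cfg$depth_m[samples$depth_index],
                     depth_index = samples$depth_index,
                     layer = cfg$layers[samples$depth_index],
                     stringsAsFactors = FALSE)
  taxonomy <- simulate_taxonomy(scen)
  cn <- simulate_copy_numbers(taxonomy)
  tree <- ape::rtree(n_asv, br = stats::rexp)
  tree$tip.label <- sample(scen$asv_id)
  planted <- list(d1_rna_share_bottom = cfg$d1_rna_share_bottom,
                  survival_to_bottom = cfg$survival_to_bottom,
                  rare_vr_active_share =
                    cfg$active_class_shares[["rare"]] +
                    cfg$active_class_shares[["very_rare"]],
                  shifter_ids =
                    scen$truth_asv$asv_id[scen$truth_asv$is_shifter])
  list(paired = pair_tables(asv_table(dna, "DNA"), asv_table(rna, "RNA")),
       meta = meta, taxonomy = taxonomy, copy_numbers = cn, tree = tree,
       truth = list(asv = scen$truth_asv, planted = planted,
                    weights = list(dna = scen$dna_w, rna = scen$rna_w),
                    presence = scen$presence, library_sizes = lib,
                    roster = scen$roster))
}

# nested random taxonomy over a marine-flavoured group set; a fraction of
# ASVs is truncated at shallower ranks to exercise the copy-number exemption
simulate_taxonomy <- function(scen) {
  n <- length(scen$asv_id)
  phyla <- c("Proteobacteria", "Cyanobacteria", "Bacteroidota",
             "Actinobacteriota", "Crenarchaeota", "Thermoplasmatota",
             "Planctomycetota", "Verrucomicrobiota", "Marinimicrobia",
             "WPS-2")
  phylum <- sample(phyla, n, replace = TRUE,
                   prob = c(0.35, 0.1, 0.12, 0.1, 0.08, 0.05, 0.06, 0.05,
                            0.05, 0.04))
  class <- ifelse(phylum == "Proteobacteria",
                  sample(c("Alphaproteobacteria", "Gammaproteobacteria"), n,
                         replace = TRUE),
                  paste0(phylum, "_cl", sample(1:2, n, replace = TRUE)))
  order <- paste0(class, "_or", sample(1:3, n, replace = TRUE))
  family <- paste0(order, "_fa", sample(1:2, n, replace = TRUE))
  genus <- paste0(family, "_ge", sample(1:2, n, replace = TRUE))
  depth <- sample(c("genus", "family", "order", "class", "phylum"), n,
                  replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
  tax <- data.frame(asv_id = scen$asv_id,
                    domain = ifelse(phylum %in% c("Crenarchaeota",
                                                  "Thermoplasmatota"),
                                    "Archaea", "Bacteria"),
                    phylum = phylum, class = class, order = order,
                    family = family, genus = genus, stringsAsFactors = FALSE)
  tax$genus[depth %in% c("family", "order", "class", "phylum")] <- NA
  tax$family[depth %in% c("order", "class", "phylum")] <- NA
  tax$order[depth %in% c("class", "phylum")] <- NA
  tax$class[depth == "phylum"] <- NA
  tax
}

simulate_copy_numbers <- function(taxonomy) {
  out <- list()
  for (rk in c("order", "family", "genus")) {
    taxa <- unique(stats::na.omit(taxonomy[[rk]]))
    out[[rk]] <- data.frame(rank = rk, taxon = taxa,
                            copy_number = stats::runif(length(taxa), 1, 8),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Closed-form expected fractions of a scenario
#'
#' Computes, without sampling, the expectations the planted scenario implies:
#' per (station, depth, pool) the expected read fraction of each
#' origin-depth category (phantoms included), the expected per-station
#' detected survival fraction of surface taxa, and the planted
#' rarity-class split of the surface-derived active bottom RNA. These are
#' the oracles the recovery tests compare pipeline output against.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `category_fractions` (data.frame: station,
#'   depth_index, pool, category, fraction), `survival` (data.frame:
#'   station, expected fraction), and `planted` (the planted fraction list).
#' @export
expected_fractions <- function(cfg) {
  scen <- build_scenario(cfg)
  tr <- scen$truth_asv
  category <- ifelse(is.na(tr$origin_depth), "phantom",
                     paste0("d", tr$origin_depth))
  out <- list()
  for (st in seq_len(cfg$n_stations)) {
    pres <- scen$presence[, st]
    for (d in 1:7) {
      for (pool in c("DNA", "RNA")) {
        w <- (if (pool == "DNA") scen$dna_w else scen$rna_w)[, d] * pres
        frac <- tapply(w, factor(category, levels = category_levels), sum,
                       default = 0) / sum(w)
        out[[length(out) + 1L]] <- data.frame(
          station = sprintf("st%02d", st), depth_index = d, pool = pool,
          category = category_levels, fraction = as.numeric(frac),
          stringsAsFactors = FALSE)
      }
    }
  }
  surv <- vapply(seq_len(cfg$n_stations), function(st) {
    d1_here <- !is.na(tr$origin_depth) & tr$origin_depth == 1 &
      scen$presence[, st]
    sum(d1_here & tr$survivor) / sum(d1_here)
  }, numeric(1))
  list(category_fractions = do.call(rbind, c(out,
                                             list(make.row.names = FALSE))),
       survival = data.frame(station = sprintf("st%02d",
                                               seq_len(cfg$n_stations)),
                             expected_survival = surv,
                             stringsAsFactors = FALSE),
       planted = list(d1_rna_share_bottom = cfg$d1_rna_share_bottom,
                      survival_to_bottom = cfg$survival_to_bottom,
                      rare_vr_active_share =
                        cfg$active_class_shares[["rare"]] +
                        cfg$active_class_shares[["very_rare"]]))
}
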