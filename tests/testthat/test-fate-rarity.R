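test_that("fate classification partitions surface taxa at the deepest sample", {
  p <- toy_paired()
  meta <- toy_meta()
  cm <- assign_depth_categories(p, meta)
  fate <- classify_fate(p, cm, meta)
  get <- function(st, asv) fate$fate[fate$station == st & fate$asv_id == asv]
  expect_equal(get("A", "v1"), "active")    # DNA 10, RNA 8 at A7
  expect_equal(get("B", "v1"), "inactive")  # DNA 10, RNA 0 at B7
  expect_equal(get("A", "v4"), "lost")      # absent from A7
  # the fates partition each station's d1 richness
  for (st in c("A", "B")) {
    d1 <- cm$asv_id[cm$station == st & cm$category == "d1"]
    expect_setequal(fate$asv_id[fate$station == st], d1)
  }
  meta_no7 <- meta[meta$depth_index != 7 | meta$station != "B", ]
  p_sub <- structure(list(dna = p$dna[meta_no7$sample_id, ],
                          rna = p$rna[meta_no7$sample_id, ]),
                     class = "paired_asv_table")
  expect_warning(f2 <- classify_fate(p_sub, cm, meta_no7), "station B")
  expect_setequal(unique(f2$station), "A")
})

test_that("fate composition fractions sum to one per class", {
  fate <- data.frame(station = "A", asv_id = c("a", "b", "c", "d"),
                     fate = c("active", "active", "lost", "lost"),
                     stringsAsFactors = FALSE)
  groups <- c(a = "G1", b = "G1", c = "G1", d = "G2")
  comp <- fate_taxonomy_composition(fate, groups)
  expect_equal(comp$fraction[comp$fate == "active" & comp$group == "G1"], 1)
  for (f in unique(comp$fate))
    expect_equal(sum(comp$fraction[comp$fate == f]), 1)
  expect_error(fate_taxonomy_composition(fate, groups[-1]), "without")
})

test_that("matched planted compositions give near-zero Jensen-Shannon divergence", {
  # inactive and lost planted with identical group composition
  set.seed(71)
  n <- 400
  grp <- sample(paste0("G", 1:5), n, replace = TRUE)
  ids <- paste0("a", seq_len(n))
  fate <- data.frame(station = "A", asv_id = rep(ids, 2),
                     fate = rep(c("inactive", "lost"), each = n),
                     stringsAsFactors = FALSE)
  comp <- fate_taxonomy_composition(fate, stats::setNames(grp, ids))
  levels_g <- sort(unique(grp))
  p1 <- comp$fraction[comp$fate == "inactive"][
    match(levels_g, comp$group[comp$fate == "inactive"])]
  p2 <- comp$fraction[comp$fate == "lost"][
    match(levels_g, comp$group[comp$fate == "lost"])]
  expect_lt(jsd(p1, p2), 0.01)
})

test_that("rarity boundaries are pinned exactly at 1 %, 0.1 %, 30 % and 70 %", {
  # 10 stations, surface totals of exactly 1000 reads
  n_st <- 10
  meta <- data.frame(sample_id = paste0("st", 1:n_st, "_d1"),
                     station = paste0("st", 1:n_st), depth_m = 3,
                     depth_index = 1L, layer = "Surface",
                     stringsAsFactors = FALSE)
  asvs <- c("at", "above", "rare_hi", "rare_lo", "vr", "filler")
  m <- matrix(0, n_st, length(asvs),
              dimnames = list(meta$sample_id, asvs))
  m[, "at"] <- 10          # exactly 1.0 % -> rare, present at all stations
  m[1, "above"] <- 11      # 1.1 % in one sample -> abundant
  m[1:7, "rare_hi"] <- 1.5 # 0.15 % at 7/10 stations -> rare, intermediate
  m[1:3, "rare_lo"] <- 2   # 0.2 % at 3/10 -> rare, intermediate (30 %)
  m[1:2, "vr"] <- 1        # exactly 0.1 % at 2/10 -> very rare, local
  m[, "filler"] <- 1000 - rowSums(m)
  r <- classify_rarity(m, meta)
  cls <- stats::setNames(r$abundance_class, r$asv_id)
  occ <- stats::setNames(r$occurrence_class, r$asv_id)
  expect_equal(unname(cls["at"]), "rare")          # > 1 % is strict
  expect_equal(unname(cls["above"]), "abundant")
  expect_equal(unname(cls["rare_hi"]), "rare")
  expect_equal(unname(cls["vr"]), "very_rare")     # <= 0.1 %
  expect_equal(unname(occ["at"]), "ubiquitous")    # 100 %
  expect_equal(unname(occ["rare_hi"]), "intermediate")  # exactly 70 %
  expect_equal(unname(occ["rare_lo"]), "intermediate")  # exactly 30 %
  expect_equal(unname(occ["vr"]), "local")         # 20 %
  # classes are exhaustive and exclusive over surface-detected ASVs
  expect_false(anyNA(r$abundance_class))
  expect_false(anyNA(r$occurrence_class))
})

test_that("rarity records count cosmopolitan depths from DNA detections", {
  meta <- rbind(toy_meta())
  p <- toy_paired()
  r <- classify_rarity(p$dna, meta)
  expect_equal(r$cosmopolitan_depths[r$asv_id == "v1"], 3)  # d1, d3, d7
  expect_equal(r$cosmopolitan_depths[r$asv_id == "v4"], 1)
  expect_false("v5" %in% r$asv_id)   # never surface-detected
})

test_that("bathypelagic active breakdown recovers the planted rarity split", {
  cfg <- small_cfg(seed = 72)
  sim <- simulate_survey(cfg)
  dna_r <- rarefy_repeated(asv_table(sim$paired$dna, "DNA"), 10000, 25,
                           seed = 8)
  rna_r <- rarefy_repeated(asv_table(sim$paired$rna, "RNA"), 10000, 25,
                           seed = 9)
  pr <- structure(list(dna = unclass(dna_r), rna = unclass(rna_r)),
                  class = "paired_asv_table")
  cm <- assign_depth_categories(pr, sim$meta)
  fate <- classify_fate(pr, cm, sim$meta)
  rar <- classify_rarity(dna_r, sim$meta)
  bk <- bathy_active_rarity_breakdown(rar, fate, pr, sim$meta)
  marg <- bk$abundance_margin
  got <- sum(marg$fraction[marg$abundance_class %in% c("rare", "very_rare")])
  want <- sim$truth$planted$rare_vr_active_share
  expect_lt(abs(got - want), 0.05)
  expect_equal(sum(bk$class_contributions$fraction), 1, tolerance = 1e-9)
  # the fate partition equals the d1 richness at every station
  for (st in unique(fate$station)) {
    d1 <- cm$asv_id[cm$station == st & cm$category == "d1"]
    expect_equal(nrow(fate[fate$station == st, ]), length(d1))
  }
})
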