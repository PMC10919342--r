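test_that("generation is deterministic and library sizes are exact", {
  cfg <- small_cfg(seed = 81)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1$paired$dna, s2$paired$dna)
  expect_identical(s1$paired$rna, s2$paired$rna)
  expect_identical(s1$truth$asv, s2$truth$asv)
  s3 <- simulate_survey(small_cfg(seed = 82))
  expect_false(identical(s1$paired$dna, s3$paired$dna))
  # multinomial totals equal the drawn library sizes
  expect_equal(unname(rowSums(s1$paired$dna)),
               unname(s1$truth$library_sizes[, "DNA"]))
  expect_equal(unname(rowSums(s1$paired$rna)),
               unname(s1$truth$library_sizes[, "RNA"]))
  lib <- s1$truth$library_sizes
  expect_true(all(lib >= 10000 & lib <= 11000))
})

test_that("scenario outputs are structurally consistent", {
  cfg <- small_cfg(seed = 83)
  sim <- simulate_survey(cfg)
  tr <- sim$truth$asv
  expect_equal(nrow(sim$meta), 4 * 7)
  expect_silent(validate_sample_meta(sim$meta))
  expect_silent(validate_taxonomy(sim$taxonomy))
  expect_setequal(sim$tree$tip.label, tr$asv_id)
  # phantoms never carry DNA weight; surface taxa never originate deeper
  ph <- tr$role == "phantom"
  expect_true(all(sim$paired$dna[, tr$asv_id[ph]] == 0))
  expect_true(all(is.na(tr$origin_depth[ph])))
  expect_true(all(tr$origin_depth[!ph] >= 1 & tr$origin_depth[!ph] <= 7))
  # survivors reach the bottom, lost surface taxa never do
  d1 <- !is.na(tr$origin_depth) & tr$origin_depth == 1
  expect_true(all(tr$max_depth[d1 & tr$survivor] == 7))
  expect_true(all(tr$max_depth[d1 & tr$fate == "lost"] < 7))
})

test_that("expected fractions are exact scenario expectations", {
  cfg <- small_cfg(seed = 84)
  ef <- expected_fractions(cfg)
  cf <- ef$category_fractions
  # fractions sum to one per (station, depth, pool)
  sums <- stats::aggregate(fraction ~ station + depth_index + pool, cf, sum)
  expect_equal(sums$fraction, rep(1, nrow(sums)), tolerance = 1e-9)
  # the planted surface share of bottom RNA holds exactly at every station
  d1d7 <- cf[cf$depth_index == 7 & cf$pool == "RNA" & cf$category == "d1", ]
  expect_equal(d1d7$fraction, rep(cfg$d1_rna_share_bottom, nrow(d1d7)),
               tolerance = 1e-9)
  # expected per-station survival sits at the configured target
  expect_true(all(abs(ef$survival$expected_survival -
                      cfg$survival_to_bottom) < 0.02))
  # DNA pool carries no phantom mass at any depth
  ph <- cf[cf$pool == "DNA" & cf$category == "phantom", ]
  expect_true(all(ph$fraction == 0))
})

test_that("expectations match empirical fractions of a large library", {
  cfg <- small_cfg(seed = 85)
  cfg$library_size_range <- c(1000000, 1000000)
  sim <- simulate_survey(cfg)
  ef <- expected_fractions(cfg)
  tr <- sim$truth$asv
  category <- ifelse(is.na(tr$origin_depth), "phantom",
                     paste0("d", tr$origin_depth))
  sid <- "st01_d4"
  w <- sim$paired$rna[sid, ]
  emp <- tapply(w, factor(category, levels = unique(category)), sum,
                default = 0) / sum(w)
  cf <- ef$category_fractions
  cf <- cf[cf$station == "st01" & cf$depth_index == 4 & cf$pool == "RNA", ]
  want <- stats::setNames(cf$fraction, cf$category)[names(emp)]
  expect_true(all(abs(emp - want) < 0.005))
})

test_that("degenerate scenarios behave as configured", {
  # identical activity: log2 RNA:DNA ratios vanish for large libraries
  cfg0 <- scenario_config(
    seed = 86, n_stations = 2, n_stations_intermediate = 1,
    n_stations_local = 1, library_size_range = c(100000, 100000),
    n_abundant = 50, n_rare = 0, n_very_rare = 0, n_sunlit = 0, n_deep = 0,
    deep_shifter_classes = c(abundant = 0, rare = 0, very_rare = 0),
    n_const_active = c(rare = 0, very_rare = 0), survival_to_bottom = 1,
    d1_rna_share_bottom = 0, deep_origin_counts = rep(0, 6), n_phantom = 0,
    activity_identity = TRUE)
  sim0 <- simulate_survey(cfg0)
  expect_lt(mean(abs(asv_ratios(sim0$paired))), 0.05)

  # zero survival: every surface taxon is lost at the bottom
  cfgL <- scenario_config(
    seed = 87, n_stations = 3, n_stations_intermediate = 2,
    n_stations_local = 1, n_abundant = 10, n_rare = 40, n_very_rare = 100,
    survival_to_bottom = 0, n_sunlit = 0, n_deep = 0,
    deep_shifter_classes = c(abundant = 0, rare = 0, very_rare = 0),
    n_const_active = c(rare = 0, very_rare = 0), d1_rna_share_bottom = 0,
    deep_origin_counts = c(40, 40, 30, 30, 20, 40), n_phantom = 10)
  simL <- simulate_survey(cfgL)
  cm <- assign_depth_categories(simL$paired, simL$meta)
  fate <- classify_fate(simL$paired, cm, simL$meta)
  expect_setequal(unique(fate$fate), "lost")
})

test_that("infeasible configurations fail before sampling", {
  expect_error(scenario_config(survival_to_bottom = 0), "infeasible")
  expect_error(scenario_config(active_class_shares = c(abundant = 0.9,
                                                       rare = 0.2,
                                                       very_rare = 0.2)),
               "sum to 1")
  expect_error(scenario_config(n_stations = 3), "exceed")
  expect_error(scenario_config(n_deep = 10), "sum to n_deep")
})
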