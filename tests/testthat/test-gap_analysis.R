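# Partitioned distance summaries, barcode gaps, deep-lineage and
# zero-distance flags.

test_that("pair classification, including open-nomenclature taxa", {
  expect_equal(classify_pair("Pachypanchax arnoulti", "Pachypanchax arnoulti"),
               "intraspecific")
  expect_equal(classify_pair("Pachypanchax arnoulti",
                             "Pachypanchax sparksorum"),
               "congeneric_interspecific")
  expect_equal(classify_pair("Oreochromis sp.", "Oreochromis niloticus"),
               "congeneric_interspecific")
  expect_equal(classify_pair("Oreochromis niloticus", "Coptodon zillii"),
               "intergeneric")
})

test_that("28-pair toy enumeration: classes 4 / 8 / 16, disjoint, exhaustive", {
  set.seed(30)
  lib <- barcode_library(toy_partition_library())
  dm <- distance_matrix(lib, "COI", mode = "msa")
  ps <- partition_summary(dm, lib)
  counts <- setNames(ps$n_pairs, ps$class)
  expect_equal(counts[["intraspecific"]], 4L)
  expect_equal(counts[["congeneric_interspecific"]], 8L)
  expect_equal(counts[["intergeneric"]], 16L)
  expect_equal(sum(ps$n_pairs), choose(8, 2))
  ok <- !is.na(ps$mean_pct)
  expect_true(all(ps$min_pct[ok] <= ps$mean_pct[ok] &
                  ps$mean_pct[ok] <= ps$max_pct[ok]))
})

test_that("class counts are disjoint and exhaustive over unmasked pairs", {
  sim <- simulate_library(simulation_config(seed = 31))
  dm <- distance_matrix(sim$library, "COI", mode = "msa")
  ps <- partition_summary(dm, sim$library)
  n <- length(dm$ids)
  expect_equal(sum(ps$n_pairs), n * (n - 1) / 2)
})

test_that("single-species library populates only the intraspecific class", {
  set.seed(32)
  lib <- barcode_library(toy_records(4))
  dm <- distance_matrix(lib, "COI", mode = "msa")
  ps <- partition_summary(dm, lib)
  expect_equal(ps$n_pairs[ps$class == "intraspecific"], 6L)
  expect_true(all(ps$n_pairs[ps$class != "intraspecific"] == 0))
  expect_true(all(is.na(ps$mean_pct[ps$class != "intraspecific"])))
})

test_that("subset filters restrict the summary", {
  sim <- simulate_library(simulation_config(seed = 33, orphan_lineage = TRUE))
  dm <- distance_matrix(sim$library, "COI", mode = "msa")
  full <- partition_summary(dm, sim$library)
  native <- partition_summary(dm, sim$library,
                              subset = function(x)
                                x$origin_status == "native",
                              label = "native only")
  expect_lt(sum(native$n_pairs), sum(full$n_pairs))
  expect_equal(attr(native, "subset"), "native only")
})

test_that("barcode gap per species: shared haplotypes, singletons, clean gaps", {
  # constructed matrix: two species sharing a haplotype + a singleton
  ids <- c("a1", "a2", "b1", "s1")
  d <- matrix(c(0,    0.01, 0,    0.08,
                0.01, 0,    0.01, 0.08,
                0,    0.01, 0,    0.08,
                0.08, 0.08, 0.08, 0), 4, 4)
  dm <- manual_dist(d, ids)
  lib <- barcode_library(toy_records(
    4, species = c("Aa x", "Aa x", "Aa y", "Bb z"), seq_length = 50,
    sample_id = ids))
  gaps <- barcode_gap_per_species(dm, lib)
  ax <- gaps[gaps$species == "Aa x", ]
  ay <- gaps[gaps$species == "Aa y", ]
  sz <- gaps[gaps$species == "Bb z", ]
  expect_false(ax$gap)                       # min_inter = 0
  expect_equal(ax$min_inter_pct, 0)
  expect_true(is.na(ay$gap))                 # singleton: indeterminate
  expect_true(is.na(ay$max_intra_pct))
  expect_equal(sz$min_inter_pct, 8)
  expect_true(is.na(sz$gap))

  # clean simulated library: every gap flag true
  sim <- simulate_library(simulation_config(seed = 34))
  dms <- distance_matrix(sim$library, "COI", mode = "msa")
  g <- barcode_gap_per_species(dms, sim$library)
  expect_true(all(g$gap))
})

test_that("min_inter agrees with direct recomputation (oracle)", {
  sim <- simulate_library(simulation_config(seed = 35))
  dm <- distance_matrix(sim$library, "COI", mode = "msa")
  g <- barcode_gap_per_species(dm, sim$library)
  sp <- sim$library$species_name
  for (k in sample(nrow(g), 4)) {
    own <- which(sp == g$species[k])
    expect_equal(g$min_inter_pct[k],
                 round(100 * min(dm$d[own, -own]), 1),
                 label = g$species[k])
  }
})

test_that("deep-lineage flags: split detection and degenerate guard", {
  # species with two site-groups 5% apart, threshold 3% -> 2 clusters
  ids <- paste0("r", 1:6)
  d <- matrix(0.05, 6, 6)
  d[1:3, 1:3] <- 0.005
  d[4:6, 4:6] <- 0.005
  diag(d) <- 0
  dm <- manual_dist(d, ids)
  lib <- barcode_library(toy_records(6, species = "Ratsirakia legendrei",
                                     sample_id = ids, seq_length = 50))
  flags <- deep_lineage_flags(dm, lib, threshold = 0.03)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$n_clusters, 2)
  expect_equal(flags$min_between_pct, 5)
  cl <- attr(flags, "clusters")[["Ratsirakia legendrei"]]
  expect_equal(unname(cl[1:3] == cl[1]), rep(TRUE, 3))
  expect_false(cl[4] == cl[1])

  # all-identical species: no flags
  d0 <- matrix(0, 4, 4)
  dm0 <- manual_dist(d0, paste0("n", 1:4))
  lib0 <- barcode_library(toy_records(4, species = "Ptychochromis oligacanthus",
                                      sample_id = paste0("n", 1:4),
                                      seq_length = 50))
  expect_equal(nrow(deep_lineage_flags(dm0, lib0)), 0)

  # degenerate threshold below the guard: flagging suppressed
  expect_equal(nrow(deep_lineage_flags(dm, lib, threshold = 0)), 0)
})

test_that("zero-distance species pairs, with exclusion list", {
  ids <- c("a1", "a2", "b1", "b2")
  d <- matrix(c(0,    0.01, 0,    0.02,
                0.01, 0,    0.01, 0.02,
                0,    0.01, 0,    0.01,
                0.02, 0.02, 0.01, 0), 4, 4)
  dm <- manual_dist(d, ids)
  lib <- barcode_library(toy_records(4, species = c("Aa x", "Aa x",
                                                    "Aa y", "Aa y"),
                                     sample_id = ids, seq_length = 50))
  z <- zero_distance_species_pairs(dm, lib)
  expect_equal(nrow(z), 1)
  expect_equal(z$species_a, "Aa x")
  expect_equal(z$species_b, "Aa y")
  expect_equal(z$n_zero_pairs, 1L)
  # excluding the introgressed-like record removes the pair
  z2 <- zero_distance_species_pairs(dm, lib, exclude = "a1")
  expect_equal(nrow(z2), 0)

  # clean simulated library: empty list
  sim <- simulate_library(simulation_config(seed = 36))
  dms <- distance_matrix(sim$library, "COI", mode = "msa")
  expect_equal(nrow(zero_distance_species_pairs(dms, sim$library)), 0)
})
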