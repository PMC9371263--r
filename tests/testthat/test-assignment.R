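# Threshold-based assignment against a reference panel, label transfer,
# syntopy reports.

# Panel over a fixed backbone with planted mismatch counts, so every
# identity is an exact fraction of the 600 comparable sites. Edits are
# spread evenly over the interior so the optimal alignment stays
# gapless (isolated mismatches never pay for a gap).
make_panel <- function(backbone, edits, species) {
  L <- nchar(backbone)
  seqs <- vapply(seq_along(edits), function(i) {
    s <- strsplit(backbone, "")[[1]]
    k <- edits[i]
    if (k > 0) {
      pos <- unique(round(seq(20, L - 20, length.out = k)))
      stopifnot(length(pos) == k)
      s[pos] <- vapply(s[pos], function(ch)
        setdiff(c("A", "C", "G", "T"), ch)[1], "")
    }
    paste(s, collapse = "")
  }, "")
  reference_panel(species, seqs, marker = "ND2")
}

test_that("best_match ranks species by max-over-exemplar identity", {
  set.seed(40)
  backbone <- random_seq(600)
  panel <- make_panel(backbone, c(0, 60, 30, 90),
                      c("Oreochromis aureus", "Oreochromis niloticus",
                        "Oreochromis niloticus", "Coptodon zillii"))
  rk <- best_match(backbone, panel)
  expect_equal(rk$species[1], "Oreochromis aureus")
  expect_equal(rk$identity_pct[1], 100)
  # per-species max over exemplars: niloticus keeps its 30-edit exemplar
  expect_equal(rk$identity_pct[rk$species == "Oreochromis niloticus"],
               100 * (1 - 30 / 600))
  expect_equal(rk$identity_pct[rk$species == "Coptodon zillii"],
               100 * (1 - 90 / 600))
  expect_true(all(diff(rk$identity_pct) <= 0))
})

test_that("identity is consistent with the distance module", {
  set.seed(41)
  backbone <- random_seq(600)
  panel <- make_panel(backbone, 12, "Oreochromis aureus")
  rk <- best_match(backbone, panel)
  aln <- pairwise_align(backbone, panel$sequence[1])
  pd <- p_distance(aln$aligned_a, aln$aligned_b)
  expect_equal(rk$identity_pct[1], 100 - 100 * pd$distance)
})

test_that("assignment calls follow the identity bands", {
  set.seed(42)
  backbone <- random_seq(600)
  panel <- make_panel(backbone, c(0, 60),
                      c("Oreochromis aureus", "Oreochromis niloticus"))
  # 3 edits -> 99.5%: assigned
  q995 <- make_panel(backbone, 3, "q")$sequence
  a <- assign_species(q995, panel)
  expect_equal(a$call, "assigned")
  expect_equal(a$best_identity_pct, 99.5)
  # 9 edits -> 98.5%: cf band
  expect_equal(assign_species(make_panel(backbone, 9, "q")$sequence,
                              panel)$call, "cf")
  # 16 edits -> 97.33% (2.7% divergent): undetermined
  a27 <- assign_species(make_panel(backbone, 16, "q")$sequence, panel)
  expect_equal(a27$call, "undetermined")
  expect_lt(a27$best_identity_pct, 97.5)
  # two species within 0.5 points at the top: ambiguous
  amb_panel <- make_panel(backbone, c(2, 3),
                          c("Oreochromis aureus", "Oreochromis niloticus"))
  amb <- assign_species(backbone, amb_panel)
  expect_equal(amb$call, "ambiguous")
  expect_equal(amb$margin_pct, 100 * (1 / 600), tolerance = 1e-9)
})

test_that("raising assign_thr never promotes a call (monotonicity)", {
  set.seed(43)
  backbone <- random_seq(600)
  panel <- make_panel(backbone, c(0, 80), c("Aa x", "Bb y"))
  rank_call <- c(assigned = 3, cf = 2, ambiguous = 2, undetermined = 1)
  for (edits in c(1, 5, 10, 14, 20, 40)) {
    q <- make_panel(backbone, edits, "q")$sequence
    calls <- vapply(c(98, 99, 99.5, 99.9), function(thr)
      assign_species(q, panel, assign_thr = thr)$call, "")
    expect_true(all(diff(rank_call[calls]) <= 0), label = edits)
  }
})

test_that("unalignable queries are reported as such", {
  panel <- reference_panel("Aa x", paste(rep("ACGT", 50), collapse = ""),
                           marker = "ND2")
  a <- assign_species(paste(rep("N", 200), collapse = ""), panel)
  expect_equal(a$call, "unalignable")
  expect_true(is.na(a$best_species))
})

test_that("labels transfer across markers within samples", {
  set.seed(44)
  tab <- toy_records(5, seq_length = 100)
  tab$sample_id <- c("s1", "s1", "s2", "s2", "s3")
  tab$marker <- c("ND2", "COI", "ND2", "COI", "ND2")
  tab$species_name <- c("", "", "", "Aa y", "")
  lib <- barcode_library(tab)
  assignments <- data.frame(
    sample_id = c("s1", "s2", "s3"),
    best_species = c("Aa x", "Aa x", "Bb z"),
    best_identity_pct = c(99.7, 99.6, 91.0),
    margin_pct = c(4, 4, 4),
    call = c("assigned", "assigned", "undetermined"),
    stringsAsFactors = FALSE)
  out <- transfer_assignments(lib, assignments)
  # s1: both markers inherit the assigned label
  expect_true(all(out$species_name[out$sample_id == "s1"] == "Aa x"))
  expect_equal(out$provenance[out$sample_id == "s1" & out$marker == "COI"],
               "transferred")
  # s2 COI had a conflicting prior label: flagged, unchanged
  expect_equal(out$species_name[out$sample_id == "s2" &
                                out$marker == "COI"], "Aa y")
  cf <- attr(out, "conflicts")
  expect_equal(cf$sample_id, "s2")
  expect_equal(cf$existing, "Aa y")
  # s3 undetermined: open-nomenclature lineage tag
  expect_equal(out$species_name[out$sample_id == "s3"], "Bb sp.")
  expect_equal(out$provenance[out$sample_id == "s3"], "lineage_tag")
})

test_that("syntopy report keys on locality, coordinates, or 'unlocalized'", {
  set.seed(45)
  tab <- toy_records(6, seq_length = 60,
                     species = c("Oreochromis aureus",
                                 "Oreochromis niloticus",
                                 "Oreochromis sp.",
                                 "Coptodon zillii",
                                 "Coptodon zillii",
                                 "Oreochromis aureus"))
  tab$locality <- c("SiteA", "SiteA", "SiteA", "SiteB", "", "")
  tab$latitude <- c(NA, NA, NA, NA, -16.63653, NA)
  tab$longitude <- c(NA, NA, NA, NA, 47.0888, NA)
  rep <- syntopy_report(barcode_library(tab))
  expect_equal(rep$max_cooccurrence, 3)
  sa <- rep$sites[rep$sites$locality == "SiteA", ]
  expect_equal(sa$n_species, 3)
  expect_match(sa$species, "Oreochromis aureus; Oreochromis niloticus")
  expect_equal(rep$sites$n_species[rep$sites$locality == "SiteB"], 1)
  expect_true("-16.637,47.089" %in% rep$sites$locality)
  expect_true("unlocalized" %in% rep$sites$locality)
})

test_that("simulated site compositions are reported exactly", {
  sim <- simulate_library(simulation_config(seed = 46))
  rep <- syntopy_report(sim$library)
  got <- rep$sites[order(rep$sites$locality), ]
  want <- sim$truth$sites[order(sim$truth$sites$site), ]
  expect_equal(got$locality, want$site)
  expect_equal(got$n_species, want$n_species, ignore_attr = TRUE)
  expect_equal(got$species, want$species)
})

test_that("panel FASTA round trip through read_panel", {
  set.seed(47)
  sim <- simulate_library(simulation_config(seed = 47))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  panel <- read_panel(file.path(dir, "panel.fasta"), marker = "COI")
  expect_equal(panel$species_name, sim$panel$species_name)
  expect_equal(panel$sequence, sim$panel$sequence)
  expect_equal(panel$accession, sim$panel$accession)
})
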