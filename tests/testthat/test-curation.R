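# Curation chain: deduplication, fragment filter, geography, merging,
# taxonomy updates, NUMT screen, summaries, idempotence.

test_that("deduplicate keys on (accession, marker, sequence)", {
  set.seed(10)
  tab <- toy_records(5, accession = c("A1", "A1", "A2", "A2", NA))
  tab$sequence[2] <- tab$sequence[1]      # exact duplicate of record 1
  tab$marker[4] <- "16S"                  # same accession, other marker
  tab$sequence[4] <- tab$sequence[3]
  expect_message(out <- deduplicate(tab), "1 duplicate")
  expect_equal(nrow(out), 4)              # 5 records, 1 exact duplicate
  expect_equal(attr(out, "removed"), 1)
  expect_true(all(c("COI", "16S") %in% out$marker))

  # identical sequences from distinct samples without accession are kept
  tab2 <- toy_records(2, accession = NA)
  tab2$sequence[2] <- tab2$sequence[1]
  expect_equal(nrow(deduplicate(tab2)), 2)

  # 5 records, 2 exact duplicates -> 3 survive
  tab3 <- toy_records(5, accession = "X9")
  tab3$sequence <- tab3$sequence[c(1, 1, 2, 2, 3)]
  expect_equal(nrow(suppressMessages(deduplicate(tab3))), 3)
})

test_that("fragment filter keeps genuine fragments, drops foreign sequence", {
  set.seed(11)
  anchor <- random_seq(650)
  # genuine record: the anchor with a few substitutions
  genuine <- strsplit(anchor, "")[[1]]
  genuine[1:20] <- vapply(genuine[1:20], function(ch)
    setdiff(c("A", "C", "G", "T"), ch)[1], "")
  # short genuine fragment (245 bp) must pass
  frag <- substr(anchor, 101, 345)
  foreign <- random_seq(600)
  tab <- toy_records(3, sequence = c(paste(genuine, collapse = ""),
                                     frag, foreign))
  out <- suppressMessages(
    filter_target_fragment(tab, anchors = c(COI = anchor)))
  expect_identical(out$sample_id, c("T001", "T002"))
  expect_equal(attr(out, "removed"), 1)

  # marker without anchor: retained with warning
  tab16 <- toy_records(1, marker = "16S")
  expect_warning(keep <- filter_target_fragment(tab16, c(COI = anchor)),
                 "no anchor")
  expect_equal(nrow(keep), 1)
})

test_that("geography filter: prefix match, whitelist, unknown origin", {
  set.seed(12)
  tab <- toy_records(4, country = c("Madagascar: Nosy Be", "madagascar",
                                    "Israel", ""))
  out <- suppressMessages(filter_geography(tab))
  expect_identical(out$sample_id, c("T001", "T002"))
  expect_equal(attr(out, "removed_foreign"), 1)
  expect_equal(attr(out, "removed_unknown"), 1)
  # reference-panel whitelisting keeps the foreign record
  out2 <- suppressMessages(filter_geography(tab, whitelist = "T003"))
  expect_true("T003" %in% out2$sample_id)
})

test_that("merge_sample_rows: linking, uniqueness, conflicts", {
  set.seed(13)
  # 10 records over 6 samples -> 6 sample entries
  tab <- toy_records(10)
  tab$sample_id <- c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4",
                     "s5", "s6")
  tab$marker <- c("COI", "16S", "COI", "16S", "COI", "16S",
                  "COI", "COI", "COI", "COI")
  tab$sequence[8] <- tab$sequence[7]      # exact (sample, marker) duplicate
  lib <- suppressWarnings(merge_sample_rows(tab))
  expect_equal(length(unique(lib$sample_id)), 6)
  expect_equal(nrow(lib), 9)
  expect_false(any(duplicated(lib[, c("sample_id", "marker")])))

  # cross-marker taxonomy conflict -> flagged, majority applied
  tab2 <- toy_records(3, species = c("Pachypanchax arnoulti",
                                     "Pachypanchax arnoulti",
                                     "Pachypanchax sparksorum"))
  tab2$sample_id <- "s1"
  tab2$marker <- c("COI", "16S", "ND2")
  lib2 <- merge_sample_rows(tab2)
  expect_equal(unique(lib2$species_name), "Pachypanchax arnoulti")
  expect_true("taxonomy_conflict" %in% attr(lib2, "sample_flags")$flag)

  # same (sample, marker), different sequences -> both kept, flagged
  tab3 <- toy_records(2)
  tab3$sample_id <- "s1"
  lib3 <- merge_sample_rows(tab3)
  expect_equal(nrow(lib3), 2)
  expect_true("conflict" %in% attr(lib3, "sample_flags")$flag)
})

test_that("taxonomy updates apply transitively; cycles are fatal", {
  set.seed(14)
  lib <- barcode_library(toy_records(
    3, species = c("Tilapia rendalli", "A b", "Coptodon zillii")))
  map <- data.frame(old = c("Tilapia rendalli", "A b"),
                    new = c("Coptodon rendalli", "A c"))
  out <- suppressMessages(apply_taxonomy_updates(lib, map))
  expect_equal(out$species_name[1], "Coptodon rendalli")
  expect_equal(out$genus[1], "Coptodon")
  expect_equal(out$species_name[3], "Coptodon zillii")  # absent -> unchanged
  expect_equal(nrow(attr(out, "changes")), 2)

  # chained map applied transitively: A -> B -> C
  chain <- data.frame(old = c("A b", "A c"), new = c("A c", "A d"))
  out2 <- suppressMessages(apply_taxonomy_updates(lib, chain))
  expect_equal(out2$species_name[2], "A d")

  cyc <- data.frame(old = c("A b", "A c"), new = c("A c", "A b"))
  expect_error(apply_taxonomy_updates(lib, cyc), "cycle")
})

test_that("NUMT screen flags stop codons, passes clean frames", {
  # clean codons in frame 1
  clean <- paste(rep("ATGGCC", 20), collapse = "")
  # stops planted so that every forward frame has an internal one:
  # frame 1 TAA at codon 2, plus shifted TAGs landing in frames 2 and 3
  dirty <- paste0("ATG", "TAA", "GTAGC", "TAGG",
                  paste(rep("GCC", 15), collapse = ""))
  ambig <- paste(rep("N", 60), collapse = "")
  tab <- toy_records(3, sequence = c(clean, dirty, ambig))
  res <- numt_screen(tab)
  expect_equal(res$flag[1], "ok")
  expect_equal(res$min_stops[1], 0L)
  expect_equal(res$flag[2], "suspect")
  expect_gte(res$min_stops[2], 1L)
  expect_equal(res$flag[3], "unscreenable")

  # non-coding marker rows are ignored
  res16 <- numt_screen(toy_records(1, marker = "16S"))
  expect_true(is.na(res16$flag))

  # clean simulated library: zero flags (coding-frame-consistent output)
  sim <- simulate_library(simulation_config(seed = 7))
  expect_true(all(numt_screen(sim$library)$flag == "ok"))
})

test_that("summaries match truth; empty library gives all zeros", {
  sim <- simulate_library(simulation_config(seed = 8))
  sm <- summarize_library(sim$library)
  truth_counts <- table(sim$truth$records$species)
  expect_equal(sm$n_records, nrow(sim$truth$records))
  expect_equal(sm$n_species, length(truth_counts))
  per_family <- table(sim$library$family)
  got <- sm$by_family
  for (fam in names(per_family))
    expect_equal(got$COI[got$family == fam], unname(per_family[fam]),
                 ignore_attr = TRUE)
  expect_equal(got$COI[got$family == "Total"], nrow(sim$library),
               ignore_attr = TRUE)

  empty <- barcode_library(toy_records(0))
  sm0 <- summarize_library(empty)
  expect_equal(sm0$n_records, 0)
  expect_true(all(sm0$by_family[sm0$by_family$family == "Total",
                                c("COI", "16S", "ND2")] == 0))
})

test_that("curation is idempotent and removals account for every record", {
  set.seed(15)
  tab <- toy_records(12, accession = sprintf("A%02d", c(1, 1, 2:11)))
  tab$sequence[2] <- tab$sequence[1]          # duplicate
  tab$country[5] <- "Israel"                  # foreign
  tab$country[6] <- ""                        # unknown origin
  cur1 <- suppressMessages(curate_library(tab))
  log <- attr(cur1, "curation_log")
  expect_equal(nrow(tab) - nrow(cur1), sum(log))
  cur2 <- suppressMessages(curate_library(as.data.frame(cur1)))
  expect_equal(as.data.frame(cur2), as.data.frame(cur1),
               ignore_attr = TRUE)
  expect_equal(sum(attr(cur2, "curation_log")), 0)
})
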