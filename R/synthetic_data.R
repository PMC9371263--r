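# Seeded generator of synthetic barcode libraries with the divergence
# structure the analysis assumes: nested taxonomy (family > genus >
# species > samples), three divergence strata (intraspecific, congeneric,
# intergeneric), a reference panel of species exemplars, known site
# compositions, and switchable anomalies (a species pair sharing a
# haplotype, a deep intraspecific split, an orphan lineage distant from
# every reference). Substitution is Jukes-Cantor style: independent
# sites, per-branch change probability 0.75 * (1 - exp(-4 r / 3)) with a
# uniform choice among the other three bases, so expected p-distances
# saturate exactly as targeted and compose along paths.

#' Expected p-distance under independent-site substitution
#'
#' For a substitution load of `rate` substitutions per site, the expected
#' uncorrected p-distance with multiple hits is
#' `0.75 * (1 - exp(-4 * rate / 3))`, approaching 0.75 as rate grows.
#'
#' @param rate substitutions per site (>= 0).
#' @return expected p-distance (fraction).
#' @export
expected_p_distance <- function(rate) {
  stopifnot(all(rate >= 0))
  0.75 * (1 - exp(-4 * rate / 3))
}

#' Substitution rate needed to reach a target expected p-distance
#'
#' Inverse of [expected_p_distance()]. Targets at or above 0.75 are
#' unreachable and fatal.
#'
#' @param target expected p-distance (fraction, < 0.75).
#' @return substitutions per site.
#' @export
p_distance_rate <- function(target) {
  stopifnot(all(target >= 0))
  if (any(target >= 0.75))
    stop("expected p-distance targets >= 0.75 are unreachable")
  -0.75 * log(1 - target / 0.75)
}

#' Simulation configuration
#'
#' Defaults are the stated desk-scale world: 2 families x 2 genera x 3
#' species x 4 samples of 600 bp, with target expected p-distances of 1\%
#' within species, 6\% between congeners and 20\% between genera (the
#' three divergence strata of a mixed reference library). Anomaly
#' switches are off by default.
#'
#' @param seed integer RNG seed.
#' @param n_families,n_genera_per_family,n_species_per_genus,n_samples_per_species
#'   taxonomy shape (all >= 1).
#' @param seq_length sequence length in bp (multiple of 3 for the coding
#'   marker).
#' @param d_w,d_c,d_g target expected p-distances (fractions) for the
#'   intraspecific, congeneric and intergeneric strata;
#'   `0 <= d_w < d_c < d_g < 0.75` required.
#' @param marker marker simulated; `"COI"` keeps reading frame 1 free of
#'   vertebrate-mitochondrial stop codons at every node.
#' @param shared_haplotype_pair inject two nominal congeneric species
#'   sharing an identical haplotype (and a common ancestor sequence).
#' @param deep_split_species inject one species whose samples split into
#'   two lineages `deep_split_depth` apart.
#' @param deep_split_depth expected p-distance between the two
#'   intraspecific lineages (default 0.05).
#' @param orphan_lineage inject an unnamed lineage ("Genus sp.") at
#'   `orphan_distance` from its nearest reference.
#' @param orphan_distance expected p-distance of the orphan to the
#'   nearest panel exemplar (default 0.10).
#' @param n_orphan_samples samples of the orphan lineage (default 2).
#' @param n_sites number of collection localities; samples are spread
#'   over them round-robin.
#' @param fragment_range optional length-2 integer vector: when given,
#'   each library sequence is truncated to a uniform random length in
#'   this range (terminal truncation only, emulating fragmentary
#'   barcodes); the panel keeps full-length exemplars.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 42, n_families = 2,
                              n_genera_per_family = 2,
                              n_species_per_genus = 3,
                              n_samples_per_species = 4,
                              seq_length = 600,
                              d_w = 0.01, d_c = 0.06, d_g = 0.20,
                              marker = "COI",
                              shared_haplotype_pair = FALSE,
                              deep_split_species = FALSE,
                              deep_split_depth = 0.05,
                              orphan_lineage = FALSE,
                              orphan_distance = 0.10,
                              n_orphan_samples = 2,
                              n_sites = 5,
                              fragment_range = NULL) {
  stopifnot(n_families >= 1, n_genera_per_family >= 1,
            n_species_per_genus >= 1, n_samples_per_species >= 1,
            seq_length >= 30, n_sites >= 1)
  if (!(0 <= d_w && d_w < d_c && d_c < d_g && d_g <= 0.75))
    stop("divergence targets must satisfy 0 <= d_w < d_c < d_g <= 0.75")
  if (d_g >= 0.75) stop("d_g must be below 0.75")
  if (!marker %in% MARKERS) stop("unknown marker: ", marker)
  structure(list(seed = as.integer(seed), n_families = n_families,
                 n_genera_per_family = n_genera_per_family,
                 n_species_per_genus = n_species_per_genus,
                 n_samples_per_species = n_samples_per_species,
                 seq_length = seq_length, d_w = d_w, d_c = d_c, d_g = d_g,
                 marker = marker,
                 shared_haplotype_pair = shared_haplotype_pair,
                 deep_split_species = deep_split_species,
                 deep_split_depth = deep_split_depth,
                 orphan_lineage = orphan_lineage,
                 orphan_distance = orphan_distance,
                 n_orphan_samples = n_orphan_samples,
                 n_sites = n_sites, fragment_range = fragment_range),
            class = "simulation_config")
}

VERT_MITO_STOP_SET <- c("TAA", "TAG", "AGA", "AGG")
BASES <- c("A", "C", "G", "T")

# random sequence (character vector); coding = keep frame 1 stop-free
.sim_root <- function(len, coding) {
  s <- sample(BASES, len, replace = TRUE)
  if (coding) {
    n_cod <- len %/% 3
    for (k in seq_len(n_cod)) {
      i <- 3 * (k - 1) + 1
      while (paste(s[i:(i + 2)], collapse = "") %in% VERT_MITO_STOP_SET)
        s[i:(i + 2)] <- sample(BASES, 3, replace = TRUE)
    }
  }
  s
}

# mutate along a branch of `rate` substitutions/site. Each site changes
# with probability 0.75(1 - exp(-4 rate/3)) to a uniformly chosen other
# base; for coding sequences, choices creating a frame-1 stop codon are
# excluded (at most two of the three alternatives ever are), which keeps
# the number of changed sites -- and hence the expected p-distance --
# intact.
.sim_mutate <- function(s, rate, coding) {
  p <- 0.75 * (1 - exp(-4 * rate / 3))
  hit <- which(stats::runif(length(s)) < p)
  for (i in hit) {
    alts <- setdiff(BASES, s[i])
    if (coding) {
      k <- ((i - 1) %/% 3)
      if (k < length(s) %/% 3) {
        pos <- 3 * k + 1:3
        ok <- vapply(alts, function(b) {
          cod <- s[pos]; cod[i - 3 * k] <- b
          !paste(cod, collapse = "") %in% VERT_MITO_STOP_SET
        }, logical(1))
        alts <- alts[ok]
      }
    }
    s[i] <- if (length(alts) == 1) alts else sample(alts, 1)
  }
  s
}

#' Simulate a barcode library, reference panel and truth table
#'
#' Sequences evolve down the taxonomy: one root, one ancestor per genus,
#' per species, and per sample, with branch loads calibrated so the
#' *expected* p-distance between two samples equals `d_w` within species,
#' `d_c` between congeners and `d_g` between genera (family membership
#' only labels genera; all intergeneric pairs are exchangeable at `d_g`).
#' The panel holds each species' ancestral sequence as its exemplar, so a
#' clean sample sits about `d_w / 2` from its own exemplar. Anomalies:
#'
#' * `shared_haplotype_pair`: the first two species of genus 1 share
#'   their ancestral sequence and one sample of the second is an exact
#'   copy of the first sample of the first (a zero cross-distance).
#' * `deep_split_species`: the last species of the last genus carries an
#'   extra branch above the second half of its samples, placing the two
#'   intraspecific lineages `deep_split_depth` apart.
#' * `orphan_lineage`: an unnamed terminal taxon ("<genus> sp.")
#'   branching off genus 1's ancestor at `orphan_distance` expected
#'   p-distance from its nearest panel exemplar, absent from the panel.
#'
#' One sample per species (the first, never a deep-split or copied one)
#' plus every orphan sample is marked as an assignment query in the truth
#' table. Identical config and seed give byte-identical outputs.
#'
#' @param config a [simulation_config()].
#' @return list with `library` (a `barcode_library`), `panel` (a
#'   `reference_panel`), `truth` (list: `records` data.frame with
#'   `sample_id`, `species`, `cluster`, `anomaly`, `site`, `is_query`;
#'   `sites` data.frame of per-site species lists) and `config`.
#' @export
simulate_library <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)
  coding <- cfg$marker == "COI"
  r_w <- p_distance_rate(cfg$d_w) / 2
  r_s <- (p_distance_rate(cfg$d_c) - p_distance_rate(cfg$d_w)) / 2
  r_g <- (p_distance_rate(cfg$d_g) - p_distance_rate(cfg$d_c)) / 2
  root <- .sim_root(cfg$seq_length, coding)

  n_gen <- cfg$n_families * cfg$n_genera_per_family
  genus_names <- sprintf("Genus%02d", seq_len(n_gen))
  family_of_genus <- rep(sprintf("Family%02d", seq_len(cfg$n_families)),
                         each = cfg$n_genera_per_family)

  gen_anc <- lapply(seq_len(n_gen), function(g) .sim_mutate(root, r_g, coding))

  recs <- list(); truth <- list(); panel_sp <- c(); panel_seq <- c()
  deep_target <- if (cfg$deep_split_species)
    c(n_gen, cfg$n_species_per_genus) else c(NA, NA)
  shared_anc <- NULL
  shared_first_sample <- NULL
  sample_counter <- 0L
  site_of <- function() {
    sample_counter <<- sample_counter + 1L
    sprintf("Site%02d", 1L + (sample_counter - 1L) %% cfg$n_sites)
  }

  for (g in seq_len(n_gen)) {
    for (s in seq_len(cfg$n_species_per_genus)) {
      sp_name <- sprintf("%s species%02d", genus_names[g], s)
      if (cfg$shared_haplotype_pair && g == 1 && s == 1) {
        sp_anc <- .sim_mutate(gen_anc[[g]], r_s, coding)
        shared_anc <- sp_anc
      } else if (cfg$shared_haplotype_pair && g == 1 && s == 2) {
        sp_anc <- shared_anc      # second nominal species, same ancestor
      } else {
        sp_anc <- .sim_mutate(gen_anc[[g]], r_s, coding)
      }
      panel_sp <- c(panel_sp, sp_name)
      panel_seq <- c(panel_seq, paste(sp_anc, collapse = ""))
      is_deep_sp <- cfg$deep_split_species &&
        g == deep_target[1] && s == deep_target[2]
      deep_anc <- if (is_deep_sp)
        .sim_mutate(sp_anc,
                    p_distance_rate(cfg$deep_split_depth) -
                      p_distance_rate(cfg$d_w), coding)
      for (k in seq_len(cfg$n_samples_per_species)) {
        deep <- is_deep_sp && k > cfg$n_samples_per_species / 2
        anc <- if (deep) deep_anc else sp_anc
        seqk <- .sim_mutate(anc, r_w, coding)
        sid <- sprintf("S%04d", sample_counter + 1L)
        site <- site_of()
        anomaly <- if (deep) "deep_split" else ""
        cluster <- paste0(sp_name, if (is_deep_sp)
          paste0("/", if (deep) "B" else "A") else "")
        recs[[length(recs) + 1]] <- data.frame(
          sample_id = sid, species_name = sp_name,
          family = family_of_genus[g], marker = cfg$marker,
          sequence = paste(seqk, collapse = ""),
          environment = "F", origin_status = "native",
          country = "Madagascar", locality = site,
          latitude = NA_real_, longitude = NA_real_,
          accession = NA_character_, source = "new",
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          sample_id = sid, species = sp_name, cluster = cluster,
          anomaly = anomaly, site = site, is_query = (k == 1),
          stringsAsFactors = FALSE)
        if (cfg$shared_haplotype_pair && g == 1 && s == 1 && k == 1)
          shared_first_sample <- recs[[length(recs)]]$sequence
      }
    }
  }

  # shared haplotype: last sample of species 2 of genus 1 becomes an
  # exact copy of the first sample of species 1
  if (cfg$shared_haplotype_pair) {
    sp2 <- sprintf("%s species02", genus_names[1])
    idx <- which(vapply(recs, function(r) r$species_name, "") == sp2)
    tgt <- idx[length(idx)]
    recs[[tgt]]$sequence <- shared_first_sample
    truth[[tgt]]$anomaly <- "shared_haplotype"
    truth[[tgt]]$is_query <- FALSE
    sp1_first <- which(vapply(recs, function(r) r$species_name, "") ==
                         sprintf("%s species01", genus_names[1]))[1]
    truth[[sp1_first]]$anomaly <- "shared_haplotype"
  }

  # orphan lineage off genus 1's ancestor, absent from the panel
  if (cfg$orphan_lineage) {
    r_o <- p_distance_rate(cfg$orphan_distance) - r_s
    if (r_o <= 0)
      stop("orphan_distance too small for the configured strata")
    orphan_anc <- .sim_mutate(gen_anc[[1]], r_o, coding)
    orphan_name <- paste(genus_names[1], "sp.")
    for (k in seq_len(cfg$n_orphan_samples)) {
      seqk <- .sim_mutate(orphan_anc, r_w, coding)
      sid <- sprintf("S%04d", sample_counter + 1L)
      site <- site_of()
      recs[[length(recs) + 1]] <- data.frame(
        sample_id = sid, species_name = orphan_name,
        family = family_of_genus[1], marker = cfg$marker,
        sequence = paste(seqk, collapse = ""),
        environment = "F", origin_status = "introduced",
        country = "Madagascar", locality = site,
        latitude = NA_real_, longitude = NA_real_,
        accession = NA_character_, source = "new",
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1]] <- data.frame(
        sample_id = sid, species = orphan_name, cluster = orphan_name,
        anomaly = "orphan", site = site, is_query = TRUE,
        stringsAsFactors = FALSE)
    }
  }

  lib <- do.call(rbind, recs)
  # optional terminal truncation to fragment lengths
  if (!is.null(cfg$fragment_range)) {
    lo <- cfg$fragment_range[1]; hi <- min(cfg$fragment_range[2],
                                           cfg$seq_length)
    for (i in seq_len(nrow(lib))) {
      L <- sample(lo:hi, 1)
      start <- sample(seq_len(cfg$seq_length - L + 1), 1)
      lib$sequence[i] <- substr(lib$sequence[i], start, start + L - 1)
    }
  }
  truth_rec <- do.call(rbind, truth)
  site_tab <- lapply(split(truth_rec$species, truth_rec$site),
                     function(x) sort(unique(x)))
  truth_sites <- data.frame(site = names(site_tab),
                            n_species = vapply(site_tab, length, 1L),
                            species = vapply(site_tab, paste, "",
                                             collapse = "; "),
                            row.names = NULL, stringsAsFactors = FALSE)
  list(library = barcode_library(lib),
       panel = reference_panel(panel_sp, panel_seq,
                               accession = sprintf("SIM%04d",
                                                   seq_along(panel_sp)),
                               marker = cfg$marker),
       truth = list(records = truth_rec, sites = truth_sites),
       config = cfg)
}

#' Write simulation outputs to a directory
#'
#' Emits the same plain-text formats the readers consume: the library
#' TSV, a per-marker FASTA, the panel FASTA and the truth tables.
#'
#' @param sim result of [simulate_library()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_library_table(sim$library, file.path(dir, "library.tsv"))
  write_fasta(sim$library, sim$config$marker,
              file.path(dir, paste0(tolower(sim$config$marker), ".fasta")))
  set <- Biostrings::BStringSet(sim$panel$sequence)
  names(set) <- paste(gsub(" ", "_", sim$panel$species_name),
                      sim$panel$accession, sep = "|")
  Biostrings::writeXStringSet(set, file.path(dir, "panel.fasta"), width = 80)
  write.table(sim$truth$records, file.path(dir, "truth_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
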