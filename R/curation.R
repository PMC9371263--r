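# Curation of the raw record table: duplicate removal, target-fragment
# filtering against marker anchors, geographic filtering, per-sample row
# merging, taxonomy updates, and the NUMT screen for the coding marker.

#' Remove duplicate records
#'
#' Records identical in `(accession, marker, sequence)` are reduced to one
#' (first occurrence kept). Identical sequences from distinct samples with
#' different/absent accessions are *not* duplicates: shared haplotypes are
#' biological signal.
#'
#' @param records record data.frame (library columns).
#' @return deduplicated records; removal count in `attr(, "removed")`.
#' @export
deduplicate <- function(records) {
  key <- paste(ifelse(is.na(records$accession), paste0("\r", seq_len(nrow(records))),
                      records$accession),
               records$marker, records$sequence, sep = "\t")
  keep <- !duplicated(key)
  removed <- sum(!keep)
  if (removed) message(removed, " duplicate record(s) removed")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Filter records to those matching the target fragments
#'
#' A record is retained iff its best free-end-gap alignment to its marker's
#' anchor (one exemplar sequence per marker) covers at least `min_overlap`
#' comparable positions at identity of at least `min_identity`. Genuine
#' short fragments (a few hundred bp) pass; foreign or random sequences
#' (expected identity about 0.25) do not.
#'
#' @param records record data.frame.
#' @param anchors named character vector: marker id to exemplar sequence.
#' @param min_overlap minimum compared sites (default 150 bp).
#' @param min_identity minimum fraction identical (default 0.60).
#' @return retained records; removals logged, counts in `attr(, "removed")`.
#' @export
filter_target_fragment <- function(records, anchors, min_overlap = 150,
                                   min_identity = 0.60) {
  if (!nrow(records)) return(records)
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    mk <- records$marker[i]
    if (!mk %in% names(anchors)) {
      warning("no anchor for marker ", mk, "; record ",
              records$sample_id[i], " retained unchecked")
      keep[i] <- TRUE
      next
    }
    aln <- pairwise_align(gsub("-", "", records$sequence[i]),
                          gsub("-", "", anchors[[mk]]))
    pd <- p_distance(aln$aligned_a, aln$aligned_b)
    keep[i] <- !is.na(pd$distance) && pd$sites >= min_overlap &&
      (1 - pd$distance) >= min_identity
  }
  removed <- sum(!keep)
  if (removed)
    message(removed, " record(s) removed: not matching target fragment")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Filter records by country of origin
#'
#' Case-insensitive prefix match on the country field (so
#' `"Madagascar: Nosy Be"` matches `"Madagascar"`). Records with an empty
#' country are removed and logged separately as unknown origin. Records
#' whitelisted as reference-panel members are kept regardless (the panel
#' deliberately contains non-target-country exemplars) but are excluded
#' from library statistics by their callers.
#'
#' @param records record data.frame.
#' @param country target country (default `"Madagascar"`).
#' @param whitelist character vector of `sample_id`s exempt from the filter.
#' @return retained records; `attr(, "removed_foreign")` and
#'   `attr(, "removed_unknown")` carry the removal counts.
#' @export
filter_geography <- function(records, country = "Madagascar",
                             whitelist = character(0)) {
  ctry <- trimws(ifelse(is.na(records$country), "", records$country))
  unknown <- !nzchar(ctry)
  match <- startsWith(tolower(ctry), tolower(country))
  keep <- (match & !unknown) | records$sample_id %in% whitelist
  n_unknown <- sum(unknown & !keep)
  n_foreign <- sum(!keep) - n_unknown
  if (n_unknown) message(n_unknown, " record(s) removed: unknown origin")
  if (n_foreign) message(n_foreign, " record(s) removed: foreign origin")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_foreign") <- n_foreign
  attr(out, "removed_unknown") <- n_unknown
  out
}

#' Merge rows belonging to the same sample
#'
#' Links records sharing a `sample_id` under one sample entry and enforces
#' uniqueness per `(sample_id, marker)`: later exact duplicates are dropped
#' with a warning; the same `(sample_id, marker)` with *different*
#' sequences keeps both rows and flags the sample `"conflict"`.
#' Conflicting taxonomy across a sample's markers is flagged and resolved
#' to the majority label (ties: first label in input order).
#'
#' @param records deduplicated record data.frame.
#' @return a `barcode_library`; per-sample flags in `attr(, "sample_flags")`
#'   (data.frame sample_id/flag).
#' @export
merge_sample_rows <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  flags <- list()
  drop <- logical(nrow(records))
  for (sid in unique(records$sample_id)) {
    idx <- which(records$sample_id == sid)
    # taxonomy consensus across the sample's markers
    sp <- records$species_name[idx]
    if (length(unique(sp)) > 1) {
      tab <- table(factor(sp, levels = unique(sp)))  # ties -> input order
      major <- names(tab)[which.max(tab)]
      records$species_name[idx] <- major
      records$genus[idx] <- genus_of(major)
      flags[[length(flags) + 1]] <-
        data.frame(sample_id = sid, flag = "taxonomy_conflict",
                   stringsAsFactors = FALSE)
    }
    # per (sample, marker) uniqueness
    for (mk in unique(records$marker[idx])) {
      midx <- idx[records$marker[idx] == mk]
      if (length(midx) > 1) {
        seqs <- records$sequence[midx]
        if (length(unique(seqs)) == 1) {
          drop[midx[-1]] <- TRUE
          warning("duplicate (", sid, ", ", mk, ") rows; later copies dropped")
        } else {
          flags[[length(flags) + 1]] <-
            data.frame(sample_id = sid, flag = "conflict",
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- barcode_library(records[!drop, , drop = FALSE])
  attr(out, "sample_flags") <-
    if (length(flags)) unique(do.call(rbind, flags))
    else data.frame(sample_id = character(0), flag = character(0))
  out
}

#' Apply taxonomy updates from a synonym map
#'
#' Rewrites species names through `old -> new` pairs, applied transitively
#' (a chained map A->B, B->C renames A to C). The genus is re-derived and a
#' change log returned. A cycle in the map is a fatal error.
#'
#' @param library a `barcode_library`.
#' @param synonym_map either a two-column data.frame (`old`, `new`) or a
#'   path to a two-column TSV without header.
#' @return updated `barcode_library`; change log in `attr(, "changes")`.
#' @export
apply_taxonomy_updates <- function(library, synonym_map) {
  if (is.character(synonym_map) && length(synonym_map) == 1) {
    synonym_map <- read.delim(synonym_map, header = FALSE, sep = "\t",
                              colClasses = "character")
  }
  stopifnot(ncol(synonym_map) >= 2)
  old <- normalize_species_name(synonym_map[[1]])
  new <- normalize_species_name(synonym_map[[2]])
  # transitive closure with cycle detection
  resolve <- function(name) {
    seen <- character(0)
    while (name %in% old) {
      if (name %in% seen) stop("cycle in synonym map at '", name, "'")
      seen <- c(seen, name)
      name <- new[match(name, old)]
    }
    name
  }
  target <- vapply(unique(old), resolve, character(1))
  cur <- library$species_name
  hit <- cur %in% names(target)
  changes <- data.frame(sample_id = library$sample_id[hit],
                        marker = library$marker[hit],
                        old = cur[hit],
                        new = unname(target[cur[hit]]),
                        stringsAsFactors = FALSE)
  library$species_name[hit] <- unname(target[cur[hit]])
  library$genus <- genus_of(library$species_name)
  if (nrow(changes))
    message(nrow(changes), " record(s) renamed by taxonomy update")
  attr(library, "changes") <- changes
  library
}

# Vertebrate mitochondrial stop codons (forward strand).
VERT_MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Screen coding-marker records for nuclear pseudogenes (NUMTs)
#'
#' For each COI record the forward reading frame (of three) minimizing
#' internal stop codons under the vertebrate mitochondrial code is chosen;
#' the record is flagged `"suspect"` if the best frame still contains one
#' or more internal stops (frameshift or pseudogene signal). Records with
#' more than 20\% ambiguity codes are flagged `"unscreenable"`.
#'
#' @param records record data.frame; non-COI records are ignored (flag
#'   `NA`).
#' @param marker coding marker screened (default `"COI"`).
#' @return data.frame: `sample_id`, `marker`, `flag` in
#'   `{"ok", "suspect", "unscreenable", NA}`, `best_frame`, `min_stops`.
#' @export
numt_screen <- function(records, marker = "COI") {
  res <- data.frame(sample_id = records$sample_id, marker = records$marker,
                    flag = NA_character_, best_frame = NA_integer_,
                    min_stops = NA_integer_, stringsAsFactors = FALSE)
  idx <- which(records$marker == marker)
  for (i in idx) {
    s <- gsub("-", "", records$sequence[i])
    chars <- strsplit(s, "")[[1]]
    if (mean(!chars %in% c("A", "C", "G", "T")) > 0.20) {
      res$flag[i] <- "unscreenable"
      next
    }
    stops <- vapply(0:2, function(off) {
      n_cod <- (nchar(s) - off) %/% 3
      if (n_cod < 2) return(0L)
      cods <- substring(s, off + 1 + 3 * (0:(n_cod - 1)),
                        off + 3 * (1:n_cod))
      sum(cods[-length(cods)] %in% VERT_MITO_STOPS)  # internal only
    }, integer(1))
    res$min_stops[i] <- min(stops)
    res$best_frame[i] <- which.min(stops)
    res$flag[i] <- if (min(stops) >= 1) "suspect" else "ok"
  }
  res
}

#' Summarize a library by family, marker, environment and origin
#'
#' Produces the reference-library tally: counts per family per marker
#' (wide), a totals row, and environment / origin-status tallies.
#'
#' @param library a `barcode_library` (possibly empty).
#' @return list with `by_family` (family x marker counts + Total),
#'   `by_environment`, `by_origin`, `n_records`, `n_species`, `n_families`.
#' @export
summarize_library <- function(library) {
  lib <- as.data.frame(library)
  mk <- factor(lib$marker, levels = MARKERS)
  fam <- if (nrow(lib)) lib$family else character(0)
  tab <- as.data.frame.matrix(table(factor(fam), mk))
  tab <- tab[order(rownames(tab)), , drop = FALSE]
  by_family <- data.frame(family = rownames(tab), tab, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  total <- data.frame(family = "Total",
                      as.list(colSums(tab[, MARKERS, drop = FALSE])),
                      check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(by_family))
    by_family <- data.frame(family = character(0),
                            setNames(rep(list(integer(0)), 3), MARKERS),
                            check.names = FALSE)
  by_family <- rbind(by_family, total)
  list(by_family = by_family,
       by_environment = table(factor(lib$environment, levels = ENVIRONMENTS)),
       by_origin = table(factor(lib$origin_status, levels = ORIGINS)),
       n_records = nrow(lib),
       n_species = length(unique(lib$species_name)),
       n_families = length(unique(lib$family)))
}

#' Run the full curation chain
#'
#' Deduplication, optional target-fragment filter, geographic filter, and
#' per-sample merging, in that order; optionally followed by taxonomy
#' updates. The chain is idempotent.
#'
#' @param records raw record data.frame (or `barcode_library`).
#' @param anchors optional named anchor sequences for
#'   [filter_target_fragment()]; `NULL` skips the fragment filter.
#' @param country target country for [filter_geography()]; `NULL` skips.
#' @param whitelist reference-panel `sample_id`s exempt from the
#'   geography filter.
#' @param synonym_map optional synonym map for [apply_taxonomy_updates()].
#' @param min_overlap,min_identity fragment-filter parameters.
#' @return curated `barcode_library`; removal counts in
#'   `attr(, "curation_log")`.
#' @export
curate_library <- function(records, anchors = NULL, country = "Madagascar",
                           whitelist = character(0), synonym_map = NULL,
                           min_overlap = 150, min_identity = 0.60) {
  n0 <- nrow(records)
  r <- deduplicate(records)
  log <- c(duplicates = attr(r, "removed"))
  if (!is.null(anchors)) {
    r <- filter_target_fragment(r, anchors, min_overlap, min_identity)
    log <- c(log, fragment = attr(r, "removed"))
  }
  if (!is.null(country)) {
    r <- filter_geography(r, country, whitelist)
    log <- c(log, foreign = attr(r, "removed_foreign"),
             unknown_origin = attr(r, "removed_unknown"))
  }
  lib <- merge_sample_rows(r)
  log <- c(log, merged_duplicates = n0 - sum(log) - nrow(lib))
  if (!is.null(synonym_map)) lib <- apply_taxonomy_updates(lib, synonym_map)
  attr(lib, "curation_log") <- log
  lib
}
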