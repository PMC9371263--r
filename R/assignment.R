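# Threshold-based species assignment against a reference panel, with
# cross-marker label transfer inside samples and per-locality syntopy
# reports (the procedure used to identify introduced tilapia lineages
# through their ND2 sequences).

#' Construct a reference panel
#'
#' Reliably identified sequences of a single marker used to assign
#' unknowns. Species may repeat (multiple exemplars per species).
#'
#' @param species_name character vector of species labels.
#' @param sequence character vector of sequences.
#' @param accession optional accessions.
#' @param marker the panel's marker.
#' @return object of class `reference_panel` (a data.frame).
#' @export
reference_panel <- function(species_name, sequence, accession = NA_character_,
                            marker = "ND2") {
  stopifnot(length(species_name) >= 1,
            length(species_name) == length(sequence))
  if (!marker %in% MARKERS) stop("unknown marker: ", marker)
  out <- data.frame(species_name = normalize_species_name(species_name),
                    marker = marker,
                    sequence = clean_sequence(sequence),
                    accession = rep_len(as.character(accession),
                                        length(sequence)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$sequence)) stop("invalid sequence in panel")
  class(out) <- c("reference_panel", "data.frame")
  out
}

#' Read a reference panel from FASTA or TSV
#'
#' FASTA headers are `species|accession` (underscores become spaces in the
#' species name); TSV needs columns `species_name`, `sequence` and
#' optionally `accession`.
#'
#' @param path input path.
#' @param marker the panel marker.
#' @param format `"fasta"` or `"tsv"` (guessed from the extension by
#'   default).
#' @return a `reference_panel`.
#' @export
read_panel <- function(path, marker = "ND2",
                       format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|fas)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  if (format == "fasta") {
    fa <- read_fasta(path)
    parts <- strsplit(fa$id, "|", fixed = TRUE)
    reference_panel(
      species_name = gsub("_", " ", vapply(parts, `[`, "", 1)),
      sequence = fa$sequence,
      accession = vapply(parts, function(p) if (length(p) > 1) p[2]
                         else NA_character_, ""),
      marker = marker)
  } else {
    tab <- read.delim(path, colClasses = "character")
    reference_panel(tab$species_name, tab$sequence,
                    if ("accession" %in% names(tab)) tab$accession
                    else NA_character_, marker)
  }
}

#' Rank panel species by identity to a query
#'
#' The query is aligned (free end gaps, strand-normalized) to every panel
#' exemplar; identity is `100 * (1 - p_distance)` under pairwise deletion.
#' Per species the maximum identity over its exemplars is kept
#' (best-close-match convention) and species are ranked by descending
#' identity, ties broken alphabetically.
#'
#' @param query ungapped query sequence.
#' @param panel a `reference_panel`.
#' @param min_sites overlap below which a comparison is discarded
#'   (default 100 bp).
#' @return data.frame ranked by identity: `species`, `identity_pct`,
#'   `best_accession`, `sites`; zero rows when the query is unalignable
#'   against every exemplar.
#' @export
best_match <- function(query, panel, min_sites = 100) {
  query <- gsub("-", "", toupper(query))
  res <- lapply(seq_len(nrow(panel)), function(i) {
    ref <- gsub("-", "", panel$sequence[i])
    q <- if (nchar(query) <= nchar(ref)) orient_strand(query, ref) else query
    r <- if (nchar(ref) < nchar(query)) orient_strand(ref, query) else ref
    aln <- pairwise_align(q, r)
    pd <- p_distance(aln$aligned_a, aln$aligned_b)
    data.frame(species = panel$species_name[i],
               identity_pct = if (is.na(pd$distance) || pd$sites < min_sites)
                 NA_real_ else 100 * (1 - pd$distance),
               accession = panel$accession[i],
               sites = pd$sites, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[!is.na(res$identity_pct), , drop = FALSE]
  if (!nrow(res))
    return(data.frame(species = character(0), identity_pct = numeric(0),
                      best_accession = character(0), sites = integer(0)))
  by_sp <- lapply(split(res, res$species), function(g) {
    g[which.max(g$identity_pct), , drop = FALSE]
  })
  out <- do.call(rbind, by_sp)
  out <- out[order(-out$identity_pct, out$species), , drop = FALSE]
  data.frame(species = out$species, identity_pct = out$identity_pct,
             best_accession = out$accession, sites = out$sites,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign a query to a species by identity thresholds
#'
#' Calls: best identity at or above `assign_thr` is `"assigned"`; in
#' `[cf_thr, assign_thr)` it is `"cf"` (distance-band usage of the open
#' nomenclature); below `cf_thr` it is `"undetermined"`. If the two top
#' species lie within 0.5 identity points of each other the call is
#' `"ambiguous"`.
#'
#' @param query ungapped query sequence.
#' @param panel a `reference_panel`.
#' @param assign_thr identity (\%) for a firm assignment (default 99.0).
#' @param cf_thr identity (\%) for a tentative "cf." call (default 97.5).
#' @param ambiguity_band top-two identity separation (\%) below which the
#'   call is ambiguous (default 0.5).
#' @param min_sites passed to [best_match()].
#' @return list of class `assignment_result`: `best_species`,
#'   `best_identity_pct`, `margin_pct` (to the second-best species; `NA`
#'   with a single panel species), `call`, `ranking`.
#' @export
assign_species <- function(query, panel, assign_thr = 99.0, cf_thr = 97.5,
                           ambiguity_band = 0.5, min_sites = 100) {
  rk <- best_match(query, panel, min_sites = min_sites)
  if (!nrow(rk))
    return(structure(list(best_species = NA_character_,
                          best_identity_pct = NA_real_, margin_pct = NA_real_,
                          call = "unalignable", ranking = rk),
                     class = "assignment_result"))
  best <- rk$identity_pct[1]
  margin <- if (nrow(rk) > 1) best - rk$identity_pct[2] else NA_real_
  call <- if (best >= assign_thr) "assigned"
          else if (best >= cf_thr) "cf"
          else "undetermined"
  if (!is.na(margin) && margin < ambiguity_band && best >= cf_thr)
    call <- "ambiguous"
  structure(list(best_species = rk$species[1], best_identity_pct = best,
                 margin_pct = margin, call = call, ranking = rk),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment: %s (%.1f%%, margin %s) -> %s\n",
              x$best_species, x$best_identity_pct,
              ifelse(is.na(x$margin_pct), "NA",
                     sprintf("%.1f%%", x$margin_pct)), x$call))
  invisible(x)
}

#' Assign a set of queries against a panel
#'
#' @param queries data.frame with `sample_id` and `sequence` columns (e.g.
#'   the panel-marker records of a library).
#' @param panel a `reference_panel`.
#' @param ... passed to [assign_species()].
#' @return data.frame: `sample_id`, `best_species`, `best_identity_pct`,
#'   `margin_pct`, `call`.
#' @export
assign_queries <- function(queries, panel, ...) {
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    a <- assign_species(queries$sequence[i], panel, ...)
    data.frame(sample_id = queries$sample_id[i],
               best_species = a$best_species,
               best_identity_pct = a$best_identity_pct,
               margin_pct = a$margin_pct, call = a$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Propagate assigned species labels across markers of a sample
#'
#' Records of other markers belonging to a sample whose panel-marker
#' sequence was `"assigned"` inherit the assigned label with provenance
#' `"transferred"`. Conflicts (an existing different label) are flagged,
#' never overwritten. Samples whose assignment is `"undetermined"` get the
#' open-nomenclature label `"<Genus> sp."` with a lineage tag.
#'
#' @param library a `barcode_library`.
#' @param assignments data.frame from [assign_queries()], keyed by
#'   `sample_id`.
#' @param unlabeled species names treated as absent labels (default
#'   `c("", NA)`); other existing labels conflict unless equal.
#' @return the library with updated labels; `provenance` column added
#'   (`"original"` / `"transferred"` / `"lineage_tag"`), conflicts in
#'   `attr(, "conflicts")`.
#' @export
transfer_assignments <- function(library, assignments,
                                 unlabeled = c("", NA_character_)) {
  lib <- as.data.frame(library)
  lib$provenance <- "original"
  conflicts <- list()
  for (k in seq_len(nrow(assignments))) {
    sid <- assignments$sample_id[k]
    call <- assignments$call[k]
    idx <- which(lib$sample_id == sid)
    if (!length(idx)) next
    if (call == "assigned") {
      label <- assignments$best_species[k]
    } else if (call == "undetermined") {
      g <- genus_of(assignments$best_species[k])
      label <- paste(g, "sp.")
    } else next
    for (i in idx) {
      cur <- lib$species_name[i]
      if (cur %in% unlabeled || is.na(cur)) {
        lib$species_name[i] <- label
        lib$provenance[i] <- if (call == "assigned") "transferred"
                             else "lineage_tag"
      } else if (cur != label) {
        conflicts[[length(conflicts) + 1]] <-
          data.frame(sample_id = sid, marker = lib$marker[i],
                     existing = cur, proposed = label,
                     stringsAsFactors = FALSE)
      }
    }
  }
  lib$genus <- genus_of(lib$species_name)
  out <- barcode_library(lib[, record_columns()])
  out$provenance <- lib$provenance
  attr(out, "conflicts") <-
    if (length(conflicts)) do.call(rbind, conflicts)
    else data.frame(sample_id = character(0), marker = character(0),
                    existing = character(0), proposed = character(0))
  out
}

#' Per-locality co-occurrence (syntopy) report
#'
#' Localities are keyed by name, or by coordinates rounded to three
#' decimals when the name is absent; records with neither are pooled under
#' `"unlocalized"`. Species lists per locality are sorted; the maximum
#' co-occurrence count is reported.
#'
#' @param library a `barcode_library` (labels already assigned or
#'   transferred).
#' @param assignments optional [assign_queries()] table: when given, the
#'   assigned/lineage labels replace the library labels for the matching
#'   samples.
#' @return list with `sites` (data.frame: `locality`, `n_species`,
#'   `species` semicolon-joined) and `max_cooccurrence`.
#' @export
syntopy_report <- function(library, assignments = NULL) {
  lib <- as.data.frame(library)
  if (!is.null(assignments)) {
    for (k in seq_len(nrow(assignments))) {
      idx <- which(lib$sample_id == assignments$sample_id[k])
      if (assignments$call[k] == "assigned")
        lib$species_name[idx] <- assignments$best_species[k]
      else if (assignments$call[k] == "undetermined")
        lib$species_name[idx] <-
          paste(genus_of(assignments$best_species[k]), "sp.")
    }
  }
  key <- ifelse(nzchar(trimws(lib$locality)), trimws(lib$locality),
                ifelse(!is.na(lib$latitude) & !is.na(lib$longitude),
                       sprintf("%.3f,%.3f", lib$latitude, lib$longitude),
                       "unlocalized"))
  sites <- lapply(split(lib$species_name, key), function(sp)
    sort(unique(sp)))
  out <- data.frame(locality = names(sites),
                    n_species = vapply(sites, length, integer(1)),
                    species = vapply(sites, paste, "", collapse = "; "),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_species, out$locality), , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out,
       max_cooccurrence = if (nrow(out)) max(out$n_species) else 0L)
}
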