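# Taxonomy-partitioned distance summaries, per-species barcode-gap
# statistics, and anomaly flags: deep intraspecific lineages (single
# linkage) and zero-distance species pairs.

PAIR_CLASSES <- c("intraspecific", "congeneric_interspecific", "intergeneric")

#' Classify a pair of records by taxonomy
#'
#' Same species name: intraspecific. Same genus, different species:
#' congeneric interspecific. Different genus (across families included):
#' intergeneric. Open-nomenclature taxa ("Oreochromis sp.") are distinct
#' species-level terminals.
#'
#' @param species_a,species_b species names.
#' @return one of `"intraspecific"`, `"congeneric_interspecific"`,
#'   `"intergeneric"` (vectorized).
#' @export
classify_pair <- function(species_a, species_b) {
  sa <- normalize_species_name(species_a)
  sb <- normalize_species_name(species_b)
  ifelse(sa == sb, "intraspecific",
         ifelse(genus_of(sa) == genus_of(sb),
                "congeneric_interspecific", "intergeneric"))
}

# Helper: align library rows to matrix ids; returns the subset data.frame
# in matrix order, or errors when inconsistent.
.match_library <- function(dm, library, exclude = character(0)) {
  lib <- as.data.frame(library)
  key <- make.unique(lib$sample_id[lib$marker == dm$marker])
  sel <- lib[lib$marker == dm$marker, , drop = FALSE]
  sel$.id <- key
  if (!all(dm$ids %in% sel$.id))
    stop("distance matrix ids not all present in library")
  sel <- sel[match(dm$ids, sel$.id), , drop = FALSE]
  keep <- !sel$.id %in% exclude & !sel$sample_id %in% exclude
  list(lib = sel[keep, , drop = FALSE],
       d = dm$d[keep, keep, drop = FALSE])
}

#' Partitioned distance summary
#'
#' Summaries (pair count, mean, min, max, as percentages) per pair class
#' over the unmasked pairs passing an optional subset filter.
#'
#' @param dm a `barcode_dist`.
#' @param library the `barcode_library` the matrix was computed from.
#' @param subset optional predicate taking the per-record data.frame and
#'   returning a logical vector (e.g.
#'   `function(x) x$origin_status == "native" & x$environment == "F"`).
#' @param exclude character vector of record/sample ids removed before
#'   partitioning (e.g. known introgressed specimens).
#' @param label descriptor stored with the summary.
#' @return data.frame, one row per class: `class`, `n_pairs`, `mean_pct`,
#'   `min_pct`, `max_pct` (stats `NA` for empty classes); the descriptor in
#'   `attr(, "subset")`.
#' @export
partition_summary <- function(dm, library, subset = NULL,
                              exclude = character(0), label = "all") {
  m <- .match_library(dm, library, exclude)
  lib <- m$lib; d <- m$d
  if (!is.null(subset)) {
    keep <- subset(lib)
    keep[is.na(keep)] <- FALSE
    lib <- lib[keep, , drop = FALSE]
    d <- d[keep, keep, drop = FALSE]
  }
  n <- nrow(lib)
  ut <- upper.tri(d)
  cls <- matrix("", n, n)
  if (n >= 2) {
    for (i in seq_len(n - 1))
      cls[i, (i + 1):n] <- classify_pair(lib$species_name[i],
                                         lib$species_name[(i + 1):n])
  }
  out <- lapply(PAIR_CLASSES, function(cl) {
    v <- d[ut & cls == cl]
    v <- v[!is.na(v)]
    if (!length(v))
      data.frame(class = cl, n_pairs = 0L, mean_pct = NA_real_,
                 min_pct = NA_real_, max_pct = NA_real_)
    else
      data.frame(class = cl, n_pairs = length(v),
                 mean_pct = round(100 * mean(v), 1),
                 min_pct = round(100 * min(v), 1),
                 max_pct = round(100 * max(v), 1))
  })
  res <- do.call(rbind, out)
  attr(res, "subset") <- label
  res
}

#' Per-species barcode-gap table
#'
#' For every species: the maximum intraspecific distance (masked for
#' singletons), the minimum distance to the nearest non-conspecific, and
#' the gap flag (`TRUE` iff `min_inter > max_intra`; `FALSE` when
#' `min_inter <= max_intra` or `min_inter` is 0; `NA` (indeterminate) for
#' singletons).
#'
#' @inheritParams partition_summary
#' @return data.frame: `species`, `n_records`, `max_intra_pct`,
#'   `min_inter_pct`, `nearest_species`, `gap`.
#' @export
barcode_gap_per_species <- function(dm, library, exclude = character(0)) {
  m <- .match_library(dm, library, exclude)
  lib <- m$lib; d <- m$d
  species <- sort(unique(lib$species_name))
  if (length(species) < 2) stop("need at least 2 species")
  rows <- lapply(species, function(sp) {
    own <- which(lib$species_name == sp)
    oth <- which(lib$species_name != sp)
    intra <- d[own, own, drop = FALSE][upper.tri(diag(length(own)))]
    max_intra <- if (length(own) < 2 || all(is.na(intra))) NA_real_
                 else max(intra, na.rm = TRUE)
    inter <- d[own, oth, drop = FALSE]
    min_inter <- suppressWarnings(min(inter, na.rm = TRUE))
    if (!is.finite(min_inter)) min_inter <- NA_real_
    nearest <- if (is.na(min_inter)) NA_character_ else {
      w <- which(inter == min_inter, arr.ind = TRUE)[1, ]
      lib$species_name[oth[w[2]]]
    }
    gap <- if (is.na(max_intra) || is.na(min_inter)) NA
           else (min_inter > max_intra) && min_inter > 0
    data.frame(species = sp, n_records = length(own),
               max_intra_pct = round(100 * max_intra, 1),
               min_inter_pct = round(100 * min_inter, 1),
               nearest_species = nearest, gap = gap,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# single-linkage clusters of a distance sub-matrix at a cutoff
.single_linkage <- function(d, cutoff) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && !is.na(d[i, j]) && d[i, j] <= cutoff &&
          comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Flag species with deep intraspecific lineages
#'
#' Within each species, single-linkage clustering of its records at the
#' threshold; species splitting into two or more clusters are flagged,
#' with cluster membership and the minimum between-cluster distance. To
#' guard against the degenerate regime where every haplotype becomes its
#' own cluster, thresholds below `min_threshold` suppress flagging.
#'
#' @inheritParams partition_summary
#' @param threshold single-linkage cutoff as a fraction (default 0.03,
#'   i.e. 3\%).
#' @param min_threshold smallest meaningful cutoff (default 0.005); below
#'   it no species is flagged.
#' @return data.frame of flagged species: `species`, `n_clusters`,
#'   `min_between_pct`; cluster membership in `attr(, "clusters")` (named
#'   list: record ids -> cluster index).
#' @export
deep_lineage_flags <- function(dm, library, threshold = 0.03,
                               exclude = character(0), min_threshold = 0.005) {
  m <- .match_library(dm, library, exclude)
  lib <- m$lib; d <- m$d
  flagged <- list(); clusters <- list()
  if (threshold >= min_threshold) {
    for (sp in unique(lib$species_name)) {
      own <- which(lib$species_name == sp)
      if (length(own) < 2) next
      sub <- d[own, own, drop = FALSE]
      cl <- .single_linkage(sub, threshold)
      if (max(cl) >= 2) {
        between <- Inf
        for (a in seq_along(own)) for (b in seq_along(own))
          if (cl[a] != cl[b] && !is.na(sub[a, b]))
            between <- min(between, sub[a, b])
        flagged[[length(flagged) + 1]] <-
          data.frame(species = sp, n_clusters = max(cl),
                     min_between_pct = round(100 * between, 1),
                     stringsAsFactors = FALSE)
        clusters[[sp]] <- setNames(cl, lib$.id[own])
      }
    }
  }
  res <- if (length(flagged)) do.call(rbind, flagged)
         else data.frame(species = character(0), n_clusters = integer(0),
                         min_between_pct = numeric(0))
  attr(res, "clusters") <- clusters
  res
}

#' Species pairs sharing identical haplotypes
#'
#' Unordered pairs of distinct species with at least one zero-distance
#' cross-pair, with the count of such record pairs. An exclusion list of
#' record ids is applied first.
#'
#' @inheritParams partition_summary
#' @return data.frame: `species_a`, `species_b`, `n_zero_pairs`.
#' @export
zero_distance_species_pairs <- function(dm, library, exclude = character(0)) {
  m <- .match_library(dm, library, exclude)
  lib <- m$lib; d <- m$d
  hits <- list()
  n <- nrow(lib)
  if (n >= 2) {
    zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
    if (nrow(zero)) {
      sa <- lib$species_name[zero[, 1]]
      sb <- lib$species_name[zero[, 2]]
      diff <- sa != sb
      if (any(diff)) {
        key <- apply(cbind(pmin(sa[diff], sb[diff]),
                           pmax(sa[diff], sb[diff])), 1, paste,
                     collapse = "\t")
        tab <- table(key)
        parts <- strsplit(names(tab), "\t", fixed = TRUE)
        hits <- data.frame(
          species_a = vapply(parts, `[`, "", 1),
          species_b = vapply(parts, `[`, "", 2),
          n_zero_pairs = as.integer(tab), stringsAsFactors = FALSE)
        rownames(hits) <- NULL
        return(hits)
      }
    }
  }
  data.frame(species_a = character(0), species_b = character(0),
             n_zero_pairs = integer(0))
}
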