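#' @useDynLib barcodelib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# Closed marker set and controlled vocabularies used across the package.
MARKERS <- c("COI", "16S", "ND2")
ENVIRONMENTS <- c("F", "FF", "MF", "M")
ORIGINS <- c("native", "introduced")
SOURCES <- c("genbank", "bold", "new")

# IUPAC nucleotide codes plus gap; sequences are stored uppercase, U -> T.
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

record_columns <- function() {
  c("sample_id", "species_name", "genus", "family", "marker", "sequence",
    "environment", "origin_status", "country", "locality",
    "latitude", "longitude", "accession", "source")
}

#' Normalize a species name
#'
#' Collapses repeated whitespace and trims. Open-nomenclature qualifiers
#' ("cf.", "sp.", "aff.") are preserved: a name such as `"Oreochromis sp."`
#' is a distinct species-level terminal taxon throughout the package.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  x
}

#' Derive the genus from a species name
#'
#' The genus is the first whitespace-separated token of the (normalized)
#' species name.
#'
#' @param species_name character vector.
#' @return character vector of genus names.
#' @export
genus_of <- function(species_name) {
  sub("\\s.*$", "", normalize_species_name(species_name))
}

# Clean a sequence string: uppercase, U -> T; returns NA when characters
# outside the IUPAC+gap alphabet remain.
clean_sequence <- function(seq) {
  s <- chartr("u", "T", toupper(as.character(seq)))
  s <- chartr("U", "T", s)
  bad <- vapply(strsplit(s, ""), function(ch) any(!ch %in% IUPAC_CHARS),
                logical(1))
  s[bad] <- NA_character_
  s
}

#' Construct a single barcode record
#'
#' One sequence of one mitochondrial marker from one sample, with taxonomy
#' and collection metadata. Invariants are enforced: non-empty sequence over
#' the IUPAC+gap alphabet, marker from the closed set
#' `{"COI", "16S", "ND2"}`, genus equal to the first token of the species
#' name, coordinates (when present) within valid ranges.
#'
#' @param sample_id opaque sample identifier.
#' @param species_name species name; may carry an open-nomenclature
#'   qualifier ("cf.", "sp.", "aff.").
#' @param family family name.
#' @param marker one of `"COI"`, `"16S"`, `"ND2"`.
#' @param sequence IUPAC nucleotide string; may contain gaps if pre-aligned.
#' @param environment habitat class: `"F"` (freshwater), `"FF"` (facultative
#'   freshwater), `"MF"`, or `"M"` (marine); `NA` allowed.
#' @param origin_status `"native"` or `"introduced"`; `NA` allowed.
#' @param country,locality collection metadata (free text).
#' @param latitude,longitude decimal degrees WGS84 (negative = south/west);
#'   optional.
#' @param accession sequence database accession; optional.
#' @param source one of `"genbank"`, `"bold"`, `"new"`.
#' @return a one-row data.frame with the canonical record columns.
#' @export
barcode_record <- function(sample_id, species_name, family, marker, sequence,
                           environment = NA_character_,
                           origin_status = NA_character_,
                           country = "", locality = "",
                           latitude = NA_real_, longitude = NA_real_,
                           accession = NA_character_, source = "new") {
  species_name <- normalize_species_name(species_name)
  marker <- as.character(marker)
  if (!marker %in% MARKERS)
    stop("marker must be one of: ", paste(MARKERS, collapse = ", "))
  seq <- clean_sequence(sequence)
  if (is.na(seq) || !nzchar(seq))
    stop("sequence must be non-empty and over the IUPAC+gap alphabet")
  if (!is.na(environment) && !environment %in% ENVIRONMENTS)
    stop("environment must be one of: ", paste(ENVIRONMENTS, collapse = ", "))
  if (!is.na(origin_status) && !origin_status %in% ORIGINS)
    stop("origin_status must be 'native' or 'introduced'")
  if (!is.na(latitude) && (latitude < -90 || latitude > 90))
    stop("latitude out of range [-90, 90]")
  if (!is.na(longitude) && (longitude < -180 || longitude > 180))
    stop("longitude out of range [-180, 180]")
  if (!source %in% SOURCES)
    stop("source must be one of: ", paste(SOURCES, collapse = ", "))
  data.frame(sample_id = as.character(sample_id),
             species_name = species_name,
             genus = genus_of(species_name),
             family = as.character(family),
             marker = marker,
             sequence = seq,
             environment = as.character(environment),
             origin_status = as.character(origin_status),
             country = as.character(country),
             locality = as.character(locality),
             latitude = as.numeric(latitude),
             longitude = as.numeric(longitude),
             accession = as.character(accession),
             source = source,
             stringsAsFactors = FALSE)
}

#' Construct a barcode library from a record table
#'
#' A `barcode_library` is a data.frame of records (one row per sequence)
#' carrying the canonical columns. Validation checks each row against the
#' record invariants; curation additionally enforces uniqueness per
#' `(sample_id, marker)` (see [merge_sample_rows()]).
#'
#' @param records data.frame with at least `sample_id`, `species_name`,
#'   `family`, `marker`, `sequence` columns; missing optional columns are
#'   added as `NA`/empty.
#' @param validate logical; check row invariants (default `TRUE`).
#' @return an object of class `barcode_library` (a data.frame).
#' @export
barcode_library <- function(records, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("sample_id", "species_name", "family", "marker", "sequence")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(record_columns(), names(records))) {
    records[[col]] <- rep(switch(col,
      latitude = , longitude = NA_real_,
      country = , locality = "",
      source = "new",
      NA_character_), nrow(records))
  }
  records$species_name <- normalize_species_name(records$species_name)
  records$genus <- genus_of(records$species_name)
  records$sequence <- clean_sequence(records$sequence)
  records <- records[, record_columns()]
  rownames(records) <- NULL
  if (validate && nrow(records)) {
    if (anyNA(records$sequence) || any(!nzchar(records$sequence)))
      stop("invalid or empty sequence in record(s): ",
           paste(which(is.na(records$sequence) |
                       !nzchar(records$sequence)), collapse = ", "))
    bad <- !records$marker %in% MARKERS
    if (any(bad))
      stop("unknown marker in record(s): ",
           paste(unique(records$marker[bad]), collapse = ", "))
    lat <- records$latitude
    lon <- records$longitude
    if (any(!is.na(lat) & (lat < -90 | lat > 90)) ||
        any(!is.na(lon) & (lon < -180 | lon > 180)))
      stop("coordinates out of range")
  }
  class(records) <- c("barcode_library", "data.frame")
  records
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode library: %d records, %d samples, %d species, markers: %s\n",
              nrow(x), length(unique(x$sample_id)),
              length(unique(x$species_name)),
              paste(sort(unique(x$marker)), collapse = ", ")))
  invisible(x)
}

#' Read a tab-delimited barcode library table
#'
#' Reads a UTF-8 TSV with a header row into a [barcode_library()]. Column
#' names are mapped through `col_map`, so tables with different headers can
#' be ingested by supplying the mapping. Rows with an empty sequence are
#' rejected with a logged reason; malformed coordinates are dropped (record
#' kept) with a warning.
#'
#' @param path path to the TSV file.
#' @param col_map named character vector mapping canonical column names
#'   (names) to the file's column names (values). Defaults to the identity
#'   mapping over the canonical schema.
#' @return a `barcode_library`; rejected rows are reported in
#'   `attr(x, "rejected")`.
#' @export
read_library_table <- function(path, col_map = NULL) {
  tab <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  default_map <- setNames(record_columns(), record_columns())
  if (!is.null(col_map)) default_map[names(col_map)] <- col_map
  mandatory <- c("sample_id", "species_name", "family", "marker", "sequence")
  have <- default_map[mandatory] %in% names(tab)
  if (!all(have))
    stop("mandatory column(s) absent from table: ",
         paste(default_map[mandatory][!have], collapse = ", "))
  out <- data.frame(row.names = seq_len(nrow(tab)))
  for (canon in record_columns()) {
    src <- default_map[[canon]]
    out[[canon]] <- if (src %in% names(tab)) tab[[src]] else NA_character_
  }
  # coordinates: malformed values dropped with a warning, record kept
  for (col in c("latitude", "longitude")) {
    raw <- out[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & nzchar(trimws(ifelse(is.na(raw), "", raw))) & is.na(num)
    rng <- if (col == "latitude") 90 else 180
    oob <- !is.na(num) & abs(num) > rng
    if (any(bad | oob)) {
      warning(sum(bad | oob), " malformed ", col,
              " value(s) dropped (records kept)")
      num[oob] <- NA_real_
    }
    out[[col]] <- num
  }
  out$country[is.na(out$country)] <- ""
  out$locality[is.na(out$locality)] <- ""
  out$source[is.na(out$source) | !out$source %in% SOURCES] <- "new"
  empty <- is.na(out$sequence) | !nzchar(trimws(ifelse(is.na(out$sequence),
                                                       "", out$sequence)))
  rejected <- data.frame(row = which(empty),
                         reason = rep("empty sequence", sum(empty)),
                         stringsAsFactors = FALSE)
  if (any(empty)) {
    message(sum(empty), " row(s) rejected: empty sequence")
    out <- out[!empty, , drop = FALSE]
  }
  lib <- barcode_library(out)
  attr(lib, "rejected") <- rejected
  lib
}

#' Write a barcode library table
#'
#' Inverse of [read_library_table()]: writes the canonical TSV so that a
#' read/write round trip preserves every retained field.
#'
#' @param library a `barcode_library`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_library_table <- function(library, path) {
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read barcode records from a GenBank flatfile
#'
#' Minimal parser for GenBank flatfiles (LOCUS/FEATURES/ORIGIN blocks):
#' `organism` becomes the species name, the `country` qualifier is split on
#' its first colon into country and locality, `isolation_source` fills the
#' locality when `country` carries none, and the marker is inferred from
#' `gene`/`product` qualifiers via a configurable keyword map.
#'
#' @param path path to the flatfile.
#' @param marker_map named character vector: lowercase keyword (a regular
#'   expression) to marker id. Records whose gene/product match nothing get
#'   marker `"unknown"` and are excluded from the returned set (reported in
#'   `attr(, "unmapped")`).
#' @param family family to assign (flatfiles carry full lineages; the
#'   family is taken from the taxonomy line when recognisable, else this
#'   default).
#' @return data.frame of records (not yet a validated library); records
#'   without an ORIGIN sequence are skipped with a warning.
#' @export
read_genbank_flatfile <- function(path,
                                  marker_map = c("co[ix1]" = "COI",
                                                 "cox1" = "COI",
                                                 "cytochrome c oxidase subunit 1" = "COI",
                                                 "cytochrome oxidase subunit 1" = "COI",
                                                 "16s" = "16S",
                                                 "nd2" = "ND2",
                                                 "nadh dehydrogenase subunit 2" = "ND2"),
                                  family = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS block found: not a GenBank flatfile")
  ends <- c(starts[-1] - 1, length(lines))
  recs <- vector("list", length(starts))
  unmapped <- character(0)
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    qual <- function(name) {
      hits <- regmatches(block,
                         regexpr(sprintf('/%s="[^"]*"?', name), block))
      if (!length(hits)) return(NA_character_)
      sub('"$', "", sub(sprintf('/%s="', name), "", hits[[1]], fixed = TRUE))
    }
    acc_line <- grep("^ACCESSION", block, value = TRUE)
    accession <- if (length(acc_line))
      strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
      else NA_character_
    organism <- qual("organism")
    country_raw <- qual("country")
    isolation <- qual("isolation_source")
    country <- locality <- ""
    if (!is.na(country_raw)) {
      parts <- strsplit(country_raw, ":", fixed = TRUE)[[1]]
      country <- trimws(parts[1])
      if (length(parts) > 1)
        locality <- trimws(paste(parts[-1], collapse = ":"))
    }
    if (!nzchar(locality) && !is.na(isolation)) locality <- isolation
    gene <- tolower(paste(stats::na.omit(c(qual("gene"), qual("product"))),
                          collapse = " "))
    marker <- "unknown"
    for (kw in names(marker_map))
      if (grepl(kw, gene)) { marker <- marker_map[[kw]]; break }
    ori <- grep("^ORIGIN", block)
    if (!length(ori)) {
      warning("record ", k, " (", accession, ") has no ORIGIN sequence; skipped")
      next
    }
    seq_lines <- block[(ori + 1):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
    if (!nzchar(seq)) {
      warning("record ", k, " (", accession, ") has empty ORIGIN; skipped")
      next
    }
    if (marker == "unknown") unmapped <- c(unmapped, accession)
    recs[[k]] <- data.frame(
      sample_id = if (!is.na(accession)) accession else paste0("gb", k),
      species_name = normalize_species_name(
        if (is.na(organism)) "Unknown sp." else organism),
      family = family,
      marker = marker,
      sequence = seq,
      country = country, locality = locality,
      accession = accession, source = "genbank",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  keep <- out$marker %in% MARKERS
  if (any(!keep))
    message(sum(!keep), " record(s) with unmappable gene name excluded ",
            "(marker 'unknown')")
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unmapped") <- unmapped
  res
}

fasta_header <- function(library) {
  h <- paste(library$sample_id, library$species_name,
             ifelse(is.na(library$accession), "", library$accession),
             sep = "|")
  gsub(" ", "_", h)
}

#' Write one marker of a library to FASTA
#'
#' One entry per record of the requested marker, headers
#' `sample_id|species_name|accession` with spaces replaced by underscores,
#' sequences wrapped at 80 columns. Gap characters (pre-aligned dialect)
#' are written verbatim.
#'
#' @param library a `barcode_library`.
#' @param marker marker id.
#' @param path output path.
#' @return invisibly, the number of entries written.
#' @export
write_fasta <- function(library, marker, path) {
  stopifnot(nrow(library) >= 1)
  sel <- library[library$marker == marker, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no records of marker ", marker, "; empty FASTA written")
    file.create(path)
    return(invisible(0L))
  }
  set <- Biostrings::BStringSet(sel$sequence)
  names(set) <- fasta_header(sel)
  Biostrings::writeXStringSet(set, path, width = 80)
  invisible(nrow(sel))
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file (gaps permitted).
#' @return data.frame with columns `id` and `sequence` (uppercase, U -> T).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  data.frame(id = names(set),
             sequence = clean_sequence(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}
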