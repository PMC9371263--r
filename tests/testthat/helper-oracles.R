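# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force / first-principles so that
# it stays independent of the implementation paths it checks.

# ---- alignment oracle -------------------------------------------------

# Score an explicit alignment (two equal-length gapped strings) under the
# package's cost model: +match/-mismatch per residue column, a gap run of
# length L costs open + (L - 1) * extend unless it touches either end of
# the alignment (end gaps free).
score_alignment <- function(a, b, match = 1, mismatch = -1,
                            open = -8, extend = -1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  stopifnot(length(ac) == length(bc), !any(ac == "-" & bc == "-"))
  s <- 0
  L <- length(ac)
  res <- ac != "-" & bc != "-"
  s <- sum(ifelse(ac[res] == bc[res], match, mismatch))
  for (row in list(ac, bc)) {
    r <- rle(row == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (starts[k] == 1 || ends[k] == L) next   # end gap: free
      s <- s + open + (r$lengths[k] - 1) * extend
    }
  }
  s
}

# Exhaustive optimum over every monotone alignment (no gap-gap columns).
# Feasible for lengths <= ~7.
brute_align_optimum <- function(a, b, ...) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score_alignment(paste(ra, collapse = ""),
                                         paste(rb, collapse = ""), ...))
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc))
      rec(i + 1, j + 1, c(ra, ac[i]), c(rb, bc[j]))
    if (i <= length(ac)) rec(i + 1, j, c(ra, ac[i]), c(rb, "-"))
    if (j <= length(bc)) rec(i, j + 1, c(ra, "-"), c(rb, bc[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# Brute-force p-distance on aligned strings: explicit column walk.
brute_p_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ok <- ac %in% c("A", "C", "G", "T") & bc %in% c("A", "C", "G", "T")
  list(distance = if (!sum(ok)) NA_real_ else mean(ac[ok] != bc[ok]),
       sites = sum(ok))
}

# ---- tree oracle ------------------------------------------------------

# All bipartitions of an unrooted tree by graph surgery: drop one edge,
# flood-fill the component containing its child node over the remaining
# adjacency, report the tip labels inside. Independent of the package's
# postorder accumulation.
brute_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  lapply(seq_len(nrow(edges)), function(k) {
    adj <- edges[-k, , drop = FALSE]
    seen <- edges[k, 2]
    repeat {
      nb <- unique(c(adj[adj[, 1] %in% seen, 2], adj[adj[, 2] %in% seen, 1]))
      new <- setdiff(nb, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    sort(tree$tip.label[seen[seen <= ntip]])
  })
}

# Monophyly verdicts by brute-force bipartition enumeration.
brute_monophyly <- function(tree, species_map) {
  sp_of <- species_map[tree$tip.label]
  sides <- brute_bipartitions(tree)
  all_tips <- sort(tree$tip.label)
  sides <- unique(c(sides, lapply(sides, function(s) setdiff(all_tips, s))))
  vapply(sort(unique(sp_of)), function(sp) {
    own <- sort(tree$tip.label[sp_of == sp])
    length(own) == 1 || identical(own, all_tips) ||
      any(vapply(sides, function(s) identical(s, own), logical(1)))
  }, logical(1))
}

# ---- fixture builders -------------------------------------------------

random_seq <- function(n, chars = c("A", "C", "G", "T")) {
  paste(sample(chars, n, replace = TRUE), collapse = "")
}

# Small record table; `...` overrides columns recycled to length n.
toy_records <- function(n, species = "Pachypanchax arnoulti",
                        marker = "COI", seq_length = 60, ...) {
  base <- data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    species_name = rep_len(species, n),
    family = rep_len("Aplocheilidae", n),
    marker = rep_len(marker, n),
    sequence = vapply(seq_len(n), function(i) random_seq(seq_length), ""),
    country = rep_len("Madagascar", n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (k in names(over)) base[[k]] <- rep_len(over[[k]], n)
  base
}

# The 8-record, 2-genera x 2-species x 2-samples toy used for partition
# counts (28 pairs: 4 intraspecific / 8 congeneric / 16 intergeneric).
toy_partition_library <- function(seq_length = 40) {
  species <- rep(c("Aa x", "Aa y", "Bb x", "Bb y"), each = 2)
  toy_records(8, species = species, seq_length = seq_length)
}

# Pairwise-mode p-distance of a single pair (strand-normalized).
p_distance_of_pair <- function(a, b) {
  lib <- barcode_library(toy_records(2, sequence = c(a, b)))
  distance_matrix(lib, "COI")$d[1, 2]
}

# A distance matrix with fully controlled entries over n ids.
manual_dist <- function(d, ids, marker = "COI") {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, sites = NULL, marker = marker,
                 mode = "msa"), class = "barcode_dist")
}

# A two-record GenBank flatfile (COI + unmappable gene), inline.
genbank_fixture <- function() {
  c("LOCUS       AB000001                 60 bp    DNA     linear   VRT",
    "ACCESSION   AB000001",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    '                     /organism="Paretroplus menarambo"',
    '                     /country="Madagascar: Nosy Be"',
    '                     /isolation_source="floodplain lake"',
    "     gene            1..60",
    '                     /gene="cox1"',
    "ORIGIN",
    "        1 gattacagat tacagattac agattacaga ttacagatta cagattacag",
    "       51 attacagatt",
    "//",
    "LOCUS       AB000002                 30 bp    DNA     linear   VRT",
    "ACCESSION   AB000002",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    '                     /organism="Paretroplus sp."',
    '                     /country="Madagascar"',
    "     gene            1..30",
    '                     /gene="cytb"',
    "ORIGIN",
    "        1 gattacagat tacagattac agattacaga",
    "//")
}

# Build a library whose distance structure is fully known, by planting a
# fixed number of mismatches into copies of one backbone sequence (all
# equal length, so msa mode gives exact fractions).
planted_library <- function(backbone, edits, species, seq_length = 200) {
  n <- length(edits)
  seqs <- vapply(seq_len(n), function(i) {
    s <- strsplit(backbone, "")[[1]]
    k <- edits[i]
    if (k > 0) {
      pos <- seq_len(k)                       # first k sites
      s[pos] <- vapply(s[pos], function(ch)
        setdiff(c("A", "C", "G", "T"), ch)[1], "")
    }
    paste(s, collapse = "")
  }, "")
  toy_records(n, species = species, seq_length = nchar(backbone),
              sequence = seqs)
}
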