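# Uncorrected p-distances with pairwise deletion, over affine-gap pairwise
# alignments (free end gaps) or a pre-computed multiple alignment. This is
# the quantitative core: all gap statistics, assignments and trees consume
# these distances.

#' Globally align two sequences with affine gap costs
#'
#' Needleman-Wunsch/Gotoh alignment with free end gaps, so short fragments
#' nest inside longer sequences without penalty. A gap run of length L
#' costs `gap_open + (L - 1) * gap_extend` unless it touches an alignment
#' end. Tie-breaking is deterministic: match/mismatch is preferred over a
#' gap, and a gap in `seq_a` over a gap in `seq_b`.
#'
#' @param seq_a,seq_b ungapped nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters (defaults
#'   +1 / -1 / -8 / -1).
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
pairwise_align <- function(seq_a, seq_b, match = 1, mismatch = -1,
                           gap_open = -8, gap_extend = -1) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  stopifnot(nzchar(seq_a), nzchar(seq_b),
            !grepl("-", seq_a, fixed = TRUE), !grepl("-", seq_b, fixed = TRUE))
  .nw_affine(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: columns where either sequence carries a gap or any
#' symbol outside `{A, C, G, T}` are excluded from both numerator and
#' denominator. With zero comparable sites the distance is `NA` (masked),
#' never 0.
#'
#' @param aligned_a,aligned_b equal-length aligned strings.
#' @return list with `distance` (fraction in `[0, 1]` or `NA`) and `sites`
#'   (number of compared positions).
#' @export
p_distance <- function(aligned_a, aligned_b) {
  a <- toupper(as.character(aligned_a)); b <- toupper(as.character(aligned_b))
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  .p_distance_aligned(a, b)
}

#' Reverse-complement a nucleotide string
#'
#' IUPAC-aware; gaps preserved.
#' @param seq nucleotide string.
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  s <- chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", toupper(seq))
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

# Orient `query` to the strand of `ref`: the orientation (as-is vs
# reverse complement) with more exact shared 11-mers wins.
orient_strand <- function(query, ref, k = 11) {
  fwd <- .shared_kmers(ref, query, k)
  rc <- reverse_complement(query)
  rev <- .shared_kmers(ref, rc, k)
  if (rev > fwd) rc else query
}

#' Pairwise distance matrix for one marker
#'
#' Computes all unordered pairs. In `pairwise_align` mode every pair is
#' aligned independently (optionally after strand normalization: the
#' orientation of the shorter sequence with more exact 11-mer matches
#' against the longer is used) and then scored with pairwise deletion. In
#' `msa` mode the sequences must already be equal-length aligned and are
#' scored directly.
#'
#' @param library a `barcode_library`.
#' @param marker marker id; only records of this marker enter the matrix.
#' @param mode `"pairwise_align"` (default) or `"msa"`.
#' @param strand_normalize logical; test both strands before aligning
#'   (default `TRUE`, `pairwise_align` mode only).
#' @param ids optional explicit record ids (defaults to `sample_id`, made
#'   unique if needed).
#' @return object of class `barcode_dist`: list with `ids`, `d` (symmetric
#'   matrix of fractions, `NA` where no sites compared), `sites` (symmetric
#'   integer matrix), `marker`, `mode`.
#' @export
distance_matrix <- function(library, marker, mode = c("pairwise_align", "msa"),
                            strand_normalize = TRUE, ids = NULL) {
  mode <- match.arg(mode)
  sel <- library[library$marker == marker, , drop = FALSE]
  if (nrow(sel) < 2) stop("need at least 2 records of marker ", marker)
  if (is.null(ids)) ids <- make.unique(sel$sample_id)
  seqs <- sel$sequence
  n <- length(seqs)
  if (mode == "msa") {
    if (length(unique(nchar(seqs))) != 1)
      stop("mode 'msa' requires equal-length (aligned) sequences")
    mats <- .p_distance_matrix_msa(seqs)
    d <- mats$d; sites <- mats$sites
  } else {
    seqs <- gsub("-", "", seqs)
    d <- matrix(0, n, n); sites <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- seqs[i]; b <- seqs[j]
        if (strand_normalize) {
          if (nchar(b) <= nchar(a)) b <- orient_strand(b, a)
          else a <- orient_strand(a, b)
        }
        aln <- pairwise_align(a, b)
        pd <- p_distance(aln$aligned_a, aln$aligned_b)
        d[i, j] <- d[j, i] <- pd$distance
        sites[i, j] <- sites[j, i] <- pd$sites
      }
    }
  }
  diag(d) <- 0
  diag(sites) <- nchar(gsub("-", "", sel$sequence))
  dimnames(d) <- dimnames(sites) <- list(ids, ids)
  structure(list(ids = ids, d = d, sites = sites, marker = marker,
                 mode = mode),
            class = "barcode_dist")
}

# msa-mode matrix in one vectorized pass
.p_distance_matrix_msa <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  d <- matrix(0, n, n); sites <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      s <- sum(comp)
      d[i, j] <- d[j, i] <- if (s == 0) NA_real_ else
        sum(m[i, comp] != m[j, comp]) / s
      sites[i, j] <- sites[j, i] <- s
    }
  }
  list(d = d, sites = sites)
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("p-distance matrix: %d x %d (%s, %s), mean off-diagonal %.4f\n",
              length(x$ids), length(x$ids), x$marker, x$mode,
              mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Write a distance matrix as square TSV
#'
#' Id header row and column; masked (no-sites) cells written as `NA`.
#'
#' @param dm a `barcode_dist`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_distance_tsv <- function(dm, path) {
  tab <- data.frame(id = dm$ids, dm$d, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a square distance TSV written by [write_distance_tsv()]
#' @param path input path.
#' @return a `barcode_dist` (marker/mode unknown, sites absent).
#' @export
read_distance_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- tab$id
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, sites = NULL, marker = NA_character_,
                 mode = NA_character_), class = "barcode_dist")
}

#' Sequence-length summary for one marker
#'
#' Ungapped lengths; the mean is rounded to the nearest integer for
#' reporting, min and max are exact.
#'
#' @param library a `barcode_library`.
#' @param marker marker id.
#' @return list with `mean`, `min`, `max`, `n`.
#' @export
length_summary <- function(library, marker) {
  sel <- library[library$marker == marker, , drop = FALSE]
  stopifnot(nrow(sel) >= 1)
  len <- nchar(gsub("-", "", sel$sequence))
  list(mean = round(mean(len)), min = min(len), max = max(len),
       n = length(len))
}
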