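# Neighbor-joining from p-distance matrices, Newick I/O, and
# reciprocal-monophyly screening of species labels on unrooted trees.
# Monophyly is decided on bipartitions, so no outgroup or rooting is
# needed and verdicts are rooting-independent.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: at each step the pair minimizing the Q
#' criterion is joined, with the standard branch-length formulas. Ties are
#' broken deterministically by the lowest index pair. Masked cells are
#' imputed with the maximum observed distance (with a warning). Negative
#' branch lengths are clamped to zero with a warning. On an additive
#' matrix the tree's path-length matrix reproduces the input.
#'
#' @param dm a `barcode_dist`, or a plain symmetric numeric matrix with
#'   dimnames.
#' @return an unrooted `phylo` tree (ape) with tip labels equal to the
#'   matrix ids.
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "barcode_dist")) dm$d else as.matrix(dm)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(d)) {
    warning("masked distances imputed with the maximum observed distance")
    d[is.na(d)] <- max(d, na.rm = TRUE)
  }
  # each active node carries a newick fragment
  labs <- vapply(ids, function(x) {
    if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'")
    else x
  }, character(1))
  frag <- unname(labs)
  act <- seq_len(n)          # active row indices into d
  clamped <- FALSE
  while (length(act) > 3) {
    r <- length(act)
    dd <- d[act, act, drop = FALSE]
    rs <- rowSums(dd)
    q <- (r - 2) * dd - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest-index pair among minima (row-major over upper triangle)
    best <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(r - 1)) for (j in (i + 1):r)
      if (q[i, j] < best) { best <- q[i, j]; bi <- i; bj <- j }
    dij <- dd[bi, bj]
    li <- dij / 2 + (rs[bi] - rs[bj]) / (2 * (r - 2))
    lj <- dij - li
    if (li < 0 || lj < 0) { clamped <- TRUE; li <- max(li, 0); lj <- max(lj, 0) }
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[act[bi]], li,
                        frag[act[bj]], lj)
    # distances from the new node u to every other active node
    others <- act[-c(bi, bj)]
    du <- (d[act[bi], others] + d[act[bj], others] - dij) / 2
    u <- act[bi]               # reuse slot bi for the new node
    d[u, others] <- du; d[others, u] <- du; d[u, u] <- 0
    frag[u] <- new_frag
    act <- c(u, others)        # drop bj
    act <- sort(act)
  }
  # final three-way join (closed form)
  a <- act[1]; b <- act[2]; c <- act[3]
  la <- (d[a, b] + d[a, c] - d[b, c]) / 2
  lb <- (d[a, b] + d[b, c] - d[a, c]) / 2
  lc <- (d[a, c] + d[b, c] - d[a, b]) / 2
  if (any(c(la, lb, lc) < 0)) clamped <- TRUE
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  if (clamped) warning("negative branch length(s) clamped to zero")
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[a], la, frag[b], lb, frag[c], lc)
  ape::read.tree(text = nwk)
}

#' Read a Newick tree
#'
#' Supports quoted labels, branch lengths, and internal support values
#' (stored as `node.label`). Unbalanced parentheses are fatal, reporting
#' the offending position.
#'
#' @param path path to a Newick file.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  in_quote <- FALSE
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == "'") in_quote <- !in_quote
    if (!in_quote) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parentheses in Newick at position ", k)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses in Newick: ", depth,
         " unclosed at end of input")
  tree <- ape::read.tree(text = txt)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @param digits branch-length precision (default 6 decimals).
#' @return invisibly, the path.
#' @export
write_newick <- function(tree, path, digits = 6) {
  needs_quote <- grepl("[ ()\\[\\]:;,]", tree$tip.label)
  tree$tip.label[needs_quote] <-
    paste0("'", gsub("'", "''", tree$tip.label[needs_quote]), "'")
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

# leaf sets of one side of every internal edge (bipartitions), as a list
# of tip-label character vectors
.bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # tips below each node, by postorder accumulation
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) {
    par <- po[k, 1]; child <- po[k, 2]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k)
    tree$tip.label[sort(below[[tree$edge[k, 2]]])])
}

#' Reciprocal-monophyly report for species labels on a tree
#'
#' A species with two or more leaves is monophyletic iff some edge
#' bipartition isolates exactly its leaf set (either side). Singletons are
#' trivially monophyletic. For failing species the minimal conflicting
#' species set is reported: the other species present in the smallest
#' bipartition side containing all of the species' leaves.
#'
#' @param tree a `phylo` tree (leaf labels = record ids).
#' @param species_map named character vector: leaf id -> species. Every
#'   leaf must be mapped (unmapped leaves are fatal).
#' @return data.frame: `species`, `n_leaves`, `monophyletic`, `trivial`
#'   (singleton), `intruders` (semicolon-joined species, `""` when
#'   monophyletic).
#' @export
monophyly_report <- function(tree, species_map) {
  tips <- tree$tip.label
  if (!all(tips %in% names(species_map)))
    stop("unmapped leaf label(s): ",
         paste(setdiff(tips, names(species_map)), collapse = ", "))
  sp_of <- species_map[tips]
  all_tips <- sort(tips)
  sides <- .bipartitions(tree)
  # both sides of every bipartition, deduplicated
  sides <- c(sides, lapply(sides, function(s) setdiff(all_tips, s)))
  sides <- unique(lapply(sides, sort))
  species <- sort(unique(sp_of))
  rows <- lapply(species, function(sp) {
    own <- sort(tips[sp_of == sp])
    trivial <- length(own) == 1
    mono <- trivial || identical(own, all_tips) ||
      any(vapply(sides, function(s) identical(s, own), logical(1)))
    intr <- ""
    if (!mono) {
      containing <- Filter(function(s) all(own %in% s), sides)
      sizes <- vapply(containing, length, integer(1))
      minimal <- containing[[which.min(sizes)]]
      intr <- paste(sort(setdiff(unique(sp_of[match(minimal, tips)]), sp)),
                    collapse = "; ")
    }
    data.frame(species = sp, n_leaves = length(own), monophyletic = mono,
               trivial = trivial, intruders = intr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
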