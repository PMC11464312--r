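# Poisson-corrected pairwise-deletion distances, Saitou-Nei neighbor
# joining with deterministic tie-breaking, and bootstrap support.

#' Read a protein alignment from FASTA
#' @param path Aligned FASTA (gap = `-`).
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  aln <- setNames(toupper(as.character(x)), names(x))
  check_alignment(aln)
  aln
}

check_alignment <- function(aln) {
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    abort("alignment rows must carry unique names")
  }
  if (length(unique(nchar(aln))) != 1) abort("alignment rows differ in length")
  invisible(aln)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

#' Poisson-corrected distance between two aligned rows
#'
#' Columns where either row carries a gap are deleted pairwise (gap-vs-gap
#' columns included); with `p` the fraction of differing retained sites,
#' the distance is `-ln(1 - p)`. The ambiguity character `X` counts as a
#' mismatch by default (`x_handling = "mismatch"`); set `"delete"` to drop
#' such columns instead.
#'
#' @param row_i,row_j Equal-length gapped amino-acid strings.
#' @param x_handling `"mismatch"` (default) or `"delete"`.
#' @return List with `d` (distance) and `n_used` (retained sites).
#' @export
poisson_distance <- function(row_i, row_j, x_handling = c("mismatch", "delete")) {
  x_handling <- match.arg(x_handling)
  if (nchar(row_i) != nchar(row_j)) abort("rows differ in length")
  a <- strsplit(toupper(row_i), "")[[1]]
  b <- strsplit(toupper(row_j), "")[[1]]
  used <- a != "-" & b != "-"
  if (x_handling == "delete") used <- used & a != "X" & b != "X"
  n_used <- sum(used)
  if (n_used == 0) abort("no shared ungapped sites: distance undefined")
  if (x_handling == "mismatch") {
    diffs <- (a[used] != b[used]) | (a[used] == "X" & b[used] == "X")
    # X-vs-X is also a mismatch: X stands for an unknown residue on each side
    p <- mean(diffs)
  } else {
    p <- mean(a[used] != b[used])
  }
  if (p >= 1) {
    abort("all retained sites differ (p = 1): Poisson distance infinite; consider removing this pair or improving the alignment")
  }
  list(d = -log(1 - p), n_used = n_used)
}

#' Poisson-corrected distance matrix for an alignment
#'
#' @param aln Named character vector of equal-length gapped sequences.
#' @inheritParams poisson_distance
#' @return List with `d` (symmetric matrix, zero diagonal) and `n_used`
#'   (matrix of retained-site counts per pair).
#' @export
poisson_dist_matrix <- function(aln, x_handling = c("mismatch", "delete")) {
  x_handling <- match.arg(x_handling)
  check_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  ok <- m != "-"
  if (x_handling == "delete") ok <- ok & m != "X"
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  nu <- matrix(nchar(aln[1]), n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      used <- ok[i, ] & ok[j, ]
      n_used <- sum(used)
      if (n_used == 0) abort(paste0("no shared ungapped sites for pair ",
                                    names(aln)[i], " / ", names(aln)[j]))
      diffs <- m[i, used] != m[j, used]
      if (x_handling == "mismatch") diffs <- diffs | (m[i, used] == "X" & m[j, used] == "X")
      p <- mean(diffs)
      if (p >= 1) abort(paste0("p = 1 for pair ", names(aln)[i], " / ", names(aln)[j],
                               ": Poisson distance infinite"))
      d[i, j] <- d[j, i] <- -log(1 - p)
      nu[i, j] <- nu[j, i] <- n_used
    }
  }
  list(d = d, n_used = nu)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, with ties broken by the
#' lexicographic order of the joined leaf-label sets so repeated runs give
#' identical trees. Negative branch lengths are clamped to zero; the
#' number clamped is recorded in the `clamped` attribute.
#'
#' @param d Symmetric distance matrix with row/col names (>= 3 taxa), or
#'   the list returned by [poisson_dist_matrix()].
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  if (is.list(d) && !is.null(d$d)) d <- d$d
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # node "newick" fragments and the lexicographically smallest leaf each
  # subtree contains (tie-break key)
  frag <- labels
  key <- labels
  D <- d
  clamped <- 0L
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ck <- apply(cand, 1, function(ij) {
      ks <- sort(c(key[ij[1]], key[ij[2]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(ck)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { clamped <- clamped + 1L; li <- 0 }
    if (lj < 0) { clamped <- clamped + 1L; lj <- 0 }
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], li, frag[j], lj)
    new_key <- min(key[i], key[j])
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk), c(dk, 0))
    D <- D2
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }
  r <- rowSums(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- c(la, lb, lc)
  clamped <- clamped + sum(lens < 0)
  lens <- pmax(lens, 0)
  ord <- order(key)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[ord[1]], lens[ord[1]], frag[ord[2]], lens[ord[2]],
                 frag[ord[3]], lens[ord[3]])
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree from Poisson-corrected pairwise-deletion distances for each
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicate trees containing the same leaf bipartition.
#' Replicates in which some pair has no shared ungapped sites (or p = 1)
#' are dropped with a warning and the denominator adjusted.
#'
#' @param aln Named character vector of equal-length gapped sequences.
#' @param n_reps Number of bootstrap replicates (default 1000); 0 returns
#'   the tree without supports.
#' @param seed Integer seed for the column resampling.
#' @inheritParams poisson_distance
#' @return An [ape::phylo] tree; internal node labels carry supports in
#'   [0, 100] (empty for the root pseudo-node). Attributes: `n_valid`
#'   (replicates used), `clamped`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1,
                              x_handling = c("mismatch", "delete")) {
  x_handling <- match.arg(x_handling)
  check_alignment(aln)
  dm <- poisson_dist_matrix(aln, x_handling)
  tree <- nj_tree(dm$d)
  if (n_reps == 0) return(tree)
  m <- aln_matrix(aln)
  L <- ncol(m)
  boot_trees <- vector("list", n_reps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dropped <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                        names(aln))
    rep_dm <- tryCatch(poisson_dist_matrix(rep_aln, x_handling), error = function(e) NULL)
    if (is.null(rep_dm)) { dropped <- dropped + 1L; next }
    boot_trees[[b]] <- nj_tree(rep_dm$d)
  }
  boot_trees <- boot_trees[!vapply(boot_trees, is.null, logical(1))]
  n_valid <- length(boot_trees)
  if (dropped > 0) {
    warn(paste0(dropped, " bootstrap replicate(s) dropped (undefined distances); ",
                "support denominator = ", n_valid))
  }
  if (n_valid == 0) abort("no valid bootstrap replicates")
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  supp <- round(100 * counts / n_valid, 1)
  lab <- as.character(supp)
  lab[is.na(lab)] <- ""
  tree$node.label <- lab
  attr(tree, "n_valid") <- n_valid
  tree
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a tree to Newick
#' @param tree [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.phylo <- function(x, ...) {
  tibble(
    parent = x$edge[, 1],
    node = x$edge[, 2],
    length = if (is.null(x$edge.length)) NA_real_ else x$edge.length,
    label = ifelse(x$edge[, 2] <= length(x$tip.label),
                   x$tip.label[x$edge[, 2]],
                   if (is.null(x$node.label)) NA_character_ else
                     x$node.label[x$edge[, 2] - length(x$tip.label)])
  )
}

#' @exportS3Method generics::glance
glance.phylo <- function(x, ...) {
  supp <- suppressWarnings(as.numeric(x$node.label))
  tibble(
    n_tips = length(x$tip.label),
    n_internal = x$Nnode,
    total_length = if (is.null(x$edge.length)) NA_real_ else sum(x$edge.length),
    mean_support = if (all(is.na(supp))) NA_real_ else mean(supp, na.rm = TRUE),
    clamped = if (is.null(attr(x, "clamped"))) NA_integer_ else attr(x, "clamped")
  )
}
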