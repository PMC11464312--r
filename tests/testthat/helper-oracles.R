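# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning / distance / enrichment code paths.

# IUPAC expansion written out by hand
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(unname(ORACLE_COMP[strsplit(s, "")[[1]]])), collapse = "")
}

# per-offset matching, one character at a time
oracle_match_offsets <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  w <- length(pc)
  L <- length(sc)
  if (L < w) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sc[off + j] %in% ORACLE_IUPAC[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# upper-tail hypergeometric by direct combinatorial enumeration
oracle_hyper_upper <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# all non-trivial leaf bipartitions of an unrooted binary phylo, as sorted
# strings, derived straight from the edge matrix by traversal
oracle_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_below))
  }
  inner <- setdiff(unique(tree$edge[, 1]), ntip + 1)  # skip the root pseudo-node
  parts <- lapply(inner, function(nd) {
    side <- sort(tips_below(nd))
    other <- sort(setdiff(tree$tip.label, side))
    # canonical form: the lexicographically smaller side first
    if (paste(side, collapse = ",") < paste(other, collapse = ",")) {
      paste(paste(side, collapse = ","), paste(other, collapse = ","), sep = "|")
    } else {
      paste(paste(other, collapse = ","), paste(side, collapse = ","), sep = "|")
    }
  })
  keep <- vapply(parts, function(p) {
    sides <- strsplit(p, "\\|")[[1]]
    all(lengths(strsplit(sides, ",")) >= 2)
  }, logical(1))
  unique(unlist(parts[keep]))
}

as_genome_charvec_for_test <- function(genome) {
  out <- as.character(genome)
  names(out) <- names(genome)
  out
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# tiny two-chromosome genome + gene models used by several io tests
toy_genome <- function(seed = 1, len = c(chr1 = 8000, chr2 = 6000)) {
  withr::with_seed(seed, {
    g <- vapply(len, function(L) random_dna(L), character(1))
    Biostrings::DNAStringSet(g)
  })
}

toy_gene <- function(gene_id, chrom, strand, start, end, exons = NULL) {
  if (is.null(exons)) exons <- matrix(as.integer(c(start, end)), ncol = 2,
                                      dimnames = list(NULL, c("start", "end")))
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    tss = as.integer(if (strand == "+") start else end - 1L),
    mrna_id = paste0(gene_id, ".t1"),
    n_exons = nrow(exons), n_cds = nrow(exons),
    exons = list(exons), cds = list(exons)
  )
}

# small expression fixture: two treatment groups at day 2 plus tissues
toy_expression <- function(values) {
  samples <- c("root_r1", "S1_r1",
               "ck_d2_r1", "ck_d2_r2", "ck_d2_r3",
               "ETH_d2_r1", "ETH_d2_r2", "ETH_d2_r3",
               "Aza_d2_r1", "Aza_d2_r2", "Aza_d2_r3")
  sheet <- tibble::tibble(
    sample = samples,
    tissue = c("root", "flower", rep("flower", 9)),
    stage = c(NA, "S1", rep(NA, 9)),
    treatment = c(NA, NA, rep(c("ck", "ETH", "Aza"), each = 3)),
    day = c(NA, NA, rep(2L, 9)),
    replicate = c(1L, 1L, rep(1:3, 3))
  )
  colnames(values) <- samples
  expr <- tibble::as_tibble(values, rownames = "gene_id")
  list(expr = expr, sheet = sheet)
}
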