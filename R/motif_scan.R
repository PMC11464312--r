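# Cis-element scanning in two modes: exact degenerate-consensus (IUPAC)
# matching, and log-odds PWM scanning thresholded at an exact p-value
# computed by dynamic programming over the background distribution.

DNA_BASES <- c("A", "C", "G", "T")

iupac_sets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(strsplit(unname(m), ""), identity) |> setNames(names(m))
}

#' The GCC-box and DRE/CRT core motif catalog
#'
#' The two cis-elements recognised by ERF- and DREB-subfamily factors:
#' the GCC box (`GCCGCC`) and the DRE/CRT core (`RCCGAC`, R = A/G).
#'
#' @return Tibble with columns `name`, `consensus`.
#' @export
default_motifs <- function() {
  tibble(name = c("GCC_box", "DRE_CRT"), consensus = c("GCCGCC", "RCCGAC"))
}

#' Read a motif catalog
#'
#' TSV with columns `name`, `consensus` and optionally `matrix_file`
#' (path, relative to the catalog file, of a count-matrix TSV whose first
#' column is the base `A/C/G/T` and remaining columns are positions).
#'
#' @param path Path to the catalog TSV.
#' @return Tibble `name`, `consensus`, and list-column `counts`
#'   (4 x w matrices or `NULL`).
#' @export
read_motifs <- function(path) {
  cat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "consensus") %in% names(cat))) {
    abort("motif catalog needs columns 'name' and 'consensus'")
  }
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", cat$consensus)
  if (any(bad)) abort(paste0("non-IUPAC consensus: ", paste(cat$name[bad], collapse = ", ")))
  counts <- vector("list", nrow(cat))
  if ("matrix_file" %in% names(cat)) {
    for (i in which(!is.na(cat$matrix_file))) {
      mf <- file.path(dirname(path), cat$matrix_file[i])
      tab <- readr::read_tsv(mf, show_col_types = FALSE, progress = FALSE)
      m <- as.matrix(tab[, -1])
      rownames(m) <- tab[[1]]
      counts[[i]] <- m[DNA_BASES, , drop = FALSE]
    }
  }
  cat$counts <- counts
  cat[, c("name", "consensus", "counts")]
}

#' Turn an IUPAC consensus into a 0/1 count matrix
#' @param consensus IUPAC DNA string.
#' @return 4 x w matrix (rows A,C,G,T).
#' @export
consensus_to_counts <- function(consensus) {
  sets <- iupac_sets()
  letters <- strsplit(consensus, "")[[1]]
  m <- vapply(letters, function(l) as.numeric(DNA_BASES %in% sets[[l]]),
              numeric(4))
  rownames(m) <- DNA_BASES
  colnames(m) <- NULL
  m
}

# 0-based offsets at which `pattern` (IUPAC) matches `seq_chars` (character
# vector of single bases). N in the sequence never matches any pattern letter.
match_iupac_offsets <- function(seq_chars, pattern) {
  sets <- iupac_sets()
  w <- nchar(pattern)
  L <- length(seq_chars)
  if (L < w) return(integer(0))
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    ok <- ok & seq_chars[j:(L - w + j)] %in% sets[[pat[j]]]
  }
  which(ok) - 1L
}

# Concatenate promoter sequences with N spacers (width w-1 is enough; use w)
# so windows never straddle two promoters; returns per-hit mapping info.
concat_scan_space <- function(sequences, w) {
  spacer <- strrep("N", w)
  big <- paste(sequences, collapse = spacer)
  lens <- nchar(sequences)
  starts <- cumsum(c(1L, head(lens, -1) + w))  # 1-based start of each promoter
  list(big = big, starts = starts, lens = lens)
}

map_hits_to_genes <- function(pos1, space, gene_ids) {
  idx <- findInterval(pos1, space$starts)
  offset <- pos1 - space$starts[idx]
  keep <- offset < space$lens[idx]  # guard: never inside a spacer
  list(gene = gene_ids[idx[keep]], offset = offset[keep], keep = keep)
}

#' Scan promoters for IUPAC consensus motifs
#'
#' Reports every offset at which the degenerate pattern matches exactly.
#' `N` in a promoter never matches. With `both_strands` the reverse
#' complement of each pattern is also scanned and its matches reported
#' with strand `-`; offsets are always 0-based in the oriented promoter.
#'
#' @param promoters Promoter tibble from [extract_promoters()] (columns
#'   `gene_id`, `sequence`).
#' @param motifs Motif catalog tibble (`name`, `consensus`), e.g.
#'   [default_motifs()].
#' @param both_strands Scan the reverse complement too? Default `TRUE`.
#' @return Tibble `gene_id`, `motif`, `offset`, `strand`, `score`,
#'   `p_value` (the last two `NA` in consensus mode).
#' @export
scan_consensus <- function(promoters, motifs, both_strands = TRUE) {
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$consensus[i]
    w <- nchar(pat)
    space <- concat_scan_space(promoters$sequence, w)
    chars <- strsplit(space$big, "")[[1]]
    strands <- if (both_strands) c("+", "-") else "+"
    for (s in strands) {
      p <- if (s == "+") pat else dna_revcomp(pat)
      off0 <- match_iupac_offsets(chars, p)
      if (length(off0) == 0) next
      mp <- map_hits_to_genes(off0 + 1L, space, promoters$gene_id)
      out[[length(out) + 1]] <- tibble(
        gene_id = mp$gene, motif = motifs$name[i],
        offset = as.integer(mp$offset), strand = s,
        score = NA_real_, p_value = NA_real_
      )
    }
  }
  res <- if (length(out) == 0) {
    tibble(gene_id = character(), motif = character(), offset = integer(),
           strand = character(), score = double(), p_value = double())
  } else bind_rows(out)
  arrange(res, .data$gene_id, .data$motif, .data$offset, .data$strand)
}

log_odds_matrix <- function(counts, background, pseudocount) {
  stopifnot(nrow(counts) == 4, all(counts >= 0), all(colSums(counts) > 0))
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  log2(freq / background)
}

#' Exact PWM score threshold for a target p-value
#'
#' Builds a log-odds matrix from the motif's counts (pseudocount added,
#' uniform background by default), discretises scores to a fixed
#' granularity in bits, computes the exact null score distribution under
#' the background by positionwise dynamic programming (convolution over
#' columns), and returns the minimal score `s` with `P(score >= s) <= alpha`.
#'
#' @param motif One row of a motif catalog (with non-NULL `counts`), or a
#'   bare 4 x w count matrix.
#' @param alpha Target p-value in (0, 1]; default 0.001.
#' @param background Base probabilities (A,C,G,T); default uniform.
#' @param pseudocount Added to every count cell; default 0.1.
#' @param granularity Score discretisation step in bits; default 1e-3.
#' @return An object of class `pwm_threshold`: the log-odds matrix, the
#'   discretised null distribution, and the threshold (in bits and in
#'   integer units).
#' @export
pwm_pvalue_threshold <- function(motif, alpha = 0.001,
                                 background = rep(0.25, 4),
                                 pseudocount = 0.1, granularity = 1e-3) {
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha <= 1)) {
    abort("alpha must be a single number in (0, 1]")
  }
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-9)
  if (is.matrix(motif)) {
    counts <- motif
    name <- "pwm"
  } else {
    counts <- motif$counts[[1]]
    if (is.null(counts)) counts <- consensus_to_counts(motif$consensus[1])
    name <- motif$name[1]
  }
  m <- log_odds_matrix(counts, background, pseudocount)
  im <- round(m / granularity)
  w <- ncol(im)

  # exact null distribution of the integer score
  cur <- 1
  cur_min <- 0L
  for (j in seq_len(w)) {
    col <- im[, j]
    new_min <- cur_min + min(col)
    new_max <- cur_min + length(cur) - 1L + max(col)
    new <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      sft <- cur_min + col[b] - new_min
      idx <- (sft + 1L):(sft + length(cur))
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    cur_min <- as.integer(new_min)
  }
  scores_int <- cur_min + seq_along(cur) - 1L
  tail_p <- rev(cumsum(rev(cur)))
  # smallest achievable score whose exact tail is within alpha
  pass <- which(tail_p <= alpha & cur > 0)
  if (length(pass) == 0) {
    thr_int <- scores_int[length(scores_int)] + 1L  # nothing passes
    achieved <- 0
  } else {
    thr_int <- scores_int[pass[1]]
    achieved <- tail_p[pass[1]]
  }
  structure(list(
    name = name, matrix = m, int_matrix = im, granularity = granularity,
    background = background, alpha = alpha,
    dist = tibble(score_int = scores_int, prob = cur, tail_p = tail_p),
    threshold_int = thr_int, threshold = thr_int * granularity,
    achieved_alpha = achieved, width = w
  ), class = "pwm_threshold")
}

#' @export
print.pwm_threshold <- function(x, ...) {
  cat(sprintf(
    "<pwm_threshold> motif '%s' (w=%d): score >= %.4f bits, P(null) = %.3g (alpha = %g)\n",
    x$name, x$width, x$threshold, x$achieved_alpha, x$alpha
  ))
  invisible(x)
}

# integer window scores of a coded sequence (codes 1..4, NA for N) for an
# integer score matrix; windows containing NA score NA
pwm_window_scores <- function(codes, im) {
  w <- ncol(im)
  L <- length(codes)
  if (L < w) return(numeric(0))
  nwin <- L - w + 1L
  sc <- numeric(nwin)
  for (j in seq_len(w)) {
    sc <- sc + im[, j][codes[j:(nwin + j - 1L)]]
  }
  sc
}

#' Scan promoters with a PWM at an exact p-value threshold
#'
#' Scores every window with the log-odds matrix of a [pwm_pvalue_threshold()]
#' object and keeps those at or above its threshold; each hit carries the
#' exact tail probability of its score under the background. Windows
#' containing `N` never match. With `both_strands` the reverse-complemented
#' matrix is applied to the same oriented sequence and hits reported with
#' strand `-`.
#'
#' @param promoters Promoter tibble (`gene_id`, `sequence`).
#' @param threshold A `pwm_threshold` object.
#' @param both_strands Default `TRUE`.
#' @return Tibble `gene_id`, `motif`, `offset`, `strand`, `score` (bits),
#'   `p_value`.
#' @export
scan_pwm <- function(promoters, threshold, both_strands = TRUE) {
  stopifnot(inherits(threshold, "pwm_threshold"))
  im <- threshold$int_matrix
  w <- ncol(im)
  space <- concat_scan_space(promoters$sequence, w)
  codes <- match(strsplit(space$big, "")[[1]], DNA_BASES)

  # tail lookup: the DP support is a contiguous integer range covering every
  # achievable window score, so indexing is direct
  dist <- threshold$dist
  tail_of <- function(s_int) dist$tail_p[s_int - dist$score_int[1] + 1L]

  rc_im <- im[4:1, w:1, drop = FALSE]
  rownames(rc_im) <- DNA_BASES
  strands <- if (both_strands) c("+", "-") else "+"
  out <- list()
  for (s in strands) {
    mm <- if (s == "+") im else rc_im
    sc <- pwm_window_scores(codes, mm)
    hit <- which(!is.na(sc) & sc >= threshold$threshold_int)
    if (length(hit) == 0) next
    mp <- map_hits_to_genes(hit, space, promoters$gene_id)
    sc_hit <- sc[hit][mp$keep]
    out[[length(out) + 1]] <- tibble(
      gene_id = mp$gene, motif = threshold$name,
      offset = as.integer(mp$offset), strand = s,
      score = sc_hit * threshold$granularity,
      p_value = tail_of(sc_hit)
    )
  }
  res <- if (length(out) == 0) {
    tibble(gene_id = character(), motif = character(), offset = integer(),
           strand = character(), score = double(), p_value = double())
  } else bind_rows(out)
  arrange(res, .data$gene_id, .data$motif, .data$offset, .data$strand)
}

#' Derive a candidate-target set from motif co-occurrence
#'
#' Genes whose promoters carry the required combination of elements
#' (presence = at least one hit). The default rule keeps genes carrying
#' every motif in `motif_names` (`"both"`); `"either"` keeps genes with
#' any of them.
#'
#' @param hits Motif-hit tibble ([scan_consensus()] / [scan_pwm()]).
#' @param motif_names Motif names entering the rule.
#' @param combine `"both"` (intersection) or `"either"` (union).
#' @param catalog Optional motif catalog used to validate `motif_names`
#'   (defaults to the motifs present in `hits`).
#' @return Object of class `erf_candidate_set`: list with `rule`, `motifs`,
#'   `genes` (sorted character vector).
#' @export
build_candidate_set <- function(hits, motif_names, combine = c("both", "either"),
                                catalog = NULL) {
  combine <- match.arg(combine)
  known <- unique(c(hits$motif, if (!is.null(catalog)) catalog$name))
  unknown <- setdiff(motif_names, known)
  if (length(unknown) > 0) {
    abort(paste0("rule references unknown motif(s): ", paste(unknown, collapse = ", ")))
  }
  by_motif <- lapply(motif_names, function(m) unique(hits$gene_id[hits$motif == m]))
  genes <- if (combine == "both") Reduce(intersect, by_motif) else Reduce(union, by_motif)
  structure(
    list(rule = combine, motifs = motif_names, genes = sort(unique(genes))),
    class = "erf_candidate_set"
  )
}

#' @export
print.erf_candidate_set <- function(x, ...) {
  cat(sprintf("<erf_candidate_set> %d genes with %s of {%s}\n",
              length(x$genes), x$rule, paste(x$motifs, collapse = ", ")))
  invisible(x)
}

candidate_genes <- function(candidates) {
  if (inherits(candidates, "erf_candidate_set")) candidates$genes
  else if (is.character(candidates)) candidates
  else if (is.data.frame(candidates)) candidates$gene_id
  else abort("cannot interpret candidate set")
}
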