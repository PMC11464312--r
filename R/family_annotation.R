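# Subfamily classification from domain evidence, tandem-duplication
# detection, and gene-structure statistics.

SUBFAMILIES <- c("AP2", "DREB", "ERF", "RAV", "Soloist")

#' Read a protein-domain hit table
#'
#' Two dialects are accepted: the HMMER3 per-domain tabular format
#' (`--domtblout`; whitespace-separated, `#` comment lines) and a plain TSV
#' with columns `gene_id`, `domain`, `env_from`, `env_to`,
#' `aligned_residues` and optional `score`. Rows naming domains other than
#' `AP2`/`B3` (or their Pfam accessions PF00847/PF02362) are dropped with a
#' warning. In the domtblout dialect the aligned domain residues are not
#' part of the format; supply `proteins` (a named AA FASTA path or
#' [Biostrings::AAStringSet]) to recover them from the envelope coordinates.
#'
#' @param path Path to the hit table.
#' @param proteins Optional protein sequences for the domtblout dialect.
#' @param evalue_max Optional independent-E-value cutoff (domtblout only);
#'   default `NULL` keeps all rows.
#' @return Tibble `gene_id`, `domain`, `env_from`, `env_to` (1-based
#'   closed, as reported), `aligned_residues`, `score`.
#' @export
read_domain_hits <- function(path, proteins = NULL, evalue_max = NULL) {
  if (!file.exists(path)) abort(paste0("domain-hit file not found: ", path))
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    return(tibble(gene_id = character(), domain = character(),
                  env_from = integer(), env_to = integer(),
                  aligned_residues = character(), score = double()))
  }
  first_fields <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (grepl("\t", body[1]) && length(strsplit(body[1], "\t")[[1]]) <= 8) {
    hits <- parse_domain_tsv(path)
  } else if (length(first_fields) >= 22) {
    hits <- parse_domtblout(body, proteins, evalue_max)
  } else {
    hits <- parse_domain_tsv(path)
  }
  keep <- normalize_domain(hits$domain) %in% c("AP2", "B3")
  if (any(!keep)) {
    warn(paste0("ignoring ", sum(!keep), " hit(s) for non-AP2/B3 domain(s): ",
                paste(unique(hits$domain[!keep]), collapse = ", ")))
  }
  hits <- hits[keep, ]
  hits$domain <- normalize_domain(hits$domain)
  arrange(hits, .data$gene_id, .data$env_from)
}

normalize_domain <- function(d) {
  up <- toupper(d)
  out <- d
  out[up %in% c("AP2", "PF00847", "PF00847.21")] <- "AP2"
  out[up %in% c("B3", "PF02362", "PF02362.23")] <- "B3"
  out
}

parse_domain_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "domain", "env_from", "env_to", "aligned_residues")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) abort(paste0("domain TSV missing column(s): ", paste(miss, collapse = ", ")))
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  if (any(tab$env_to <= tab$env_from - 1)) {
    abort("domain envelope with non-positive length")
  }
  tab[, c("gene_id", "domain", "env_from", "env_to", "aligned_residues", "score")]
}

parse_domtblout <- function(body, proteins, evalue_max) {
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(rows, length, integer(1)) < 22)
  if (length(bad) > 0) {
    abort(paste0("malformed domtblout row (fewer than 22 fields) at data line ", bad[1]))
  }
  get <- function(i) vapply(rows, `[`, character(1), i)
  out <- tibble(
    gene_id = get(1),
    domain = get(4),
    ievalue = suppressWarnings(as.numeric(get(13))),
    score = suppressWarnings(as.numeric(get(14))),
    env_from = suppressWarnings(as.integer(get(20))),
    env_to = suppressWarnings(as.integer(get(21)))
  )
  if (anyNA(out$env_from) || anyNA(out$env_to)) {
    abort(paste0("malformed domtblout row: non-numeric envelope at data line ",
                 which(is.na(out$env_from) | is.na(out$env_to))[1]))
  }
  if (!is.null(evalue_max)) out <- out[!is.na(out$ievalue) & out$ievalue <= evalue_max, ]
  out$aligned_residues <- NA_character_
  if (!is.null(proteins)) {
    if (is.character(proteins) && length(proteins) == 1) {
      proteins <- Biostrings::readAAStringSet(proteins)
      names(proteins) <- vapply(strsplit(names(proteins), "\\s+"), `[`, character(1), 1)
    }
    pseq <- as.character(proteins)
    idx <- match(out$gene_id, names(pseq))
    out$aligned_residues <- ifelse(
      is.na(idx), NA_character_,
      substr(pseq[idx], out$env_from, out$env_to)
    )
  }
  out[, c("gene_id", "domain", "env_from", "env_to", "aligned_residues", "score")]
}

# identity between two residue strings; Hamming when equal length, else
# global alignment percent identity
residue_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(mean(ca == cb))
  }
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                      type = "global")
  Biostrings::pid(al, type = "PID2") / 100
}

#' Classify genes into AP2/ERF subfamilies
#'
#' Architecture and residue rules: two or more AP2 domains gives `AP2`;
#' one AP2 plus a B3 domain gives `RAV`; a single AP2 domain is split on
#' the residues at domain positions 14 and 19 (1-based within the reported
#' envelope, shiftable via `residue_offset`): alanine/aspartate (A, D)
#' gives `ERF`, valine/glutamate (V, E) gives `DREB`. Genes with any other
#' residue pair are compared to the supplied Soloist reference sequences
#' and assigned `Soloist` when the best identity reaches `identity_min`;
#' otherwise they fall back to `fallback` (default `ERF`) with
#' `unresolved = TRUE`.
#'
#' @param hits Domain-hit tibble ([read_domain_hits()]).
#' @param soloist_refs Optional character vector of Soloist domain-region
#'   reference sequences.
#' @param residue_offset Shift added to positions 14/19; default 0.
#' @param identity_min Identity threshold for Soloist assignment; default 0.7.
#' @param fallback Subfamily for unresolved single-AP2 genes; default "ERF".
#' @return Tibble `gene_id`, `subfamily`, `architecture` (e.g. `"AP2x2"`),
#'   `res14`, `res19`, `unresolved`.
#' @export
classify_subfamilies <- function(hits, soloist_refs = NULL, residue_offset = 0,
                                 identity_min = 0.7, fallback = "ERF") {
  stopifnot(fallback %in% SUBFAMILIES)
  genes <- unique(hits$gene_id)
  rows <- lapply(genes, function(g) {
    h <- hits[hits$gene_id == g, ]
    n_ap2 <- sum(h$domain == "AP2")
    n_b3 <- sum(h$domain == "B3")
    if (n_ap2 == 0) {
      abort(paste0("not an AP2/ERF gene (no AP2 domain hit): ", g))
    }
    arch <- paste0("AP2x", n_ap2, if (n_b3 > 0) paste0("+B3x", n_b3) else "")
    if (n_ap2 >= 2) {
      return(tibble(gene_id = g, subfamily = "AP2", architecture = arch,
                    res14 = NA_character_, res19 = NA_character_, unresolved = FALSE))
    }
    if (n_b3 >= 1) {
      return(tibble(gene_id = g, subfamily = "RAV", architecture = arch,
                    res14 = NA_character_, res19 = NA_character_, unresolved = FALSE))
    }
    res <- h$aligned_residues[h$domain == "AP2"][1]
    p14 <- 14 + residue_offset
    p19 <- 19 + residue_offset
    if (is.na(res) || nchar(res) < p19) {
      abort(paste0("aligned domain residues too short for residue rule: ", g))
    }
    r14 <- substr(res, p14, p14)
    r19 <- substr(res, p19, p19)
    base <- tibble(gene_id = g, subfamily = NA_character_, architecture = arch,
                   res14 = r14, res19 = r19, unresolved = FALSE)
    if (r14 == "A" && r19 == "D") {
      base$subfamily <- "ERF"
    } else if (r14 == "V" && r19 == "E") {
      base$subfamily <- "DREB"
    } else if (!is.null(soloist_refs) &&
               max(vapply(soloist_refs, residue_identity, numeric(1), a = res)) >= identity_min) {
      base$subfamily <- "Soloist"
    } else {
      base$subfamily <- fallback
      base$unresolved <- TRUE
    }
    base
  })
  bind_rows(rows)
}

#' Detect tandem-duplicate gene pairs
#'
#' Pairs of family genes on the same chromosome separated by at most
#' `max_intervening` other annotated genes (counting every gene in
#' `genes`, not only family members, unless `count_family_only`) and
#' homologous under the default rule: same subfamily and domain-region
#' identity of at least `identity_min`.
#'
#' @param calls Subfamily-call tibble ([classify_subfamilies()]).
#' @param genes Full gene-model tibble ([read_gff3()]) supplying order.
#' @param hits Domain-hit tibble (for domain-region identity).
#' @param max_intervening Maximum intervening genes; default 1.
#' @param identity_min Homology identity threshold; default 0.7.
#' @param count_family_only Count only family genes as intervening? Default
#'   `FALSE`.
#' @param identity_fn Optional replacement homology predicate
#'   `function(gene_a, gene_b)` returning `TRUE`/`FALSE`.
#' @return Tibble `gene_a`, `gene_b` (lexicographically ordered), `chrom`,
#'   `n_intervening`, `identity`.
#' @export
detect_tandem_duplicates <- function(calls, genes, hits = NULL,
                                     max_intervening = 1, identity_min = 0.7,
                                     count_family_only = FALSE,
                                     identity_fn = NULL) {
  fam <- calls$gene_id
  ord <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  if (count_family_only) ord <- ord[ord$gene_id %in% fam, ]
  ord <- ord %>% group_by(.data$chrom) %>% mutate(pos = row_number()) %>% ungroup()
  fam_ord <- ord[ord$gene_id %in% fam, ]
  dom_of <- function(g) {
    if (is.null(hits)) return(NA_character_)
    r <- hits$aligned_residues[hits$gene_id == g & hits$domain == "AP2"]
    if (length(r) == 0) NA_character_ else r[1]
  }
  subfam <- setNames(calls$subfamily, calls$gene_id)
  out <- list()
  for (chr in unique(fam_ord$chrom)) {
    fc <- fam_ord[fam_ord$chrom == chr, ]
    if (nrow(fc) < 2) next
    for (i in seq_len(nrow(fc) - 1)) {
      for (j in (i + 1):nrow(fc)) {
        n_between <- fc$pos[j] - fc$pos[i] - 1L
        if (n_between > max_intervening) break
        a <- fc$gene_id[i]; b <- fc$gene_id[j]
        if (!is.null(identity_fn)) {
          homologous <- identity_fn(a, b)
          ident <- NA_real_
        } else {
          same_sub <- identical(subfam[[a]], subfam[[b]])
          da <- dom_of(a); db <- dom_of(b)
          ident <- if (!is.na(da) && !is.na(db)) residue_identity(da, db) else NA_real_
          homologous <- same_sub && !is.na(ident) && ident >= identity_min
        }
        if (isTRUE(homologous)) {
          pr <- sort(c(a, b))
          out[[length(out) + 1]] <- tibble(
            gene_a = pr[1], gene_b = pr[2], chrom = chr,
            n_intervening = n_between, identity = ident
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(gene_a = character(), gene_b = character(), chrom = character(),
                  n_intervening = integer(), identity = double()))
  }
  arrange(bind_rows(out), .data$chrom, .data$gene_a, .data$gene_b)
}

#' Per-gene intron and CDS-segment counts
#'
#' Introns are `max(0, n_exons - 1)` for the canonical mRNA; CDS segments
#' are counted as annotated.
#'
#' @param genes Gene-model tibble.
#' @param calls Optional subfamily calls to attach a `subfamily` column.
#' @return Tibble `gene_id`, `n_exons`, `n_introns`, `n_cds`
#'   (and `subfamily` when `calls` given).
#' @export
gene_structure_stats <- function(genes, calls = NULL) {
  out <- tibble(
    gene_id = genes$gene_id,
    n_exons = genes$n_exons,
    n_introns = pmax(0L, genes$n_exons - 1L),
    n_cds = genes$n_cds
  )
  if (!is.null(calls)) {
    out <- left_join(out, calls[, c("gene_id", "subfamily")], by = "gene_id")
  }
  out
}

#' Per-subfamily means of intron and CDS counts
#' @param stats Output of [gene_structure_stats()] with a `subfamily` column.
#' @return Tibble `subfamily`, `n_genes`, `mean_introns`, `mean_cds`.
#' @export
structure_summary <- function(stats) {
  if (!"subfamily" %in% names(stats)) abort("stats lack a subfamily column; pass calls to gene_structure_stats()")
  stats %>%
    filter(!is.na(.data$subfamily)) %>%
    group_by(.data$subfamily) %>%
    summarise(n_genes = dplyr::n(),
              mean_introns = mean(.data$n_introns),
              mean_cds = mean(.data$n_cds), .groups = "drop")
}
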