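# Coordinate convention used throughout: 0-based half-open intervals on the
# forward genome strand. GFF3 (1-based closed) is converted at the I/O
# boundary and nowhere else.

VALID_TISSUES <- c("root", "stem", "leaf", "flower")
VALID_STAGES <- paste0("S", 1:6)
VALID_TREATMENTS <- c("ck", "ETH", "Aza")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement honouring the full IUPAC alphabet
#' (so `R` maps to `Y`, `N` to `N`, ...).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' dna_revcomp("GCCGAC")
dna_revcomp <- function(x) {
  rev1 <- function(s) intToUtf8(rev(utf8ToInt(s)))
  out <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                "TGCAYRSWMKVHDBNtgcayrswmkvhdbn",
                vapply(x, rev1, character(1)))
  unname(out)
}

normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

#' Read a genome FASTA
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased and any letter outside `A,C,G,T,N` is mapped
#' to `N`.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA record id(s): ", paste(unique(dup), collapse = ", ")))
  }
  chr <- normalize_dna(as.character(seqs))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- ids
  out
}

#' Write a genome FASTA
#'
#' @param genome Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome_charvec(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), path, width = 70
  )
  invisible(path)
}

as_genome_charvec <- function(genome) {
  if (methods::is(genome, "DNAStringSet") || methods::is(genome, "BStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort("genome must be a named DNAStringSet or a named character vector")
}

#' Genome chromosome lengths
#' @param genome Genome as returned by [read_genome()].
#' @return Named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  g <- as_genome_charvec(genome)
  setNames(nchar(g), names(g))
}

#' Read gene models from GFF3
#'
#' Parses standard `gene`/`mRNA`/`exon`/`CDS` features. GFF3 1-based closed
#' coordinates are converted to 0-based half-open. When a gene carries
#' several mRNAs the longest (by span) is taken as canonical. The TSS is
#' the gene-span start on the `+` strand and `end - 1` (0-based) on `-`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `n_exons`, `n_cds`, and list-columns `exons`,
#'   `cds` of two-column (start, end) integer matrices (0-based half-open).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  gff <- as_tibble(rtracklayer::readGFF(
    path, columns = c("seqid", "start", "end", "strand", "type"),
    tags = c("ID", "Parent")
  ))
  gff$Parent <- vapply(gff$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  gff$seqid <- as.character(gff$seqid)
  gff$type <- as.character(gff$type)
  gff$strand <- as.character(gff$strand)

  genes <- gff[gff$type == "gene", ]
  if (nrow(genes) == 0) abort(paste0("no gene features in ", path))
  bad_strand <- genes$ID[!genes$strand %in% c("+", "-")]
  if (length(bad_strand) > 0) {
    abort(paste0("unknown strand for gene(s): ", paste(bad_strand, collapse = ", ")))
  }
  mrnas <- gff[gff$type == "mRNA", ]
  parts <- gff[gff$type %in% c("exon", "CDS"), ]

  build_one <- function(i) {
    gid <- genes$ID[i]
    g_start <- genes$start[i] - 1L  # to 0-based half-open
    g_end <- genes$end[i]
    strand <- genes$strand[i]
    gm <- mrnas[!is.na(mrnas$Parent) & mrnas$Parent == gid, ]
    if (nrow(gm) > 0) {
      span <- gm$end - gm$start
      mr <- gm[order(-span, gm$ID), ][1, ]
      mrna_id <- mr$ID
      px <- parts[!is.na(parts$Parent) & parts$Parent == mrna_id, ]
    } else {
      # gene without mRNA level: take parts parented to the gene directly
      mrna_id <- NA_character_
      px <- parts[!is.na(parts$Parent) & parts$Parent == gid, ]
    }
    exon_rows <- px[px$type == "exon", ]
    cds_rows <- px[px$type == "CDS", ]
    mk <- function(df) {
      if (nrow(df) == 0) {
        return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
      }
      m <- cbind(start = as.integer(df$start - 1L), end = as.integer(df$end))
      m[order(m[, 1]), , drop = FALSE]
    }
    ex <- mk(exon_rows)
    if (nrow(ex) == 0) ex <- matrix(c(g_start, g_end), ncol = 2,
                                    dimnames = list(NULL, c("start", "end")))
    cd <- mk(cds_rows)
    if (any(ex[, 1] < g_start) || any(ex[, 2] > g_end)) {
      abort(paste0("exon outside gene span for gene: ", gid))
    }
    if (nrow(cd) > 0 && (any(cd[, 1] < g_start) || any(cd[, 2] > g_end))) {
      abort(paste0("CDS outside gene span for gene: ", gid))
    }
    tibble(
      gene_id = gid, chrom = genes$seqid[i], strand = strand,
      start = as.integer(g_start), end = as.integer(g_end),
      tss = as.integer(if (strand == "+") g_start else g_end - 1L),
      mrna_id = mrna_id,
      n_exons = nrow(ex), n_cds = nrow(cd),
      exons = list(ex), cds = list(cd)
    )
  }
  out <- bind_rows(lapply(seq_len(nrow(genes)), build_one))
  arrange(out, .data$chrom, .data$start, .data$gene_id)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()] (coordinates converted back to 1-based closed).
#'
#' @param genes Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mk <- function(type, s, e, id, parent = NULL) {
      attr <- if (is.null(parent)) paste0("ID=", id) else paste0("ID=", id, ";Parent=", parent)
      paste(g$chrom, "erfnet", type, as.integer(s) + 1L, as.integer(e),
            ".", g$strand, ".", attr, sep = "\t")
    }
    mid <- if (is.na(g$mrna_id)) paste0(g$gene_id, ".t1") else g$mrna_id
    lines <- c(lines,
               mk("gene", g$start, g$end, g$gene_id),
               mk("mRNA", g$start, g$end, mid, g$gene_id))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, mk("exon", ex[j, 1], ex[j, 2], paste0(mid, ".exon", j), mid))
    }
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, mk("CDS", cd[j, 1], cd[j, 2], paste0(mid, ".cds", j), mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract promoter windows upstream of the TSS
#'
#' Takes the `window` bases immediately upstream of each gene's
#' transcription start site: genomic `[tss - window, tss)` for `+` strand
#' genes and `[tss + 1, tss + 1 + window)` reverse-complemented for `-`
#' strand genes, so the returned sequence always reads 5' to 3' toward the
#' gene. Windows are clipped at chromosome edges and flagged `truncated`
#' rather than dropped.
#'
#' @param genes Gene-model tibble ([read_gff3()]).
#' @param genome Genome ([read_genome()]).
#' @param window Window size in bp (default 2000).
#' @return Tibble: `gene_id`, `chrom`, `strand`, `start`, `end` (genomic,
#'   0-based half-open), `truncated`, `sequence` (oriented 5'->3').
#' @export
extract_promoters <- function(genes, genome, window = 2000) {
  stopifnot(window >= 1)
  g <- as_genome_charvec(genome)
  missing_chr <- setdiff(unique(genes$chrom), names(g))
  if (length(missing_chr) > 0) {
    abort(paste0("chromosome(s) absent from genome: ", paste(missing_chr, collapse = ", ")))
  }
  lens <- nchar(g)[genes$chrom]
  if (any(genes$tss < 0 | genes$tss >= lens)) {
    bad <- genes$gene_id[genes$tss < 0 | genes$tss >= lens]
    abort(paste0("TSS outside chromosome for gene(s): ", paste(bad, collapse = ", ")))
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$tss - as.integer(window)), genes$tss + 1L)
  end <- ifelse(plus, genes$tss, pmin(lens, genes$tss + 1L + as.integer(window)))
  truncated <- ifelse(plus, genes$tss - window < 0, genes$tss + 1L + window > lens)
  seqs <- substr(g[genes$chrom], start + 1L, end)
  seqs[!plus] <- dna_revcomp(seqs[!plus])
  tibble(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    start = as.integer(start), end = as.integer(end),
    truncated = as.logical(truncated), sequence = unname(seqs)
  )
}

#' Write promoter windows to FASTA
#' @param promoters Promoter tibble from [extract_promoters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  x <- Biostrings::DNAStringSet(setNames(promoters$sequence, promoters$gene_id))
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

validate_sheet <- function(sheet) {
  need <- c("sample", "tissue", "stage", "treatment", "day", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss) > 0) abort(paste0("sample sheet missing column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(stats::na.omit(unique(sheet$tissue)), VALID_TISSUES)
  if (length(bad) > 0) abort(paste0("unknown tissue level(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(stats::na.omit(unique(sheet$stage)), VALID_STAGES)
  if (length(bad) > 0) abort(paste0("unknown stage level(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(stats::na.omit(unique(sheet$treatment)), VALID_TREATMENTS)
  if (length(bad) > 0) abort(paste0("unknown treatment level(s): ", paste(bad, collapse = ", ")))
  invisible(sheet)
}

#' Read an FPKM expression matrix and its sample sheet
#'
#' The matrix is a TSV with gene ids in column 1 (`gene_id`) and one column
#' per sample; the sheet is a TSV with columns `sample`, `tissue`, `stage`,
#' `treatment`, `day`, `replicate`. Sample ids must agree between the two
#' files; any mismatch raises an error listing the symmetric difference.
#' Negative FPKM values are rejected.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sheet_path Path to the sample-sheet TSV.
#' @return A list with elements `expr` (tibble, `gene_id` + sample columns)
#'   and `sheet` (tibble).
#' @export
read_expression <- function(matrix_path, sheet_path) {
  expr <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene_id"
  sheet <- readr::read_tsv(sheet_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             sample = "c", tissue = "c", stage = "c",
                             treatment = "c", day = "i", replicate = "i"
                           ))
  validate_expression(expr, sheet)
  list(expr = expr, sheet = sheet)
}

validate_expression <- function(expr, sheet) {
  validate_sheet(sheet)
  samp_mat <- setdiff(names(expr), "gene_id")
  only_sheet <- setdiff(sheet$sample, samp_mat)
  only_mat <- setdiff(samp_mat, sheet$sample)
  if (length(only_sheet) > 0 || length(only_mat) > 0) {
    abort(paste0(
      "sample-sheet / matrix id mismatch; only in sheet: {",
      paste(only_sheet, collapse = ", "), "}; only in matrix: {",
      paste(only_mat, collapse = ", "), "}"
    ))
  }
  vals <- as.matrix(expr[, samp_mat])
  if (anyNA(vals)) abort("expression matrix contains missing values")
  if (any(vals < 0)) abort("expression matrix contains negative FPKM values")
  if (anyDuplicated(expr$gene_id)) abort("duplicate gene ids in expression matrix")
  invisible(TRUE)
}

#' Write an expression matrix and sample sheet to TSV
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param sheet Sample-sheet tibble.
#' @param matrix_path,sheet_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, sheet, matrix_path, sheet_path) {
  readr::write_tsv(expr, matrix_path, progress = FALSE)
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  invisible(matrix_path)
}

# genes x samples numeric matrix from the expression tibble
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}
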