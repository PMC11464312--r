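# Domain-hit parsing, the subfamily classification rules, tandem
# duplication, and gene-structure statistics.

mk_hit <- function(gene, domain, res = NULL, from = 8L, to = 67L) {
  if (is.null(res)) res <- strrep("Q", 60)
  tibble::tibble(gene_id = gene, domain = domain, env_from = from, env_to = to,
                 aligned_residues = res, score = 100)
}

res_with <- function(r14, r19, base = strrep("Q", 60)) {
  substr(base, 14, 14) <- r14
  substr(base, 19, 19) <- r19
  base
}

test_that("the plain-TSV hit dialect parses and filters foreign domains", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(dplyr::bind_rows(
    mk_hit("g1", "AP2", res_with("A", "D")),
    mk_hit("g1", "AP2", res_with("A", "D"), from = 120L, to = 179L),
    mk_hit("g2", "WD40")
  ), path)
  expect_warning(hits <- read_domain_hits(path), "WD40")
  expect_equal(nrow(hits), 2)
  expect_true(all(hits$gene_id == "g1"))
})

test_that("the HMMER3 domtblout dialect parses, with residues from proteins", {
  # synthetic domtblout-format lines (22+ whitespace-separated fields)
  row <- function(target, query, ieval, envf, envt) {
    paste(target, "-", 300, query, "-", 60, "1e-20", 80.1, 0.1, 1, 1,
          "1e-21", ieval, 79.9, 0.1, 1, 60, envf, envt, envf, envt, 0.98,
          "synthetic protein")
  }
  path <- tempfile(fileext = ".domtblout")
  writeLines(c("# comment line", row("gene1", "AP2", "1e-18", 10, 69),
               row("gene1", "B3", "1e-9", 120, 219),
               row("gene2", "PF00847", "0.5", 5, 64)), path)
  prot <- Biostrings::AAStringSet(c(
    gene1 = paste(rep("ACDEFGHIKLMNPQRSTVWY", 15), collapse = ""),
    gene2 = paste(rep("MKVAY", 60), collapse = "")
  ))
  hits <- read_domain_hits(path, proteins = prot)
  expect_equal(nrow(hits), 3)
  expect_equal(sort(unique(hits$domain)), c("AP2", "B3"))
  g1 <- hits[hits$gene_id == "gene1" & hits$domain == "AP2", ]
  expect_equal(nchar(g1$aligned_residues), 60)
  expect_equal(g1$aligned_residues,
               substr(as.character(prot[["gene1"]]), 10, 69))
  # E-value cutoff drops the weak PF00847 row
  hits2 <- read_domain_hits(path, proteins = prot, evalue_max = 1e-3)
  expect_equal(sort(unique(hits2$gene_id)), "gene1")
  # comment-only file gives an empty table
  writeLines("# nothing here", path)
  expect_equal(nrow(read_domain_hits(path)), 0)
})

test_that("classification truth table is exhaustive over architectures and residues", {
  # the Soloist reference lives on a distinct backbone, so residue-ambiguous
  # genes on the Q backbone are NOT reference-similar and fall back to ERF
  soloist_ref <- res_with("G", "K", strrep("S", 60))
  pairs <- list(c("A", "D"), c("V", "E"), c("A", "E"), c("V", "D"), c("G", "K"))
  for (arch in c("AP2x1", "AP2x2", "AP2+B3")) {
    for (p in pairs) {
      res <- res_with(p[1], p[2])
      hits <- switch(arch,
        AP2x1 = mk_hit("g", "AP2", res),
        AP2x2 = dplyr::bind_rows(mk_hit("g", "AP2", res),
                                 mk_hit("g", "AP2", res, from = 120L, to = 179L)),
        "AP2+B3" = dplyr::bind_rows(mk_hit("g", "AP2", res),
                                    mk_hit("g", "B3", strrep("W", 100),
                                           from = 120L, to = 219L))
      )
      call <- classify_subfamilies(hits, soloist_refs = soloist_ref)
      expected <- if (arch == "AP2x2") "AP2"
        else if (arch == "AP2+B3") "RAV"
        else if (p[1] == "A" && p[2] == "D") "ERF"
        else if (p[1] == "V" && p[2] == "E") "DREB"
        else "ERF"                                      # ambiguous fallback
      expect_identical(call$subfamily, expected,
                       info = paste(arch, p[1], p[2]))
      if (arch == "AP2x1" && !(identical(p, c("A", "D")) ||
                               identical(p, c("V", "E")))) {
        expect_true(call$unresolved, info = paste(p, collapse = ""))
      }
    }
  }
  # a residue-ambiguous gene similar to the reference IS a Soloist
  near_ref <- res_with("G", "K", strrep("S", 60))
  substr(near_ref, 30, 33) <- "AAAA"
  call <- classify_subfamilies(mk_hit("g", "AP2", near_ref),
                               soloist_refs = soloist_ref)
  expect_identical(call$subfamily, "Soloist")
  expect_false(call$unresolved)
})

test_that("classification rejects impossible inputs", {
  expect_error(classify_subfamilies(mk_hit("g", "B3")), "not an AP2/ERF")
  short <- mk_hit("g", "AP2", strrep("A", 10))
  expect_error(classify_subfamilies(short), "too short")
})

test_that("residue offset shifts the diagnostic positions", {
  res <- strrep("Q", 60)
  substr(res, 16, 16) <- "V"
  substr(res, 21, 21) <- "E"
  call <- classify_subfamilies(mk_hit("g", "AP2", res), residue_offset = 2)
  expect_identical(call$subfamily, "DREB")
})

test_that("recovered subfamily labels equal planted labels on a clean cohort", {
  cfg <- sim_config(seed = 31, n_genes = 150, n_family = 60, n_tfs = 4,
                    class_counts = c(K1 = 1, K2_opposite = 1, K2_aza = 1, K3 = 1),
                    n_targets_per_tf = 3, tandem_pairs = 2)
  gg <- simulate_genome_and_genes(cfg)
  truth <- assign_regulation(cfg, gg$truth)
  dom <- simulate_domain_hits(cfg, truth)
  calls <- classify_subfamilies(dom$hits, soloist_refs = dom$soloist_refs)
  lab <- setNames(truth$genes$subfamily, truth$genes$gene_id)
  expect_equal(unname(lab[calls$gene_id]), calls$subfamily)
})

tandem_fixture <- function() {
  genes <- dplyr::bind_rows(
    toy_gene("e1", "chr1", "+", 1000, 2000),
    toy_gene("e2", "chr1", "+", 2200, 3200),   # adjacent to e1
    toy_gene("x1", "chr1", "+", 3400, 4400),   # non-family filler
    toy_gene("x2", "chr1", "+", 4600, 5600),
    toy_gene("e3", "chr1", "+", 5800, 6800),   # 2 intervening from e2
    toy_gene("d1", "chr1", "+", 7000, 8000),   # DREB adjacent to e3
    toy_gene("e4", "chr2", "+", 1000, 2000)    # other chromosome
  )
  dom <- strrep("Q", 60)
  hits <- dplyr::bind_rows(
    mk_hit("e1", "AP2", res_with("A", "D", dom)),
    mk_hit("e2", "AP2", res_with("A", "D", dom)),
    mk_hit("e3", "AP2", res_with("A", "D", dom)),
    mk_hit("d1", "AP2", res_with("V", "E", dom)),
    mk_hit("e4", "AP2", res_with("A", "D", dom))
  )
  calls <- classify_subfamilies(hits)
  list(genes = genes, hits = hits, calls = calls)
}

test_that("tandem detection applies the one-intervening-gene and homology rules", {
  fx <- tandem_fixture()
  tp <- detect_tandem_duplicates(fx$calls, fx$genes, fx$hits)
  # e1-e2 adjacent same subfamily, identical domains -> the only pair;
  # e2-e3 are separated by two non-family genes; e3-d1 differ in subfamily
  expect_equal(nrow(tp), 1)
  expect_equal(c(tp$gene_a, tp$gene_b), c("e1", "e2"))
  expect_equal(tp$n_intervening, 0L)
  expect_gte(tp$identity, 0.7)

  # counting only family members as intervening rescues e2-e3
  tp2 <- detect_tandem_duplicates(fx$calls, fx$genes, fx$hits,
                                  count_family_only = TRUE)
  expect_true(any(tp2$gene_a == "e2" & tp2$gene_b == "e3"))

  # low domain identity breaks the pair
  hits_lo <- fx$hits
  hits_lo$aligned_residues[hits_lo$gene_id == "e2"] <-
    res_with("A", "D", strrep("M", 60))
  tp3 <- detect_tandem_duplicates(fx$calls, fx$genes, hits_lo)
  expect_equal(nrow(tp3), 0)
})

test_that("tandem detection is invariant to gene renaming", {
  fx <- tandem_fixture()
  ren <- c(e1 = "zz9", e2 = "aa1", x1 = "x1", x2 = "x2", e3 = "e3",
           d1 = "d1", e4 = "e4")
  genes2 <- fx$genes; genes2$gene_id <- unname(ren[genes2$gene_id])
  hits2 <- fx$hits; hits2$gene_id <- unname(ren[hits2$gene_id])
  calls2 <- classify_subfamilies(hits2)
  tp <- detect_tandem_duplicates(calls2, genes2, hits2)
  expect_equal(nrow(tp), 1)
  expect_setequal(c(tp$gene_a, tp$gene_b), c("zz9", "aa1"))
})

test_that("intron and CDS counts follow the canonical-mRNA definitions", {
  ex1 <- matrix(as.integer(c(100, 200)), ncol = 2)
  ex2 <- matrix(as.integer(c(100, 150, 200, 260, 300, 400)), ncol = 2, byrow = TRUE)
  ex10 <- matrix(as.integer(c(seq(100, 1000, by = 100),
                              seq(150, 1050, by = 100))), ncol = 2)
  genes <- dplyr::bind_rows(
    toy_gene("one_exon", "chr1", "+", 100, 200, ex1),
    toy_gene("three_exon", "chr1", "+", 100, 400, ex2),
    toy_gene("ten_cds", "chr1", "+", 100, 1050, ex10)
  )
  st <- gene_structure_stats(genes)
  expect_equal(st$n_introns[st$gene_id == "one_exon"], 0L)
  expect_equal(st$n_introns[st$gene_id == "three_exon"], 2L)
  expect_equal(st$n_cds[st$gene_id == "ten_cds"], 10L)
  calls <- tibble::tibble(gene_id = genes$gene_id,
                          subfamily = c("ERF", "ERF", "AP2"))
  sm <- structure_summary(gene_structure_stats(genes, calls))
  expect_equal(sm$mean_introns[sm$subfamily == "ERF"], 1)
  expect_equal(sm$mean_cds[sm$subfamily == "AP2"], 10)
})
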