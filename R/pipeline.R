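# One-config pipeline front-end chaining the stages:
# simulate -> extract-promoters -> classify -> tree -> scan -> network -> enrich

#' Default pipeline configuration
#'
#' All stage parameters with their canonical defaults: 2,000 bp promoter
#' window, motif-scan p-value 0.001, FPKM > 1 expression floor,
#' |log2FC| > 1 and FDR < 0.05 differential calls at day 2, |r| > 0.8 and
#' p < 0.05 edge filter, 1,000 bootstrap replicates.
#'
#' @param seed Integer seed.
#' @param out_dir Run directory.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(seed = 42, out_dir = tempfile("erfnet_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = TRUE,
    sim = list(),             # overrides passed to sim_config()
    genome = NULL, gff = NULL, domains = NULL, proteins = NULL,
    motifs = NULL, expr = NULL, sheet = NULL, annotation = NULL,
    soloist_refs = NULL,
    window = 2000,
    scan_mode = "consensus",  # or "pwm"
    alpha = 0.001,
    fpkm_min = 1,
    lfc_min = 1,
    fdr_max = 0.05,
    day = 2,
    r_min = 0.8,
    p_max = 0.05,
    sample_scope = "treatment",
    bootstrap = 1000,
    candidate_rule = "both"
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' effective configuration is echoed into the run manifest.
#'
#' @param path YAML file.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), c(names(cfg), "sim"))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage_log <- function(stage, t0, ...) {
  msg <- paste(..., collapse = "; ")
  inform(sprintf("[%s] %s (%.2fs)", stage, msg,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}

#' Run the full pipeline from one configuration
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' under `out_dir` and a `manifest.json` recording the effective
#' configuration, per-stage output files with MD5 checksums, and record
#' counts. Identical configuration and seed give byte-identical outputs.
#'
#' @param config A `run_config` list ([default_run_config()]), a path to a
#'   YAML file, or `NULL` for the defaults.
#' @param out_dir Optional override of the run directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) default_run_config()
  else if (is.character(config)) read_run_config(config)
  else config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")], stages = list())
  outputs <- character(0)
  add_stage <- function(name, files, counts) {
    manifest$stages[[name]] <<- list(
      outputs = as.list(setNames(unname(tools::md5sum(files)), basename(files))),
      counts = counts
    )
    outputs <<- c(outputs, files)
  }

  # -- simulate ---------------------------------------------------------
  t0 <- Sys.time()
  if (isTRUE(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed,
                                       promoter_window = cfg$window), cfg$sim)
    scfg <- do.call(sim_config, sim_args)
    sim_dir <- file.path(cfg$out_dir, "sim")
    sim <- simulate_dataset(scfg, sim_dir)
    cfg$genome <- sim$files[["genome"]]
    cfg$gff <- sim$files[["gff"]]
    cfg$domains <- sim$files[["domains"]]
    cfg$motifs <- sim$files[["motifs"]]
    cfg$expr <- sim$files[["expr"]]
    cfg$sheet <- sim$files[["sheet"]]
    cfg$annotation <- sim$files[["annotation"]]
    soloist_refs <- sim$soloist_refs
    add_stage("simulate", unname(sim$files),
              list(genes = nrow(sim$genes), samples = nrow(sim$sheet),
                   planted_edges = nrow(sim$truth$edges)))
    stage_log("simulate", t0, paste0(nrow(sim$genes), " genes, ",
                                     nrow(sim$sheet), " samples"))
  } else {
    sim <- NULL
    for (k in c("genome", "gff", "domains", "expr", "sheet")) {
      if (is.null(cfg[[k]])) abort(paste0("config field '", k,
                                          "' is required when simulate is disabled"))
    }
    soloist_refs <- if (!is.null(cfg$soloist_refs)) {
      x <- Biostrings::readAAStringSet(cfg$soloist_refs)
      as.character(x)
    } else NULL
  }

  # -- extract-promoters ------------------------------------------------
  t0 <- Sys.time()
  genome <- read_genome(cfg$genome)
  genes <- read_gff3(cfg$gff)
  promoters <- extract_promoters(genes, genome, cfg$window)
  prom_fa <- file.path(cfg$out_dir, "promoters.fa")
  write_promoters_fasta(promoters, prom_fa)
  add_stage("extract_promoters", prom_fa, list(promoters = nrow(promoters)))
  stage_log("extract-promoters", t0, paste0(nrow(promoters), " windows"))

  # -- classify ---------------------------------------------------------
  t0 <- Sys.time()
  hits <- read_domain_hits(cfg$domains, proteins = cfg$proteins)
  calls <- classify_subfamilies(hits, soloist_refs = soloist_refs)
  tandem <- detect_tandem_duplicates(calls, genes, hits)
  stats_tab <- gene_structure_stats(genes, calls)
  f_calls <- file.path(cfg$out_dir, "subfamily_calls.tsv")
  f_tandem <- file.path(cfg$out_dir, "tandem_pairs.tsv")
  f_stats <- file.path(cfg$out_dir, "gene_structure.tsv")
  readr::write_tsv(calls, f_calls, progress = FALSE)
  readr::write_tsv(tandem, f_tandem, progress = FALSE)
  readr::write_tsv(stats_tab, f_stats, progress = FALSE)
  add_stage("classify", c(f_calls, f_tandem, f_stats),
            list(family_genes = nrow(calls), tandem_pairs = nrow(tandem)))
  stage_log("classify", t0, paste0(nrow(calls), " family genes in, ",
                                   nrow(tandem), " tandem pairs out"))

  # -- tree -------------------------------------------------------------
  t0 <- Sys.time()
  ap2 <- hits %>% filter(.data$domain == "AP2") %>%
    group_by(.data$gene_id) %>% dplyr::slice(1) %>% ungroup()
  aln <- setNames(ap2$aligned_residues, ap2$gene_id)
  if (length(unique(nchar(aln))) != 1) {
    abort("domain regions are not aligned (unequal lengths); supply an aligned FASTA")
  }
  tree <- bootstrap_support(aln, n_reps = cfg$bootstrap, seed = cfg$seed)
  f_tree <- file.path(cfg$out_dir, "tree.nwk")
  write_tree_newick(tree, f_tree)
  add_stage("tree", f_tree, list(tips = length(tree$tip.label),
                                 bootstrap = cfg$bootstrap))
  stage_log("tree", t0, paste0(length(tree$tip.label), " tips, ",
                               cfg$bootstrap, " bootstrap replicates"))

  # -- scan -------------------------------------------------------------
  t0 <- Sys.time()
  motif_cat <- if (is.null(cfg$motifs)) default_motifs() else read_motifs(cfg$motifs)
  if (identical(cfg$scan_mode, "pwm")) {
    scan_hits <- bind_rows(lapply(seq_len(nrow(motif_cat)), function(i) {
      thr <- pwm_pvalue_threshold(motif_cat[i, ], alpha = cfg$alpha)
      scan_pwm(promoters, thr)
    }))
  } else {
    scan_hits <- scan_consensus(promoters, motif_cat)
  }
  candidates <- build_candidate_set(scan_hits, motif_cat$name,
                                    combine = cfg$candidate_rule,
                                    catalog = motif_cat)
  f_hits <- file.path(cfg$out_dir, "motif_hits.tsv")
  f_cand <- file.path(cfg$out_dir, "candidate_targets.tsv")
  readr::write_tsv(scan_hits, f_hits, progress = FALSE)
  readr::write_tsv(tibble(gene_id = candidates$genes), f_cand, progress = FALSE)
  add_stage("scan", c(f_hits, f_cand),
            list(hits = nrow(scan_hits), candidates = length(candidates$genes)))
  stage_log("scan", t0, paste0(nrow(scan_hits), " hits, ",
                               length(candidates$genes), " candidate targets"))

  # -- network ----------------------------------------------------------
  t0 <- Sys.time()
  ex <- read_expression(cfg$expr, cfg$sheet)
  expressed <- expression_filter(ex$expr, ex$sheet, fpkm_min = cfg$fpkm_min)
  eth <- call_differential(ex$expr, ex$sheet, c("ETH", "ck"), day = cfg$day,
                           lfc_min = cfg$lfc_min, fdr_max = cfg$fdr_max)
  aza <- call_differential(ex$expr, ex$sheet, c("Aza", "ck"), day = cfg$day,
                           lfc_min = cfg$lfc_min, fdr_max = cfg$fdr_max)
  fam_ids <- calls$gene_id
  classes <- classify_response_classes(eth[eth$gene_id %in% fam_ids, ],
                                       aza[aza$gene_id %in% fam_ids, ])
  edges <- infer_edges(classes, candidates, ex$expr, ex$sheet,
                       r_min = cfg$r_min, p_max = cfg$p_max,
                       sample_scope = cfg$sample_scope)
  hubs <- if (nrow(edges) > 0) score_hubs(edges) else NULL
  f_expd <- file.path(cfg$out_dir, "expressed_sets.tsv")
  f_de <- file.path(cfg$out_dir, "differential_calls.tsv")
  f_cls <- file.path(cfg$out_dir, "response_classes.tsv")
  f_edges <- file.path(cfg$out_dir, "edges.tsv")
  f_venn <- file.path(cfg$out_dir, "target_set_overlap.tsv")
  readr::write_tsv(expressed, f_expd, progress = FALSE)
  readr::write_tsv(bind_rows(eth, aza), f_de, progress = FALSE)
  readr::write_tsv(classes, f_cls, progress = FALSE)
  readr::write_tsv(edges, f_edges, progress = FALSE)
  venn_tab <- if (is.null(hubs)) tibble(region = character(), size = integer())
  else hubs$venn
  readr::write_tsv(venn_tab, f_venn, progress = FALSE)
  add_stage("network", c(f_expd, f_de, f_cls, f_edges, f_venn),
            list(de_calls = sum(eth$call != "ns") + sum(aza$call != "ns"),
                 k_classes = sum(classes$class != "none"),
                 edges = nrow(edges)))
  stage_log("network", t0, paste0(nrow(ex$expr), " genes in, ",
                                  nrow(edges), " edges out"))

  # -- enrich -----------------------------------------------------------
  t0 <- Sys.time()
  enr <- NULL
  f_enr <- file.path(cfg$out_dir, "enrichment.tsv")
  if (!is.null(cfg$annotation) && !is.null(hubs)) {
    ann <- readr::read_tsv(cfg$annotation, show_col_types = FALSE, progress = FALSE)
    universe <- candidates$genes
    enr <- bind_rows(lapply(c("K1", "K2", "K3"), function(k) {
      qs <- intersect(hubs$target_sets[[k]], universe)
      if (length(qs) == 0) return(NULL)
      res <- suppressWarnings(enrich_hypergeometric(qs, ann, universe))
      res$class <- k
      res
    }))
  }
  if (is.null(enr)) {
    enr <- tibble(term = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p = double(), fdr = double(),
                  class = character())
  }
  readr::write_tsv(enr, f_enr, progress = FALSE)
  add_stage("enrich", f_enr, list(terms_tested = nrow(enr)))
  stage_log("enrich", t0, paste0(nrow(enr), " class-term tests"))

  f_manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(list(
    config = cfg, manifest = manifest, manifest_path = f_manifest,
    genes = genes, promoters = promoters, calls = calls, tandem = tandem,
    tree = tree, hits = scan_hits, candidates = candidates,
    expressed = expressed, de = list(ETH = eth, Aza = aza),
    classes = classes, edges = edges, hubs = hubs, enrichment = enr,
    sim = sim
  ))
}
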