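# Seeded generator for a miniature study: genome + gene models, domain-hit
# tables covering all five subfamilies, promoters with planted cis-elements,
# and an FPKM matrix with planted treatment effects and planted
# regulator->target structure. Every planted object is recorded in a
# ground-truth table so each pipeline stage can be checked for exact
# recovery in the zero-noise limit.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# all stage-local generators derive from the one config seed by fixed offsets
stage_seed <- function(cfg, offset) {
  (cfg$seed + offset * 1009L) %% (.Machine$integer.max - 1L)
}

with_stage_seed <- function(cfg, offset, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(cfg, offset))
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a compact two-treatment cut-flower study: a handful
#' of chromosomes carrying 500 genes of which 40 are AP2/ERF family
#' members in the canonical subfamily proportions, 20 ERF/DREB regulators
#' with planted response classes, 10 planted targets per regulator whose
#' promoters carry both the GCC box and the DRE/CRT core, and an FPKM
#' matrix over tissues, six flower stages and a ck/ETH/Aza treatment
#' course (3 treatments x 3 days x 3 replicates). `edge_strength` is
#' derived from `target_edge_r` (planted regulator-target correlation,
#' default 0.95) unless supplied explicitly.
#'
#' @param seed Integer seed; all stage generators derive from it.
#' @param n_chroms,n_genes,n_family,n_tfs,n_targets_per_tf Cohort sizes.
#' @param subfamily_mix Proportions over AP2/DREB/ERF/RAV/Soloist.
#' @param tandem_pairs Number of adjacent same-subfamily pairs planted.
#' @param promoter_window Promoter size in bp.
#' @param motifs Motif catalog (`name`, `consensus`).
#' @param motif_plant_rate Per-motif probability that a background
#'   (non-family, non-target) gene promoter receives a planted instance.
#' @param class_counts Named counts for planted response classes
#'   (`K1`, `K2_opposite`, `K2_aza`, `K3`); must sum to `n_tfs`.
#' @param treatments,days,n_treat_reps,tissues,n_tissue_reps,stages,n_stage_reps
#'   Sample layout.
#' @param class_day Day at which planted responses carry the full effect
#'   (the day response classes are defined on); default 2.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2-FPKM distribution.
#' @param baseline_family_log2_mean,baseline_family_log2_sd Baseline for
#'   family genes (regulators are solidly expressed, as in real TF cohorts).
#' @param noise_sd Residual sd on log2 FPKM (>= 0).
#' @param day_profile_sd Sd of the per-gene day/stage profile shared across
#'   treatments (gives each family gene an individual temporal signature,
#'   so regulators sharing a response class remain distinguishable).
#' @param bg_profile_sd Sd of the treatment-course day profile of
#'   non-family genes (default 0: background genes are flat over the
#'   course up to noise).
#' @param effect_log2fc Planted treatment effect on log2 FPKM.
#' @param target_edge_r Planted regulator-target correlation magnitude.
#' @param edge_strength Override for the derived edge coefficient.
#' @param frac_de_background Fraction of background genes planted DE under
#'   a random single treatment.
#' @param n_terms Annotation terms emitted for the enrichment stage.
#' @param chrom_length Optional fixed chromosome length; genes that cannot
#'   fit raise an error (default: sized automatically).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 5, n_genes = 500, n_family = 40, n_tfs = 20,
                       n_targets_per_tf = 10,
                       subfamily_mix = c(AP2 = 35, DREB = 57, ERF = 125, RAV = 6, Soloist = 4) / 227,
                       tandem_pairs = 3,
                       promoter_window = 2000,
                       motifs = default_motifs(),
                       motif_plant_rate = 0.15,
                       class_counts = c(K1 = 6, K2_opposite = 2, K2_aza = 5, K3 = 7),
                       treatments = c("ck", "ETH", "Aza"), days = 1:3, n_treat_reps = 3,
                       class_day = 2,
                       tissues = c("root", "stem", "leaf"), n_tissue_reps = 3,
                       stages = paste0("S", 1:6), n_stage_reps = 3,
                       baseline_log2_mean = 3, baseline_log2_sd = 2,
                       baseline_family_log2_mean = 5, baseline_family_log2_sd = 1,
                       noise_sd = 0.2, day_profile_sd = 2,
                       bg_profile_sd = 0,
                       effect_log2fc = 3, target_edge_r = 0.95,
                       edge_strength = NULL,
                       frac_de_background = 0.05,
                       n_terms = 20,
                       chrom_length = NULL) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(subfamily_mix) - 1) < 1e-8,
            baseline_log2_sd > 0, day_profile_sd > 0, noise_sd >= 0,
            bg_profile_sd >= 0,
            n_family <= n_genes, "ck" %in% treatments, class_day %in% days,
            target_edge_r > 0, target_edge_r < 1)
  if (sum(class_counts) != n_tfs) {
    abort("class_counts must sum to n_tfs")
  }
  if (!all(names(class_counts) == c("K1", "K2_opposite", "K2_aza", "K3"))) {
    abort("class_counts must be named K1, K2_opposite, K2_aza, K3")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> seed %d: %d genes (%d family, %d TFs, %d targets/TF) on %d chromosomes;\n",
    "  effect %.3g log2FC, noise sd %.3g, day-profile sd %.3g, planted |r| %.3g\n"),
    x$seed, x$n_genes, x$n_family, x$n_tfs, x$n_targets_per_tf, x$n_chroms,
    x$effect_log2fc, x$noise_sd, x$day_profile_sd, x$target_edge_r))
  invisible(x)
}

subfamily_counts <- function(cfg) {
  # largest-remainder apportionment of n_family over the mix
  raw <- cfg$subfamily_mix * cfg$n_family
  base <- floor(raw)
  left <- cfg$n_family - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(cfg$subfamily_mix))
}

#' Simulate a miniature genome with gene models
#'
#' Uniform-background DNA; genes placed non-overlapping with at least
#' twice the promoter window between consecutive genes (so no two planted
#' promoters overlap), except for the planted tandem pairs, which sit
#' adjacently with a short gap. Family genes receive subfamily labels in
#' the configured proportions.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` (named character vector), `genes` (gene-model
#'   tibble as from [read_gff3()]), `truth` (list of ground-truth tibbles:
#'   `genes`, `tandem_pairs`).
#' @export
simulate_genome_and_genes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_stage_seed(cfg, 1, {
    ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    fam_idx <- sort(sample.int(cfg$n_genes, cfg$n_family))
    counts <- subfamily_counts(cfg)
    labels <- rep(NA_character_, cfg$n_genes)
    labels[fam_idx] <- sample(rep(names(counts), counts))

    # placement order = natural order, with tandem-pair partners pulled adjacent
    order_ids <- seq_len(cfg$n_genes)
    tandem <- list()
    if (cfg$tandem_pairs > 0) {
      pool_sub <- names(counts)[counts >= 2]
      if (length(pool_sub) == 0) abort("no subfamily has >= 2 members for tandem pairs")
      for (t in seq_len(cfg$tandem_pairs)) {
        sub <- sample(pool_sub, 1)
        members <- which(labels == sub)
        members <- members[!members %in% unlist(tandem)]
        if (length(members) < 2) {
          sub <- pool_sub[which.max(vapply(pool_sub, function(s)
            sum(!which(labels == s) %in% unlist(tandem)), numeric(1)))]
          members <- setdiff(which(labels == sub), unlist(tandem))
        }
        if (length(members) < 2) abort("not enough family genes for the requested tandem pairs")
        tandem[[t]] <- sample(members, 2)
      }
      for (t in seq_along(tandem)) {
        pr <- tandem[[t]]
        order_ids <- setdiff(order_ids, pr[2])
        at <- which(order_ids == pr[1])
        order_ids <- append(order_ids, pr[2], after = at)
      }
    }
    tandem_first <- vapply(tandem, `[`, integer(1), 1)

    # contiguous blocks of the placement order onto chromosomes
    chrom_of_block <- sort(rep_len(seq_len(cfg$n_chroms), length(order_ids)))
    w <- cfg$promoter_window
    rows <- vector("list", length(order_ids))
    chrom_len_needed <- numeric(cfg$n_chroms)
    pos <- rep(w + 200L, cfg$n_chroms)  # leading buffer per chromosome
    for (k in seq_along(order_ids)) {
      gi <- order_ids[k]
      chr <- chrom_of_block[k]
      glen <- sample(600:3000, 1)
      n_ex <- sample(1:5, 1, prob = c(0.35, 0.30, 0.15, 0.12, 0.08))
      strand <- sample(c("+", "-"), 1)
      g_start <- pos[chr]
      g_end <- g_start + glen
      # exon layout: alternate exon/intron lengths filling the span
      if (n_ex == 1) {
        ex <- matrix(as.integer(c(g_start, g_end)), ncol = 2)
      } else {
        cuts <- sort(sample(seq(g_start + 50, g_end - 50, by = 10), 2 * (n_ex - 1)))
        starts <- c(g_start, cuts[seq(2, length(cuts), by = 2)])
        ends <- c(cuts[seq(1, length(cuts), by = 2)], g_end)
        ex <- cbind(as.integer(starts), as.integer(ends))
      }
      colnames(ex) <- c("start", "end")
      gap <- if (gi %in% tandem_first) 200L else 2L * w + sample(0:500, 1)
      pos[chr] <- g_end + gap
      chrom_len_needed[chr] <- g_end + w + 200L
      rows[[k]] <- tibble(
        gene_id = ids[gi], chrom = paste0("chr", chr), strand = strand,
        start = as.integer(g_start), end = as.integer(g_end),
        tss = as.integer(if (strand == "+") g_start else g_end - 1L),
        mrna_id = paste0(ids[gi], ".t1"),
        n_exons = nrow(ex), n_cds = nrow(ex),
        exons = list(ex), cds = list(ex)
      )
    }
    genes <- arrange(bind_rows(rows), .data$chrom, .data$start)
    if (!is.null(cfg$chrom_length)) {
      if (any(chrom_len_needed > cfg$chrom_length)) {
        abort(paste0("genes cannot fit on chromosomes of length ", cfg$chrom_length,
                     "; need at least ", max(chrom_len_needed),
                     " -- use larger chromosomes or fewer genes"))
      }
      chrom_len_needed[] <- cfg$chrom_length
    }
    genome <- vapply(seq_len(cfg$n_chroms), function(chr) {
      paste(sample(DNA_BASES, ceiling(chrom_len_needed[chr]), replace = TRUE),
            collapse = "")
    }, character(1))
    names(genome) <- paste0("chr", seq_len(cfg$n_chroms))

    truth_genes <- tibble(gene_id = ids, subfamily = labels,
                          is_family = !is.na(labels))
    truth_tandem <- if (length(tandem) == 0) {
      tibble(gene_a = character(), gene_b = character(), subfamily = character())
    } else {
      bind_rows(lapply(tandem, function(pr) {
        ab <- sort(ids[pr])
        tibble(gene_a = ab[1], gene_b = ab[2], subfamily = labels[pr[1]])
      }))
    }
    list(genome = genome, genes = genes,
         truth = list(genes = truth_genes, tandem_pairs = truth_tandem))
  })
}

#' Simulate a domain-hit table from planted subfamily labels
#'
#' AP2-labelled genes get two AP2 envelopes; RAV one AP2 plus one B3;
#' DREB/ERF/Soloist a single AP2. Domain residues at positions 14/19 are
#' set to (V, E) for DREB and (A, D) for ERF; Soloist genes carry a
#' non-canonical pair and are near-copies (about 90% identity) of the
#' emitted Soloist reference sequences.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_genome_and_genes()].
#' @return List: `hits` (tibble in the plain-TSV hit schema),
#'   `soloist_refs` (character vector of reference domain sequences).
#' @export
simulate_domain_hits <- function(cfg, truth) {
  with_stage_seed(cfg, 2, {
    dom_len <- 60L
    set_pos <- function(s, p, ch) { substr(s, p, p) <- ch; s }
    # homologous domains: one family ancestor, diverged per subfamily and
    # again per gene, so pairwise identities are high within a subfamily
    # (~80%), moderate across subfamilies, and Poisson distances finite
    mutate_seq <- function(s, rate) {
      k <- round(rate * nchar(s))
      pos <- sample.int(nchar(s), k)
      ch <- strsplit(s, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(old)
        sample(setdiff(AA_LETTERS, old), 1), character(1))
      paste(ch, collapse = "")
    }
    ancestor <- paste(sample(AA_LETTERS, dom_len, replace = TRUE), collapse = "")
    sub_anc <- lapply(setNames(nm = names(cfg$subfamily_mix)), function(s)
      mutate_seq(ancestor, 0.25))
    ref <- set_pos(set_pos(sub_anc$Soloist, 14, "G"), 19, "K")
    fam <- truth$genes[truth$genes$is_family, ]
    rows <- list()
    for (i in seq_len(nrow(fam))) {
      g <- fam$gene_id[i]
      sub <- fam$subfamily[i]
      mk <- function(domain, from, to, res) {
        tibble(gene_id = g, domain = domain, env_from = from, env_to = to,
               aligned_residues = res, score = round(runif(1, 50, 200), 1))
      }
      gene_dom <- function(anc, r14 = NULL, r19 = NULL) {
        res <- mutate_seq(anc, 0.1)
        if (!is.null(r14)) res <- set_pos(res, 14, r14)
        if (!is.null(r19)) res <- set_pos(res, 19, r19)
        res
      }
      rows[[length(rows) + 1]] <- switch(sub,
        AP2 = bind_rows(mk("AP2", 5L, 64L, gene_dom(sub_anc$AP2)),
                        mk("AP2", 120L, 179L, gene_dom(sub_anc$AP2))),
        RAV = bind_rows(mk("AP2", 10L, 69L, gene_dom(sub_anc$RAV)),
                        mk("B3", 120L, 219L, paste(sample(AA_LETTERS, 100, TRUE), collapse = ""))),
        DREB = mk("AP2", 8L, 67L, gene_dom(sub_anc$DREB, "V", "E")),
        ERF = mk("AP2", 8L, 67L, gene_dom(sub_anc$ERF, "A", "D")),
        Soloist = mk("AP2", 8L, 67L, gene_dom(ref, "G", "K"))
      )
    }
    list(hits = arrange(bind_rows(rows), .data$gene_id, .data$env_from),
         soloist_refs = ref)
  })
}

resolve_iupac <- function(consensus) {
  sets <- iupac_sets()
  paste(vapply(strsplit(consensus, "")[[1]],
               function(l) sample(sets[[l]], 1), character(1)), collapse = "")
}

#' Plant cis-element instances into promoter windows
#'
#' Every planted target receives one instance of each catalog motif in its
#' promoter (random offset and strand); background genes (non-family,
#' non-target) receive instances at `motif_plant_rate` per motif. Planted
#' instances are written into the genome sequence; afterwards every
#' promoter is re-scanned naively so the ground truth records all
#' occurrences (planted and background alike).
#'
#' @param genome Named character vector (modified copy returned).
#' @param genes Gene-model tibble.
#' @param truth Truth list carrying `genes` and `edges` tables.
#' @param cfg A [sim_config()].
#' @return List: `genome` (modified), `planted` (tibble `gene_id`, `motif`,
#'   `offset`, `strand`, `word`), `occurrences` (tibble of all matches per
#'   promoter after planting).
#' @export
plant_motifs <- function(genome, genes, truth, cfg) {
  with_stage_seed(cfg, 3, {
    w_win <- cfg$promoter_window
    motifs <- cfg$motifs
    targets <- unique(truth$edges$target_id)
    tfs <- unique(truth$edges$tf_id)
    background <- setdiff(truth$genes$gene_id[!truth$genes$is_family], c(targets, tfs))
    plant_plan <- list()
    for (g in targets) {
      plant_plan[[g]] <- motifs$name
    }
    for (g in background) {
      picked <- motifs$name[runif(nrow(motifs)) < cfg$motif_plant_rate]
      if (length(picked) > 0) plant_plan[[g]] <- picked
    }
    planted <- list()
    gene_idx <- match(names(plant_plan), genes$gene_id)
    for (k in seq_along(plant_plan)) {
      gi <- gene_idx[k]
      g <- genes[gi, ]
      if (g$strand == "+" && g$tss - w_win < 0) next
      if (g$strand == "-" && g$tss + 1 + w_win > nchar(genome[[g$chrom]])) next
      # oriented promoter sequence
      if (g$strand == "+") {
        p_start <- g$tss - w_win
        oriented <- substr(genome[[g$chrom]], p_start + 1, g$tss)
      } else {
        p_start <- g$tss + 1
        oriented <- dna_revcomp(substr(genome[[g$chrom]], p_start + 1, p_start + w_win))
      }
      used <- integer(0)
      for (mname in plant_plan[[k]]) {
        cons <- motifs$consensus[motifs$name == mname]
        w <- nchar(cons)
        for (try in 1:50) {
          off <- sample.int(w_win - w + 1, 1) - 1L
          if (!any(abs(off - used) < w + 2)) break
        }
        used <- c(used, off)
        strand <- sample(c("+", "-"), 1)
        word <- resolve_iupac(cons)
        ins <- if (strand == "+") word else dna_revcomp(word)
        substr(oriented, off + 1, off + w) <- ins
        planted[[length(planted) + 1]] <- tibble(
          gene_id = g$gene_id, motif = mname, offset = off,
          strand = strand, word = word
        )
      }
      # write the edited window back in genome coordinates
      if (g$strand == "+") {
        substr(genome[[g$chrom]], p_start + 1, g$tss) <- oriented
      } else {
        substr(genome[[g$chrom]], p_start + 1, p_start + w_win) <- dna_revcomp(oriented)
      }
    }
    planted <- if (length(planted) == 0) {
      tibble(gene_id = character(), motif = character(), offset = integer(),
             strand = character(), word = character())
    } else bind_rows(planted)

    # record every occurrence (planted + background) by re-scanning the
    # finished promoters
    promoters <- extract_promoters(genes, genome, w_win)
    occurrences <- scan_consensus(promoters, motifs)[
      , c("gene_id", "motif", "offset", "strand")]
    list(genome = genome, planted = arrange(planted, .data$gene_id, .data$motif),
         occurrences = occurrences)
  })
}

#' Plant regulators, response classes, targets and annotation terms
#'
#' Chooses `n_tfs` regulators among the family's ERF/DREB members, assigns
#' the configured K1/K2 (opposite-direction and Aza-only)/K3 response
#' patterns, plants one differential-expression record per affected
#' treatment, draws disjoint target sets per regulator from the
#' non-family genes (with random activation/repression signs), plants
#' additional background DE genes, and emits a term-annotation map whose
#' first term is enriched in the planted targets.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [simulate_genome_and_genes()].
#' @return The truth list extended with `tf_classes`, `de`, `edges`,
#'   `annotation`.
#' @export
assign_regulation <- function(cfg, truth) {
  with_stage_seed(cfg, 4, {
    fam <- truth$genes
    tf_pool <- fam$gene_id[fam$is_family & fam$subfamily %in% c("ERF", "DREB")]
    if (length(tf_pool) < cfg$n_tfs) {
      abort("not enough ERF/DREB family genes for the requested number of regulators")
    }
    tfs <- sort(sample(tf_pool, cfg$n_tfs))
    subtype <- sample(rep(names(cfg$class_counts), cfg$class_counts))
    sign <- sample(c(1, -1), cfg$n_tfs, replace = TRUE)
    tf_classes <- tibble(
      tf_id = tfs, subtype = subtype,
      class = dplyr::recode(subtype, K1 = "K1", K2_opposite = "K2",
                            K2_aza = "K2", K3 = "K3"),
      direction = ifelse(sign > 0, "up", "down")
    )
    e <- cfg$effect_log2fc
    class_day <- cfg$class_day
    # day-resolved effects: the response at the classification day is the
    # full +/- effect; on other days each regulator follows its own random
    # trajectory (transient / delayed / biphasic responses), which keeps
    # same-class regulators' expression patterns distinguishable
    day_effects <- function(gene, treatment, s) {
      w <- stats::runif(length(cfg$days), -1, 1)
      w[cfg$days == class_day] <- 1
      tibble(gene_id = gene, treatment = treatment, day = cfg$days,
             effect = s * e * w)
    }
    de_rows <- list()
    for (i in seq_len(cfg$n_tfs)) {
      s <- sign[i]
      de_rows[[i]] <- switch(subtype[i],
        K1 = bind_rows(day_effects(tfs[i], "ETH", s), day_effects(tfs[i], "Aza", s)),
        K2_opposite = bind_rows(day_effects(tfs[i], "ETH", s), day_effects(tfs[i], "Aza", -s)),
        K2_aza = day_effects(tfs[i], "Aza", s),
        K3 = day_effects(tfs[i], "ETH", s)
      )
    }
    nonfam <- fam$gene_id[!fam$is_family]
    n_targets <- cfg$n_tfs * cfg$n_targets_per_tf
    if (length(nonfam) < n_targets) abort("not enough non-family genes for targets")
    target_ids <- sample(nonfam, n_targets)
    edges <- tibble(
      tf_id = rep(tfs, each = cfg$n_targets_per_tf),
      target_id = target_ids,
      sign = sample(c(1, -1), n_targets, replace = TRUE)
    )
    background <- setdiff(nonfam, target_ids)
    n_bg_de <- round(cfg$frac_de_background * length(background))
    if (n_bg_de > 0) {
      bg <- sample(background, n_bg_de)
      bg_trt <- sample(c("ETH", "Aza"), n_bg_de, replace = TRUE)
      bg_sign <- sample(c(1, -1), n_bg_de, replace = TRUE)
      for (b in seq_len(n_bg_de)) {
        de_rows[[length(de_rows) + 1]] <- day_effects(bg[b], bg_trt[b], bg_sign[b])
      }
    }
    de <- arrange(bind_rows(de_rows), .data$gene_id, .data$treatment, .data$day)

    ann_rows <- list()
    all_ids <- fam$gene_id
    hi <- max(2L, min(60L, length(all_ids) - 1L))
    lo <- min(10L, hi)
    for (t in seq_len(cfg$n_terms)) {
      term <- sprintf("term%02d", t)
      size <- sample(lo:hi, 1)
      members <- if (t == 1 && n_targets > 0) {
        # first term is enriched in the planted targets
        unique(c(sample(target_ids, min(ceiling(size / 2), n_targets)),
                 sample(all_ids, size)))
      } else {
        sample(all_ids, size)
      }
      ann_rows[[t]] <- tibble(term = term, gene_id = sort(members))
    }
    truth$tf_classes <- tf_classes
    truth$de <- de
    truth$edges <- arrange(edges, .data$tf_id, .data$target_id)
    truth$annotation <- bind_rows(ann_rows)
    truth
  })
}

build_sample_sheet <- function(cfg) {
  tiss <- tidyr::expand_grid(tissue = cfg$tissues, replicate = seq_len(cfg$n_tissue_reps)) %>%
    mutate(stage = NA_character_, treatment = NA_character_, day = NA_integer_,
           sample = paste0(.data$tissue, "_r", .data$replicate))
  stg <- tidyr::expand_grid(stage = cfg$stages, replicate = seq_len(cfg$n_stage_reps)) %>%
    mutate(tissue = "flower", treatment = NA_character_, day = NA_integer_,
           sample = paste0(.data$stage, "_r", .data$replicate))
  trt <- tidyr::expand_grid(treatment = cfg$treatments, day = cfg$days,
                            replicate = seq_len(cfg$n_treat_reps)) %>%
    mutate(tissue = "flower", stage = NA_character_,
           sample = paste0(.data$treatment, "_d", .data$day, "_r", .data$replicate))
  bind_rows(tiss, stg, trt) %>%
    select("sample", "tissue", "stage", "treatment", "day", "replicate")
}

# expected population variance of a regulator's log2 profile across the
# treatment-course samples: planted effect pattern + day profile + noise
tf_profile_var <- function(cfg, de_rows) {
  sheet <- build_sample_sheet(cfg)
  trt <- sheet[!is.na(sheet$treatment), ]
  eff <- rep(0, nrow(trt))
  for (i in seq_len(nrow(de_rows))) {
    eff[trt$treatment == de_rows$treatment[i] & trt$day == de_rows$day[i]] <-
      de_rows$effect[i]
  }
  v_pat <- mean(eff^2) - mean(eff)^2
  n_days <- length(unique(trt$day))
  v_day <- cfg$day_profile_sd^2 * (n_days - 1) / n_days  # family-gene profile
  v_pat + v_day + cfg$noise_sd^2
}

derive_edge_strength <- function(cfg, de_rows) {
  if (!is.null(cfg$edge_strength)) return(cfg$edge_strength)
  v_tf <- tf_profile_var(cfg, de_rows)
  r2 <- cfg$target_edge_r^2
  if (cfg$noise_sd == 0) return(1)
  sqrt(r2 * cfg$noise_sd^2 / ((1 - r2) * v_tf))
}

#' Simulate the FPKM expression matrix
#'
#' log2 FPKM = per-gene baseline + per-gene temporal profile (a day offset
#' shared across treatments, a stage offset, a tissue offset) + planted
#' treatment effect + regulator term + Gaussian noise; values are
#' exponentiated to FPKM. Planted targets carry no temporal profile of
#' their own: their profile is inherited through the regulator term
#' `sign x edge_strength x (TF deviation)`, which is what pins the
#' planted regulator-target correlation at the configured magnitude.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth list from [assign_regulation()].
#' @return List: `expr` (tibble `gene_id` + samples), `sheet`,
#'   `edge_strength` (named per regulator).
#' @export
simulate_expression <- function(cfg, truth) {
  with_stage_seed(cfg, 5, {
    sheet <- build_sample_sheet(cfg)
    ids <- truth$genes$gene_id
    n <- length(ids)
    ns <- nrow(sheet)
    targets <- unique(truth$edges$target_id)
    tfs <- unique(truth$edges$tf_id)

    is_fam <- truth$genes$is_family
    baseline <- ifelse(
      is_fam,
      rnorm(n, cfg$baseline_family_log2_mean, cfg$baseline_family_log2_sd),
      rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    )
    lmat <- matrix(baseline, n, ns)
    rownames(lmat) <- ids
    colnames(lmat) <- sheet$sample

    # per-gene profiles; planted targets carry none of their own (theirs is
    # inherited through the regulator term). The day profile is what keeps
    # same-class regulators distinguishable over the treatment course, so
    # family genes get a strong one and background genes essentially none;
    # stage and tissue structure is shared by all non-target genes.
    is_target <- ids %in% targets
    day_sd <- ifelse(is_target, 0, ifelse(is_fam, cfg$day_profile_sd, cfg$bg_profile_sd))
    other_sd <- ifelse(is_target, 0, ifelse(is_fam, cfg$day_profile_sd, 1))
    day_levels <- sort(unique(stats::na.omit(sheet$day)))
    for (d in day_levels) {
      off <- rnorm(n, 0, 1) * day_sd
      cols <- !is.na(sheet$day) & sheet$day == d
      lmat[, cols] <- lmat[, cols] + off
    }
    for (s in cfg$stages) {
      off <- rnorm(n, 0, 1) * other_sd
      cols <- !is.na(sheet$stage) & sheet$stage == s
      lmat[, cols] <- lmat[, cols] + off
    }
    for (tis in cfg$tissues) {
      off <- rnorm(n, 0, 1) * pmin(other_sd, 1)
      cols <- !is.na(sheet$tissue) & sheet$tissue == tis
      lmat[, cols] <- lmat[, cols] + off
    }

    # planted treatment effects, per treatment x day cell
    if (nrow(truth$de) > 0) {
      for (i in seq_len(nrow(truth$de))) {
        cols <- !is.na(sheet$treatment) & sheet$treatment == truth$de$treatment[i] &
          !is.na(sheet$day) & sheet$day == truth$de$day[i]
        lmat[truth$de$gene_id[i], cols] <- lmat[truth$de$gene_id[i], cols] +
          truth$de$effect[i]
      }
    }

    # regulator noise first, so targets inherit the realised TF profile
    noise <- matrix(rnorm(n * ns, 0, cfg$noise_sd), n, ns)
    lmat[tfs, ] <- lmat[tfs, , drop = FALSE] + noise[match(tfs, ids), , drop = FALSE]

    es <- vapply(tfs, function(tf) {
      derive_edge_strength(cfg, truth$de[truth$de$gene_id == tf, , drop = FALSE])
    }, numeric(1))
    if (nrow(truth$edges) > 0) {
      for (i in seq_len(nrow(truth$edges))) {
        tf <- truth$edges$tf_id[i]
        tg <- truth$edges$target_id[i]
        dev <- lmat[tf, ] - mean(lmat[tf, ])
        lmat[tg, ] <- lmat[tg, ] + truth$edges$sign[i] * es[[tf]] * dev
      }
    }
    rest <- setdiff(ids, tfs)
    lmat[rest, ] <- lmat[rest, , drop = FALSE] + noise[match(rest, ids), , drop = FALSE]

    fpkm <- 2^lmat
    expr <- as_tibble(fpkm, rownames = "gene_id")
    list(expr = expr, sheet = sheet, edge_strength = es)
  })
}

#' Generate the full synthetic dataset
#'
#' Runs every generator stage in order and (optionally) writes the exact
#' file formats the readers consume, plus `truth/*.tsv` ground-truth
#' tables.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List: `genome`, `genes`, `domain_hits`, `soloist_refs`,
#'   `promoters`, `planted_motifs`, `motif_occurrences`, `expr`, `sheet`,
#'   `edge_strength`, `truth` (list of tables), `files` (paths when
#'   `out_dir` given).
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  gg <- simulate_genome_and_genes(cfg)
  truth <- assign_regulation(cfg, gg$truth)
  dom <- simulate_domain_hits(cfg, truth)
  pm <- plant_motifs(gg$genome, gg$genes, truth, cfg)
  truth$planted_motifs <- pm$planted
  truth$motif_occurrences <- pm$occurrences
  ex <- simulate_expression(cfg, truth)
  promoters <- extract_promoters(gg$genes, pm$genome, cfg$promoter_window)
  out <- list(
    genome = pm$genome, genes = gg$genes, domain_hits = dom$hits,
    soloist_refs = dom$soloist_refs, promoters = promoters,
    planted_motifs = pm$planted, motif_occurrences = pm$occurrences,
    expr = ex$expr, sheet = ex$sheet, edge_strength = ex$edge_strength,
    truth = truth
  )
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome = file.path(out_dir, "genome.fa"),
      gff = file.path(out_dir, "genes.gff3"),
      domains = file.path(out_dir, "domain_hits.tsv"),
      motifs = file.path(out_dir, "motifs.tsv"),
      expr = file.path(out_dir, "expression.tsv"),
      sheet = file.path(out_dir, "samples.tsv"),
      annotation = file.path(out_dir, "annotation.tsv")
    )
    write_genome(out$genome, files[["genome"]])
    write_gff3(out$genes, files[["gff"]])
    readr::write_tsv(out$domain_hits, files[["domains"]], progress = FALSE)
    readr::write_tsv(cfg$motifs, files[["motifs"]], progress = FALSE)
    write_expression(out$expr, out$sheet, files[["expr"]], files[["sheet"]])
    readr::write_tsv(truth$annotation, files[["annotation"]], progress = FALSE)
    for (nm in c("genes", "tandem_pairs", "tf_classes", "de", "edges",
                 "planted_motifs", "motif_occurrences")) {
      readr::write_tsv(truth[[nm]], file.path(out_dir, "truth", paste0(nm, ".tsv")),
                       progress = FALSE)
    }
    writeLines(c(">soloist_ref", dom$soloist_refs),
               file.path(out_dir, "truth", "soloist_refs.fa"))
    out$files <- files
  }
  out
}
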