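# Expression filtering, two-treatment differential-expression calling,
# K1/K2/K3 response classification, correlation edge inference, hub
# scoring, and hypergeometric enrichment.

#' Per-group expressed-gene sets under an FPKM floor
#'
#' A gene counts as expressed in a group when its FPKM exceeds `fpkm_min`
#' (strictly) in at least one sample of the group. With the default
#' `group_by = "tissue"` the flower group pools all stage samples (S1-S6),
#' so a flower-expressed gene is one expressed at any stage.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param sheet Sample sheet.
#' @param group_by Sheet column defining groups; default `"tissue"`.
#' @param fpkm_min Strict floor; default 1.
#' @param min_samples Required samples above the floor; default 1. Set to
#'   `"mean"` to require the group mean to exceed the floor instead.
#' @return Tibble `group`, `gene_id`, one row per expressed gene per group.
#' @export
expression_filter <- function(expr, sheet, group_by = "tissue", fpkm_min = 1,
                              min_samples = 1) {
  if (!group_by %in% names(sheet)) abort(paste0("no '", group_by, "' column in sample sheet"))
  validate_expression(expr, sheet)
  m <- expr_matrix(expr)
  groups <- stats::na.omit(unique(sheet[[group_by]]))
  out <- list()
  for (g in groups) {
    samp <- sheet$sample[!is.na(sheet[[group_by]]) & sheet[[group_by]] == g]
    if (length(samp) == 0) abort(paste0("empty sample group: ", g))
    sub <- m[, samp, drop = FALSE]
    expressed <- if (identical(min_samples, "mean")) {
      rowMeans(sub) > fpkm_min
    } else {
      rowSums(sub > fpkm_min) >= min_samples
    }
    out[[g]] <- tibble(group = g, gene_id = rownames(m)[expressed])
  }
  bind_rows(out)
}

contrast_samples <- function(sheet, level, day) {
  if (!level %in% stats::na.omit(unique(sheet$treatment))) {
    abort(paste0("unknown treatment level: ", level))
  }
  sheet$sample[!is.na(sheet$treatment) & sheet$treatment == level &
                 !is.na(sheet$day) & sheet$day == day]
}

#' Call differential expression between two treatment groups
#'
#' Welch's t-test on `log2(FPKM + pseudocount)` per gene, with
#' Benjamini-Hochberg FDR across genes. The reported fold change is
#' `log2((mean_t + pseudocount) / (mean_c + pseudocount))` on the FPKM
#' scale. Calls: `up` when `log2fc > lfc_min` and `fdr < fdr_max`, `down`
#' symmetrically, otherwise `ns`. Degenerate cases are flagged: groups
#' with under two replicates give `p = NA` and the call falls back to the
#' fold change alone; zero-variance unequal groups give `p = 0`.
#'
#' @param expr Expression tibble.
#' @param sheet Sample sheet.
#' @param contrast Length-2 character, treatment vs control level, e.g.
#'   `c("ETH", "ck")`.
#' @param day Day of the contrast; default 2.
#' @param lfc_min Fold-change threshold (strict); default 1.
#' @param fdr_max FDR cutoff (strict); default 0.05.
#' @param pseudocount Added before logs and ratios; default 1.
#' @return Tibble of class `erf_de`: `gene_id`, `contrast`, `log2fc`, `p`,
#'   `fdr`, `call`, `flag`.
#' @export
call_differential <- function(expr, sheet, contrast = c("ETH", "ck"), day = 2,
                              lfc_min = 1, fdr_max = 0.05, pseudocount = 1) {
  stopifnot(length(contrast) == 2)
  validate_expression(expr, sheet)
  st <- contrast_samples(sheet, contrast[1], day)
  sc <- contrast_samples(sheet, contrast[2], day)
  if (length(st) == 0 || length(sc) == 0) {
    abort(paste0("no samples for contrast ", contrast[1], "_d", day,
                 "_vs_", contrast[2], "_d", day))
  }
  m <- expr_matrix(expr)
  mt <- m[, st, drop = FALSE]
  mc <- m[, sc, drop = FALSE]
  log2fc <- log2((rowMeans(mt) + pseudocount) / (rowMeans(mc) + pseudocount))

  lt <- log2(mt + pseudocount)
  lc <- log2(mc + pseudocount)
  nt <- ncol(lt); nc <- ncol(lc)
  flag <- rep("", nrow(m))
  if (nt < 2 || nc < 2) {
    p <- rep(NA_real_, nrow(m))
    flag[] <- "fc_only"
  } else {
    vt <- apply(lt, 1, var); vc <- apply(lc, 1, var)
    se2 <- vt / nt + vc / nc
    dmean <- rowMeans(lt) - rowMeans(lc)
    p <- rep(NA_real_, nrow(m))
    zero_var <- se2 == 0
    p[zero_var & dmean == 0] <- 1
    p[zero_var & dmean != 0] <- 0
    flag[zero_var] <- "degenerate_variance"
    ok <- !zero_var
    tstat <- dmean[ok] / sqrt(se2[ok])
    df <- se2[ok]^2 / ((vt[ok] / nt)^2 / (nt - 1) + (vc[ok] / nc)^2 / (nc - 1))
    p[ok] <- 2 * pt(-abs(tstat), df)
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  call <- dplyr::case_when(
    is.na(p) & log2fc > lfc_min ~ "up",
    is.na(p) & log2fc < -lfc_min ~ "down",
    is.na(p) ~ "ns",
    log2fc > lfc_min & fdr < fdr_max ~ "up",
    log2fc < -lfc_min & fdr < fdr_max ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(
    gene_id = rownames(m),
    contrast = paste0(contrast[1], "_d", day, "_vs_", contrast[2], "_d", day),
    log2fc = unname(log2fc), p = unname(p), fdr = unname(fdr),
    call = call, flag = flag
  )
  class(out) <- c("erf_de", class(out))
  out
}

#' Partition responsive factors into K1/K2/K3 classes
#'
#' Given same-day differential calls under the two treatments, each gene
#' is assigned: `K1` when differentially expressed under both treatments
#' in the same direction (shared, ethylene-dependent response), `K2` when
#' affected by both in opposite directions or by Aza only
#' (demethylation-dependent response), `K3` when affected by ETH only
#' (ethylene-only response), and `none` otherwise. The classes partition
#' the genes differentially expressed under at least one treatment.
#'
#' @param eth_calls,aza_calls `erf_de` tibbles over the same gene universe.
#' @return Tibble of class `erf_response`: `tf_id`, `class`, `eth_call`,
#'   `aza_call`.
#' @export
classify_response_classes <- function(eth_calls, aza_calls) {
  only_e <- setdiff(eth_calls$gene_id, aza_calls$gene_id)
  only_a <- setdiff(aza_calls$gene_id, eth_calls$gene_id)
  if (length(only_e) > 0 || length(only_a) > 0) {
    abort(paste0("call universes differ; only in ETH calls: {",
                 paste(head(only_e, 5), collapse = ", "), "}; only in Aza calls: {",
                 paste(head(only_a, 5), collapse = ", "), "}"))
  }
  j <- inner_join(
    eth_calls %>% select(gene_id = "gene_id", eth_call = "call"),
    aza_calls %>% select(gene_id = "gene_id", aza_call = "call"),
    by = "gene_id"
  )
  de <- c("up", "down")
  out <- j %>% mutate(
    class = dplyr::case_when(
      .data$eth_call %in% de & .data$aza_call %in% de & .data$eth_call == .data$aza_call ~ "K1",
      .data$eth_call %in% de & .data$aza_call %in% de ~ "K2",
      !(.data$eth_call %in% de) & .data$aza_call %in% de ~ "K2",
      .data$eth_call %in% de ~ "K3",
      TRUE ~ "none"
    )
  ) %>%
    select(tf_id = "gene_id", "class", "eth_call", "aza_call") %>%
    arrange(.data$tf_id)
  class(out) <- c("erf_response", class(out))
  out
}

#' Infer regulator-to-target edges by co-expression
#'
#' Pearson (default) or Spearman correlation between each regulator and
#' each candidate target across the chosen sample scope; the two-sided
#' p-value comes from `t = r sqrt((n-2)/(1-r^2))`. An edge is kept when
#' `|r| > r_min` and `p < p_max`. Zero-variance expression vectors yield
#' no edges (with a message). Self-pairs are skipped.
#'
#' @param tfs Character vector of regulator gene ids, or an `erf_response`
#'   tibble (class labels are then carried onto the edges).
#' @param candidates Candidate target set (`erf_candidate_set`, character
#'   vector, or tibble with `gene_id`).
#' @param expr Expression tibble.
#' @param sheet Sample sheet.
#' @param r_min Correlation threshold (strict); default 0.8.
#' @param p_max p-value cutoff (strict); default 0.05.
#' @param sample_scope `"treatment"` (default; all treatment-course
#'   samples), `"stages"` (flower stages), or `"all"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble of class `erf_edges`: `tf_id`, `target_id`, `class`,
#'   `r`, `p`, `n`.
#' @export
infer_edges <- function(tfs, candidates, expr, sheet, r_min = 0.8, p_max = 0.05,
                        sample_scope = c("treatment", "stages", "all"),
                        method = c("pearson", "spearman")) {
  sample_scope <- match.arg(sample_scope)
  method <- match.arg(method)
  classes <- NULL
  if (is.data.frame(tfs) && "tf_id" %in% names(tfs)) {
    classes <- tfs
    tf_ids <- tfs$tf_id[tfs$class %in% c("K1", "K2", "K3")]
  } else {
    tf_ids <- as.character(tfs)
  }
  cand <- candidate_genes(candidates)
  samp <- switch(sample_scope,
    treatment = sheet$sample[!is.na(sheet$treatment)],
    stages = sheet$sample[!is.na(sheet$stage)],
    all = sheet$sample
  )
  if (length(samp) < 3) abort("fewer than 3 samples in scope")
  m <- expr_matrix(expr)
  missing_tf <- setdiff(tf_ids, rownames(m))
  if (length(missing_tf) > 0) {
    abort(paste0("regulator(s) absent from expression matrix: ",
                 paste(missing_tf, collapse = ", ")))
  }
  cand <- intersect(cand, rownames(m))
  lm_ <- log2(m[, samp, drop = FALSE] + 1)
  tf_m <- t(lm_[tf_ids, , drop = FALSE])
  cd_m <- t(lm_[cand, , drop = FALSE])
  tf_const <- apply(tf_m, 2, function(x) var(x) == 0)
  cd_const <- apply(cd_m, 2, function(x) var(x) == 0)
  if (any(tf_const) || any(cd_const)) {
    inform(paste0(sum(tf_const) + sum(cd_const),
                  " zero-variance expression vector(s) excluded from edge inference"))
    tf_m <- tf_m[, !tf_const, drop = FALSE]
    cd_m <- cd_m[, !cd_const, drop = FALSE]
  }
  if (ncol(tf_m) == 0 || ncol(cd_m) == 0) {
    return(empty_edges(classes))
  }
  n <- nrow(tf_m)
  r <- cor(tf_m, cd_m, method = method)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  keep <- abs(r) > r_min & p < p_max
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble(
    tf_id = rownames(r)[idx[, 1]],
    target_id = colnames(r)[idx[, 2]],
    r = r[idx], p = p[idx], n = n
  )
  out <- out[out$tf_id != out$target_id, ]
  if (!is.null(classes)) {
    out <- left_join(out, classes %>% select("tf_id", "class"), by = "tf_id") %>%
      select("tf_id", "target_id", "class", "r", "p", "n")
  } else {
    out$class <- NA_character_
    out <- out %>% select("tf_id", "target_id", "class", "r", "p", "n")
  }
  out <- arrange(out, .data$tf_id, .data$target_id)
  class(out) <- c("erf_edges", class(out))
  out
}

empty_edges <- function(classes) {
  out <- tibble(tf_id = character(), target_id = character(),
                class = character(), r = double(), p = double(), n = integer())
  class(out) <- c("erf_edges", class(out))
  out
}

#' Node degrees and per-class target-set overlaps
#'
#' Degree of every regulator and target in the edge list, plus the Venn
#' decomposition of the K1/K2/K3 downstream target sets (each class's set
#' is the union of its member regulators' targets).
#'
#' @param edges `erf_edges` tibble.
#' @return List of class `erf_hubs`: `degrees` (tibble `node`, `role`,
#'   `degree`), `target_sets` (named list of character vectors),
#'   `venn` (tibble `region`, `size`), `union_size`.
#' @export
score_hubs <- function(edges) {
  if (nrow(edges) == 0) abort("empty edge list")
  deg_tf <- edges %>% group_by(node = .data$tf_id) %>%
    summarise(degree = dplyr::n(), .groups = "drop") %>% mutate(role = "tf")
  deg_tg <- edges %>% group_by(node = .data$target_id) %>%
    summarise(degree = dplyr::n(), .groups = "drop") %>% mutate(role = "target")
  degrees <- bind_rows(deg_tf, deg_tg) %>%
    select("node", "role", "degree") %>% arrange(dplyr::desc(.data$degree), .data$node)
  classes <- c("K1", "K2", "K3")
  sets <- lapply(classes, function(k) sort(unique(edges$target_id[!is.na(edges$class) & edges$class == k])))
  names(sets) <- classes
  all_targets <- sort(unique(unlist(sets)))
  member <- vapply(classes, function(k) all_targets %in% sets[[k]],
                   logical(length(all_targets)))
  if (length(all_targets) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, classes))
  membership <- apply(member, 1, function(row) paste(classes[row], collapse = "&"))
  venn_regions <- c("K1", "K2", "K3", "K1&K2", "K1&K3", "K2&K3", "K1&K2&K3")
  venn <- tibble(
    region = venn_regions,
    size = vapply(venn_regions, function(rg) sum(membership == rg), integer(1))
  )
  structure(list(
    degrees = degrees, target_sets = sets, venn = venn,
    union_size = length(all_targets)
  ), class = "erf_hubs")
}

#' @export
print.erf_hubs <- function(x, ...) {
  cat(sprintf("<erf_hubs> %d distinct targets; class set sizes: %s\n",
              x$union_size,
              paste(sprintf("%s=%d", names(x$target_sets),
                            lengths(x$target_sets)), collapse = ", ")))
  invisible(x)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For each term with `K` genes in the universe (size `N`) and `k` genes
#' in the query (size `n`), the upper-tail hypergeometric probability
#' `P(X >= k)` is computed, then Benjamini-Hochberg adjusted across terms.
#' Terms with no genes in the universe are skipped with a warning.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param annotation Tibble with columns `term`, `gene_id`.
#' @param universe Character vector of background genes.
#' @return Tibble of class `erf_enrichment`: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr`, sorted by `p`.
#' @export
enrich_hypergeometric <- function(query, annotation, universe) {
  query <- unique(query)
  universe <- unique(universe)
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0) {
    abort(paste0("query gene(s) outside the universe: ", paste(head(out_q, 5), collapse = ", ")))
  }
  ann <- annotation[annotation$gene_id %in% universe, ]
  empty <- setdiff(unique(annotation$term), unique(ann$term))
  if (length(empty) > 0) {
    warn(paste0("term(s) with no genes in universe skipped: ", paste(empty, collapse = ", ")))
  }
  N <- length(universe)
  n <- length(query)
  res <- ann %>% group_by(term = .data$term) %>%
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(intersect(.data$gene_id, query)),
              .groups = "drop") %>%
    mutate(n = n, N = N,
           p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
           fdr = p.adjust(.data$p, method = "BH")) %>%
    select("term", "k", "K", "n", "N", "p", "fdr") %>%
    arrange(.data$p, .data$term)
  class(res) <- c("erf_enrichment", class(res))
  res
}
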