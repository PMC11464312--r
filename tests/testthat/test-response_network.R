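# Expression filter, differential calls, K-class partition, edge
# inference, hubs, and enrichment.

test_that("the FPKM > 1 filter is strict and group-wise", {
  vals <- rbind(
    flower_only = c(0.5, 1.2, rep(0.5, 9)),      # 1.2 at stage S1 only
    boundary    = rep(1.0, 11),                  # exactly 1 everywhere
    root_only   = c(5, 0.2, rep(0.2, 9))
  )
  fx <- toy_expression(vals)
  sets <- expression_filter(fx$expr, fx$sheet)
  in_set <- function(g, grp) any(sets$gene_id == g & sets$group == grp)
  expect_true(in_set("flower_only", "flower"))
  expect_false(in_set("flower_only", "root"))
  expect_false(any(sets$gene_id == "boundary"))
  expect_true(in_set("root_only", "root"))
  expect_false(in_set("root_only", "flower"))
  # group-mean variant
  sets_m <- expression_filter(fx$expr, fx$sheet, min_samples = "mean")
  expect_true(any(sets_m$gene_id == "root_only" & sets_m$group == "root"))
})

test_that("differential calls follow the fold-change and FDR rules", {
  withr::with_seed(3, {
    n <- 60
    base <- matrix(2^rnorm(n * 11, 4, 0.15), n, 11)
    rownames(base) <- sprintf("g%02d", 1:n)
  })
  # plant one clean up gene (ETH columns 6:8) and one identical-groups gene
  base["g01", 6:8] <- base["g01", 3:5] * 16
  base["g02", 6:8] <- base["g02", 3:5]
  fx <- toy_expression(base)
  de <- call_differential(fx$expr, fx$sheet, c("ETH", "ck"), day = 2)
  expect_s3_class(de, "erf_de")
  expect_equal(de$contrast[1], "ETH_d2_vs_ck_d2")
  expect_equal(de$call[de$gene_id == "g01"], "up")
  expect_equal(de$call[de$gene_id == "g02"], "ns")
  expect_equal(de$log2fc[de$gene_id == "g02"], 0, tolerance = 0.25)
  # calls respect their own thresholds
  up <- de[de$call == "up", ]
  expect_true(all(up$log2fc > 1 & up$fdr < 0.05))

  # means 7 vs 1 with pseudocount 1 give log2fc = 2 exactly
  m2 <- matrix(1, 2, 11, dimnames = list(c("a", "b"), NULL))
  m2["a", 6:8] <- 7
  fx2 <- toy_expression(m2)
  de2 <- call_differential(fx2$expr, fx2$sheet, c("ETH", "ck"), day = 2)
  expect_equal(de2$log2fc[de2$gene_id == "a"], 2)
  # zero variance with unequal means: p = 0, flagged
  expect_equal(de2$p[de2$gene_id == "a"], 0)
  expect_equal(de2$flag[de2$gene_id == "a"], "degenerate_variance")
  expect_equal(de2$call[de2$gene_id == "a"], "up")

  expect_error(call_differential(fx$expr, fx$sheet, c("heat", "ck")), "heat")
})

test_that("single-replicate groups fall back to fold-change-only calls", {
  sheet <- tibble::tibble(
    sample = c("ck_d2_r1", "ETH_d2_r1"),
    tissue = "flower", stage = NA_character_,
    treatment = c("ck", "ETH"), day = 2L, replicate = 1L
  )
  expr <- tibble::tibble(gene_id = c("a", "b"),
                         ck_d2_r1 = c(1, 5), ETH_d2_r1 = c(7, 5))
  de <- call_differential(expr, sheet, c("ETH", "ck"), day = 2)
  expect_true(all(is.na(de$p)))
  expect_equal(de$flag, c("fc_only", "fc_only"))
  expect_equal(de$call, c("up", "ns"))
})

test_that("the null DE rate is controlled when nothing is planted", {
  # generator with no family, no regulators, no planted effects
  cfg <- sim_config(seed = 19, n_genes = 2000, n_family = 0, n_tfs = 0,
                    class_counts = c(K1 = 0, K2_opposite = 0, K2_aza = 0, K3 = 0),
                    n_targets_per_tf = 0, tandem_pairs = 0,
                    frac_de_background = 0)
  truth <- list(
    genes = tibble::tibble(gene_id = sprintf("n%04d", 1:2000),
                           subfamily = NA_character_, is_family = FALSE),
    de = tibble::tibble(gene_id = character(), treatment = character(),
                        day = integer(), effect = double()),
    edges = tibble::tibble(tf_id = character(), target_id = character(),
                           sign = double())
  )
  ex <- simulate_expression(cfg, truth)
  de <- call_differential(ex$expr, ex$sheet, c("ETH", "ck"), day = 2)
  frac <- mean(de$call != "ns")
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("worked K-class examples and the partition property hold", {
  mk_calls <- function(ids, calls, contrast) {
    out <- tibble::tibble(gene_id = ids, contrast = contrast,
                          log2fc = 0, p = 0.5, fdr = 0.5, call = calls,
                          flag = "")
    class(out) <- c("erf_de", class(out))
    out
  }
  ids <- paste0("t", 1:5)
  eth <- mk_calls(ids, c("up", "up", "ns", "down", "ns"), "ETH_d2_vs_ck_d2")
  aza <- mk_calls(ids, c("up", "down", "up", "ns", "ns"), "Aza_d2_vs_ck_d2")
  cl <- classify_response_classes(eth, aza)
  expect_equal(setNames(cl$class, cl$tf_id),
               c(t1 = "K1", t2 = "K2", t3 = "K2", t4 = "K3", t5 = "none"))

  expect_error(classify_response_classes(eth[1:4, ], aza), "universes differ")

  withr::with_seed(8, {
    for (case in 1:25) {
      n <- sample(5:40, 1)
      ids <- paste0("g", seq_len(n))
      eth <- mk_calls(ids, sample(c("up", "down", "ns"), n, TRUE), "e")
      aza <- mk_calls(ids, sample(c("up", "down", "ns"), n, TRUE), "a")
      cl <- classify_response_classes(eth, aza)
      de_any <- eth$call != "ns" | aza$call != "ns"
      # classes partition exactly the genes DE under at least one treatment
      expect_setequal(cl$tf_id[cl$class != "none"], ids[de_any])
      expect_equal(anyDuplicated(cl$tf_id), 0)
    }
  })
})

test_that("edge inference keeps perfect copies and inversions, drops flat rows", {
  samples27 <- tidyr::expand_grid(treatment = c("ck", "ETH", "Aza"),
                                  day = 1:3, replicate = 1:3)
  sheet <- tibble::tibble(
    sample = sprintf("%s_d%d_r%d", samples27$treatment, samples27$day,
                     samples27$replicate),
    tissue = "flower", stage = NA_character_,
    treatment = samples27$treatment, day = samples27$day,
    replicate = samples27$replicate
  )
  withr::with_seed(5, tfvals <- 2^rnorm(27, 4, 1))
  anti <- 2^(8 - log2(tfvals + 1)) - 1  # exactly inverted on the log2(x+1) scale
  vals <- rbind(tfvals, tfvals, anti, rep(3, 27), 2^rnorm(27, 4, 1))
  dimnames(vals) <- list(NULL, sheet$sample)
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = c("tf", "copy", "anti", "flat", "noise")),
    tibble::as_tibble(vals))
  expect_message(
    edges <- infer_edges("tf", c("copy", "anti", "flat", "noise"), expr, sheet),
    "zero-variance")
  expect_setequal(edges$target_id, c("copy", "anti"))
  expect_equal(edges$r[edges$target_id == "copy"], 1, tolerance = 1e-12)
  expect_equal(edges$r[edges$target_id == "anti"], -1, tolerance = 1e-12)
  expect_equal(edges$n, c(27L, 27L))
})

test_that("under independent noise the edge rate respects the p threshold", {
  # Monte-Carlo calibration of the correlation t approximation at n = 10
  withr::with_seed(77, {
    n <- 10
    n_pairs <- 10000
    a <- matrix(rnorm(n * n_pairs), n)
    b <- matrix(rnorm(n * n_pairs), n)
    r <- colSums(scale(a) * scale(b)) / (n - 1)
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), n - 2)
    rate <- mean(p < 0.05)
    expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs))
    expect_gte(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / n_pairs))
  })
})

test_that("hub scoring reports degrees and a well-formed target-set Venn", {
  edges <- tibble::tibble(
    tf_id = c(rep("hub", 5), "k3tf", "k3tf"),
    target_id = c("a", "b", "c", "d", "e", "b", "f"),
    class = c(rep("K1", 5), "K3", "K3"),
    r = 0.9, p = 0.001, n = 27L
  )
  class(edges) <- c("erf_edges", class(edges))
  hubs <- score_hubs(edges)
  expect_equal(hubs$degrees$degree[hubs$degrees$node == "hub"], 5L)
  expect_setequal(hubs$target_sets$K1, c("a", "b", "c", "d", "e"))
  expect_setequal(hubs$target_sets$K3, c("b", "f"))
  venn <- setNames(hubs$venn$size, hubs$venn$region)
  expect_equal(venn[["K1&K3"]], 1L)   # {b}
  expect_equal(venn[["K1"]], 4L)
  expect_equal(venn[["K2"]], 0L)      # empty class still well-formed
  expect_equal(hubs$union_size, 6L)
  expect_error(score_hubs(edges[0, ]), "empty")
})

test_that("hypergeometric enrichment matches the exact combinatorial example", {
  universe <- paste0("u", 1:10)
  ann <- tibble::tibble(term = "T1", gene_id = universe[1:5])
  query <- universe[1:4]
  res <- enrich_hypergeometric(query, ann, universe)
  # N=10, K=5, n=4, k=4: p = C(5,4)/C(10,4) = 5/210
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$k, 4L)

  # query = universe saturates every term, nothing significant
  ann2 <- tibble::tibble(term = rep(c("T1", "T2"), c(5, 3)),
                         gene_id = c(universe[1:5], universe[6:8]))
  res2 <- enrich_hypergeometric(universe, ann2, universe)
  expect_true(all(res2$p == 1))

  expect_error(enrich_hypergeometric(c("u1", "zz"), ann, universe), "outside")
  ann3 <- dplyr::bind_rows(ann2, tibble::tibble(term = "T3", gene_id = "not_there"))
  expect_warning(enrich_hypergeometric(query, ann3, universe), "T3")
})

test_that("an expected-sized overlap is never significant after adjustment", {
  # K = n = N/2 and k equal to the expected value K n / N
  for (N in c(8, 12, 16)) {
    universe <- paste0("u", seq_len(N))
    K <- N / 2
    k_exp <- K * K / N
    ann <- tibble::tibble(term = "T", gene_id = universe[1:K])
    query <- c(universe[seq_len(k_exp)], universe[K + seq_len(K - k_exp)])
    res <- enrich_hypergeometric(query, ann, universe)
    expect_gt(res$fdr, 0.05)
    expect_equal(res$p, oracle_hyper_upper(k_exp, K, K, N), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone in raw p-value rank", {
  withr::with_seed(12, {
    universe <- paste0("u", 1:40)
    ann <- dplyr::bind_rows(lapply(1:12, function(t) {
      tibble::tibble(term = paste0("T", t),
                     gene_id = sample(universe, sample(5:20, 1)))
    }))
    res <- enrich_hypergeometric(sample(universe, 15), ann, universe)
    expect_true(all(diff(res$fdr[order(res$p)]) >= -1e-12))
    expect_true(all(res$fdr >= res$p - 1e-12))
  })
})
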