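# Consensus scanning against a naive oracle, exact PWM p-values by DP
# against enumeration, and candidate-set logic.

prom1 <- function(seq, id = "g1") tibble::tibble(gene_id = id, sequence = seq)

test_that("worked consensus examples behave as specified", {
  gcc <- default_motifs()[1, ]
  dre <- default_motifs()[2, ]
  h <- scan_consensus(prom1("AAGCCGCCTT"), gcc)
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 2L)
  expect_equal(h$strand, "+")
  # R degeneracy: both ACCGAC and GCCGAC match
  expect_equal(scan_consensus(prom1("TTACCGACTT"), dre, both_strands = FALSE)$offset, 2L)
  expect_equal(scan_consensus(prom1("TTGCCGACTT"), dre, both_strands = FALSE)$offset, 2L)
  # GTCGGC is the reverse complement of GCCGAC: one minus-strand hit
  h2 <- scan_consensus(prom1("AAGTCGGCAA"), dre)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$offset, 2L)
  # N never matches, empty promoter gives an empty frame
  expect_equal(nrow(scan_consensus(prom1("AAGCCGNCTT"), gcc)), 0)
  expect_equal(nrow(scan_consensus(prom1(""), gcc)), 0)
})

test_that("consensus scan equals the naive per-offset oracle on 200 random cases", {
  withr::with_seed(101, {
    for (case in 1:200) {
      L <- sample(30:80, 1)
      seq <- random_dna(L, c("A", "C", "G", "T", "N"))
      w <- sample(4:8, 1)
      pat <- random_dna(w, c("A", "C", "G", "T", "R", "Y", "S", "W", "N"))
      motif <- tibble::tibble(name = "m", consensus = pat)
      got <- scan_consensus(prom1(seq), motif)
      want_plus <- oracle_match_offsets(seq, pat)
      want_minus <- oracle_match_offsets(seq, oracle_revcomp(pat))
      expect_equal(sort(got$offset[got$strand == "+"]), sort(want_plus))
      expect_equal(sort(got$offset[got$strand == "-"]), sort(want_minus))
    }
  })
})

test_that("scanning is strand-symmetric under sequence reversal", {
  withr::with_seed(55, {
    for (case in 1:30) {
      L <- sample(40:60, 1)
      seq <- random_dna(L)
      pat <- random_dna(6, c("A", "C", "G", "T", "R", "Y"))
      motif <- tibble::tibble(name = "m", consensus = pat)
      fwd <- scan_consensus(prom1(seq), motif)
      rev <- scan_consensus(prom1(oracle_revcomp(seq)), motif)
      # a + hit at offset o maps to a - hit at L - o - w in the mirrored scan
      mapped <- sort(L - fwd$offset[fwd$strand == "+"] - 6)
      expect_equal(sort(rev$offset[rev$strand == "-"]), mapped)
    }
  })
})

test_that("scan hits across multiple promoters map back to the right genes", {
  proms <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    sequence = c("AAGCCGCCTT", "GCCGCCGCCGCC", "TTTTTTTTTT")
  )
  h <- scan_consensus(proms, default_motifs()[1, ], both_strands = FALSE)
  expect_equal(h$gene_id, c("a", "b", "b", "b"))
  expect_equal(h$offset[h$gene_id == "b"], c(0L, 3L, 6L))  # overlaps count
  # no window may straddle two promoters: "TT|GC..." junctions never match
  proms2 <- tibble::tibble(gene_id = c("x", "y"), sequence = c("AAGCC", "GCCTT"))
  expect_equal(nrow(scan_consensus(proms2, default_motifs()[1, ])), 0)
})

test_that("single-base PWM threshold reproduces the textbook case", {
  counts <- matrix(c(0, 1, 0, 0), 4, 1, dimnames = list(c("A", "C", "G", "T"), NULL))
  thr <- pwm_pvalue_threshold(counts, alpha = 0.25)
  expect_equal(thr$achieved_alpha, 0.25, tolerance = 1e-12)
  hits <- scan_pwm(prom1("ACGT"), thr, both_strands = FALSE)
  expect_equal(hits$offset, 1L)  # only the C position passes
  expect_equal(hits$p_value, 0.25, tolerance = 1e-9)
})

test_that("the DP score distribution equals exhaustive enumeration (w <= 6)", {
  withr::with_seed(77, {
    for (w in 3:6) {
      counts <- matrix(rpois(4 * w, 5) + 0.5, 4, w,
                       dimnames = list(c("A", "C", "G", "T"), NULL))
      thr <- pwm_pvalue_threshold(counts, alpha = 0.01)
      expect_equal(sum(thr$dist$prob), 1, tolerance = 1e-12)
      # enumerate all 4^w words with the same discretized matrix
      im <- thr$int_matrix
      words <- as.matrix(expand.grid(rep(list(1:4), w)))
      scores <- vapply(seq_len(nrow(words)), function(i)
        sum(im[cbind(words[i, ], seq_len(w))]), numeric(1))
      enum <- table(scores) / 4^w
      dp <- thr$dist[thr$dist$prob > 0, ]
      expect_equal(as.integer(names(enum)), dp$score_int)
      expect_equal(unname(c(enum)), dp$prob, tolerance = 1e-12)
      # the threshold is the smallest score whose enumerated tail is <= alpha
      tail_enum <- vapply(dp$score_int, function(s) mean(scores >= s), numeric(1))
      pass <- dp$score_int[tail_enum <= 0.01]
      if (length(pass) == 0) {
        expect_gt(thr$threshold_int, max(dp$score_int))  # nothing can pass
      } else {
        expect_equal(thr$threshold_int, pass[1])
      }
    }
  })
})

test_that("alpha boundaries behave: alpha 1 admits everything, bad alpha errors", {
  counts <- consensus_to_counts("GCCGCC")
  thr <- pwm_pvalue_threshold(counts, alpha = 1)
  expect_equal(thr$threshold_int, thr$dist$score_int[1])
  expect_equal(thr$achieved_alpha, 1, tolerance = 1e-12)
  expect_error(pwm_pvalue_threshold(counts, alpha = 0), "alpha")
  expect_error(pwm_pvalue_threshold(counts, alpha = 1.5), "alpha")
})

test_that("PWM scanning finds planted words, skips Ns, handles short windows", {
  counts <- consensus_to_counts("GCCGCC") * 20
  thr <- pwm_pvalue_threshold(counts, alpha = 0.001)
  seq <- paste0(strrep("T", 40), "GCCGCC", strrep("T", 40))
  hits <- scan_pwm(prom1(seq), thr)
  expect_true(40L %in% hits$offset[hits$strand == "+"])
  top <- hits[which.max(hits$score), ]
  expect_equal(top$offset, 40L)
  expect_equal(nrow(scan_pwm(prom1(strrep("N", 50)), thr)), 0)
  expect_equal(nrow(scan_pwm(prom1("GCC"), thr)), 0)
})

test_that("PWM minus-strand hits equal plus-strand hits on the mirrored sequence", {
  withr::with_seed(91, {
    counts <- matrix(rpois(4 * 5, 4) + 0.5, 4, 5,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    thr <- pwm_pvalue_threshold(counts, alpha = 0.02)
    for (case in 1:10) {
      seq <- random_dna(80)
      got <- scan_pwm(prom1(seq), thr)
      mirrored <- scan_pwm(prom1(oracle_revcomp(seq)), thr, both_strands = FALSE)
      mapped <- sort(80 - got$offset[got$strand == "-"] - 5)
      expect_equal(sort(mirrored$offset), mapped)
    }
  })
})

test_that("candidate sets follow the boolean rule over element presence", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3"),
    motif = c("GCC_box", "GCC_box", "DRE_CRT", "DRE_CRT"),
    offset = 0L, strand = "+", score = NA_real_, p_value = NA_real_
  )
  both <- build_candidate_set(hits, c("GCC_box", "DRE_CRT"))
  expect_equal(both$genes, "g2")   # g1 has only the GCC box
  either <- build_candidate_set(hits, c("GCC_box", "DRE_CRT"), combine = "either")
  expect_setequal(either$genes, c("g1", "g2", "g3"))
  expect_true(all(both$genes %in% either$genes))
  expect_error(build_candidate_set(hits, c("GCC_box", "TATA")), "unknown")
  # a catalog makes a zero-hit motif known (and empties the intersection)
  cat <- tibble::tibble(name = c("GCC_box", "DRE_CRT", "TATA"),
                        consensus = c("GCCGCC", "RCCGAC", "TATAAA"))
  both2 <- build_candidate_set(hits, c("GCC_box", "TATA"), catalog = cat)
  expect_equal(length(both2$genes), 0)
})
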