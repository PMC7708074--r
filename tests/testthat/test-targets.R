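# counts object with exact RPM values via a filler transcript
rpm_fixture <- function(crac_rpm, rna_rpm, crac_lib = 1e7, rna_lib = 1e6) {
  crac <- vapply(crac_rpm, function(r) c(as.integer(r * crac_lib / 1e6)),
                 integer(1))
  rna <- vapply(rna_rpm, function(r) c(as.integer(r * rna_lib / 1e6)),
                integer(1))
  counts <- rbind(t1 = c(crac, rna),
                  fill = c(crac_lib - crac, rna_lib - rna))
  colnames(counts) <- c(sprintf("c%d", seq_along(crac)),
                        sprintf("r%d", seq_along(rna)))
  rpm_normalize(manual_counts(counts,
                              roles = c(rep("crac_tagged", length(crac)),
                                        rep("rnaseq", length(rna)))))
}

test_that("enrichment p-values match the long-hand Welch oracle", {
  x <- c(8, 8.1, 7.9, 8.05); y <- c(4.0, 4.1)
  expect_equal(as.numeric(enrichment_pvalue(x, y)),
               oracle_welch_p(log2(x + 0.5), log2(y + 0.5)))
  ## one-sided symmetry for continuous data
  p1 <- as.numeric(enrichment_pvalue(x, y))
  p2 <- as.numeric(enrichment_pvalue(y, x))
  expect_equal(p1 + p2, 1)
  ## degenerate rules
  expect_identical(as.numeric(enrichment_pvalue(c(5, 5), c(5, 5))), 1)
  d <- enrichment_pvalue(c(5, 5), c(2, 2))
  expect_identical(as.numeric(d), .Machine$double.xmin)
  expect_true(isTRUE(attr(d, "degenerate")))
  expect_identical(as.numeric(enrichment_pvalue(c(2, 2), c(5, 5))), 1)
  expect_error(enrichment_pvalue(5, c(1, 2)), ">= 2 values")
})

test_that("the three filters are strict inequalities and combine by conjunction", {
  ## CRAC RPM 200, ratio 2, p ~ 0 -> high confidence
  tc <- call_targets(rpm_fixture(rep(200, 4), rep(100, 2)),
                     method = "welch")
  r1 <- tc[tc$transcript_id == "t1", ]
  expect_true(r1$pass_rpm && r1$pass_ratio && r1$pass_p &&
                r1$high_confidence)
  expect_equal(r1$ratio, 2)

  ## CRAC RPM exactly 128 fails the strict RPM filter
  tc2 <- call_targets(rpm_fixture(rep(128, 4), rep(50, 2)),
                      method = "welch")
  r2 <- tc2[tc2$transcript_id == "t1", ]
  expect_identical(r2$crac_rpm, 128)
  expect_false(r2$pass_rpm)
  expect_false(r2$high_confidence)
  expect_true(r2$pass_ratio && r2$pass_p)

  ## ratio exactly 1.5 fails the strict ratio filter
  tc3 <- call_targets(rpm_fixture(rep(192, 4), rep(128, 2)),
                      method = "welch")
  r3 <- tc3[tc3$transcript_id == "t1", ]
  expect_identical(r3$ratio, 1.5)
  expect_false(r3$pass_ratio)
  expect_false(r3$high_confidence)

  ## zero RNA-seq: infinite ratio passes only with the RPM filter
  tc4 <- call_targets(rpm_fixture(rep(200, 4), rep(0, 2)),
                      method = "welch")
  r4 <- tc4[tc4$transcript_id == "t1", ]
  expect_true(is.infinite(r4$ratio) && r4$pass_ratio)
  tc5 <- call_targets(rpm_fixture(rep(100, 4), rep(0, 2)),
                      method = "welch")
  r5 <- tc5[tc5$transcript_id == "t1", ]
  expect_true(is.infinite(r5$ratio) && !r5$pass_ratio)

  norna <- rpm_fixture(rep(200, 4), rep(100, 2))
  norna$samples$role[5:6] <- "riboseq"
  expect_error(call_targets(norna), "rnaseq")
})

test_that("raising any threshold never increases the number of calls", {
  cfg <- sim_config(n_mrna = 300L,
                    n_ncrna = c(rRNA = 3L, tRNA = 6L, snRNA = 2L,
                                snoRNA = 4L, other = 2L),
                    reads_per_sample = 2e5, n_true_targets = 20L,
                    target_enrichment = c(4, 8), seed = 55L)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_crac_experiment(sim, control = FALSE)
  cm <- rpm_normalize(count_per_transcript(reads, sim$annotation))
  cm <- add_counts(cm, simulate_quant_experiment(sim, "rnaseq"), "rnaseq")
  cmm <- mrna_counts(cm, sim$annotation)
  base <- sum(call_targets(cmm)$high_confidence)
  for (th in list(calling_thresholds(rpm = 256),
                  calling_thresholds(ratio = 2.5),
                  calling_thresholds(p = 0.001)))
    expect_lte(sum(call_targets(cmm, th)$high_confidence), base)
})

test_that("strongly enriched spike-ins are recovered at default thresholds", {
  cfg <- sim_config(n_mrna = 800L,
                    n_ncrna = c(rRNA = 8L, tRNA = 20L, snRNA = 2L,
                                snoRNA = 10L, other = 4L),
                    reads_per_sample = 5e5, n_true_targets = 30L,
                    target_enrichment = c(8, 10), seed = 77L)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_crac_experiment(sim, control = FALSE)
  cm <- rpm_normalize(count_per_transcript(reads, sim$annotation))
  cm <- add_counts(cm, simulate_quant_experiment(sim, "rnaseq"), "rnaseq")
  tc <- call_targets(mrna_counts(cm, sim$annotation))
  truth <- sim$truth$table
  called <- tc$transcript_id[tc$high_confidence]
  tp <- sum(called %in% truth$id[truth$is_target])
  expect_gte(tp / length(called), 0.85)
  expect_gte(tp / sum(truth$is_target), 0.8)
  ## output ordering contract: ascending p, ties by id
  expect_identical(order(tc$p_value, tc$transcript_id), seq_len(nrow(tc)))
})

test_that("coverage tracks equal interval arithmetic and a per-base counter", {
  r1 <- make_reads(10)
  expect_equal(export_track(r1),
               data.frame(chrom = "chr1", start = 10, end = 40,
                          count = 1))
  r2 <- make_reads(c(10, 20))
  expect_equal(export_track(r2)[, c("start", "end", "count")],
               data.frame(start = c(10, 20, 40), end = c(20, 40, 50),
                          count = c(1, 2, 1)))

  set.seed(99)
  s0 <- sample(0:900, 100, replace = TRUE)
  rr <- make_reads(s0, width = 25)
  tr <- export_track(rr, chrom = "chr1")
  v <- oracle_coverage(s0, s0 + 25, 1000)
  recon <- integer(1000)
  for (i in seq_len(nrow(tr)))
    recon[(tr$start[i] + 1):tr$end[i]] <- tr$count[i]
  expect_identical(recon, v)

  expect_error(export_track(rr, chrom = "chrZ"), "chrZ")

  p <- tempfile(fileext = ".bedgraph")
  export_track(r1, path = p)
  expect_identical(readLines(p), "chr1\t10\t40\t1")
})
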