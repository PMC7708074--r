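test_that("bin_index follows the region-rescaling rule and its edge cases", {
  t <- make_tx(exons = cbind(0, 1200), utr5 = 100, cds = 900, utr3 = 200)
  expect_identical(bin_index(t, 50L), 5L)
  expect_identical(bin_index(t, 100L), 10L)          # first CDS base
  expect_identical(bin_index(t, 1199L), 119L)        # last 3'UTR base clips
  expect_error(bin_index(t, 1200L), "out of range")
  flagged <- make_tx(utr5 = 0, cds = 250, utr3 = 50)
  expect_error(bin_index(flagged, 0L), "zero-length region")
})

test_that("bin_index equals the exhaustive per-position oracle on random transcripts", {
  set.seed(41)
  for (k in 1:10) {
    t <- random_mrna(sprintf("b%d", k))
    m <- 0:(t$mature_len - 1L)
    expect_identical(bin_index(t, m),
                     vapply(m, function(x) as.integer(oracle_bin(t, x)),
                            integer(1)))
  }
})

test_that("transcript profiles are unit-sum histograms matching a brute-force count", {
  t <- make_tx(exons = cbind(0, 1200), utr5 = 100, cds = 900, utr3 = 200)
  ## mature 1100 falls in 3'UTR bin 115 (0-based): d = 100, floor(100*10/200)
  expect_identical(bin_index(t, 1100L), 115L)
  p1 <- transcript_profile(t, rep(1100L, 4))
  expect_identical(p1[116], 1)
  expect_identical(sum(p1), 1)
  p2 <- transcript_profile(t, c(50L, 1100L))
  expect_identical(p2[6], 0.5)
  expect_identical(p2[116], 0.5)

  set.seed(51)
  pos <- sample(0:(t$mature_len - 1L), 50, replace = TRUE)
  p <- transcript_profile(t, pos)
  manual <- tabulate(vapply(pos, function(m) oracle_bin(t, m) + 1,
                            numeric(1)), 120) / 50
  expect_equal(p, manual)
  expect_error(transcript_profile(t, integer(0)), "at least one")
})

test_that("profiles from reads are unit-sum and the aggregate is an unweighted mean", {
  cfg <- sim_config(n_mrna = 100L,
                    n_ncrna = c(rRNA = 2L, tRNA = 4L, snRNA = 1L,
                                snoRNA = 2L, other = 1L),
                    reads_per_sample = 5e4, n_true_targets = 5L, seed = 61L)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_crac_experiment(sim, control = FALSE)
  profs <- metagene_profiles(reads, sim$annotation)
  expect_true(all(abs(rowSums(profs$profile) - 1) < 1e-9))
  cm <- rpm_normalize(count_per_transcript(reads, sim$annotation))
  agg <- aggregate_metagene(profs, cm, min_rpm = 100)
  expect_lt(abs(sum(agg$values) - 1), 1e-9)
  expect_equal(agg$values,
               colMeans(profs$profile[agg$transcript_ids, ]))

  ## two identical profiles average to themselves
  two <- profs
  two$profile <- profs$profile[c(1, 1), ]
  rownames(two$profile) <- c("x1", "x2")
  cm2 <- manual_counts(cbind(s1 = c(x1 = 1000L, x2 = 1000L)),
                       roles = "crac_tagged")
  agg2 <- aggregate_metagene(two, cm2, min_rpm = 100)
  expect_equal(agg2$values, unname(profs$profile[1, ]))
  expect_identical(agg2$n_transcripts, 2L)

  expect_error(aggregate_metagene(profs, cm, min_rpm = 1e9),
               "no transcript passes")
})

test_that("flagged transcripts are excluded from profiles and reported", {
  ann <- build_annotation(list(
    make_tx("ok", exons = cbind(0, 300)),
    make_tx("noutr", exons = cbind(1000, 1250), utr5 = 0, cds = 200,
            utr3 = 50)), TOY_GENOME)
  reads <- make_reads(c(100, 1100), width = 20)
  profs <- metagene_profiles(reads, ann, samples = "s1")
  expect_identical(rownames(profs$profile), "ok")
  expect_identical(profs$skipped, "noutr")
})

test_that("adding 3'UTR reads never decreases the 3'UTR profile mass", {
  t <- make_tx(exons = cbind(0, 1200), utr5 = 100, cds = 900, utr3 = 200)
  set.seed(71)
  pos <- sample(0:(t$mature_len - 1L), 30, replace = TRUE)
  mass3 <- function(p) sum(p[111:120])
  base <- mass3(transcript_profile(t, pos))
  for (extra in c(1, 5, 20)) {
    pos2 <- c(pos, sample(1000:1199, extra, replace = TRUE))
    expect_gte(mass3(transcript_profile(t, pos2)), base)
  }
})

test_that("region fractions are exact arithmetic on the counts", {
  rc <- data.frame(transcript_id = c("a", "b"), sample = "s",
                   utr5 = c(5L, 0L), cds = c(20L, 0L), utr3 = c(75L, 10L))
  rf <- region_fraction(rc)
  expect_identical(rf$f5, c(0.05, 0))
  expect_identical(rf$fcds, c(0.20, 0))
  expect_identical(rf$f3, c(0.75, 1))
  expect_error(region_fraction(rc[integer(0), ]), "no transcripts")
})

test_that("boxplot summaries use type-7 quartiles and 1.5 IQR whiskers", {
  b <- boxplot_summary(1:9)
  expect_identical(c(b$q1, b$median, b$q3), c(3, 5, 7))
  expect_equal(c(b$whisker_low, b$whisker_high), c(1, 9))
  expect_identical(length(b$outliers), 0L)

  bc <- boxplot_summary(rep(4.2, 5))
  expect_identical(c(bc$q1, bc$median, bc$q3, bc$whisker_low,
                     bc$whisker_high), rep(4.2, 5))

  v <- c(1:9, 100)
  bo <- boxplot_summary(v)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_identical(c(bo$q1, bo$q3), q)
  expect_identical(bo$outliers, 100)       # beyond q3 + 1.5 IQR
  expect_identical(bo$whisker_high, 9)     # whisker is an attained point
  expect_error(boxplot_summary(numeric(0)), "at least one")
})

test_that("heatmap rows are unit-sum and ordered by 3'UTR fraction", {
  t <- make_tx(exons = cbind(0, 1200), utr5 = 100, cds = 900, utr3 = 200)
  mk <- function(n3, n5) c(rep(50L, n5), rep(1150L, n3))
  profs <- structure(list(
    profile = rbind(hi = transcript_profile(t, mk(9, 1)),
                    lo = transcript_profile(t, mk(1, 9)),
                    mid = transcript_profile(t, mk(5, 5))),
    scheme = bin_scheme(), n_reads = c(10L, 10L, 10L),
    skipped = character(0)), class = "metagene_profiles")
  h <- heatmap_matrix(profs, "by_3utr_fraction")
  expect_identical(rownames(h), c("hi", "mid", "lo"))
  expect_identical(rownames(heatmap_matrix(profs, "by_id")),
                   c("hi", "lo", "mid"))
  expect_true(all(abs(rowSums(h) - 1) < 1e-9))
  one <- profs; one$profile <- profs$profile[1, , drop = FALSE]
  expect_identical(dim(heatmap_matrix(one)), c(1L, 120L))
})
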