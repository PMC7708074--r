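# two overlapping same-strand transcripts plus ncRNA for priority tests
overlap_ann <- function() {
  build_annotation(list(
    make_tx("mA", exons = cbind(100, 400), utr5 = 50, cds = 200, utr3 = 50),
    make_tx("rB", exons = cbind(300, 500), class = "rRNA"),
    make_tx("mC", exons = cbind(380, 680), utr5 = 50, cds = 200, utr3 = 50)),
    TOY_GENOME)
}

test_that("class priority and intergenic assignment follow the stated rules", {
  ann <- overlap_ann()
  ## midpoint 315 inside both mA (mRNA) and rB (rRNA) -> rRNA wins
  r <- make_reads(300)
  sh <- classify_reads(r, ann)
  expect_identical(sh$count[sh$class == "rRNA"], 1L)
  expect_identical(sum(sh$count[sh$class == "mRNA"]), 0L)

  r2 <- make_reads(c(5000, 6000, 7000))
  sh2 <- classify_reads(r2, ann)
  expect_identical(sh2$fraction[sh2$class == "intergenic"], 1)
  expect_identical(sum(sh2$fraction), 1)

  ## 10 reads: 6 mRNA, 3 rRNA, 1 intergenic by construction
  r3 <- make_reads(c(rep(150, 6), rep(430, 3), 5000))
  sh3 <- classify_reads(r3, ann)
  expect_identical(sh3$fraction[sh3$class == "mRNA"], 0.6)
  expect_identical(sh3$fraction[sh3$class == "rRNA"], 0.3)
  expect_identical(sh3$fraction[sh3$class == "intergenic"], 0.1)

  expect_error(classify_reads(make_reads(10, chrom = "chrZ",
                                         genome = c(chrZ = 100)), ann),
               "chrZ")
})

test_that("midpoint counting resolves ties by overlap then id", {
  ann <- overlap_ann()
  ## read [380,410): midpoint 394 in mA and mC; overlap mA = 20, mC = 30
  cm <- count_per_transcript(make_reads(380), ann)
  expect_identical(cm$counts["mC", 1], 1L)
  ## read [370,400): midpoint 384 in both; overlap mA = 30 > mC = 20
  cm2 <- count_per_transcript(make_reads(370), ann)
  expect_identical(cm2$counts["mA", 1], 1L)
  ## antisense read is unassigned
  cm3 <- count_per_transcript(make_reads(150, strand = "-"), ann)
  expect_identical(sum(cm3$counts), 0L)
  expect_identical(unname(cm3$lib_size[1]), 0)
})

test_that("equal-overlap ties go to the lexicographically smaller id and are order-free", {
  ann <- build_annotation(list(
    make_tx("tB", exons = cbind(100, 400), utr5 = 50, cds = 200, utr3 = 50),
    make_tx("tA", exons = cbind(100, 400), utr5 = 100, cds = 100,
            utr3 = 100)), TOY_GENOME)
  cm <- count_per_transcript(make_reads(200), ann)
  expect_identical(cm$counts["tA", 1], 1L)
})

test_that("counting matches the per-read brute-force oracle on a random fixture", {
  set.seed(21)
  models <- c(lapply(1:6, function(i) random_mrna(sprintf("m%02d", i))),
              list(make_tx("rr1", exons = cbind(200, 420), class = "rRNA"),
                   make_tx("tt1", exons = cbind(600, 700), class = "tRNA",
                           strand = "-")))
  ann <- build_annotation(models, TOY_GENOME)
  n <- 100
  s0 <- sample(0:990, n, replace = TRUE)
  str <- sample(c("+", "-"), n, replace = TRUE)
  reads <- make_reads(s0, width = 10, strand = str,
                      sample = sample(c("sa", "sb"), n, replace = TRUE))
  cm <- count_per_transcript(reads, ann)

  expected <- matrix(0L, nrow(ann$transcripts), ncol(cm$counts),
                     dimnames = dimnames(cm$counts))
  samp <- as.character(S4Vectors::mcols(reads)$sample)
  for (i in seq_len(n)) {
    tx <- oracle_assign_read("chr1", s0[i], s0[i] + 10, str[i], models)
    if (!is.na(tx)) expected[tx, samp[i]] <- expected[tx, samp[i]] + 1L
  }
  expect_identical(cm$counts, expected)
  expect_identical(unname(cm$lib_size), unname(colSums(expected)))

  ## order invariance
  perm <- sample(n)
  cmp <- count_per_transcript(reads[perm], ann)
  expect_identical(cmp$counts, cm$counts)
})

test_that("region tallies agree with a brute-force per-read tally and sum to counts", {
  t <- make_tx("tx", exons = cbind(1000, 1360), utr5 = 60, cds = 240,
               utr3 = 60)
  ann <- build_annotation(list(t), TOY_GENOME)
  set.seed(31)
  mids <- sample(0:359, 20, replace = TRUE)     # mature midpoint targets
  ## place width-1 reads exactly at the genomic image of each mature midpoint
  g <- vapply(mids, function(m) to_genomic_coord(t, m), integer(1))
  reads <- make_reads(g, width = 1)
  rc <- count_by_region(reads, ann)
  manual <- table(factor(ifelse(mids < 60, "utr5",
                                ifelse(mids < 300, "cds", "utr3")),
                         levels = c("utr5", "cds", "utr3")))
  expect_identical(rc$utr5, unname(manual[["utr5"]]))
  expect_identical(rc$cds, unname(manual[["cds"]]))
  expect_identical(rc$utr3, unname(manual[["utr3"]]))

  cm <- count_per_transcript(reads, ann)
  expect_identical(rc$utr5 + rc$cds + rc$utr3, unname(cm$counts["tx", 1]))

  ## all reads placed in the 3'UTR by construction
  g3 <- vapply(300:309, function(m) to_genomic_coord(t, m), integer(1))
  rc3 <- count_by_region(make_reads(g3, width = 1), ann)
  expect_identical(c(rc3$utr5, rc3$cds, rc3$utr3), c(0L, 0L, 10L))
})

test_that("RPM normalization is exact arithmetic and preserves counts", {
  counts <- cbind(s1 = c(5L, 49995L), s2 = c(0L, 50000L))
  rownames(counts) <- c("a", "b")
  cm <- manual_counts(counts, roles = c("crac_tagged", "crac_tagged"))
  cm <- rpm_normalize(cm)
  expect_identical(cm$rpm["a", "s1"], 100)
  expect_identical(cm$rpm["a", "s2"], 0)
  expect_identical(unname(colSums(cm$rpm)), c(1e6, 1e6))
  expect_identical(cm$counts, counts)

  bad <- manual_counts(cbind(s1 = c(0L, 0L)), roles = "crac_tagged")
  expect_error(rpm_normalize(bad), "zero library size")
})

test_that("multi-mapped reads are excluded from all tallies", {
  ann <- overlap_ann()
  r <- make_reads(c(150, 150))
  S4Vectors::mcols(r)$unique <- c(TRUE, FALSE)
  cm <- count_per_transcript(r, ann)
  expect_identical(sum(cm$counts), 1L)
  sh <- classify_reads(r, ann)
  expect_identical(sum(sh$count), 1L)
})
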