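test_that("GFF3 coordinates are converted to 0-based half-open on load", {
  gff <- c("##gff-version 3",
           paste("chr1", "test", "gene", 1, 10, ".", "+", ".",
                 "ID=gene:g1", sep = "\t"),
           paste("chr1", "test", "mRNA", 1, 10, ".", "+", ".",
                 "ID=t1;Parent=gene:g1", sep = "\t"),
           paste("chr1", "test", "exon", 1, 10, ".", "+", ".",
                 "ID=t1.e1;Parent=t1", sep = "\t"),
           paste("chr1", "test", "five_prime_UTR", 1, 2, ".", "+", ".",
                 "ID=t1.u5;Parent=t1", sep = "\t"),
           paste("chr1", "test", "CDS", 3, 8, ".", "+", "0",
                 "ID=t1.c;Parent=t1", sep = "\t"),
           paste("chr1", "test", "three_prime_UTR", 9, 10, ".", "+", ".",
                 "ID=t1.u3;Parent=t1", sep = "\t"))
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  ann <- load_annotation(f, NULL)
  t1 <- transcript(ann, "t1")
  expect_identical(unname(t1$exons[1, ]), c(0L, 10L))
  expect_identical(t1$utr5_len, 2L)
  expect_identical(t1$cds_len, 6L)
  expect_identical(t1$utr3_len, 2L)
  expect_identical(t1$gene, "g1")
})

test_that("UTR lengths are derived from CDS extent when UTR features are absent", {
  gff <- c("##gff-version 3",
           paste("chr1", "test", "mRNA", 101, 300, ".", "-", ".",
                 "ID=t1", sep = "\t"),
           paste("chr1", "test", "exon", 101, 300, ".", "-", ".",
                 "ID=t1.e1;Parent=t1", sep = "\t"),
           paste("chr1", "test", "CDS", 151, 250, ".", "-", "0",
                 "ID=t1.c;Parent=t1", sep = "\t"))
  f <- tempfile(fileext = ".gff3")
  writeLines(gff, f)
  ann <- load_annotation(f, NULL)
  t1 <- transcript(ann, "t1")
  ## minus strand: 5'UTR is the genomic-right part [251..300]
  expect_identical(t1$utr5_len, 50L)
  expect_identical(t1$cds_len, 100L)
  expect_identical(t1$utr3_len, 50L)
  ## the 3' end (last mature base) is the genomic-left exon base
  expect_identical(to_genomic_coord(t1, t1$mature_len - 1L), 100L)
  expect_identical(region_at(t1, t1$mature_len - 1L), "utr3")
})

test_that("malformed GFF3 and invalid models raise informative errors", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\ttest\tgene\t1\t10"), f)
  expect_error(load_annotation(f, NULL), "line 2")

  gff <- c("##gff-version 3",
           paste("chr1", "t", "mRNA", 101, 200, ".", "+", ".", "ID=t1",
                 sep = "\t"),
           paste("chr1", "t", "exon", 101, 200, ".", "+", ".",
                 "Parent=t1", sep = "\t"),
           paste("chr1", "t", "CDS", 151, 260, ".", "+", "0",
                 "Parent=t1", sep = "\t"))
  f2 <- tempfile(fileext = ".gff3")
  writeLines(gff, f2)
  expect_error(load_annotation(f2, NULL), "CDS outside exons")

  m <- make_tx("dup")
  expect_error(build_annotation(list(m, m), TOY_GENOME), "duplicated")
  expect_error(make_tx(utr5 = 10, cds = 100, utr3 = 10),
               "do not sum")
  expect_error(
    build_annotation(list(make_tx(exons = cbind(9900, 10200),
                                  utr5 = 50, cds = 200, utr3 = 50)),
                     TOY_GENOME),
    "beyond chromosome end")
})

test_that("mature coordinate mapping matches spec examples", {
  tp <- make_tx(exons = cbind(100, 200), utr5 = 10, cds = 80, utr3 = 10)
  expect_identical(to_mature_coord(tp, 100L), 0L)
  tm <- make_tx(strand = "-", exons = cbind(100, 200), utr5 = 10,
                cds = 80, utr3 = 10)
  expect_identical(to_mature_coord(tm, 199L), 0L)
  t2 <- make_tx(exons = rbind(c(0, 50), c(100, 150)), utr5 = 10,
                cds = 80, utr3 = 10)
  expect_identical(to_mature_coord(t2, 110L), 60L)
  expect_true(is.na(to_mature_coord(t2, 75L)))
})

test_that("mature mapping is a bijection onto [0, mature length)", {
  set.seed(11)
  for (k in 1:20) {
    t <- random_mrna(sprintf("r%d", k))
    bases <- oracle_exon_bases(t)
    mature <- vapply(bases, function(g) to_mature_coord(t, g), integer(1))
    expect_identical(mature, seq_len(t$mature_len) - 1L)
    back <- vapply(mature, function(m) to_genomic_coord(t, m), integer(1))
    expect_identical(back, as.integer(bases))
  }
})

test_that("region_at partitions the mature length per the stored lengths", {
  t <- make_tx(exons = cbind(0, 1100), utr5 = 100, cds = 900, utr3 = 100)
  expect_identical(region_at(t, 99L), "utr5")
  expect_identical(region_at(t, 100L), "cds")
  expect_identical(region_at(t, 1000L), "utr3")
  r <- region_at(t, 0:(t$mature_len - 1L))
  expect_identical(unname(table(r)[c("utr5", "cds", "utr3")]),
                   table(factor(c(rep("utr5", 100), rep("cds", 900),
                                  rep("utr3", 100)),
                                levels = c("utr5", "cds", "utr3"))) |>
                     unname())
  expect_error(region_at(t, 1100L), "out of range")
  expect_error(region_at(make_tx(class = "rRNA"), 0L), "mRNA only")
})

test_that("zero-UTR mRNAs load but are flagged", {
  t <- make_tx(utr5 = 0, cds = 250, utr3 = 50)
  expect_true(t$flagged)
  ann <- build_annotation(list(t), TOY_GENOME)
  expect_true(ann$transcripts["tx1", "flagged"])
})

test_that("written GFF3 round-trips through load_annotation", {
  cfg <- sim_config(n_mrna = 15, n_ncrna = c(rRNA = 2, tRNA = 2, snRNA = 1,
                                             snoRNA = 1, other = 1),
                    reads_per_sample = 100, n_true_targets = 2, seed = 5)
  sim <- simulate_transcriptome(cfg)
  d <- tempfile()
  write_simulation(sim, d)
  ann2 <- load_annotation(file.path(d, "annotation.gff3"),
                          file.path(d, "genome.fa"))
  o <- order(sim$annotation$transcripts$id)
  expect_equal(sim$annotation$transcripts[o, ],
               ann2$transcripts[order(ann2$transcripts$id), ])
  expect_identical(sim$annotation$genome_lengths[
    sort(names(sim$annotation$genome_lengths))],
    ann2$genome_lengths[sort(names(ann2$genome_lengths))])
})
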