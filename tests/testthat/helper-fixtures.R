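# Fixture builders and independent brute-force oracles. Oracles are kept
# deliberately naive (per-base / per-read enumeration, definitional
# formulas) so they share no code path with the implementation.

TOY_GENOME <- c(chr1 = 10000, chr2 = 8000)

make_tx <- function(id = "tx1", chrom = "chr1", strand = "+",
                    exons = cbind(100, 400), class = "mRNA",
                    utr5 = 50, cds = 200, utr3 = 50) {
  if (class == "mRNA")
    transcript_model(id, chrom, strand, exons, "mRNA",
                     utr5_len = utr5, cds_len = cds, utr3_len = utr3)
  else
    transcript_model(id, chrom, strand, exons, class)
}

make_reads <- function(starts0, width = 30, chrom = "chr1", strand = "+",
                       sample = "s1", genome = TOY_GENOME) {
  n <- length(starts0)
  GenomicRanges::GRanges(
    seqnames = rep(chrom, length.out = n),
    ranges = IRanges::IRanges(start = starts0 + 1L, width = width),
    strand = rep(strand, length.out = n),
    sample = factor(rep(sample, length.out = n)),
    unique = rep(TRUE, n),
    seqlengths = genome)
}

# random mRNA with 1..max_exons exons, total length < 1 kb, nonzero regions
random_mrna <- function(id, chrom = "chr1", max_exons = 3) {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample.int(max_exons, 1)
  cuts <- sort(sample(0:999, 2 * n_ex))
  ex <- cbind(cuts[seq(1, by = 2, length.out = n_ex)],
              cuts[seq(2, by = 2, length.out = n_ex)])
  L <- sum(ex[, 2] - ex[, 1])
  if (L < 3) return(random_mrna(id, chrom, max_exons))
  u5 <- sample.int(L - 2, 1)
  cds <- sample.int(L - u5 - 1, 1)
  transcript_model(id, chrom, strand, ex, "mRNA", utr5_len = u5,
                   cds_len = cds, utr3_len = L - u5 - cds)
}

# --- oracles ---------------------------------------------------------------

# genomic positions of transcript bases, in 5'->3' transcript order
oracle_exon_bases <- function(t) {
  unlist(lapply(seq_len(nrow(t$exons)), function(i) {
    b <- t$exons[i, "start"]:(t$exons[i, "end"] - 1L)
    if (t$strand == "-") rev(b) else b
  }))
}

oracle_mature <- function(t, g) {
  i <- match(g, oracle_exon_bases(t))
  if (is.na(i)) NA_integer_ else i - 1L
}

oracle_bin <- function(t, m, n5 = 10, nc = 100, n3 = 10) {
  stopifnot(m >= 0, m < t$mature_len)
  if (m < t$utr5_len) {
    min(floor(m * n5 / t$utr5_len), n5 - 1)
  } else if (m < t$utr5_len + t$cds_len) {
    d <- m - t$utr5_len
    n5 + min(floor(d * nc / t$cds_len), nc - 1)
  } else {
    d <- m - t$utr5_len - t$cds_len
    n5 + nc + min(floor(d * n3 / t$utr3_len), n3 - 1)
  }
}

# per-read assignment over a list of transcript_model objects
oracle_assign_read <- function(chrom, s0, e0, strand, models) {
  mid <- floor((s0 + e0 - 1) / 2)
  cand <- Filter(function(t)
    t$chrom == chrom && t$strand == strand &&
      any(t$exons[, "start"] <= mid & mid < t$exons[, "end"]), models)
  if (!length(cand)) return(NA_character_)
  ov <- vapply(cand, function(t)
    sum(pmax(0, pmin(e0, t$exons[, "end"]) - pmax(s0, t$exons[, "start"]))),
    numeric(1))
  ids <- vapply(cand, `[[`, character(1), "id")
  ids[order(-ov, ids)][1]
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_midrank <- function(x)
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))

oracle_spearman <- function(x, y)
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))

# one-sided Welch p computed long-hand from the definitional formulas
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  stats::pt(tstat, df, lower.tail = FALSE)
}

# per-base coverage counter
oracle_coverage <- function(starts0, ends0, L) {
  v <- integer(L)
  for (i in seq_along(starts0))
    v[(starts0[i] + 1):ends0[i]] <- v[(starts0[i] + 1):ends0[i]] + 1L
  v
}

# position-by-position motif checker
oracle_motif <- function(seq, pattern, plus = c("K", "R")) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  for (i in seq_len(length(s) - length(p) + 1)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      c <- s[i + j - 1]
      if (p[j] == "X") next
      if (p[j] == "+") { if (!c %in% plus) { ok <- FALSE; break } }
      else if (c != p[j]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

random_protein <- function(n)
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")

# small counts object with chosen roles, built without the read path
manual_counts <- function(counts, roles, bio = NULL) {
  si <- data.frame(sample = colnames(counts), role = roles)
  if (!is.null(bio)) si$bio <- bio
  cracbind:::new_crac_counts(counts, si)
}
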