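## 120-bin per-transcript-normalized metagene profiles, region fractions,
## and the boxplot summary convention used for figure-style outputs.
##
## Each mRNA is rescaled to a fixed bin layout (default 10 bins for the
## 5'UTR, 100 for the CDS, 10 for the 3'UTR). All reads mapping to a given
## transcript are normalized to 1, so every transcript contributes equally
## to the aggregate profile regardless of abundance.

#' Bin scheme for metagene profiles
#'
#' @param n_utr5,n_cds,n_utr3 bins per region (defaults 10/100/10,
#'   total 120).
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(n_utr5 = 10L, n_cds = 100L, n_utr3 = 10L) {
  stopifnot(n_utr5 >= 1L, n_cds >= 1L, n_utr3 >= 1L)
  structure(list(n_utr5 = as.integer(n_utr5), n_cds = as.integer(n_cds),
                 n_utr3 = as.integer(n_utr3),
                 total = as.integer(n_utr5 + n_cds + n_utr3)),
            class = "bin_scheme")
}

#' Metagene bin of a mature position
#'
#' Within a region of length `L` at offset `d`, the local bin is
#' `min(floor(d * n_region / L), n_region - 1)`; global bins stack the
#' 5'UTR block first, then CDS, then 3'UTR (0-based, 0..119 under
#' defaults).
#'
#' @param t a [transcript_model()] of class mRNA with all three region
#'   lengths > 0.
#' @param m 0-based mature position(s).
#' @param scheme a [bin_scheme()].
#' @return Integer bin index (vectorized over `m`).
#' @export
bin_index <- function(t, m, scheme = bin_scheme()) {
  stopifnot(inherits(t, "transcript_model"), inherits(scheme, "bin_scheme"))
  if (t$rna_class != "mRNA") stop("bin_index is defined for mRNA only")
  if (t$utr5_len == 0L || t$cds_len == 0L || t$utr3_len == 0L)
    stop("transcript '", t$id,
         "' has a zero-length region; excluded from metagene binning")
  if (any(m < 0L | m >= t$mature_len)) stop("mature position out of range")
  reg_len <- c(t$utr5_len, t$cds_len, t$utr3_len)
  reg_off <- c(0L, t$utr5_len, t$utr5_len + t$cds_len)
  nbin <- c(scheme$n_utr5, scheme$n_cds, scheme$n_utr3)
  bin_off <- c(0L, scheme$n_utr5, scheme$n_utr5 + scheme$n_cds)
  reg <- ifelse(m < t$utr5_len, 1L,
                ifelse(m < t$utr5_len + t$cds_len, 2L, 3L))
  d <- m - reg_off[reg]
  local <- pmin(floor(d * nbin[reg] / reg_len[reg]), nbin[reg] - 1L)
  as.integer(bin_off[reg] + local)
}

#' Unit-sum binding profile of one transcript
#'
#' @param t a [transcript_model()] (mRNA with nonzero regions).
#' @param positions 0-based mature midpoint coordinates of the reads
#'   assigned to `t` (at least one).
#' @param scheme a [bin_scheme()].
#' @return Numeric vector of length `scheme$total` summing to 1.
#' @export
transcript_profile <- function(t, positions, scheme = bin_scheme()) {
  if (length(positions) == 0L)
    stop("transcript_profile requires at least one assigned read")
  b <- bin_index(t, positions, scheme)
  tabulate(b + 1L, nbins = scheme$total) / length(positions)
}

#' Per-transcript metagene profile matrix from reads
#'
#' Assigns reads (see [count_per_transcript()] for the midpoint rule),
#' pools the requested samples, and bins each transcript's mature
#' midpoints. Transcripts with a zero-length region are excluded and
#' reported in the `skipped` element.
#'
#' @param reads `GRanges` of aligned reads.
#' @param ann a `crac_annotation`.
#' @param samples sample ids to pool (default: all `crac_tagged` reads, or
#'   all reads when no role metadata is present).
#' @param scheme a [bin_scheme()].
#' @return An object of class `metagene_profiles`: unit-sum row matrix
#'   `profile` (transcripts x bins), per-transcript read totals `n_reads`,
#'   the `scheme`, and `skipped` transcript ids.
#' @export
metagene_profiles <- function(reads, ann, samples = NULL,
                              scheme = bin_scheme()) {
  asn <- assign_reads(reads, ann)
  role <- S4Vectors::mcols(.unique_reads(reads))$role
  if (is.null(samples) && !is.null(role)) {
    keep_samp <- unique(as.character(asn$sample)[as.character(role) ==
                                                   "crac_tagged"])
    if (length(keep_samp)) samples <- keep_samp
  }
  if (!is.null(samples))
    asn <- asn[as.character(asn$sample) %in% samples, , drop = FALSE]
  asn <- asn[!is.na(asn$region), , drop = FALSE]
  if (!nrow(asn)) stop("no mRNA-assigned reads in the selected samples")

  tx <- ann$transcripts
  ok_tx <- tx$id[tx$rna_class == "mRNA" & !tx$flagged]
  skipped <- setdiff(unique(asn$transcript_id), ok_tx)
  asn <- asn[asn$transcript_id %in% ok_tx, , drop = FALSE]

  f <- factor(asn$transcript_id)
  u5 <- tx[levels(f), "utr5_len"]; cd <- tx[levels(f), "cds_len"]
  u3 <- tx[levels(f), "utr3_len"]
  i <- as.integer(f)
  m <- asn$mature_mid
  reg <- ifelse(m < u5[i], 1L, ifelse(m < u5[i] + cd[i], 2L, 3L))
  reg_len <- cbind(u5, cd, u3)
  reg_off <- cbind(0L, u5, u5 + cd)
  nbin <- c(scheme$n_utr5, scheme$n_cds, scheme$n_utr3)
  bin_off <- c(0L, scheme$n_utr5, scheme$n_utr5 + scheme$n_cds)
  d <- m - reg_off[cbind(i, reg)]
  bin <- bin_off[reg] +
    pmin(floor(d * nbin[reg] / reg_len[cbind(i, reg)]), nbin[reg] - 1L)

  cnt <- table(f)
  cell <- (i - 1L) * scheme$total + as.integer(bin) + 1L
  prof <- matrix(tabulate(cell, nbins = nlevels(f) * scheme$total),
                 nrow = nlevels(f), ncol = scheme$total, byrow = TRUE,
                 dimnames = list(levels(f), NULL))
  prof <- prof / as.numeric(cnt)
  structure(list(profile = prof, n_reads = as.integer(cnt),
                 scheme = scheme, skipped = skipped),
            class = "metagene_profiles")
}

#' @export
print.metagene_profiles <- function(x, ...) {
  cat("<metagene_profiles>", nrow(x$profile), "transcripts x",
      x$scheme$total, "bins;", length(x$skipped),
      "transcript(s) skipped (zero-length region)\n")
  invisible(x)
}

#' Aggregate metagene profile over RPM-filtered transcripts
#'
#' The aggregate is the arithmetic mean of per-transcript unit-sum
#' profiles (not a pooled read histogram), so each filtered transcript
#' contributes equally. Transcripts are filtered on mean CRAC RPM
#' (default > 100 RPM, strict) or, alternatively, on raw read counts.
#'
#' @param profiles a `metagene_profiles`.
#' @param cm an RPM-normalized `crac_counts` from the same sample(s).
#' @param min_rpm RPM threshold (used when `filter = "rpm"`).
#' @param filter `"rpm"` (mean RPM over `samples` > `min_rpm`) or
#'   `"reads"` (total reads over `samples` >= `min_reads`).
#' @param min_reads read-count threshold for `filter = "reads"`.
#' @param samples columns of `cm` to average (default: `crac_tagged`
#'   samples, else all).
#' @return An object of class `metagene_profile` with elements `values`
#'   (unit-sum, length `scheme$total`), `n_transcripts` and `scheme`.
#' @export
aggregate_metagene <- function(profiles, cm, min_rpm = 100,
                               filter = c("rpm", "reads"), min_reads = 100,
                               samples = NULL) {
  stopifnot(inherits(profiles, "metagene_profiles"),
            inherits(cm, "crac_counts"))
  filter <- match.arg(filter)
  if (is.null(samples)) {
    samples <- cm$samples$sample[cm$samples$role == "crac_tagged"]
    if (!length(samples)) samples <- cm$samples$sample
  }
  if (filter == "rpm") {
    if (is.null(cm$rpm)) cm <- rpm_normalize(cm)
    stat <- rowMeans(cm$rpm[, samples, drop = FALSE])
    pass <- rownames(cm$counts)[stat > min_rpm]
  } else {
    stat <- rowSums(cm$counts[, samples, drop = FALSE])
    pass <- rownames(cm$counts)[stat >= min_reads]
  }
  keep <- intersect(rownames(profiles$profile), pass)
  if (!length(keep))
    stop("no transcript passes the metagene filter")
  structure(list(values = colMeans(profiles$profile[keep, , drop = FALSE]),
                 n_transcripts = length(keep), scheme = profiles$scheme,
                 transcript_ids = keep),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  s <- x$scheme
  u3 <- sum(x$values[(s$n_utr5 + s$n_cds + 1):s$total])
  cat(sprintf("<metagene_profile> aggregate over %d transcripts; 3'UTR mass %.3f\n",
              x$n_transcripts, u3))
  invisible(x)
}

#' Plot an aggregate metagene profile
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  s <- x$scheme
  graphics::plot(seq_len(s$total) - 1L, x$values, type = "h",
                 xlab = "bin (5'UTR | CDS | 3'UTR)", ylab = "mean density",
                 ...)
  graphics::abline(v = c(s$n_utr5, s$n_utr5 + s$n_cds) - 0.5, lty = 2)
  invisible(x)
}

#' Region fractions per transcript
#'
#' Fractions of a transcript's reads in the 5'UTR, CDS and 3'UTR.
#'
#' @param rc region-count table from [count_by_region()] (rows with zero
#'   totals are dropped).
#' @return The input with added columns `f5`, `fcds`, `f3` summing to 1
#'   per row.
#' @export
region_fraction <- function(rc) {
  tot <- rc$utr5 + rc$cds + rc$utr3
  rc <- rc[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  if (!nrow(rc)) stop("no transcripts with region counts")
  rc$f5 <- rc$utr5 / tot
  rc$fcds <- rc$cds / tot
  rc$f3 <- rc$utr3 / tot
  rc
}

#' Pool region counts across samples
#'
#' Sums the per-sample region counts of each transcript, e.g. over all
#' tagged replicates.
#'
#' @param rc region-count table from [count_by_region()].
#' @param samples samples to pool (default all in `rc`).
#' @return One row per transcript with summed `utr5`, `cds`, `utr3`.
#' @export
pool_region_counts <- function(rc, samples = NULL) {
  if (!is.null(samples)) rc <- rc[rc$sample %in% samples, , drop = FALSE]
  if (!nrow(rc)) stop("no region counts to pool")
  agg <- rowsum(rc[, c("utr5", "cds", "utr3")], rc$transcript_id)
  data.frame(transcript_id = rownames(agg), sample = "pooled", agg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median and mean region fractions across transcripts
#'
#' The median is the headline figure-facing number.
#'
#' @param rf output of [region_fraction()].
#' @return data.frame with rows `median` and `mean` over `f5`, `fcds`,
#'   `f3`.
#' @export
region_fraction_summary <- function(rf) {
  data.frame(f5 = c(median(rf$f5), mean(rf$f5)),
             fcds = c(median(rf$fcds), mean(rf$fcds)),
             f3 = c(median(rf$f3), mean(rf$f3)),
             row.names = c("median", "mean"))
}

#' Boxplot summary (Tukey convention)
#'
#' Quartiles by linear interpolation between order statistics
#' ([stats::quantile()] type 7); whiskers are the most extreme data points
#' within 1.5 x IQR of the quartiles; points beyond are outliers.
#'
#' @param values numeric vector (non-empty).
#' @return An object of class `boxplot_summary` with `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("boxplot_summary requires at least one value")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(values[inside]),
                 whisker_high = max(values[inside]),
                 outliers = sort(values[!inside])),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf("<boxplot_summary> median %.4g [q1 %.4g, q3 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
              length(x$outliers)))
  invisible(x)
}

#' Heatmap matrix of per-transcript profiles
#'
#' @param profiles a `metagene_profiles`.
#' @param ordering `"by_3utr_fraction"` (decreasing 3'UTR bin mass, ties
#'   by id) or `"by_id"`.
#' @return Matrix rows = transcripts (ordered), cols = bins; every row
#'   sums to 1.
#' @export
heatmap_matrix <- function(profiles,
                           ordering = c("by_3utr_fraction", "by_id")) {
  stopifnot(inherits(profiles, "metagene_profiles"))
  ordering <- match.arg(ordering)
  p <- profiles$profile
  if (!nrow(p)) stop("empty profile set")
  s <- profiles$scheme
  if (ordering == "by_3utr_fraction") {
    f3 <- rowSums(p[, (s$n_utr5 + s$n_cds + 1):s$total, drop = FALSE])
    p[order(-f3, rownames(p)), , drop = FALSE]
  } else {
    p[order(rownames(p)), , drop = FALSE]
  }
}
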