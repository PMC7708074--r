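## High-confidence target calling: RPM filter, enrichment ratio over
## RNA-seq, and a replicate-based one-sided enrichment test; plus
## per-base coverage-track export.

#' Target-calling thresholds
#'
#' All three criteria are strict inequalities: CRAC RPM > `rpm`,
#' CRAC/RNA-seq ratio > `ratio`, p < `p`.
#'
#' @param rpm RPM threshold (default 128).
#' @param ratio enrichment-ratio threshold (default 1.5).
#' @param p p-value threshold (default 0.01).
#' @return An object of class `calling_thresholds`.
#' @export
calling_thresholds <- function(rpm = 128, ratio = 1.5, p = 0.01) {
  stopifnot(rpm > 0, ratio > 0, p > 0)
  structure(list(rpm = rpm, ratio = ratio, p = p),
            class = "calling_thresholds")
}

#' One-sided enrichment p-value (CRAC > RNA-seq)
#'
#' Welch t-test on `log2(rpm + pseudocount)` across replicates, one-sided
#' with alternative "CRAC greater". Degenerate inputs: when both groups
#' have zero variance, p = 1 for equal means and the smallest representable
#' positive value (flagged via the `"degenerate"` attribute) when the CRAC
#' mean is greater.
#'
#' @param crac_rpms per-replicate CRAC RPM values (>= 2).
#' @param rnaseq_rpms per-replicate RNA-seq RPM values (>= 2).
#' @param pseudocount added before the log (default 0.5).
#' @return p-value in (0, 1].
#' @export
enrichment_pvalue <- function(crac_rpms, rnaseq_rpms, pseudocount = 0.5) {
  if (length(crac_rpms) < 2L || length(rnaseq_rpms) < 2L)
    stop("enrichment_pvalue requires >= 2 values per group")
  x <- log2(crac_rpms + pseudocount)
  y <- log2(rnaseq_rpms + pseudocount)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) > mean(y))
      return(structure(.Machine$double.xmin, degenerate = TRUE))
    return(1)
  }
  t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value
}

## moderated alternative: effect / robust transcriptome-wide scale,
## standard-normal one-sided p; robust to a minority of enriched rows
.pooled_z_pvalues <- function(lc, lr) {
  eff <- rowMeans(lc) - rowMeans(lr)
  s0 <- mad(eff)
  if (s0 == 0) stop("degenerate effect distribution in pooled_z test")
  pnorm(eff - median(eff), sd = s0, lower.tail = FALSE)
}

#' Call high-confidence targets
#'
#' Per mRNA: mean CRAC and RNA-seq RPM, enrichment ratio, and an
#' enrichment p-value across replicates; a transcript is a high-confidence
#' target when it passes all three (strict) thresholds. When the RNA-seq
#' mean is 0 the ratio is infinite and the ratio criterion passes only if
#' the RPM criterion does. Output rows are ordered by ascending p, then
#' id. A Benjamini-Hochberg column is included for information only (the
#' three criteria use the raw p).
#'
#' Replicate handling: technical replicates are not independent (they
#' share the biological sample), so by default CRAC RPM values are
#' averaged within each biological replicate before the test; grouping
#' uses the `bio` column of `cm$samples`, falling back to sample ids of
#' the form `<role>_b<i>t<j>`, and finally to one group per sample (in
#' which case the default is an ordinary Welch test across samples).
#' `method = "welch_all"` skips the averaging and treats every sample as
#' independent (anti-conservative under shared biological noise).
#'
#' @param cm an RPM-normalized `crac_counts` with >= 2 `crac_tagged` and
#'   >= 2 `rnaseq` samples (technical replicates count).
#' @param thresholds a [calling_thresholds()].
#' @param method `"pooled_z"` (default, moderated one-sided z of the
#'   per-transcript log2 CRAC-vs-RNA-seq effect against the robust
#'   transcriptome-wide effect scale; calibrated whatever the replicate
#'   correlation and the most powerful option at 2 biological
#'   replicates), `"welch"` (one-sided Welch t-test on
#'   biological-replicate RPMs via [enrichment_pvalue()]) or
#'   `"welch_all"` (Welch across all samples without technical-replicate
#'   averaging).
#' @param pseudocount added before the log (default 0.5).
#' @return An object of class `target_calls`: data.frame with columns
#'   `transcript_id`, `crac_rpm`, `rnaseq_rpm`, `ratio`, `p_value`,
#'   `padj_bh`, `pass_rpm`, `pass_ratio`, `pass_p`, `high_confidence`.
#' @export
call_targets <- function(cm, thresholds = calling_thresholds(),
                         method = c("pooled_z", "welch", "welch_all"),
                         pseudocount = 0.5) {
  stopifnot(inherits(cm, "crac_counts"))
  method <- match.arg(method)
  crac_sel <- cm$samples$role == "crac_tagged"
  rna_sel <- cm$samples$role == "rnaseq"
  crac_cols <- cm$samples$sample[crac_sel]
  rna_cols <- cm$samples$sample[rna_sel]
  if (length(crac_cols) < 2L)
    stop("call_targets needs >= 2 samples with role 'crac_tagged'")
  if (length(rna_cols) < 2L)
    stop("call_targets needs >= 2 samples with role 'rnaseq'")
  if (is.null(cm$rpm)) cm <- rpm_normalize(cm)

  ## calling is defined over mRNAs: restrict with mrna_counts() first
  ids <- rownames(cm$counts)
  crac <- cm$rpm[, crac_cols, drop = FALSE]
  rna <- cm$rpm[, rna_cols, drop = FALSE]
  crac_mean <- rowMeans(crac)
  rna_mean <- rowMeans(rna)
  ratio <- ifelse(rna_mean == 0, Inf, crac_mean / rna_mean)

  group_means <- function(m, labels) {
    g <- factor(labels)
    if (nlevels(g) == ncol(m)) return(m)
    vapply(levels(g), function(l)
      rowMeans(m[, g == l, drop = FALSE]), numeric(nrow(m)))
  }
  if (method != "welch_all") {
    crac_t <- group_means(crac, .bio_labels(cm$samples[crac_sel, ]))
    rna_t <- group_means(rna, .bio_labels(cm$samples[rna_sel, ]))
  } else {
    crac_t <- crac; rna_t <- rna
  }
  if (method != "pooled_z" && (ncol(crac_t) < 2L || ncol(rna_t) < 2L))
    stop("need >= 2 biological replicates per group for the Welch test")

  p <- if (method == "pooled_z")
    .pooled_z_pvalues(log2(crac_t + pseudocount), log2(rna_t + pseudocount))
  else
    vapply(seq_along(ids), function(i)
      as.numeric(enrichment_pvalue(crac_t[i, ], rna_t[i, ], pseudocount)),
      numeric(1))

  pass_rpm <- crac_mean > thresholds$rpm
  pass_ratio <- ifelse(is.infinite(ratio), pass_rpm,
                       ratio > thresholds$ratio)
  pass_p <- p < thresholds$p
  d <- data.frame(transcript_id = ids, crac_rpm = crac_mean,
                  rnaseq_rpm = rna_mean, ratio = ratio, p_value = p,
                  padj_bh = p.adjust(p, "BH"),
                  pass_rpm = pass_rpm, pass_ratio = pass_ratio,
                  pass_p = pass_p,
                  high_confidence = pass_rpm & pass_ratio & pass_p,
                  stringsAsFactors = FALSE)
  d <- d[order(d$p_value, d$transcript_id), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("target_calls", "data.frame"),
            thresholds = thresholds, method = method)
}

#' @export
print.target_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("<target_calls> %d transcripts, %d high-confidence (RPM > %g, ratio > %g, p < %g; %s test)\n",
              nrow(x), sum(x$high_confidence), th$rpm, th$ratio, th$p,
              attr(x, "method")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Restrict a count matrix to mRNA transcripts
#'
#' Convenience for target calling, which is defined over mRNAs.
#'
#' @param cm a `crac_counts`.
#' @param ann the matching `crac_annotation`.
#' @return The `crac_counts` with only mRNA rows (library sizes and RPM
#'   are kept from the full matrix: RPM stays per-million of all
#'   transcriptome-assigned reads).
#' @export
mrna_counts <- function(cm, ann) {
  stopifnot(inherits(cm, "crac_counts"), inherits(ann, "crac_annotation"))
  keep <- intersect(rownames(cm$counts),
                    ann$transcripts$id[ann$transcripts$rna_class == "mRNA"])
  out <- cm
  out$counts <- cm$counts[keep, , drop = FALSE]
  if (!is.null(cm$rpm)) out$rpm <- cm$rpm[keep, , drop = FALSE]
  out
}

#' Per-base coverage track (bedGraph)
#'
#' Each unique read of the selected sample contributes 1 over its full
#' interval; runs of equal coverage become bedGraph lines (0-based
#' half-open on disk); zero-coverage runs are omitted.
#'
#' @param reads `GRanges` of aligned reads.
#' @param sample sample id to export (default: all reads).
#' @param chrom restrict to one chromosome (optional).
#' @param path optional output path; when given the track is written and
#'   the path returned invisibly.
#' @return data.frame with columns `chrom`, `start`, `end`, `count`.
#' @export
export_track <- function(reads, sample = NULL, chrom = NULL, path = NULL) {
  reads <- .unique_reads(reads)
  if (!is.null(sample)) {
    samp <- as.character(.read_samples(reads))
    reads <- reads[samp == sample]
  }
  if (!is.null(chrom)) {
    known <- GenomeInfoDb::seqlevels(reads)
    if (length(known) && !chrom %in% known)
      stop("unknown chromosome '", chrom, "'")
    reads <- reads[as.character(GenomicRanges::seqnames(reads)) == chrom]
  }
  cov <- GenomicRanges::coverage(reads)
  out <- list()
  for (ch in names(cov)) {
    r <- cov[[ch]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    ends <- cumsum(len)
    starts0 <- ends - len            # 0-based run starts
    nz <- v > 0
    if (!any(nz)) next
    out[[ch]] <- data.frame(chrom = ch, start = starts0[nz],
                            end = ends[nz], count = v[nz],
                            stringsAsFactors = FALSE)
  }
  d <- if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), start = integer(),
                  end = integer(), count = integer())
  rownames(d) <- NULL
  if (!is.null(path)) {
    write.table(d, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  d
}
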