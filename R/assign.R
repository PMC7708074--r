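## Partition uniquely mapped reads into RNA classes, count reads per
## transcript and per mRNA region, and normalize to RPM.
##
## Every read is assigned by its midpoint: for the 0-based half-open
## interval [s, e) the midpoint is floor((s + e - 1) / 2). The midpoint
## rule gives a single unambiguous assignment per read and keeps class,
## transcript and region tallies mutually consistent.

.read_midpoints <- function(reads) {
  ## 1-based midpoint of a 1-based closed [start, end] interval equals
  ## floor((start + end) / 2), matching floor((s0 + e0 - 1)/2) 0-based
  mid <- as.integer(floor((BiocGenerics::start(reads) +
                           BiocGenerics::end(reads)) / 2))
  GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                         IRanges::IRanges(mid, width = 1L),
                         strand = BiocGenerics::strand(reads))
}

.check_read_chroms <- function(reads, ann) {
  bad <- setdiff(as.character(unique(GenomicRanges::seqnames(reads))),
                 names(ann$genome_lengths))
  if (length(bad))
    stop("read(s) on unknown chromosome(s): ", paste(bad, collapse = ", "))
}

.unique_reads <- function(reads) {
  u <- S4Vectors::mcols(reads)$unique
  if (is.null(u)) reads else reads[as.logical(u)]
}

.read_samples <- function(reads) {
  s <- S4Vectors::mcols(reads)$sample
  if (is.null(s)) factor(rep("sample1", length(reads)))
  else factor(as.character(s))
}

## Core per-read assignment shared by classification, counting, region
## tallies and metagene profiling. Returns, for each unique read, the
## winning transcript (or NA), its class, the mature midpoint coordinate
## and the mRNA region. Ties between transcripts containing the midpoint
## are broken by largest exonic overlap with the read, then smallest id,
## so the result is independent of read order.
assign_reads <- function(reads, ann) {
  stopifnot(inherits(ann, "crac_annotation"))
  reads <- .unique_reads(reads)
  .check_read_chroms(reads, ann)
  n <- length(reads)
  samp <- .read_samples(reads)
  mid <- .read_midpoints(reads)
  ex <- ann$exons
  exm <- S4Vectors::mcols(ex)

  hits <- GenomicRanges::findOverlaps(mid, ex, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)

  ## resolve reads whose midpoint lies in exons of >1 transcript
  tx_of_hit <- exm$transcript_id[s]
  first <- !duplicated(q)
  keep <- first
  if (any(!first)) {
    amb_reads <- unique(q[duplicated(q)])
    sel <- q %in% amb_reads
    ov_hits <- GenomicRanges::findOverlaps(reads[amb_reads], ex,
                                           ignore.strand = FALSE)
    ovw <- BiocGenerics::width(IRanges::pintersect(
      GenomicRanges::ranges(reads[amb_reads])[S4Vectors::queryHits(ov_hits)],
      GenomicRanges::ranges(ex)[S4Vectors::subjectHits(ov_hits)]))
    okey <- paste(amb_reads[S4Vectors::queryHits(ov_hits)],
                  exm$transcript_id[S4Vectors::subjectHits(ov_hits)])
    ov_tx <- rowsum(ovw, okey)
    cand_key <- paste(q[sel], tx_of_hit[sel])
    cand_ov <- ov_tx[cand_key, 1L]
    ## order candidates: read, decreasing overlap, increasing transcript id;
    ## drop duplicate (read, transcript) pairs from multi-exon midpoint hits
    o <- order(q[sel], -cand_ov, tx_of_hit[sel])
    si <- which(sel)[o]
    best <- si[!duplicated(q[si])]
    keep <- rep(FALSE, length(q))
    keep[which(first & !(q %in% amb_reads))] <- TRUE
    keep[best] <- TRUE
  }
  q <- q[keep]; s <- s[keep]

  tx_id <- rep(NA_character_, n)
  cls <- rep(NA_character_, n)
  mature <- rep(NA_integer_, n)
  tx_id[q] <- exm$transcript_id[s]
  cls[q] <- exm$rna_class[s]
  mpos <- BiocGenerics::start(mid)[q]
  plus <- as.character(BiocGenerics::strand(ex))[s] == "+"
  off <- ifelse(plus, mpos - BiocGenerics::start(ex)[s],
                BiocGenerics::end(ex)[s] - mpos)
  mature[q] <- exm$cum_before[s] + as.integer(off)

  region <- rep(NA_character_, n)
  is_m <- !is.na(cls) & cls == "mRNA"
  if (any(is_m)) {
    tx <- ann$transcripts[tx_id[is_m], ]
    region[is_m] <- ifelse(mature[is_m] < tx$utr5_len, "utr5",
                           ifelse(mature[is_m] < tx$utr5_len + tx$cds_len,
                                  "cds", "utr3"))
  }
  data.frame(sample = samp, transcript_id = tx_id, rna_class = cls,
             mature_mid = mature, region = region, stringsAsFactors = FALSE)
}

#' Per-sample RNA-class shares of uniquely mapped reads
#'
#' Each unique read is assigned to exactly one class by midpoint overlap
#' with annotated exons (strand-aware), with priority
#' rRNA > tRNA > snRNA > snoRNA > mRNA > other when annotations overlap;
#' reads overlapping nothing are `"intergenic"`. Shares sum to 1 per
#' sample.
#'
#' @param reads `GRanges` of aligned reads with optional `sample` and
#'   `unique` metadata columns.
#' @param ann a `crac_annotation`.
#' @param priority named integer priority over classes (smaller wins).
#' @return data.frame with columns `sample`, `class`, `count`, `fraction`.
#' @export
classify_reads <- function(reads, ann, priority = CLASS_PRIORITY) {
  stopifnot(inherits(ann, "crac_annotation"))
  reads <- .unique_reads(reads)
  .check_read_chroms(reads, ann)
  samp <- .read_samples(reads)
  mid <- .read_midpoints(reads)
  ex <- ann$exons
  hits <- GenomicRanges::findOverlaps(mid, ex, ignore.strand = FALSE)
  cls_hit <- S4Vectors::mcols(ex)$rna_class[S4Vectors::subjectHits(hits)]
  pr <- priority[cls_hit]
  o <- order(S4Vectors::queryHits(hits), pr)
  qo <- S4Vectors::queryHits(hits)[o]
  firsts <- !duplicated(qo)
  cls <- rep("intergenic", length(reads))
  cls[qo[firsts]] <- cls_hit[o][firsts]

  levels_all <- c(names(sort(priority)), "intergenic")
  tab <- table(sample = samp, class = factor(cls, levels = levels_all))
  d <- as.data.frame(tab, responseName = "count", stringsAsFactors = FALSE)
  tot <- tapply(d$count, d$sample, sum)
  d$fraction <- d$count / as.numeric(tot[d$sample])
  d[order(d$sample, match(d$class, levels_all)), , drop = FALSE]
}

#' Count uniquely mapped reads per transcript
#'
#' A read is assigned to the same-strand transcript whose exons contain
#' its midpoint; when several transcripts contain the midpoint the one
#' with the largest total exonic overlap with the read wins, remaining
#' ties go to the lexicographically smallest transcript id. The per-sample
#' library size is the number of transcriptome-assigned unique reads.
#'
#' @inheritParams classify_reads
#' @param sample_info optional data.frame with columns `sample` and `role`
#'   (`crac_tagged`, `crac_control`, `rnaseq`, `riboseq`); by default roles
#'   are taken from the reads' `role` metadata column.
#' @return An object of class `crac_counts`: raw counts matrix
#'   (transcripts x samples), per-sample `lib_size`, a `samples` table with
#'   roles, and (after [rpm_normalize()]) an `rpm` matrix.
#' @export
count_per_transcript <- function(reads, ann, sample_info = NULL) {
  asn <- assign_reads(reads, ann)
  samples <- sort(unique(as.character(asn$sample)))
  counts <- matrix(0L, nrow = nrow(ann$transcripts), ncol = length(samples),
                   dimnames = list(ann$transcripts$id, samples))
  ok <- !is.na(asn$transcript_id)
  if (any(ok)) {
    tab <- table(factor(asn$transcript_id[ok],
                        levels = ann$transcripts$id),
                 factor(as.character(asn$sample)[ok], levels = samples))
    counts[] <- as.integer(tab)
  }
  if (is.null(sample_info)) {
    m <- S4Vectors::mcols(.unique_reads(reads))
    if (!is.null(m$role)) {
      map <- unique(data.frame(sample = as.character(.read_samples(reads)),
                               role = as.character(m$role),
                               bio = if (!is.null(m$bio)) as.integer(m$bio)
                                     else NA_integer_))
      sample_info <- map[match(samples, map$sample), ]
    } else {
      sample_info <- data.frame(sample = samples, role = "unknown")
    }
  }
  sample_info <- sample_info[match(samples, sample_info$sample), ]
  new_crac_counts(counts, sample_info)
}

## biological-replicate label: explicit column, else parsed from sample ids
## of the form "<role>_b<i>t<j>", else each sample is its own replicate
.bio_labels <- function(sample_info) {
  bio <- if ("bio" %in% names(sample_info)) sample_info$bio
         else rep(NA, nrow(sample_info))
  parsed <- sub("^.*_b([0-9]+)t[0-9]+$", "\\1", sample_info$sample)
  parse_ok <- grepl("_b[0-9]+t[0-9]+$", sample_info$sample)
  bio <- ifelse(!is.na(bio), bio, ifelse(parse_ok, parsed, NA))
  ifelse(is.na(bio), paste0("s:", sample_info$sample),
         paste0(sample_info$role, ":b", bio))
}

new_crac_counts <- function(counts, sample_info) {
  structure(list(counts = counts,
                 samples = data.frame(sample = colnames(counts),
                                      role = sample_info$role,
                                      bio = if ("bio" %in% names(sample_info))
                                        sample_info$bio else NA_integer_,
                                      stringsAsFactors = FALSE),
                 lib_size = colSums(counts),
                 rpm = NULL),
            class = "crac_counts")
}

#' @export
print.crac_counts <- function(x, ...) {
  cat("<crac_counts>", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples\n")
  print(data.frame(x$samples, lib_size = x$lib_size))
  invisible(x)
}

#' Add an externally quantified count table (RNA-seq / Ribo-seq)
#'
#' Appends count columns whose library size is their own column total.
#'
#' @param cm a `crac_counts`.
#' @param counts matrix (transcripts x samples) whose rownames match the
#'   annotation's transcript ids.
#' @param role sample role for the new columns.
#' @return The extended `crac_counts` (RPM is recomputed if present).
#' @export
add_counts <- function(cm, counts, role) {
  stopifnot(inherits(cm, "crac_counts"))
  counts <- as.matrix(counts)
  m <- matrix(0, nrow(cm$counts), ncol(counts),
              dimnames = list(rownames(cm$counts), colnames(counts)))
  common <- intersect(rownames(cm$counts), rownames(counts))
  m[common, ] <- counts[common, ]
  had_rpm <- !is.null(cm$rpm)
  out <- new_crac_counts(cbind(cm$counts, m),
                         data.frame(sample = c(cm$samples$sample,
                                               colnames(counts)),
                                    role = c(cm$samples$role,
                                             rep(role, ncol(counts))),
                                    bio = c(cm$samples$bio,
                                            rep(NA_integer_, ncol(counts)))))
  if (had_rpm) out <- rpm_normalize(out) else out
}

#' RPM-normalize a count matrix
#'
#' `rpm = count / library_size * 1e6`; raw counts are preserved.
#'
#' @param cm a `crac_counts`.
#' @return The `crac_counts` with its `rpm` matrix filled in.
#' @export
rpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "crac_counts"))
  if (any(cm$lib_size == 0))
    stop("zero library size for sample(s): ",
         paste(cm$samples$sample[cm$lib_size == 0], collapse = ", "))
  cm$rpm <- sweep(cm$counts, 2, cm$lib_size, "/") * 1e6
  cm
}

#' Count mRNA reads per region (5'UTR / CDS / 3'UTR)
#'
#' The region of each mRNA-assigned read is that of its midpoint's mature
#' coordinate; per transcript and sample the three region counts sum to
#' the transcript's count.
#'
#' @inheritParams classify_reads
#' @return data.frame with columns `transcript_id`, `sample`, `utr5`,
#'   `cds`, `utr3`.
#' @export
count_by_region <- function(reads, ann) {
  asn <- assign_reads(reads, ann)
  asn <- asn[!is.na(asn$region), , drop = FALSE]
  if (!nrow(asn))
    return(data.frame(transcript_id = character(), sample = character(),
                      utr5 = integer(), cds = integer(), utr3 = integer()))
  key <- interaction(asn$transcript_id, asn$sample, drop = TRUE, sep = "\r")
  tab <- table(key, factor(asn$region, levels = c("utr5", "cds", "utr3")))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  d <- data.frame(transcript_id = parts[, 1], sample = parts[, 2],
                  utr5 = as.integer(tab[, "utr5"]),
                  cds = as.integer(tab[, "cds"]),
                  utr3 = as.integer(tab[, "utr3"]),
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d[order(d$sample, d$transcript_id), , drop = FALSE]
}
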