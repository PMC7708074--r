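## Read-alignment I/O: BED6 and SAM/BAM in, BED6 out.

#' Read aligned reads from BED6 or SAM/BAM
#'
#' BED6: the name field is taken as the sample id and a score of 1 marks a
#' uniquely mapped read (the on-disk 0-based half-open convention is
#' converted on import). SAM/BAM (requires the Rsamtools package; SAM is
#' converted on the fly): secondary alignments are dropped and reads with
#' mapping quality 0 are flagged non-unique.
#'
#' @param path input path (`.bed`, `.sam` or `.bam`).
#' @param sample sample id override (required for SAM/BAM, optional for
#'   BED where the name field is the default).
#' @param role sample role (`crac_tagged`, `crac_control`, `rnaseq`,
#'   `riboseq`); derived from sample-id prefixes `tagged`/`control` when
#'   missing.
#' @return `GRanges` with metadata columns `sample`, `role`, `unique`.
#' @export
read_reads <- function(path, sample = NULL, role = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    m <- S4Vectors::mcols(gr)
    samp <- if (!is.null(sample)) rep(sample, length(gr))
            else if (!is.null(m$name)) as.character(m$name)
            else rep("sample1", length(gr))
    uniq <- if (!is.null(m$score)) is.na(m$score) | m$score == 1
            else rep(TRUE, length(gr))
  } else if (ext %in% c("sam", "bam")) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading SAM/BAM requires the Rsamtools package")
    bam <- if (ext == "sam")
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE)
    else path
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand", "mapq"),
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isUnmappedQuery = FALSE))
    b <- Rsamtools::scanBam(bam, param = p)[[1]]
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(b$rname),
      ranges = IRanges::IRanges(start = b$pos, width = b$qwidth),
      strand = b$strand)
    samp <- rep(if (is.null(sample)) "sample1" else sample, length(gr))
    uniq <- is.na(b$mapq) | b$mapq > 0
  } else {
    stop("unsupported read format '.", ext, "'")
  }
  if (is.null(role)) {
    role <- ifelse(startsWith(samp, "tagged"), "crac_tagged",
                   ifelse(startsWith(samp, "control"), "crac_control",
                          "unknown"))
  } else role <- rep(role, length(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample = factor(samp), role = factor(role), unique = uniq)
  gr
}

#' Write reads as BED6
#'
#' name = sample id, score = 1 for uniquely mapped reads (0 otherwise).
#'
#' @param reads `GRanges` with `sample` (and optionally `unique`) metadata.
#' @param path output path.
#' @export
write_reads_bed <- function(reads, path) {
  m <- S4Vectors::mcols(reads)
  gr <- GenomicRanges::granges(reads)
  u <- if (is.null(m$unique)) rep(TRUE, length(reads)) else
    as.logical(m$unique)
  S4Vectors::mcols(gr)$name <- as.character(.read_samples(reads))
  S4Vectors::mcols(gr)$score <- as.integer(u)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

write_tsv <- function(d, path, col.names = TRUE) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
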