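## Transcriptome data model: GFF3/FASTA input, genomic <-> mature (spliced)
## coordinate mapping, and 5'UTR/CDS/3'UTR region lookup.

RNA_CLASSES <- c("mRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "other")

## class priority used when a read midpoint overlaps several annotations;
## mimics abundant-RNA masking in CRAC pipelines (configurable in
## classify_reads)
CLASS_PRIORITY <- c(rRNA = 1L, tRNA = 2L, snRNA = 3L, snoRNA = 4L,
                    mRNA = 5L, other = 6L)

#' Build a transcript model
#'
#' A transcript with strand, RNA class and, for mRNAs, a mature-coordinate
#' segmentation into 5'UTR, CDS and 3'UTR. Exons are given in 0-based
#' half-open genomic coordinates and must be non-overlapping, on one strand
#' and one chromosome; they are stored sorted 5' to 3' in transcript
#' orientation.
#'
#' @param id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of 0-based half-open
#'   `start`, `end` genomic exon coordinates (any row order).
#' @param rna_class one of `"mRNA"`, `"rRNA"`, `"tRNA"`, `"snRNA"`,
#'   `"snoRNA"`, `"other"`.
#' @param gene gene name (defaults to `id`).
#' @param utr5_len,cds_len,utr3_len region lengths in mature coordinates;
#'   required for mRNA (must sum to the mature length, `cds_len > 0`),
#'   ignored otherwise.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, rna_class = "mRNA",
                             gene = id, utr5_len = 0L, cds_len = 0L,
                             utr3_len = 0L) {
  rna_class <- match.arg(rna_class, RNA_CLASSES)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            length(chrom) == 1L, nzchar(chrom),
            strand %in% c("+", "-"))
  exons <- as.matrix(as.data.frame(exons)[, 1:2])
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "start"] < 0L) || any(exons[, "end"] <= exons[, "start"]))
    stop("invalid exon interval for transcript '", id,
         "': need 0 <= start < end")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"]))
    stop("overlapping exons in transcript '", id, "'")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  widths <- exons[, "end"] - exons[, "start"]
  mature_len <- sum(widths)
  if (rna_class == "mRNA") {
    if (cds_len <= 0L)
      stop("mRNA '", id, "' must have cds_len > 0")
    if (utr5_len < 0L || utr3_len < 0L)
      stop("negative UTR length for '", id, "'")
    if (utr5_len + cds_len + utr3_len != mature_len)
      stop("region lengths of '", id, "' do not sum to the mature length (",
           utr5_len + cds_len + utr3_len, " vs ", mature_len, ")")
  } else {
    utr5_len <- cds_len <- utr3_len <- NA_integer_
  }
  structure(list(
    id = id, gene = gene, rna_class = rna_class, chrom = chrom,
    strand = strand, exons = exons,
    utr5_len = as.integer(utr5_len), cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len), mature_len = as.integer(mature_len),
    cum_before = as.integer(cumsum(c(0L, widths[-length(widths)]))),
    flagged = isTRUE(rna_class == "mRNA" && (utr5_len == 0L || utr3_len == 0L))
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s%s) %d exon(s), mature %d nt\n",
              x$id, x$rna_class, x$chrom, x$strand, nrow(x$exons),
              x$mature_len))
  if (x$rna_class == "mRNA")
    cat(sprintf("  5'UTR %d | CDS %d | 3'UTR %d%s\n", x$utr5_len, x$cds_len,
                x$utr3_len, if (x$flagged) "  [flagged: zero-length UTR]" else ""))
  invisible(x)
}

#' Assemble a transcriptome annotation from transcript models
#'
#' @param models list of [transcript_model()] objects with unique ids.
#' @param genome_lengths named integer vector of chromosome lengths; every
#'   exon must lie within its chromosome.
#' @return An object of class `crac_annotation` holding a transcript table
#'   and an exon-level `GRanges` used for read assignment.
#' @export
build_annotation <- function(models, genome_lengths) {
  if (length(models) == 0L) stop("no transcripts")
  ids <- vapply(models, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated transcript id(s): ", paste(unique(dup), collapse = ", "))
  stopifnot(!is.null(names(genome_lengths)))
  genome_lengths <- setNames(as.numeric(genome_lengths), names(genome_lengths))

  tx <- data.frame(
    id = ids,
    gene = vapply(models, `[[`, character(1), "gene"),
    rna_class = vapply(models, `[[`, character(1), "rna_class"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"),
    n_exons = vapply(models, function(m) nrow(m$exons), integer(1)),
    mature_len = vapply(models, `[[`, integer(1), "mature_len"),
    utr5_len = vapply(models, `[[`, integer(1), "utr5_len"),
    cds_len = vapply(models, `[[`, integer(1), "cds_len"),
    utr3_len = vapply(models, `[[`, integer(1), "utr3_len"),
    flagged = vapply(models, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)
  rownames(tx) <- tx$id

  bad_chrom <- setdiff(tx$chrom, names(genome_lengths))
  if (length(bad_chrom))
    stop("transcript chromosome(s) not in genome: ",
         paste(bad_chrom, collapse = ", "))

  ex <- do.call(rbind, lapply(models, function(m)
    data.frame(chrom = m$chrom, start0 = m$exons[, "start"],
               end0 = m$exons[, "end"], strand = m$strand,
               transcript_id = m$id, exon_rank = seq_len(nrow(m$exons)),
               cum_before = m$cum_before, rna_class = m$rna_class,
               stringsAsFactors = FALSE)))
  over <- ex$end0 > genome_lengths[ex$chrom]
  if (any(over))
    stop("exon(s) beyond chromosome end in transcript(s): ",
         paste(unique(ex$transcript_id[over]), collapse = ", "))
  exons <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start0 + 1L, end = ex$end0),
    strand = ex$strand,
    transcript_id = ex$transcript_id, exon_rank = ex$exon_rank,
    cum_before = ex$cum_before, rna_class = ex$rna_class,
    seqlengths = genome_lengths[sort(names(genome_lengths))])
  structure(list(transcripts = tx, exons = exons,
                 genome_lengths = genome_lengths),
            class = "crac_annotation")
}

#' @export
print.crac_annotation <- function(x, ...) {
  cat("<crac_annotation>", nrow(x$transcripts), "transcripts on",
      length(x$genome_lengths), "chromosome(s)\n")
  print(table(x$transcripts$rna_class))
  invisible(x)
}

#' Retrieve one transcript model from an annotation
#'
#' @param ann a `crac_annotation`.
#' @param id transcript identifier.
#' @return A [transcript_model()].
#' @export
transcript <- function(ann, id) {
  stopifnot(inherits(ann, "crac_annotation"))
  if (!id %in% ann$transcripts$id) stop("unknown transcript id '", id, "'")
  r <- ann$transcripts[id, ]
  sel <- S4Vectors::mcols(ann$exons)$transcript_id == id
  e <- ann$exons[sel]
  e <- e[order(S4Vectors::mcols(e)$exon_rank)]
  ex <- cbind(start = BiocGenerics::start(e) - 1L, end = BiocGenerics::end(e))
  if (r$rna_class == "mRNA")
    transcript_model(r$id, r$chrom, r$strand, ex, r$rna_class, r$gene,
                     r$utr5_len, r$cds_len, r$utr3_len)
  else
    transcript_model(r$id, r$chrom, r$strand, ex, r$rna_class, r$gene)
}

#' Load a transcriptome annotation from GFF3 (+ genome FASTA)
#'
#' Reads a GFF3 with `gene`/`mRNA`/`exon`/`CDS`/`five_prime_UTR`/
#' `three_prime_UTR` features and ncRNA feature types (`rRNA`, `tRNA`,
#' `snRNA`, `snoRNA`; `ncRNA` maps to class `"other"`). On-disk 1-based
#' inclusive coordinates are converted to the package's internal 0-based
#' half-open convention. mRNA UTR lengths come from the UTR features when
#' present, otherwise from the CDS extent relative to the exons.
#'
#' @param gff3_path path to the GFF3 file.
#' @param fasta_path path to the genome FASTA (used for chromosome lengths);
#'   may be `NULL`, in which case lengths are taken from the rightmost
#'   feature per chromosome.
#' @return A `crac_annotation`.
#' @export
load_annotation <- function(gff3_path, fasta_path = NULL) {
  lines <- readLines(gff3_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GFF3 line ", which(body)[nf != 9L][1L], " in ",
         gff3_path, " (expected 9 tab-separated fields)")
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  id <- as.character(m$ID)
  parent <- vapply(as.list(m$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))

  class_of_type <- c(mRNA = "mRNA", rRNA = "rRNA", tRNA = "tRNA",
                     snRNA = "snRNA", snoRNA = "snoRNA", ncRNA = "other",
                     transcript = "other")
  is_tx <- type %in% names(class_of_type)
  if (!any(is_tx)) stop("no transcript-level features found in ", gff3_path)
  tx_ids <- id[is_tx]
  if (anyNA(tx_ids)) stop("transcript feature without ID attribute")
  if (anyDuplicated(tx_ids))
    stop("duplicated transcript id(s): ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "))

  if (is.null(fasta_path)) {
    genome_lengths <- tapply(BiocGenerics::end(gr),
                             as.character(GenomicRanges::seqnames(gr)), max)
    genome_lengths <- setNames(as.numeric(genome_lengths),
                               names(genome_lengths))
  } else {
    genome_lengths <- Biostrings::fasta.seqlengths(fasta_path)
  }

  gene_of <- function(i) {
    p <- parent[i]
    if (is.na(p)) return(id[i])
    sub("^gene:", "", p)
  }

  models <- vector("list", sum(is_tx))
  for (k in seq_along(models)) {
    i <- which(is_tx)[k]
    tid <- id[i]
    chrom <- as.character(GenomicRanges::seqnames(gr))[i]
    str <- as.character(BiocGenerics::strand(gr))[i]
    if (!str %in% c("+", "-"))
      stop("transcript '", tid, "' lacks a stranded location")
    child <- !is.na(parent) & parent == tid
    exi <- child & type == "exon"
    if (any(exi)) {
      ex <- cbind(start = BiocGenerics::start(gr)[exi] - 1L,
                  end = BiocGenerics::end(gr)[exi])
    } else {
      ex <- cbind(start = BiocGenerics::start(gr)[i] - 1L,
                  end = BiocGenerics::end(gr)[i])
    }
    cls <- class_of_type[[type[i]]]
    if (cls != "mRNA") {
      models[[k]] <- transcript_model(tid, chrom, str, ex, cls,
                                      gene = gene_of(i))
      next
    }
    cdsi <- child & type == "CDS"
    if (!any(cdsi)) stop("mRNA '", tid, "' has no CDS feature")
    cds <- cbind(start = BiocGenerics::start(gr)[cdsi] - 1L,
                 end = BiocGenerics::end(gr)[cdsi])
    ## every CDS piece must be contained in an exon
    contained <- vapply(seq_len(nrow(cds)), function(j)
      any(ex[, "start"] <= cds[j, "start"] & cds[j, "end"] <= ex[, "end"]),
      logical(1))
    if (!all(contained)) stop("CDS outside exons for mRNA '", tid, "'")
    cds_len <- sum(cds[, "end"] - cds[, "start"])
    u5i <- child & type == "five_prime_UTR"
    u3i <- child & type == "three_prime_UTR"
    if (any(u5i) || any(u3i)) {
      utr5 <- sum(BiocGenerics::width(gr)[u5i])
      utr3 <- sum(BiocGenerics::width(gr)[u3i])
    } else {
      ## derive from CDS vs exon extent in mature coordinates
      tmp <- transcript_model(tid, chrom, str, ex, "other")
      cds_first_g <- if (str == "+") min(cds[, "start"]) else max(cds[, "end"]) - 1L
      utr5 <- to_mature_coord(tmp, cds_first_g)
      if (is.na(utr5)) stop("CDS outside exons for mRNA '", tid, "'")
      utr3 <- tmp$mature_len - utr5 - cds_len
    }
    models[[k]] <- transcript_model(tid, chrom, str, ex, "mRNA",
                                    gene = gene_of(i), utr5_len = utr5,
                                    cds_len = cds_len, utr3_len = utr3)
  }
  build_annotation(models, genome_lengths)
}

#' Map a genomic position to a mature (spliced) coordinate
#'
#' @param t a [transcript_model()].
#' @param g 0-based genomic position.
#' @return 0-based offset along the spliced transcript in 5' to 3'
#'   orientation, or `NA` if `g` falls outside every exon.
#' @export
to_mature_coord <- function(t, g) {
  stopifnot(inherits(t, "transcript_model"))
  ex <- t$exons
  hit <- which(ex[, "start"] <= g & g < ex[, "end"])
  if (!length(hit)) return(NA_integer_)
  off <- if (t$strand == "+") g - ex[hit, "start"] else ex[hit, "end"] - 1L - g
  as.integer(t$cum_before[hit] + off)
}

#' Map a mature coordinate back to a genomic position
#'
#' Inverse of [to_mature_coord()].
#'
#' @param t a [transcript_model()].
#' @param m 0-based mature position, `0 <= m <` mature length.
#' @return 0-based genomic position.
#' @export
to_genomic_coord <- function(t, m) {
  stopifnot(inherits(t, "transcript_model"))
  if (m < 0L || m >= t$mature_len) stop("mature position out of range")
  widths <- t$exons[, "end"] - t$exons[, "start"]
  hit <- findInterval(m, c(t$cum_before, t$mature_len),
                      rightmost.closed = FALSE)
  off <- m - t$cum_before[hit]
  if (t$strand == "+") as.integer(t$exons[hit, "start"] + off)
  else as.integer(t$exons[hit, "end"] - 1L - off)
}

#' Region of a mature position on an mRNA
#'
#' Half-open boundaries: positions `[0, utr5_len)` are 5'UTR,
#' `[utr5_len, utr5_len + cds_len)` CDS, the rest 3'UTR.
#'
#' @param t a [transcript_model()] of class mRNA.
#' @param m 0-based mature position(s).
#' @return Character vector over `"utr5"`, `"cds"`, `"utr3"`.
#' @export
region_at <- function(t, m) {
  stopifnot(inherits(t, "transcript_model"))
  if (t$rna_class != "mRNA") stop("region_at is defined for mRNA only")
  if (any(m < 0L | m >= t$mature_len)) stop("mature position out of range")
  ifelse(m < t$utr5_len, "utr5",
         ifelse(m < t$utr5_len + t$cds_len, "cds", "utr3"))
}

#' Write the transcript table as TSV
#'
#' Columns: id, gene, class, chrom, strand, utr5_len, cds_len, utr3_len.
#'
#' @param ann a `crac_annotation`.
#' @param path output path.
#' @export
write_transcript_table <- function(ann, path) {
  stopifnot(inherits(ann, "crac_annotation"))
  d <- ann$transcripts[, c("id", "gene", "rna_class", "chrom", "strand",
                           "utr5_len", "cds_len", "utr3_len")]
  names(d)[3] <- "class"
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
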