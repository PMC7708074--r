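## Seeded generator of a toy genome, annotation, CRAC read alignments and
## RNA-seq/Ribo-seq count tables with the statistical structure the
## downstream analysis assumes, plus ground truth for recovery tests.

## deterministic sub-seed derivation; keeps every derived seed < 2^31
.sub_seed <- function(seed, a, b = 0L, c = 0L) {
  s <- (as.numeric(seed) %% 65521) * 32749 + a * 10007 + b * 101 + c
  as.integer(s %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults describe the emulated experiment: 2,000 mRNAs plus a small
#' ncRNA complement, log-normal transcript abundance, mRNA-biased class
#' composition of the tagged library, strongly 3'UTR-biased crosslink
#' placement (75% of mRNA reads in 3'UTRs), 160 enriched true-target
#' transcripts drawn from the more abundant half of the mRNAs, two
#' biological x two technical tagged replicates whose per-transcript
#' log-normal noise (sd 0.5, natural-log scale) is calibrated so that
#' between-biological-replicate rank correlation is about 0.8, and a low
#' uniform background in the untagged control.
#'
#' @param n_mrna number of mRNAs.
#' @param n_ncrna named counts of non-coding transcripts per class
#'   (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `other`).
#' @param utr5_range,cds_range,utr3_range uniform length ranges (nt) for
#'   the three mRNA regions.
#' @param ncrna_len_range uniform length range (nt) for ncRNAs.
#' @param abundance_meanlog,abundance_sdlog log-normal transcript abundance.
#' @param class_abundance_scale multiplicative abundance scale per RNA
#'   class, reflecting cellular RNA composition (rRNA and tRNA far more
#'   abundant per transcript than mRNA); keeps the CRAC/RNA-seq RPM ratio
#'   of unenriched mRNAs centered near 1, as in published target scatters.
#' @param propensity_sdlog log-normal spread of the per-transcript binding
#'   propensity (kept small so that ground-truth target labels remain
#'   identifiable; preferential binding is carried by the enrichment
#'   factors).
#' @param class_read_shares simplex over RNA classes for the tagged sample.
#' @param region_weights simplex `(utr5, cds, utr3)` for crosslink
#'   placement within mRNAs.
#' @param n_true_targets number of enriched target mRNAs.
#' @param target_enrichment multiplicative enrichment factor range.
#' @param target_abundance_quantile targets are drawn from mRNAs above this
#'   abundance quantile ("high abundance" targets).
#' @param replicate_noise_sd per-transcript log-normal sd applied per
#'   biological replicate (natural-log scale); technical replicates share
#'   the biological factor and differ only by counting noise.
#' @param control_background fraction of control reads placed uniformly
#'   over the genome.
#' @param reads_per_sample sequencing depth per sample.
#' @param read_length fixed read length (nt).
#' @param n_bio,n_tech tagged replicate structure.
#' @param n_quant_rep replicates per quantification assay (RNA-seq,
#'   Ribo-seq).
#' @param te_sdlog log-normal sd of the Ribo-seq translation-efficiency
#'   factor.
#' @param intergenic_gap spacing (nt) between packed transcripts.
#' @param n_chrom number of chromosomes the transcripts are packed onto.
#' @param seed integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 2000L,
                       n_ncrna = c(rRNA = 20L, tRNA = 60L, snRNA = 6L,
                                   snoRNA = 40L, other = 10L),
                       utr5_range = c(30L, 150L),
                       cds_range = c(300L, 1800L),
                       utr3_range = c(60L, 400L),
                       ncrna_len_range = c(80L, 300L),
                       abundance_meanlog = 0, abundance_sdlog = 1,
                       class_abundance_scale = c(mRNA = 1, rRNA = 60,
                                                 tRNA = 10, snRNA = 5,
                                                 snoRNA = 5, other = 1),
                       propensity_sdlog = 0.1,
                       class_read_shares = c(mRNA = 0.60, rRNA = 0.25,
                                             tRNA = 0.05, snRNA = 0.02,
                                             snoRNA = 0.03, other = 0.05),
                       region_weights = c(utr5 = 0.05, cds = 0.20,
                                          utr3 = 0.75),
                       n_true_targets = 160L,
                       target_enrichment = c(2.5, 4),
                       target_abundance_quantile = 0.5,
                       replicate_noise_sd = 0.5,
                       control_background = 0.10,
                       reads_per_sample = 1e6,
                       read_length = 30L,
                       n_bio = 2L, n_tech = 2L, n_quant_rep = 2L,
                       te_sdlog = 0.5,
                       intergenic_gap = 200L, n_chrom = 4L,
                       seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_ncrna = n_ncrna,
              utr5_range = utr5_range, cds_range = cds_range,
              utr3_range = utr3_range, ncrna_len_range = ncrna_len_range,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              class_abundance_scale = class_abundance_scale,
              propensity_sdlog = propensity_sdlog,
              class_read_shares = class_read_shares,
              region_weights = region_weights,
              n_true_targets = as.integer(n_true_targets),
              target_enrichment = target_enrichment,
              target_abundance_quantile = target_abundance_quantile,
              replicate_noise_sd = replicate_noise_sd,
              control_background = control_background,
              reads_per_sample = reads_per_sample,
              read_length = as.integer(read_length),
              n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
              n_quant_rep = as.integer(n_quant_rep),
              te_sdlog = te_sdlog,
              intergenic_gap = as.integer(intergenic_gap),
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$class_read_shares) - 1) > 1e-9)
    stop("class_read_shares must sum to 1")
  if (abs(sum(cfg$region_weights) - 1) > 1e-9)
    stop("region_weights must sum to 1")
  if (length(cfg$region_weights) != 3L)
    stop("region_weights must have three components (utr5, cds, utr3)")
  if (cfg$reads_per_sample <= 0) stop("reads_per_sample must be > 0")
  if (any(cfg$target_enrichment <= 1))
    stop("target enrichment factors must be > 1")
  if (cfg$n_true_targets > cfg$n_mrna)
    stop("more true targets than mRNAs")
  if (cfg$n_mrna > 0 &&
      (cfg$utr5_range[1] < 1L || cfg$utr3_range[1] < 1L))
    stop("simulated mRNAs must have nonzero UTRs")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d mRNA + %d ncRNA, depth %g, %dx%d ",
                     "tagged replicates, %d targets (%.1f-%.1fx), seed %d\n"),
              x$n_mrna, sum(x$n_ncrna), x$reads_per_sample, x$n_bio,
              x$n_tech, x$n_true_targets, x$target_enrichment[1],
              x$target_enrichment[2], x$seed))
  invisible(x)
}

#' Simulate a toy transcriptome with ground truth
#'
#' Generates transcripts (about half per strand) packed without overlap on
#' `n_chrom` chromosomes, draws per-transcript abundance, binding
#' propensity, Ribo-seq translation efficiency, and spikes
#' `n_true_targets` enriched mRNAs among the more abundant half. Fully
#' deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `crac_sim` with elements `annotation`
#'   (a `crac_annotation`), `truth` (per-transcript ground-truth
#'   data.frame plus the region weights used) and `config`.
#' @export
simulate_transcriptome <- function(cfg = sim_config()) {
  cfg <- validate_sim_config(cfg)
  set.seed(.sub_seed(cfg$seed, 1L))
  runif_int <- function(n, range)
    as.integer(floor(runif(n, range[1], range[2] + 1)))

  n_nc <- cfg$n_ncrna[cfg$n_ncrna > 0]
  classes <- c(rep("mRNA", cfg$n_mrna),
               rep(names(n_nc), as.integer(n_nc)))
  n <- length(classes)
  if (n == 0L) stop("empty transcriptome configuration")
  u5 <- runif_int(n, cfg$utr5_range)
  cds <- runif_int(n, cfg$cds_range)
  u3 <- runif_int(n, cfg$utr3_range)
  len <- ifelse(classes == "mRNA", u5 + cds + u3,
                runif_int(n, cfg$ncrna_len_range))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  chrom_idx <- rep_len(seq_len(cfg$n_chrom), n)
  ids <- sprintf("%s_%05d", classes, seq_len(n))

  models <- vector("list", n)
  offsets <- rep(cfg$intergenic_gap, cfg$n_chrom)
  chrom_names <- sprintf("chrI%02d", seq_len(cfg$n_chrom))
  for (i in seq_len(n)) {
    ci <- chrom_idx[i]
    s0 <- offsets[ci]
    e0 <- s0 + len[i]
    offsets[ci] <- e0 + cfg$intergenic_gap
    models[[i]] <- if (classes[i] == "mRNA")
      transcript_model(ids[i], chrom_names[ci], strand[i],
                       cbind(s0, e0), "mRNA", gene = sub("mRNA", "GENE", ids[i]),
                       utr5_len = u5[i], cds_len = cds[i], utr3_len = u3[i])
    else
      transcript_model(ids[i], chrom_names[ci], strand[i], cbind(s0, e0),
                       classes[i], gene = ids[i])
  }
  genome_lengths <- setNames(offsets, chrom_names)
  ann <- build_annotation(models, genome_lengths)

  scale <- cfg$class_abundance_scale
  scale <- ifelse(classes %in% names(scale), scale[classes], 1)
  abundance <- scale * rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
  propensity <- rlnorm(n, 0, cfg$propensity_sdlog)
  te <- rlnorm(n, 0, cfg$te_sdlog)
  enrichment <- rep(1, n)
  is_target <- rep(FALSE, n)
  if (cfg$n_true_targets > 0L && cfg$n_mrna > 0L) {
    mi <- which(classes == "mRNA")
    cut <- quantile(abundance[mi], cfg$target_abundance_quantile, type = 7)
    pool <- mi[abundance[mi] >= cut]
    targ <- sample(pool, cfg$n_true_targets)
    is_target[targ] <- TRUE
    enrichment[targ] <- runif(cfg$n_true_targets,
                              cfg$target_enrichment[1],
                              cfg$target_enrichment[2])
  }
  truth <- list(
    table = data.frame(id = ids, rna_class = classes,
                       abundance = abundance, propensity = propensity,
                       enrichment = enrichment, te = te,
                       is_target = is_target, stringsAsFactors = FALSE),
    region_weights = cfg$region_weights)
  structure(list(annotation = ann, truth = truth, config = cfg),
            class = "crac_sim")
}

#' @export
print.crac_sim <- function(x, ...) {
  cat("<crac_sim> seed", x$config$seed, "\n")
  print(x$annotation)
  cat(sum(x$truth$table$is_target), "true target mRNAs\n")
  invisible(x)
}

## per-transcript single-exon genomic anchors, used for fast read placement
.tx_anchor <- function(ann) {
  ex <- ann$exons
  m <- S4Vectors::mcols(ex)
  first <- !duplicated(m$transcript_id)
  data.frame(id = m$transcript_id[first],
             chrom = as.character(GenomicRanges::seqnames(ex))[first],
             start0 = BiocGenerics::start(ex)[first] - 1L,
             end0 = BiocGenerics::end(ex)[first],
             strand = as.character(BiocGenerics::strand(ex))[first],
             row.names = m$transcript_id[first],
             stringsAsFactors = FALSE)
}

#' Simulate one CRAC sample
#'
#' Reads are placed class-first (by `class_read_shares`), then on a
#' transcript with probability proportional to abundance x propensity
#' (x enrichment for true targets) x the biological-replicate noise
#' factor, then, for mRNAs, in a region drawn from `region_weights` with
#' the read midpoint uniform within the region. The control role ignores
#' propensity and enrichment and places a `control_background` fraction of
#' its reads uniformly over the genome. Technical replicates of the same
#' biological replicate share the noise factor and differ only by the
#' multinomial draw.
#'
#' @param sim a `crac_sim` from [simulate_transcriptome()].
#' @param role `"tagged"` or `"control"`.
#' @param bio,tech replicate indices.
#' @return A `GRanges` of `reads_per_sample` uniquely mapped reads with
#'   metadata columns `sample`, `role`, `bio`, `tech`, `unique`.
#' @export
simulate_crac_sample <- function(sim, role = c("tagged", "control"),
                                 bio = 1L, tech = 1L) {
  stopifnot(inherits(sim, "crac_sim"))
  role <- match.arg(role)
  cfg <- sim$config
  ann <- sim$annotation
  tt <- sim$truth$table
  anchor <- .tx_anchor(ann)[tt$id, ]
  n_tx <- nrow(tt)
  N <- as.integer(cfg$reads_per_sample)
  rl <- cfg$read_length
  half <- (rl - 1L) %/% 2L

  ## biological noise factor, shared by technical replicates of (role, bio)
  set.seed(.sub_seed(cfg$seed, 2L, bio, as.integer(role == "control")))
  noise <- if (cfg$replicate_noise_sd > 0)
    rlnorm(n_tx, 0, cfg$replicate_noise_sd) else rep(1, n_tx)

  set.seed(.sub_seed(cfg$seed, 3L, bio * 10L + tech,
                     as.integer(role == "control")))
  w <- tt$abundance * noise
  if (role == "tagged") w <- w * tt$propensity * tt$enrichment

  n_bg <- if (role == "control") round(cfg$control_background * N) else 0L
  n_fg <- N - n_bg

  shares <- cfg$class_read_shares
  present <- intersect(names(shares)[shares > 0], unique(tt$rna_class))
  if (!length(present)) stop("no transcript class matches class_read_shares")
  shares <- shares[present] / sum(shares[present])
  cls_draw <- sample(present, n_fg, replace = TRUE, prob = shares)

  idx <- integer(n_fg)
  for (cl in present) {
    sel <- which(cls_draw == cl)
    pool <- which(tt$rna_class == cl)
    idx[sel] <- if (length(pool) == 1L) pool else
      pool[sample.int(length(pool), length(sel), replace = TRUE,
                      prob = w[pool])]
  }

  ## mature midpoint per read
  tx <- ann$transcripts[tt$id, ]
  m <- integer(n_fg)
  is_m <- tt$rna_class[idx] == "mRNA"
  if (any(is_m)) {
    i <- idx[is_m]
    reg <- sample.int(3L, sum(is_m), replace = TRUE,
                      prob = cfg$region_weights)
    L <- cbind(tx$utr5_len[i], tx$cds_len[i], tx$utr3_len[i])
    off <- cbind(0L, tx$utr5_len[i], tx$utr5_len[i] + tx$cds_len[i])
    pick <- cbind(seq_along(i), reg)
    m[is_m] <- off[pick] + as.integer(floor(runif(sum(is_m)) * L[pick]))
  }
  if (any(!is_m)) {
    i <- idx[!is_m]
    m[!is_m] <- as.integer(floor(runif(sum(!is_m)) * tx$mature_len[i]))
  }

  plus <- anchor$strand[idx] == "+"
  g <- ifelse(plus, anchor$start0[idx] + m, anchor$end0[idx] - 1L - m)
  chrom <- anchor$chrom[idx]
  str <- anchor$strand[idx]

  if (n_bg > 0L) {
    gl <- ann$genome_lengths
    bg_chrom <- sample(names(gl), n_bg, replace = TRUE, prob = gl)
    bg_g <- as.integer(floor(runif(n_bg) * gl[bg_chrom]))
    chrom <- c(chrom, bg_chrom)
    g <- c(g, bg_g)
    str <- c(str, sample(c("+", "-"), n_bg, replace = TRUE))
  }

  s0 <- as.integer(g) - half
  maxs <- ann$genome_lengths[chrom] - rl
  s0 <- pmax(0L, pmin(s0, as.integer(maxs)))
  sample_id <- sprintf("%s_b%dt%d", role, bio, tech)
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = s0 + 1L, width = rl),
    strand = str,
    sample = factor(rep(sample_id, N)),
    role = factor(rep(if (role == "tagged") "crac_tagged" else "crac_control",
                      N)),
    bio = rep(as.integer(bio), N), tech = rep(as.integer(tech), N),
    unique = rep(TRUE, N),
    seqlengths = ann$genome_lengths[sort(names(ann$genome_lengths))])
}

#' Simulate the full CRAC replicate set
#'
#' All tagged biological x technical replicates plus one untagged control.
#'
#' @param sim a `crac_sim`.
#' @param control include the untagged control sample.
#' @return A single `GRanges` with per-read sample labels.
#' @export
simulate_crac_experiment <- function(sim, control = TRUE) {
  cfg <- sim$config
  out <- list()
  for (b in seq_len(cfg$n_bio))
    for (te in seq_len(cfg$n_tech))
      out[[length(out) + 1L]] <- simulate_crac_sample(sim, "tagged", b, te)
  if (control)
    out[[length(out) + 1L]] <- simulate_crac_sample(sim, "control", 1L, 1L)
  do.call(c, out)
}

#' Simulate an RNA-seq or Ribo-seq count table
#'
#' Counts are multinomial over transcripts with probabilities proportional
#' to true abundance (times the per-transcript translation-efficiency
#' factor for Ribo-seq), at depth `reads_per_sample`.
#'
#' @param sim a `crac_sim`.
#' @param assay `"rnaseq"` or `"riboseq"`.
#' @param replicate_id replicate index.
#' @return Named integer vector of counts per transcript.
#' @export
simulate_quant_counts <- function(sim, assay = c("rnaseq", "riboseq"),
                                  replicate_id = 1L) {
  stopifnot(inherits(sim, "crac_sim"))
  assay <- match.arg(assay)
  cfg <- sim$config
  tt <- sim$truth$table
  prob <- tt$abundance
  if (assay == "riboseq") prob <- prob * tt$te
  set.seed(.sub_seed(cfg$seed, 4L + (assay == "riboseq"),
                     as.integer(replicate_id)))
  counts <- as.integer(rmultinom(1, cfg$reads_per_sample, prob / sum(prob)))
  setNames(counts, tt$id)
}

#' @rdname simulate_quant_counts
#' @param n_rep number of replicates (defaults to the config's
#'   `n_quant_rep`).
#' @return `simulate_quant_experiment`: transcripts x replicates count
#'   matrix with columns `<assay>_r<i>`.
#' @export
simulate_quant_experiment <- function(sim, assay = c("rnaseq", "riboseq"),
                                      n_rep = NULL) {
  assay <- match.arg(assay)
  if (is.null(n_rep)) n_rep <- sim$config$n_quant_rep
  m <- vapply(seq_len(n_rep), function(r)
    simulate_quant_counts(sim, assay, r),
    numeric(nrow(sim$truth$table)))
  dimnames(m) <- list(sim$truth$table$id,
                      sprintf("%s_r%d", assay, seq_len(n_rep)))
  m
}

#' Write a simulation to disk
#'
#' Writes `genome.fa` (random sequence, seeded), `annotation.gff3`,
#' `truth.tsv` and `config.yaml` (all defaults serialized) into `dir`.
#' Byte-identical across runs for the same config and seed.
#'
#' @param sim a `crac_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "crac_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  gl <- sim$annotation$genome_lengths
  set.seed(.sub_seed(cfg$seed, 9L))
  seqs <- Biostrings::DNAStringSet(vapply(gl, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(seqs) <- names(gl)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write.table(sim$truth$table, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg_out <- cfg
  cfg_out$class_read_shares <- as.list(cfg$class_read_shares)
  cfg_out$class_abundance_scale <- as.list(cfg$class_abundance_scale)
  cfg_out$n_ncrna <- as.list(cfg$n_ncrna)
  cfg_out$region_weights <- as.list(cfg$region_weights)
  yaml::write_yaml(unclass(cfg_out), file.path(dir, "config.yaml"))
  invisible(dir)
}

## map a mature interval [m0, m1) to genomic 0-based half-open pieces
.mature_interval_to_genomic <- function(t, m0, m1) {
  widths <- t$exons[, "end"] - t$exons[, "start"]
  out <- NULL
  for (i in seq_len(nrow(t$exons))) {
    c0 <- t$cum_before[i]; c1 <- c0 + widths[i]
    a <- max(m0, c0); b <- min(m1, c1)
    if (a >= b) next
    if (t$strand == "+")
      piece <- c(t$exons[i, "start"] + (a - c0), t$exons[i, "start"] + (b - c0))
    else
      piece <- c(t$exons[i, "end"] - (b - c0), t$exons[i, "end"] - (a - c0))
    out <- rbind(out, piece)
  }
  out
}

#' Write an annotation as GFF3
#'
#' Emits gene/transcript/exon features, and five_prime_UTR/CDS/
#' three_prime_UTR features for mRNAs (1-based inclusive on disk).
#'
#' @param ann a `crac_annotation`.
#' @param path output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "crac_annotation"))
  rows <- list()
  add <- function(chrom, s0, e0, str, type, id = NA, parent = NA,
                  phase = NA_integer_)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = s0 + 1L, end = e0, strand = str, type = type,
      ID = id, Parent = parent, phase = phase, stringsAsFactors = FALSE)
  type_of_class <- c(mRNA = "mRNA", rRNA = "rRNA", tRNA = "tRNA",
                     snRNA = "snRNA", snoRNA = "snoRNA", other = "ncRNA")
  for (id in ann$transcripts$id) {
    t <- transcript(ann, id)
    span <- c(min(t$exons[, "start"]), max(t$exons[, "end"]))
    gid <- paste0("gene:", t$gene)
    add(t$chrom, span[1], span[2], t$strand, "gene", id = gid)
    add(t$chrom, span[1], span[2], t$strand, type_of_class[[t$rna_class]],
        id = t$id, parent = gid)
    for (i in seq_len(nrow(t$exons)))
      add(t$chrom, t$exons[i, "start"], t$exons[i, "end"], t$strand, "exon",
          id = sprintf("%s.exon%d", t$id, i), parent = t$id)
    if (t$rna_class == "mRNA") {
      bounds <- list(
        five_prime_UTR = c(0L, t$utr5_len),
        CDS = c(t$utr5_len, t$utr5_len + t$cds_len),
        three_prime_UTR = c(t$utr5_len + t$cds_len, t$mature_len))
      for (ft in names(bounds)) {
        b <- bounds[[ft]]
        if (b[1] == b[2]) next
        pieces <- .mature_interval_to_genomic(t, b[1], b[2])
        for (j in seq_len(nrow(pieces)))
          add(t$chrom, pieces[j, 1], pieces[j, 2], t$strand, ft,
              id = sprintf("%s.%s.%d", t$id, ft, j), parent = t$id,
              phase = if (ft == "CDS") 0L else NA_integer_)
      }
    }
  }
  d <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = d$chrom, ranges = IRanges::IRanges(d$start, d$end),
    strand = d$strand, type = d$type, ID = d$ID,
    Parent = ifelse(is.na(d$Parent), "", d$Parent), phase = d$phase)
  S4Vectors::mcols(gr)$Parent <- S4Vectors::mcols(gr)$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
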