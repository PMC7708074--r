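## Pipeline orchestration: run the stages end-to-end on synthetic data
## (or from previously written artifacts), with fixed artifact names in a
## run directory and a JSON manifest recording parameters and checksums.

PIPELINE_STAGES <- c("simulate", "classify", "count", "metagene", "stats",
                     "call-targets", "track", "domains")

.artifact <- function(outdir, name) file.path(outdir, name)

.need_file <- function(stage, path) {
  if (!file.exists(path))
    stop("stage '", stage, "': missing input '", basename(path),
         "' (run the producing stage first)")
  path
}

#' Run the CRAC analysis pipeline
#'
#' Executes the requested stages in order, chaining results in memory and
#' writing fixed-name TSV/bedGraph artifacts plus a `manifest.json`
#' (parameters, seed, package version, file checksums) into `outdir`.
#' `stages = "all"` runs simulate, classify, count, metagene, stats,
#' call-targets, track and domains end-to-end on synthetic data. A stage
#' started without its inputs (in memory or on disk) fails naming the
#' missing artifact.
#'
#' @param config a [sim_config()]; its seed drives all randomness.
#' @param outdir run directory (created if needed).
#' @param stages `"all"` or a subset of
#'   `c("simulate", "classify", "count", "metagene", "stats",
#'   "call-targets", "track", "domains")`.
#' @param min_rpm metagene RPM filter.
#' @param metagene_filter `"rpm"` or `"reads"`.
#' @param thresholds a [calling_thresholds()].
#' @param protein_fasta protein FASTA for the domains stage (defaults to
#'   the synthetic R3H-SUZ family shipped with the package).
#' @param motif consensus pattern for the domains stage.
#' @param write_reads also write all simulated reads as `reads.bed`
#'   (needed to run later stages in a separate invocation; off by default
#'   because the file is large at full depth).
#' @param plot write PDF plots of the aggregate metagene and PCA.
#' @return Invisibly, a list with the in-memory stage products
#'   (`sim`, `reads`, `counts`, `aggregate`, `targets`, ...).
#' @export
run_pipeline <- function(config = sim_config(), outdir, stages = "all",
                         min_rpm = 100, metagene_filter = "rpm",
                         thresholds = calling_thresholds(),
                         protein_fasta = NULL, motif = "EERXXXYXXXRX+IF",
                         write_reads = FALSE, plot = FALSE) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- list()
  written <- character(0)
  emit <- function(name) written[[length(written) + 1L]] <<- name

  load_reads <- function(stage) {
    if (!is.null(st$reads)) return(st$reads)
    p <- .need_file(stage, .artifact(outdir, "reads.bed"))
    read_reads(p)
  }
  load_ann <- function(stage) {
    if (!is.null(st$sim)) return(st$sim$annotation)
    load_annotation(.need_file(stage, .artifact(outdir, "annotation.gff3")),
                    .artifact(outdir, "genome.fa"))
  }
  load_counts <- function(stage) {
    if (!is.null(st$cm)) return(st$cm)
    cp <- .need_file(stage, .artifact(outdir, "counts.tsv"))
    sp <- .need_file(stage, .artifact(outdir, "samples.tsv"))
    counts <- as.matrix(read.table(cp, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
    si <- read_tsv(sp)
    cm <- new_crac_counts(counts, si)
    cm$lib_size <- setNames(si$lib_size, si$sample)
    rpm_normalize(cm)
  }

  if ("simulate" %in% stages) {
    sim <- simulate_transcriptome(config)
    write_simulation(sim, outdir)
    emit("genome.fa"); emit("annotation.gff3"); emit("truth.tsv")
    emit("config.yaml")
    write_transcript_table(sim$annotation,
                           .artifact(outdir, "transcripts.tsv"))
    emit("transcripts.tsv")
    reads <- simulate_crac_experiment(sim)
    rnaseq <- simulate_quant_experiment(sim, "rnaseq")
    riboseq <- simulate_quant_experiment(sim, "riboseq")
    write_tsv(data.frame(transcript_id = rownames(rnaseq), rnaseq,
                         check.names = FALSE),
              .artifact(outdir, "rnaseq_counts.tsv"))
    emit("rnaseq_counts.tsv")
    write_tsv(data.frame(transcript_id = rownames(riboseq), riboseq,
                         check.names = FALSE),
              .artifact(outdir, "riboseq_counts.tsv"))
    emit("riboseq_counts.tsv")
    if (write_reads) {
      write_reads_bed(reads, .artifact(outdir, "reads.bed"))
      emit("reads.bed")
    }
    st$sim <- sim; st$reads <- reads
    st$rnaseq <- rnaseq; st$riboseq <- riboseq
  }

  if ("classify" %in% stages) {
    shares <- classify_reads(load_reads("classify"), load_ann("classify"))
    write_tsv(shares, .artifact(outdir, "class_shares.tsv"))
    emit("class_shares.tsv")
    st$shares <- shares
  }

  if ("count" %in% stages) {
    ann <- load_ann("count")
    reads <- load_reads("count")
    cm <- rpm_normalize(count_per_transcript(reads, ann))
    for (nm in c("rnaseq", "riboseq")) {
      qc <- st[[nm]]
      if (is.null(qc)) {
        p <- .artifact(outdir, paste0(nm, "_counts.tsv"))
        if (file.exists(p)) {
          q <- read.table(p, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
          qc <- as.matrix(q)
        }
      }
      if (!is.null(qc)) cm <- add_counts(cm, qc, nm)
    }
    write_tsv(data.frame(transcript_id = rownames(cm$counts), cm$counts,
                         check.names = FALSE),
              .artifact(outdir, "counts.tsv"))
    emit("counts.tsv")
    write_tsv(data.frame(transcript_id = rownames(cm$rpm),
                         round(cm$rpm, 4), check.names = FALSE),
              .artifact(outdir, "rpm.tsv"))
    emit("rpm.tsv")
    write_tsv(data.frame(cm$samples, lib_size = cm$lib_size),
              .artifact(outdir, "samples.tsv"))
    emit("samples.tsv")
    rc <- count_by_region(reads, ann)
    write_tsv(rc, .artifact(outdir, "region_counts.tsv"))
    emit("region_counts.tsv")
    st$cm <- cm; st$region_counts <- rc
  }

  if ("metagene" %in% stages) {
    ann <- load_ann("metagene")
    reads <- load_reads("metagene")
    cm <- load_counts("metagene")
    profs <- metagene_profiles(reads, ann)
    agg <- aggregate_metagene(profs, cm, min_rpm = min_rpm,
                              filter = metagene_filter)
    write_tsv(data.frame(transcript_id = rownames(profs$profile),
                         round(profs$profile, 6), check.names = FALSE),
              .artifact(outdir, "metagene_profiles.tsv"))
    emit("metagene_profiles.tsv")
    write_tsv(data.frame(bin = seq_along(agg$values) - 1L,
                         density = round(agg$values, 8)),
              .artifact(outdir, "aggregate_profile.tsv"))
    emit("aggregate_profile.tsv")
    rc <- if (!is.null(st$region_counts)) st$region_counts else
      read_tsv(.need_file("metagene", .artifact(outdir, "region_counts.tsv")))
    rc <- rc[rc$transcript_id %in% agg$transcript_ids, , drop = FALSE]
    rf <- region_fraction(rc)
    write_tsv(rf, .artifact(outdir, "region_fractions.tsv"))
    emit("region_fractions.tsv")
    write_tsv(cbind(stat = rownames(region_fraction_summary(rf)),
                    region_fraction_summary(rf)),
              .artifact(outdir, "region_fraction_summary.tsv"))
    emit("region_fraction_summary.tsv")
    if (plot) {
      grDevices::pdf(.artifact(outdir, "metagene.pdf"), 6, 4)
      plot(agg, main = sprintf("aggregate metagene (n = %d)",
                               agg$n_transcripts))
      grDevices::dev.off()
      emit("metagene.pdf")
    }
    st$profiles <- profs; st$aggregate <- agg; st$region_fractions <- rf
  }

  if ("stats" %in% stages) {
    cm <- load_counts("stats")
    sm <- sample_matrix(cm)
    for (meth in c("spearman", "pearson")) {
      cmx <- correlate_matrix(sm, meth)
      write_tsv(data.frame(sample = rownames(cmx), round(cmx, 4),
                           check.names = FALSE),
                .artifact(outdir, paste0("correlations_", meth, ".tsv")))
      emit(paste0("correlations_", meth, ".tsv"))
    }
    pca <- pca_samples(sm)
    write_tsv(data.frame(sample = rownames(pca$coords),
                         round(pca$coords, 4), check.names = FALSE),
              .artifact(outdir, "pca_coords.tsv"))
    emit("pca_coords.tsv")
    write_tsv(data.frame(component = seq_along(pca$var_explained),
                         var_explained = round(pca$var_explained, 4)),
              .artifact(outdir, "pca_variance.tsv"))
    emit("pca_variance.tsv")
    if (plot) {
      grDevices::pdf(.artifact(outdir, "pca.pdf"), 5, 5)
      plot(pca, main = "sample PCA")
      grDevices::dev.off()
      emit("pca.pdf")
    }
    st$pca <- pca; st$sm <- sm
  }

  if ("call-targets" %in% stages) {
    cm <- load_counts("call-targets")
    ann <- load_ann("call-targets")
    tc <- call_targets(mrna_counts(cm, ann), thresholds)
    write_tsv(as.data.frame(tc), .artifact(outdir, "targets.tsv"))
    emit("targets.tsv")
    st$targets <- tc
  }

  if ("track" %in% stages) {
    reads <- load_reads("track")
    ann <- load_ann("track")
    tc <- st$targets
    if (is.null(tc)) {
      p <- .need_file("track", .artifact(outdir, "targets.tsv"))
      tc <- read_tsv(p)
    }
    top <- if (any(tc$high_confidence)) tc$transcript_id[tc$high_confidence][1]
           else tc$transcript_id[1]
    chrom <- ann$transcripts[top, "chrom"]
    samp <- levels(.read_samples(reads))[1]
    export_track(reads, sample = samp, chrom = chrom,
                 path = .artifact(outdir, "track.bedgraph"))
    emit("track.bedgraph")
  }

  if ("domains" %in% stages) {
    if (is.null(protein_fasta))
      protein_fasta <- system.file("extdata",
                                   "synthetic_r3h_suz_proteins.fasta",
                                   package = "cracbind")
    .need_file("domains", protein_fasta)
    seqs <- read_protein_fasta(protein_fasta)
    pat <- consensus_pattern(motif)
    hits <- do.call(rbind, lapply(names(seqs), function(nm) {
      pos <- scan_motif(seqs[[nm]], pat)
      if (!length(pos)) return(NULL)
      data.frame(protein = nm, start = pos, stringsAsFactors = FALSE)
    }))
    if (is.null(hits)) hits <- data.frame(protein = character(),
                                          start = integer())
    write_tsv(hits, .artifact(outdir, "motif_matches.tsv"))
    emit("motif_matches.tsv")
    kept <- reduce_redundancy(seqs, threshold = 60)
    write_protein_fasta(kept, .artifact(outdir, "reduced_proteins.fasta"))
    emit("reduced_proteins.fasta")
    st$motif_matches <- hits; st$kept_proteins <- kept
  }

  manifest <- list(
    tool = "cracbind",
    version = as.character(utils::packageVersion("cracbind")),
    seed = config$seed,
    stages = stages,
    parameters = list(min_rpm = min_rpm, metagene_filter = metagene_filter,
                      thresholds = unclass(thresholds),
                      motif = motif,
                      config = unclass(config)),
    files = as.list(tools::md5sum(file.path(outdir, sort(unlist(written))))))
  names(manifest$files) <- sort(unlist(written))
  jsonlite::write_json(manifest, .artifact(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(st)
}

#' Command-line entry point
#'
#' Thin wrapper over [run_pipeline()] used by `inst/scripts/cracbind.R`.
#' Usage: `cracbind.R <stage|all> --outdir DIR [--config cfg.yaml]
#' [--seed N] [--min-rpm X] [--protein-fasta F] [--motif PAT] [--plot]
#' [--write-reads] [--log-level L]`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit status (0 on success), invisibly.
#' @export
cracbind_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: cracbind.R <",
                  paste(c(PIPELINE_STAGES, "all"), collapse = "|"),
                  "> --outdir DIR [--config cfg.yaml] [--seed N]\n",
                  "       [--min-rpm X] [--protein-fasta F] [--motif PAT]",
                  " [--plot] [--write-reads] [--log-level L]")
  status <- tryCatch({
    if (!length(args)) stop(usage, call. = FALSE)
    stage <- args[1]
    args <- args[-1]
    opt <- list(outdir = NULL, config = NULL, seed = NULL,
                `min-rpm` = "100", `protein-fasta` = NULL, motif =
                  "EERXXXYXXXRX+IF", `log-level` = "info")
    flags <- c(plot = FALSE, `write-reads` = FALSE)
    i <- 1L
    while (i <= length(args)) {
      a <- sub("^--", "", args[i])
      if (a %in% names(flags)) { flags[a] <- TRUE; i <- i + 1L; next }
      if (!a %in% names(opt)) stop("unknown option --", a, "\n", usage,
                                   call. = FALSE)
      if (i == length(args)) stop("option --", a, " needs a value",
                                  call. = FALSE)
      opt[[a]] <- args[i + 1L]
      i <- i + 2L
    }
    if (is.null(opt$outdir)) stop("--outdir is required\n", usage,
                                  call. = FALSE)
    cfg_args <- if (!is.null(opt$config)) yaml::read_yaml(opt$config)
                else list()
    for (nm in c("class_read_shares", "region_weights", "n_ncrna",
                 "class_abundance_scale"))
      if (!is.null(cfg_args[[nm]])) cfg_args[[nm]] <- unlist(cfg_args[[nm]])
    if (!is.null(opt$seed)) cfg_args$seed <- as.integer(opt$seed)
    cfg <- do.call(sim_config, cfg_args)
    run_pipeline(cfg, outdir = opt$outdir, stages =
                   if (stage == "all") "all" else stage,
                 min_rpm = as.numeric(opt$`min-rpm`),
                 protein_fasta = opt$`protein-fasta`, motif = opt$motif,
                 write_reads = flags[["write-reads"]],
                 plot = flags[["plot"]])
    0L
  }, error = function(e) {
    message("cracbind: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
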