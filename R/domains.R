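## Protein-domain toolkit for R3H-SUZ conservation analysis: consensus
## motif scanning (SUZ motif EERXXXYXXXRX+IF), pairwise identity and
## similarity over a global alignment, and greedy redundancy reduction.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

#' Parse a consensus pattern
#'
#' Pattern notation: literal residues, `X` for any residue, `+` for a
#' positively charged residue (`K`/`R` by default; histidine optionally
#' included).
#'
#' @param pattern pattern string, e.g. `"EERXXXYXXXRX+IF"`.
#' @param plus_residues residues matched by `+`.
#' @return An object of class `consensus_pattern`.
#' @export
consensus_pattern <- function(pattern, plus_residues = c("K", "R")) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  sym <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(sym, c(AA20, "X", "+"))
  if (length(bad))
    stop("invalid pattern symbol(s): ", paste(unique(bad), collapse = ", "))
  stopifnot(all(plus_residues %in% AA20))
  allowed <- lapply(sym, function(s) {
    if (s == "X") AA20 else if (s == "+") plus_residues else s
  })
  structure(list(pattern = toupper(pattern), symbols = sym,
                 allowed = allowed, plus_residues = plus_residues),
            class = "consensus_pattern")
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("<consensus_pattern> %s ('+' = {%s})\n", x$pattern,
              paste(x$plus_residues, collapse = ",")))
  invisible(x)
}

.check_protein <- function(seq) {
  if (inherits(seq, "AAString") || inherits(seq, "AAStringSet"))
    seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(ch, AA20)
  if (length(bad))
    stop("non-amino-acid character(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  seq
}

#' Scan a protein sequence for a consensus motif
#'
#' Reports all (possibly overlapping) placements where every position
#' satisfies its pattern symbol.
#'
#' @param seq protein sequence (character or `AAString`) over the 20
#'   standard residues.
#' @param pattern a [consensus_pattern()] or pattern string.
#' @return Integer vector of 1-based match start positions.
#' @export
scan_motif <- function(seq, pattern) {
  seq <- .check_protein(seq)
  if (!inherits(pattern, "consensus_pattern"))
    pattern <- consensus_pattern(pattern)
  ## overlapping matches via a zero-width lookahead regex
  rx <- paste(vapply(pattern$allowed, function(a)
    if (length(a) == 20L) "." else if (length(a) == 1L) a
    else paste0("[", paste(a, collapse = ""), "]"),
    character(1)), collapse = "")
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Pairwise identity and similarity from a global alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine
#' gaps (opening 10, extension 0.5 by default). Percent identity is the
#' fraction of aligned columns with identical residues; percent similarity
#' counts columns whose substitution score is positive (identities
#' included). The denominator is all aligned columns, including columns
#' where one sequence has a gap.
#'
#' @param a,b protein sequences (character or `AAString`), non-empty.
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties.
#' @return An object of class `pairwise_result` with `identity`,
#'   `similarity` (percent), `aligned_length`, `gaps`.
#' @export
pairwise_identity_similarity <- function(a, b,
                                         substitution_matrix = "BLOSUM62",
                                         gap_open = 10, gap_extend = 0.5) {
  a <- .check_protein(a); b <- .check_protein(b)
  mat <- .subst_matrix(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ncol_aln <- length(pa)
  no_gap <- pa != "-" & sa != "-"
  ident <- no_gap & pa == sa
  score_pos <- no_gap
  score_pos[no_gap] <- mat[cbind(pa[no_gap], sa[no_gap])] > 0
  structure(list(identity = 100 * sum(ident) / ncol_aln,
                 similarity = 100 * sum(score_pos) / ncol_aln,
                 aligned_length = ncol_aln,
                 gaps = sum(!no_gap)),
            class = "pairwise_result")
}

.subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("<pairwise_result> identity %.1f%%, similarity %.1f%% over %d columns (%d gap positions)\n",
              x$identity, x$similarity, x$aligned_length, x$gaps))
  invisible(x)
}

#' Greedy redundancy reduction
#'
#' Scans sequences in input order and keeps a sequence iff its pairwise
#' identity (via [pairwise_identity_similarity()]) to every already-kept
#' sequence is below the threshold. Input order is preserved in the
#' output.
#'
#' @param seqs named character vector or `AAStringSet` (>= 1 sequence).
#' @param threshold percent-identity threshold (default 60).
#' @param ... passed to [pairwise_identity_similarity()].
#' @return The kept subset, same type ordering as the input (named
#'   character vector).
#' @export
reduce_redundancy <- function(seqs, threshold = 60, ...) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  kept <- character(0)
  for (i in seq_along(seqs)) {
    ok <- TRUE
    for (k in kept) {
      if (pairwise_identity_similarity(seqs[[i]], seqs[[k]], ...)$identity >=
          threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, names(seqs)[i])
  }
  seqs[kept]
}

#' Domain annotation of an R3H-SUZ protein
#'
#' Residue intervals are 1-based inclusive. Defaults describe Rbs1: R3H
#' domain at residues 5-90 with key residues Arg57 and His61, SUZ domain
#' at 124-195.
#'
#' @param protein_id protein identifier.
#' @param r3h_span,suz_span residue intervals `c(start, end)`.
#' @param key_residues named residue positions.
#' @param seq_length optional sequence length for span validation.
#' @return An object of class `domain_annotation`.
#' @export
domain_annotation <- function(protein_id = "Rbs1", r3h_span = c(5L, 90L),
                              suz_span = c(124L, 195L),
                              key_residues = c(Arg = 57L, His = 61L),
                              seq_length = NULL) {
  stopifnot(r3h_span[1] >= 1L, r3h_span[1] <= r3h_span[2],
            suz_span[1] >= 1L, suz_span[1] <= suz_span[2])
  if (!is.null(seq_length) && max(r3h_span[2], suz_span[2]) > seq_length)
    stop("domain span beyond sequence length")
  structure(list(protein_id = protein_id, r3h_span = as.integer(r3h_span),
                 suz_span = as.integer(suz_span),
                 key_residues = key_residues),
            class = "domain_annotation")
}

#' Extract the R3H-SUZ region of a protein
#'
#' By default the union span of the R3H and SUZ domains (Rbs1 residues
#' 5-195), the region used for cross-species identity/similarity
#' comparisons.
#'
#' @param seq protein sequence.
#' @param dom a [domain_annotation()] (or `span = c(start, end)` given
#'   directly, 1-based inclusive).
#' @param span explicit residue interval overriding `dom`.
#' @return Character sequence of the region.
#' @export
r3h_suz_region <- function(seq, dom = domain_annotation(), span = NULL) {
  seq <- .check_protein(seq)
  if (is.null(span))
    span <- c(min(dom$r3h_span[1], dom$suz_span[1]),
              max(dom$r3h_span[2], dom$suz_span[2]))
  if (span[2] > nchar(seq)) stop("region span beyond sequence length")
  substr(seq, span[1], span[2])
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  setNames(as.character(s), sub("\\s.*$", "", names(s)))
}

#' Write protein sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  s <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}
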