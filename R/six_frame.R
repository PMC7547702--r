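#' Six-frame translated homology search
#'
#' Desk-scale translated search: translates each genome sequence in all six
#' reading frames and aligns every protein query against every frame with an
#' affine-gap local (Smith-Waterman) alignment under BLOSUM62. The best local
#' alignment per query x frame is reported as a hit when its raw score
#' reaches `min_score`, with percent identity over the alignment length and
#' frame-correct nucleotide coordinates on the original sequence.
#' Ambiguous codons translate to `X`.
#'
#' E-values are approximated from the gapped Karlin-Altschul parameters for
#' BLOSUM62 (lambda = 0.267, K = 0.041) and are intended for threshold
#' filtering of fixtures, not as reproductions of NCBI e-values.
#'
#' @param genome A [Biostrings::DNAStringSet], a single `DNAString`, or a
#'   FASTA path.
#' @param queries A [Biostrings::AAStringSet] or FASTA path of protein
#'   queries.
#' @param substitution_matrix Scoring matrix name or matrix
#'   (default "BLOSUM62").
#' @param gap_opening,gap_extension Affine gap penalties as positive costs; a
#'   gap of length L costs `gap_opening + L * gap_extension`
#'   (defaults 11 and 1).
#' @param min_score Minimum raw alignment score to report (default 50).
#' @return Hit `data.frame` in the [parse_hits()] layout (plus a `frame`
#'   column: 1..3 forward, -1..-3 reverse).
#' @export
six_frame_search <- function(genome, queries,
                             substitution_matrix = "BLOSUM62",
                             gap_opening = 11, gap_extension = 1,
                             min_score = 50) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(genome)
    names(genome) <- "seq1"
  }
  if (is.character(queries)) queries <- Biostrings::readAAStringSet(queries)
  if (methods::is(queries, "AAString")) {
    queries <- Biostrings::AAStringSet(queries)
    names(queries) <- "query1"
  }
  if (length(genome) == 0) stop("empty genome")
  if (length(queries) == 0) stop("empty query set")
  if (is.character(substitution_matrix)) {
    submat <- get(data(list = substitution_matrix,
                       package = "Biostrings",
                       envir = environment()))
  } else {
    submat <- substitution_matrix
  }

  # strip names to first token, as BLAST does
  names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[`, character(1), 1)
  names(queries) <- vapply(strsplit(names(queries), "\\s+"), `[`, character(1), 1)

  hits <- list()
  for (gi in seq_along(genome)) {
    gseq <- genome[[gi]]
    L <- length(gseq)
    rc <- Biostrings::reverseComplement(gseq)
    for (fr in c(1, 2, 3, -1, -2, -3)) {
      src <- if (fr > 0) gseq else rc
      off <- abs(fr) - 1
      n_codons <- (length(src) - off) %/% 3
      if (n_codons < 1) next
      aa <- suppressWarnings(Biostrings::translate(
        Biostrings::subseq(src, off + 1, off + 3 * n_codons),
        if.fuzzy.codon = "X", no.init.codon = TRUE))
      aa_chr <- chartr("*", "X", as.character(aa))
      if (nchar(aa_chr) == 0) next
      frame_seq <- Biostrings::AAString(aa_chr)
      for (qi in seq_along(queries)) {
        aln <- Biostrings::pairwiseAlignment(
          queries[[qi]], frame_seq, type = "local",
          substitutionMatrix = submat,
          gapOpening = gap_opening, gapExtension = gap_extension)
        sc <- Biostrings::score(aln)
        if (sc < min_score) next
        alen <- Biostrings::nchar(aln)
        nid <- Biostrings::nmatch(aln)
        s_aa <- c(Biostrings::start(Biostrings::subject(aln)),
                  Biostrings::end(Biostrings::subject(aln)))
        # aa -> nt coordinates in the frame's source strand
        nt1 <- off + 3 * (s_aa[1] - 1) + 1
        nt2 <- off + 3 * s_aa[2]
        if (fr > 0) {
          sstart <- nt1; send <- nt2; strand <- "+"
        } else {
          sstart <- L - nt2 + 1; send <- L - nt1 + 1; strand <- "-"
        }
        bit <- (0.267 * sc - log(0.041)) / log(2)
        evalue <- length(queries[[qi]]) * nchar(aa_chr) * 2^(-bit)
        hits[[length(hits) + 1]] <- data.frame(
          query_gene = names(queries)[qi],
          subject_id = names(genome)[gi],
          percent_identity = round(100 * nid / alen, 2),
          align_length = alen,
          mismatches = Biostrings::nmismatch(aln),
          gap_opens = count_gap_opens(aln),
          query_start = Biostrings::start(Biostrings::pattern(aln)),
          query_end = Biostrings::end(Biostrings::pattern(aln)),
          subject_start = sstart,
          subject_end = send,
          e_value = evalue,
          bit_score = round(bit, 1),
          strand = strand,
          frame = fr,
          score = sc,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) {
    out <- empty_hits()
    out$frame <- integer(0)
    out$score <- numeric(0)
    return(out)
  }
  do.call(rbind, hits)
}

# number of gap openings in an alignment (runs of "-" in either aligned string)
count_gap_opens <- function(aln) {
  n_runs <- function(s) {
    m <- gregexpr("-+", s)[[1]]
    if (m[1] == -1) 0L else length(m)
  }
  n_runs(as.character(Biostrings::alignedPattern(aln))) +
    n_runs(as.character(Biostrings::alignedSubject(aln)))
}
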