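# Exact shared-substring alignment for synthetic (desk-scale) genome
# pairs: non-overlapping query k-mers are matched exactly against every
# reference chromosome on both strands (Biostrings PDict search), and the
# resulting anchors are chained into synteny blocks. With i.i.d. random
# sequence and verbatim-copied segments, k-mers of >= ~32 bp are unique,
# so the chained anchors recover the true homology segments exactly.

#' Exact-match alignment of two genomes into synteny blocks
#'
#' Intended for truth-known synthetic genome pairs (e.g. the output of
#' [rearrange_genome()]) where homologous segments are exact copies; it is
#' not a substitute for a scoring aligner on real, diverged genomes.
#'
#' @param ref,query Named [Biostrings::DNAStringSet]s or `TruthGenome`s.
#' @param k Anchor k-mer length in bp (default 64). Anchors are taken at
#'   non-overlapping offsets `0, k, 2k, ...` of each query chromosome.
#' @param chain Chain collinear anchors into blocks (default TRUE).
#' @param max_gap Maximum gap passed to [chain_blocks()] (default `2 * k`,
#'   enough to jump one missing anchor).
#' @return Synteny blocks as for [read_alignments()]; each unchained
#'   anchor has `length = k`.
#' @export
align_exact <- function(ref, query, k = 64L, chain = TRUE, max_gap = 2L * k) {
  if (inherits(ref, "TruthGenome")) ref <- ref$seqs
  if (inherits(query, "TruthGenome")) query <- query$seqs
  stopifnot(methods::is(ref, "DNAStringSet"), methods::is(query, "DNAStringSet"),
            !is.null(names(ref)), !is.null(names(query)))

  anchors <- list()
  for (qname in names(query)) {
    qseq <- query[[qname]]
    L <- length(qseq)
    if (L < k) next
    offs <- seq.int(0L, L - k, by = k)
    kmers <- Biostrings::DNAStringSet(qseq, start = offs + 1L, width = k)
    pd_fwd <- Biostrings::PDict(kmers)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(kmers))
    for (rname in names(ref)) {
      rseq <- ref[[rname]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_fwd else pd_rev
        m <- Biostrings::matchPDict(pd, rseq)
        cnt <- S4Vectors::elementNROWS(m)
        if (sum(cnt) == 0L) next
        starts <- IRanges::start(unlist(m))
        qi <- rep(seq_along(cnt), cnt)
        anchors[[length(anchors) + 1L]] <- data.frame(
          ref_chrom = rname, ref_start = starts - 1L,
          ref_end = starts - 1L + k,
          query_chrom = qname,
          query_start = offs[qi], query_end = offs[qi] + k,
          strand = strand, length = k, score = as.numeric(k),
          stringsAsFactors = FALSE)
      }
    }
  }
  blocks <- if (length(anchors)) new_blocks(do.call(rbind, anchors)) else
    empty_blocks()
  if (chain && nrow(blocks) > 1L)
    blocks <- chain_blocks(blocks, max_gap = max_gap)
  blocks
}
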