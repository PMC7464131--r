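# File writers for the synthetic-data and pipeline outputs. All tabular
# output is plain TSV; sequence output is FASTA via Biostrings; interval
# tracks are BED (0-based half-open, as the format requires).

#' Write synthetic-data artifacts to disk
#'
#' Serialises a truth genome, assembly and BAC set in standard formats:
#' FASTA for sequences, BED for the scaffold truth map, TSV for the FISH
#' truth table, plus a JSON run manifest echoing the configuration.
#'
#' @param dir Output directory (created if absent).
#' @param truth Optional `TruthGenome`.
#' @param assembly Optional `AssemblyWithTruth`.
#' @param bacs Optional `BacSet`.
#' @param manifest Optional named list of run parameters (seeds, sizes,
#'   rates) echoed verbatim into `manifest.json`.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_data <- function(dir, truth = NULL, assembly = NULL,
                                 bacs = NULL, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  add <- function(p) paths <<- c(paths, p)
  if (!is.null(truth)) {
    p <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(truth$seqs, p); add(p)
    p <- file.path(dir, "chromosomes.tsv")
    write_tsv(truth$chromosomes, p); add(p)
  }
  if (!is.null(assembly)) {
    p <- file.path(dir, "assembly.fa")
    Biostrings::writeXStringSet(assembly$scaffolds, p); add(p)
    p <- file.path(dir, "truth_map.bed")
    tm <- assembly$truth_map
    bed <- data.frame(tm$scaffold, tm$s_start, tm$s_end,
                      sprintf("%s:%d-%d", tm$chrom, tm$c_start, tm$c_end),
                      0L, tm$orientation)
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    add(p)
  }
  if (!is.null(bacs)) {
    p <- file.path(dir, "clones.fa")
    Biostrings::writeXStringSet(bacs$seqs, p); add(p)
    p <- file.path(dir, "fish_truth.tsv")
    write_tsv(bacs$clones, p); add(p)
  }
  if (!is.null(manifest)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    add(p)
  }
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
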