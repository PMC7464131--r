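# Sliding-window BAC mapping: split clone sequences into overlapping
# windows, map the windows to an assembly, and call clone placements from
# window-count support.

#' Split a sequence into sliding windows
#'
#' Produces windows at offsets `0, step, 2*step, ...` while
#' `offset + window <= length(sequence)`. Because `window >= step`, the
#' trailing remainder after the last full window is always shorter than
#' `step`, so full windows leave at most `step - 1` bases unexamined and no
#' tail window is needed; a tail would only ever be added if more than
#' `step` bases remained uncovered, which cannot occur for valid inputs.
#' A sequence shorter than `window` yields a single full-length window
#' flagged `short`.
#'
#' @param sequence Character scalar or [Biostrings::DNAString].
#' @param window Window length in bp (default 150).
#' @param step Step size in bp (default 50); must satisfy
#'   `window >= step >= 1`.
#' @return data.frame with columns `index` (0-based ordinal), `offset`
#'   (bp, equal to `index * step`), `length`, `sequence`, `short`.
#' @examples
#' nrow(split_windows(strrep("A", 250)))  # offsets 0, 50, 100
#' @export
split_windows <- function(sequence, window = 150L, step = 50L) {
  if (step < 1L || window < step)
    stop("need window >= step >= 1", call. = FALSE)
  s <- as.character(sequence)
  L <- nchar(s)
  if (L < window) {
    return(data.frame(index = 0L, offset = 0L, length = L,
                      sequence = s, short = TRUE, stringsAsFactors = FALSE))
  }
  offsets <- seq.int(0L, L - window, by = step)
  remainder <- L - (offsets[length(offsets)] + window)
  if (remainder > step)  # unreachable when window >= step; kept as a guard
    offsets <- c(offsets, offsets[length(offsets)] + step)
  data.frame(index = seq_along(offsets) - 1L, offset = offsets,
             length = pmin(window, L - offsets),
             sequence = substring(s, offsets + 1L, offsets + window),
             short = FALSE, stringsAsFactors = FALSE)
}

#' Map clone windows onto an assembly by ungapped matching
#'
#' Scans both strands of every scaffold for ungapped occurrences of each
#' window at identity at or above `min_identity`, reporting every position
#' attaining the threshold. Matching uses exact/mismatch-tolerant string
#' search ([Biostrings::vmatchPattern()]); windows with more than 10%
#' ambiguous bases are skipped (counted in the `n_skipped` attribute).
#'
#' @param windows data.frame as from [split_windows()], plus a `clone_id`
#'   column when windows from several clones are pooled (added
#'   automatically by [map_bac_windows()]).
#' @param assembly Named [Biostrings::DNAStringSet] of scaffolds.
#' @param min_identity Minimum identity fraction in (0, 1].
#' @return data.frame of window hits: `clone_id`, `window_index`,
#'   `scaffold`, `offset` (0-based), `length`, `strand`, `identity`,
#'   ordered by (scaffold, offset). Attribute `n_skipped` counts
#'   ambiguous-base windows dropped.
#' @export
map_windows <- function(windows, assembly, min_identity = 0.95) {
  if (!methods::is(assembly, "DNAStringSet"))
    assembly <- Biostrings::DNAStringSet(assembly)
  if (length(assembly) == 0L) stop("empty assembly", call. = FALSE)
  if (is.null(names(assembly)))
    stop("assembly scaffolds must be named", call. = FALSE)
  if (is.null(windows$clone_id)) windows$clone_id <- "query"

  res <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(windows))) {
    wseq <- windows$sequence[i]
    wlen <- nchar(wseq)
    if (sum(strsplit(wseq, "")[[1]] %in% c("A", "C", "G", "T")) < 0.9 * wlen) {
      n_skipped <- n_skipped + 1L
      next
    }
    max_mm <- floor((1 - min_identity) * wlen)
    pat <- Biostrings::DNAString(wseq)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::vmatchPattern(p, assembly, max.mismatch = max_mm)
      for (j in seq_along(m)) {
        r <- m[[j]]
        if (length(r) == 0L) next
        starts <- IRanges::start(r)
        # drop ranges clipped at scaffold edges (ungapped full-length only)
        keep <- starts >= 1L & IRanges::end(r) <= Biostrings::width(assembly)[j]
        if (!any(keep)) next
        starts <- starts[keep]
        mm <- vapply(starts, function(st)
          Biostrings::neditStartingAt(p, assembly[[j]], starting.at = st,
                                      with.indels = FALSE), integer(1))
        res[[length(res) + 1L]] <- data.frame(
          clone_id = windows$clone_id[i],
          window_index = windows$index[i],
          scaffold = names(assembly)[j],
          offset = starts - 1L, length = wlen, strand = strand,
          identity = 1 - mm / wlen, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(clone_id = character(), window_index = integer(),
               scaffold = character(), offset = integer(),
               length = integer(), strand = character(),
               identity = numeric(), stringsAsFactors = FALSE)
  out <- out[out$identity >= min_identity, , drop = FALSE]
  out <- out[order(out$scaffold, out$offset, out$clone_id, out$window_index), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Window-map a set of BAC clones against an assembly
#'
#' Convenience pipeline: splits every clone into sliding windows, maps all
#' windows with [map_windows()], and returns the hits together with the
#' per-clone window totals needed by [call_placements()].
#'
#' @param clones Named [Biostrings::DNAStringSet] of clone sequences, or a
#'   `BacSet` from [sample_bac_clones()].
#' @param assembly Named DNAStringSet of scaffolds, or an
#'   `AssemblyWithTruth`.
#' @param window,step Window length and step in bp (defaults 150/50).
#' @param min_identity Minimum identity fraction for a window hit.
#' @return list with `hits` (see [map_windows()]) and `totals` (named
#'   integer vector: windows per clone).
#' @export
map_bac_windows <- function(clones, assembly, window = 150L, step = 50L,
                            min_identity = 0.95) {
  if (inherits(clones, "BacSet")) clones <- clones$seqs
  if (inherits(assembly, "AssemblyWithTruth")) assembly <- assembly$scaffolds
  wl <- lapply(names(clones), function(id) {
    w <- split_windows(clones[[id]], window, step)
    w$clone_id <- id
    w
  })
  windows <- do.call(rbind, wl)
  totals <- vapply(wl, nrow, integer(1))
  names(totals) <- names(clones)
  list(hits = map_windows(windows, assembly, min_identity), totals = totals)
}

# ---- external aligner output ------------------------------------------------

sam_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Read window alignments from SAM or PAF files
#'
#' Parses external-aligner output where each record's query name encodes
#' the clone and window as `"cloneID:windowIndex"`. Secondary and
#' supplementary records are retained but marked; unmapped records are
#' dropped and counted.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"sam"` or `"paf"`.
#' @param max_malformed Maximum tolerated fraction of malformed records
#'   before the whole file is rejected (each malformed record also raises
#'   a warning).
#' @return data.frame of window hits with the same core columns as
#'   [map_windows()] plus `secondary`; attributes `n_unmapped` and
#'   `n_malformed` carry the drop counters. PAF target coordinates are
#'   already 0-based half-open; SAM `POS` is converted from 1-based.
#' @export
read_window_alignments <- function(path, format = c("auto", "sam", "paf"),
                                   max_malformed = 0.2) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.paf(\\.|$)", path, ignore.case = TRUE)) "paf" else "sam"
  lines <- readLines(path)
  if (format == "sam") lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  n_unmapped <- 0L; n_malformed <- 0L
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rec <- tryCatch({
      if (format == "sam") {
        if (length(f) < 11L) stop("short SAM record")
        flag <- as.integer(f[2])
        if (sam_flag(flag, 0x4L)) { n_unmapped <- n_unmapped + 1L; NULL }
        else {
          wlen <- if (f[10] != "*") nchar(f[10]) else {
            # sum of M/=/X/I/S lengths from CIGAR for the read length
            ops <- gregexpr("\\d+[MIDNSHP=X]", f[6])[[1]]
            parts <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
            sum(as.integer(sub("[A-Z=]", "", parts[grepl("[MIS=X]$", parts)])))
          }
          data.frame(qname = f[1],
                     scaffold = f[3], offset = as.integer(f[4]) - 1L,
                     length = wlen,
                     strand = if (sam_flag(flag, 0x10L)) "-" else "+",
                     identity = NA_real_,
                     secondary = sam_flag(flag, 0x100L) || sam_flag(flag, 0x800L),
                     stringsAsFactors = FALSE)
        }
      } else {
        if (length(f) < 12L) stop("short PAF record")
        if (f[6] == "*") { n_unmapped <- n_unmapped + 1L; NULL }
        else data.frame(qname = f[1],
                        scaffold = f[6], offset = as.integer(f[8]),
                        length = as.integer(f[9]) - as.integer(f[8]),
                        strand = f[5],
                        identity = as.numeric(f[10]) / as.numeric(f[11]),
                        secondary = any(grepl("^tp:A:[SI]$", f[-(1:12)])),
                        stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      n_malformed <<- n_malformed + 1L
      warning(sprintf("malformed %s record at line %d: %s",
                      toupper(format), i, conditionMessage(e)), call. = FALSE)
      NULL
    })
    rows[[i]] <- rec
  }
  if (length(lines) > 0L && n_malformed / length(lines) > max_malformed)
    stop(sprintf("%d of %d records malformed (> %.0f%% tolerated)",
                 n_malformed, length(lines), 100 * max_malformed),
         call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(qname = character(), scaffold = character(),
                      offset = integer(), length = integer(),
                      strand = character(), identity = numeric(),
                      secondary = logical(), stringsAsFactors = FALSE)
  # decode "cloneID:windowIndex" query names (last colon splits)
  pos <- regexpr(":[0-9]+$", out$qname)
  if (nrow(out) > 0L && any(pos < 0L))
    stop("query names must encode the window as 'cloneID:windowIndex'",
         call. = FALSE)
  out$clone_id <- substr(out$qname, 1L, pos - 1L)
  out$window_index <- as.integer(substring(out$qname, pos + 1L))
  out$qname <- NULL
  out <- out[, c("clone_id", "window_index", "scaffold", "offset", "length",
                 "strand", "identity", "secondary")]
  out <- out[order(out$scaffold, out$offset, out$clone_id, out$window_index), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_malformed") <- n_malformed
  out
}

#' Call BAC-to-scaffold placements from window-count support
#'
#' For every (clone, scaffold) pair, support is the number of *distinct*
#' window indices with at least one hit (so tandem duplications do not
#' inflate support). The best-supported scaffold is accepted when its
#' support fraction reaches `min_support_fraction` and it beats the
#' second-best scaffold by at least `min_margin`; otherwise all candidate
#' scaffolds are emitted flagged `multi`, the machine analogue of flagging
#' a clone for manual curation. Clones with zero hits yield an unplaced
#' record.
#'
#' @param hits Window hits from [map_windows()] or
#'   [read_window_alignments()].
#' @param total_windows Named integer vector (or data.frame with
#'   `clone_id`, `n_windows`) giving each clone's total window count.
#' @param min_support_fraction Minimum supported-window fraction for
#'   acceptance (default 0.5).
#' @param min_margin Minimum ratio of best to second-best support
#'   (default 2).
#' @return data.frame of placements: `clone_id`, `scaffold`, `start`,
#'   `end`, `support`, `support_fraction`, `multi`, `unplaced`.
#' @export
call_placements <- function(hits, total_windows, min_support_fraction = 0.5,
                            min_margin = 2.0) {
  if (is.data.frame(total_windows))
    total_windows <- setNames(total_windows$n_windows, total_windows$clone_id)
  missing <- setdiff(unique(hits$clone_id), names(total_windows))
  if (length(missing))
    stop("clones missing from the totals table: ",
         paste(missing, collapse = ", "), call. = FALSE)

  out <- list()
  for (cl in names(total_windows)) {
    h <- hits[hits$clone_id == cl, , drop = FALSE]
    tot <- total_windows[[cl]]
    if (nrow(h) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        clone_id = cl, scaffold = NA_character_, start = NA_integer_,
        end = NA_integer_, support = 0L, support_fraction = 0,
        multi = FALSE, unplaced = TRUE, stringsAsFactors = FALSE)
      next
    }
    sup <- vapply(split(h$window_index, h$scaffold),
                  function(x) length(unique(x)), integer(1))
    sup <- sort(sup, decreasing = TRUE)
    best <- sup[1]
    second <- if (length(sup) > 1L) sup[2] else 0L
    accepted <- (best / tot >= min_support_fraction) &&
      (second == 0L || best / second >= min_margin)
    scafs <- if (accepted) names(sup)[1] else names(sup)
    for (sc in scafs) {
      hs <- h[h$scaffold == sc, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        clone_id = cl, scaffold = sc,
        start = min(hs$offset), end = max(hs$offset + hs$length),
        support = unname(sup[sc]),
        support_fraction = unname(sup[sc]) / tot,
        multi = !accepted, unplaced = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$clone_id, -res$support), ]
  rownames(res) <- NULL
  res
}
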