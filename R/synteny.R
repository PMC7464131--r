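# Post-processing of pairwise whole-genome alignments into filtered,
# chained synteny blocks; homology matrices; correspondence calls; circos
# and dot-plot exports.

empty_blocks <- function() {
  data.frame(ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), query_chrom = character(),
             query_start = integer(), query_end = integer(),
             strand = character(), length = integer(), score = numeric(),
             stringsAsFactors = FALSE)
}

new_blocks <- function(df) {
  df <- df[, names(empty_blocks())]
  rownames(df) <- NULL
  df
}

#' Read pairwise alignment blocks from PAF or MAF files
#'
#' Normalises all coordinates to 0-based half-open on the forward strand
#' of both sequences; minus-strand alignments keep their query interval in
#' forward-strand coordinates with the `strand` flag set. In PAF the
#' target is taken as the reference; in MAF the first `s` line of each
#' block is the reference. Aligned `length` is the reference span of the
#' block; `score` is the PAF match count or the MAF `score=` field.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"paf"` or `"maf"`.
#' @return data.frame of synteny blocks (`ref_chrom`, `ref_start`,
#'   `ref_end`, `query_chrom`, `query_start`, `query_end`, `strand`,
#'   `length`, `score`). Attribute `n_malformed` counts skipped records
#'   (each also warns).
#' @export
read_alignments <- function(path, format = c("auto", "paf", "maf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.maf(\\.|$)", path, ignore.case = TRUE)) "maf" else "paf"
  if (format == "paf") read_paf_blocks(path) else read_maf_blocks(path)
}

read_paf_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_bad <- 0L
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    tryCatch({
      if (length(f) < 12L) stop("short PAF record")
      data.frame(ref_chrom = f[6],
                 ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
                 query_chrom = f[1],
                 query_start = as.integer(f[3]), query_end = as.integer(f[4]),
                 strand = f[5],
                 length = as.integer(f[9]) - as.integer(f[8]),
                 score = as.numeric(f[10]), stringsAsFactors = FALSE)
    }, error = function(e) {
      n_bad <<- n_bad + 1L
      warning("malformed PAF record at line ", i, call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- if (is.null(out)) empty_blocks() else new_blocks(out)
  attr(out, "n_malformed") <- n_bad
  out
}

# MAF s-line coordinates are given on the aligning strand; convert to the
# forward strand: fwd_start = srcSize - (start + size) for '-' segments.
read_maf_blocks <- function(path) {
  lines <- readLines(path)
  n_bad <- 0L
  rows <- list()
  i <- 1L
  score <- NA_real_
  seg <- list()
  flush <- function() {
    if (length(seg) >= 2L) {
      r <- seg[[1]]; q <- seg[[2]]
      strand <- if (r$strand == q$strand) "+" else "-"
      # present the reference on its forward strand
      fix <- function(s) {
        if (s$strand == "-") {
          st <- s$src_size - (s$start + s$size)
          c(st, st + s$size)
        } else c(s$start, s$start + s$size)
      }
      rr <- fix(r); qq <- fix(q)
      rows[[length(rows) + 1L]] <<- data.frame(
        ref_chrom = r$name, ref_start = rr[1], ref_end = rr[2],
        query_chrom = q$name, query_start = qq[1], query_end = qq[2],
        strand = strand, length = r$size, score = score,
        stringsAsFactors = FALSE)
    } else if (length(seg) == 1L) {
      n_bad <<- n_bad + 1L
      warning("MAF block with a single sequence skipped", call. = FALSE)
    }
    seg <<- list(); score <<- NA_real_
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "a")) {
      flush()
      m <- regmatches(ln, regexpr("score=([-0-9.eE+]+)", ln))
      score <- if (length(m)) as.numeric(sub("score=", "", m)) else NA_real_
    } else if (startsWith(ln, "s")) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      ok <- length(f) >= 7L
      if (!ok) {
        n_bad <- n_bad + 1L
        warning("malformed MAF s line at ", i, call. = FALSE)
      } else {
        seg[[length(seg) + 1L]] <- list(
          name = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
          strand = f[5], src_size = as.integer(f[6]))
      }
    } else if (!nzchar(trimws(ln)) || startsWith(ln, "#")) {
      if (!nzchar(trimws(ln))) flush()
    }
  }
  flush()
  out <- if (length(rows)) new_blocks(do.call(rbind, rows)) else empty_blocks()
  attr(out, "n_malformed") <- n_bad
  out
}

#' Filter synteny blocks by minimum aligned length
#'
#' The appropriate minimum depends on the divergence of the genome pair:
#' close pairs tolerate large thresholds that suppress repeat-driven
#' noise, distant pairs need small ones or genuine homology disappears.
#' [synteny_min_block_presets] ships the preset lengths used for turtle
#' vs turtle (12 kb), turtle vs distant chelonian (7 kb) and turtle vs
#' squamate/bird (1 kb) comparisons.
#'
#' @param blocks Synteny blocks.
#' @param min_length Minimum aligned length in bp (or a preset name).
#' @return The surviving blocks, in their original order.
#' @export
filter_blocks <- function(blocks, min_length = 0) {
  if (is.character(min_length))
    min_length <- synteny_min_block_presets[[min_length]]
  if (is.null(min_length) || min_length < 0)
    stop("min_length must be a non-negative number or a preset name",
         call. = FALSE)
  out <- blocks[blocks$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum-block-size presets by genome-pair divergence class
#'
#' Named bp thresholds: `close` (congeneric/confamilial pairs, 12 kb),
#' `intermediate` (same order, different families, 7 kb), `distant`
#' (across orders/classes, 1 kb).
#' @export
synteny_min_block_presets <- c(close = 12000, intermediate = 7000,
                               distant = 1000)

#' Chain collinear synteny blocks
#'
#' Merges block pairs that are collinear on both genomes: same chromosome
#' pair, same strand (unless `require_same_strand = FALSE`), gaps at most
#' `max_gap` on both sides, and order-preserving (for minus-strand chains
#' the query runs in reverse along the reference). Merging is repeated to
#' a fixed point, so the operation is idempotent. The aligned length of a
#' merged block is the *sum* of its parts (gaps are not counted), which
#' conserves total aligned bp.
#'
#' @param blocks Synteny blocks.
#' @param max_gap Maximum unaligned gap in bp on either genome (default
#'   10,000).
#' @param require_same_strand Refuse to merge opposite-strand blocks
#'   (default TRUE; merging across strands is never order-preserving, the
#'   flag only exists to chain unstranded input).
#' @return Chained blocks sorted by (ref_chrom, ref_start).
#' @export
chain_blocks <- function(blocks, max_gap = 10000L, require_same_strand = TRUE) {
  if (nrow(blocks) <= 1L) return(blocks)
  repeat {
    key <- paste(blocks$ref_chrom, blocks$query_chrom,
                 if (require_same_strand) blocks$strand else "*", sep = "\r")
    merged_any <- FALSE
    pieces <- lapply(split(blocks, key), function(g) {
      g <- g[order(g$ref_start), , drop = FALSE]
      out <- g[1, , drop = FALSE]
      for (i in seq_len(nrow(g) - 1L)) {
        b <- g[i + 1L, , drop = FALSE]
        a <- out[nrow(out), , drop = FALSE]
        rgap <- b$ref_start - a$ref_end
        qgap <- if (a$strand == "+") b$query_start - a$query_end
                else a$query_start - b$query_end
        if (rgap >= 0 && rgap <= max_gap && qgap >= 0 && qgap <= max_gap) {
          a$ref_end <- b$ref_end
          a$query_start <- min(a$query_start, b$query_start)
          a$query_end <- max(a$query_end, b$query_end)
          a$length <- a$length + b$length
          a$score <- sum(a$score, b$score, na.rm = TRUE)
          out[nrow(out), ] <- a
          merged_any <<- TRUE
        } else out <- rbind(out, b)
      }
      out
    })
    blocks <- do.call(rbind, pieces)
    if (!merged_any) break
  }
  blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Aggregate synteny blocks into a chromosome-pair homology matrix
#'
#' Entries are summed aligned bp per (reference chromosome, query
#' chromosome) pair; marginals are the row/column sums. Optional
#' scaffold-to-chromosome maps (e.g. from the anchoring step) relabel
#' blocks first; block names missing from a supplied map are binned as
#' `"unplaced"`.
#'
#' @param blocks Synteny blocks.
#' @param ref_map,query_map Optional named vectors scaffold -> chromosome
#'   label.
#' @param dedupe Merge overlapping reference intervals per chromosome pair
#'   before summation (so bp covered twice count once). Default FALSE:
#'   raw summed aligned length, which partitions the blocks' total bp
#'   exactly. When TRUE the raw sum is still available in attribute
#'   `raw_bp`.
#' @return list of class `HomologyMatrix`: `matrix` (ref rows x query
#'   columns), `ref_marginals`, `query_marginals`.
#' @export
homology_matrix <- function(blocks, ref_map = NULL, query_map = NULL,
                            dedupe = FALSE) {
  relabel <- function(x, map) {
    if (is.null(map)) return(x)
    y <- unname(map[x])
    y[is.na(y)] <- "unplaced"
    y
  }
  rc <- relabel(blocks$ref_chrom, ref_map)
  qc <- relabel(blocks$query_chrom, query_map)
  raw <- NULL
  if (nrow(blocks) == 0L) {
    m <- matrix(numeric(), 0, 0)
  } else if (!dedupe) {
    m <- as.matrix(stats::xtabs(blocks$length ~ rc + qc))
  } else {
    raw <- as.matrix(stats::xtabs(blocks$length ~ rc + qc))
    key <- paste(rc, qc, sep = "\r")
    agg <- vapply(split(seq_len(nrow(blocks)), key), function(idx)
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
        start = blocks$ref_start[idx] + 1L, end = blocks$ref_end[idx])))),
      numeric(1))
    ks <- strsplit(names(agg), "\r", fixed = TRUE)
    m <- matrix(0, nrow = length(unique(rc)), ncol = length(unique(qc)),
                dimnames = list(sort(unique(rc)), sort(unique(qc))))
    for (i in seq_along(agg))
      m[ks[[i]][1], ks[[i]][2]] <- agg[i]
  }
  names(dimnames(m)) <- NULL
  out <- structure(list(matrix = m,
                        ref_marginals = rowSums(m),
                        query_marginals = colSums(m)),
                   class = "HomologyMatrix")
  if (!is.null(raw)) attr(out, "raw_bp") <- raw
  out
}

#' @export
print.HomologyMatrix <- function(x, ...) {
  cat(sprintf("HomologyMatrix: %d reference x %d query chromosomes, %s aligned bp\n",
              nrow(x$matrix), ncol(x$matrix),
              format(sum(x$matrix), big.mark = ",")))
  invisible(x)
}

#' Classify chromosome correspondence patterns from a homology matrix
#'
#' A reference chromosome is `one-to-one` when its top partner holds at
#' least `dominant_fraction` of its aligned bp, `one-to-many` when two or
#' more partners each exceed `minor_floor`, and `unassigned` when it has
#' no aligned bp at all.
#'
#' @param hm A `HomologyMatrix` (or a plain matrix, rows = reference).
#' @param dominant_fraction Fraction of a chromosome's aligned bp its top
#'   partner must hold for a one-to-one call (default 0.8).
#' @param minor_floor Minimum fraction for a partner to count as real
#'   (default 0.05).
#' @return data.frame: `ref_chrom`, `pattern`, `n_partners`, `partners`
#'   (comma-separated `chrom:fraction` pairs, decreasing).
#' @export
classify_correspondence <- function(hm, dominant_fraction = 0.8,
                                    minor_floor = 0.05) {
  if (dominant_fraction <= 0 || dominant_fraction >= 1 ||
      minor_floor <= 0 || minor_floor >= 1)
    stop("thresholds must lie strictly in (0, 1)", call. = FALSE)
  m <- if (inherits(hm, "HomologyMatrix")) hm$matrix else hm
  rows <- lapply(rownames(m), function(rc) {
    v <- m[rc, ]
    tot <- sum(v)
    if (tot == 0)
      return(data.frame(ref_chrom = rc, pattern = "unassigned",
                        n_partners = 0L, partners = "",
                        stringsAsFactors = FALSE))
    fr <- sort(v[v > 0] / tot, decreasing = TRUE)
    pattern <- if (fr[1] >= dominant_fraction) "one-to-one"
      else if (sum(fr >= minor_floor) >= 2L) "one-to-many"
      else "one-to-one"  # dominated by one partner plus trace noise
    keep <- fr[fr >= minor_floor]
    data.frame(ref_chrom = rc, pattern = pattern,
               n_partners = length(keep),
               partners = paste(sprintf("%s:%.3f", names(keep), keep),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- link / dot-plot exports ------------------------------------------------

#' Write synteny blocks as a circos link file
#'
#' One line per block: `ref start end query start end options`, with the
#' options column carrying `strand=` (and the block's aligned length) so a
#' re-parse can reconstruct the blocks.
#'
#' @param blocks Non-empty synteny blocks.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_circos_links <- function(blocks, path) {
  if (nrow(blocks) == 0L) stop("no blocks to write", call. = FALSE)
  lines <- sprintf("%s %d %d %s %d %d strand=%s,length=%d",
                   blocks$ref_chrom, blocks$ref_start, blocks$ref_end,
                   blocks$query_chrom, blocks$query_start, blocks$query_end,
                   blocks$strand, blocks$length)
  writeLines(lines, path)
  invisible(path)
}

#' Re-read a circos link file written by [write_circos_links()]
#' @param path Link file path.
#' @return Synteny blocks (score is NA; it is not representable in a link
#'   file).
#' @export
read_circos_links <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_blocks())
  f <- do.call(rbind, strsplit(lines, " ", fixed = TRUE))
  opts <- f[, 7]
  strand <- sub(".*strand=([+-]).*", "\\1", opts)
  len <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", opts)))
  new_blocks(data.frame(
    ref_chrom = f[, 1], ref_start = as.integer(f[, 2]),
    ref_end = as.integer(f[, 3]), query_chrom = f[, 4],
    query_start = as.integer(f[, 5]), query_end = as.integer(f[, 6]),
    strand = strand,
    length = ifelse(is.na(len),
                    as.integer(f[, 3]) - as.integer(f[, 2]), len),
    score = NA_real_, stringsAsFactors = FALSE))
}

#' Write a dot-plot table of block endpoints
#'
#' One row per block with both endpoint pairs; minus-strand blocks carry
#' `orientation = "anti"` (anti-diagonal on a dot plot).
#'
#' @param blocks Synteny blocks.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dotplot_table <- function(blocks, path) {
  df <- data.frame(
    ref_chrom = blocks$ref_chrom,
    x1 = blocks$ref_start, x2 = blocks$ref_end,
    query_chrom = blocks$query_chrom,
    y1 = ifelse(blocks$strand == "+", blocks$query_start, blocks$query_end),
    y2 = ifelse(blocks$strand == "+", blocks$query_end, blocks$query_start),
    orientation = ifelse(blocks$strand == "+", "diag", "anti"),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}
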