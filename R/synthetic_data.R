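#' Generate a truth-known karyotype of macro- and microchromosomes
#'
#' Builds a synthetic genome with a sauropsid-style karyotype: a set of
#' large macrochromosomes and small microchromosomes, each with a
#' centromere (arm boundary) placed uniformly within the middle 60% of the
#' chromosome. Chromosome labels are `1..n` in decreasing nominal size, as
#' in standard karyotype nomenclature. Sequences are i.i.d. nucleotides at
#' a configurable GC fraction; no repeat families are simulated.
#'
#' @param n_macro,n_micro Number of macro- and microchromosomes. Their sum
#'   must be at least 1.
#' @param macro_size_range,micro_size_range Length-2 numeric vectors
#'   `c(min, max)` in bp from which chromosome sizes are drawn uniformly.
#' @param gc GC fraction in (0, 1). Default 0.44, typical of turtle
#'   genomes.
#' @param seed Integer seed; the result is byte-identical for a fixed seed.
#' @param species Free-text species tag stored with the genome.
#' @return An object of class `TruthGenome`: a list with `chromosomes`
#'   (data.frame: `label`, `length`, `arm_boundary`, `type`), `seqs`
#'   (named [Biostrings::DNAStringSet]) and `species`.
#' @examples
#' g <- make_truth_genome(2, 3, c(50e3, 80e3), c(15e3, 25e3), seed = 7)
#' g$chromosomes
#' @export
make_truth_genome <- function(n_macro, n_micro,
                              macro_size_range = c(80e3, 150e3),
                              micro_size_range = c(15e3, 40e3),
                              gc = 0.44, seed = NULL,
                              species = "synthetic") {
  n_macro <- stopifnot_scalar_count(n_macro, "n_macro")
  n_micro <- stopifnot_scalar_count(n_micro, "n_micro")
  if (n_macro + n_micro < 1L)
    stop("empty karyotype: n_macro + n_micro must be >= 1", call. = FALSE)
  for (r in list(macro_size_range, micro_size_range))
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop("size ranges must be positive and ordered c(min, max)",
           call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)", call. = FALSE)

  with_seed(seed, {
    sizes <- c(
      if (n_macro > 0) round(runif(n_macro, macro_size_range[1], macro_size_range[2])),
      if (n_micro > 0) round(runif(n_micro, micro_size_range[1], micro_size_range[2]))
    )
    type <- rep(c("macro", "micro"), c(n_macro, n_micro))
    ord <- order(sizes, decreasing = TRUE)
    sizes <- sizes[ord]; type <- type[ord]
    n <- length(sizes)
    # centromere drawn uniformly in the middle 60% of each chromosome
    arm <- round(runif(n, 0.2 * sizes, 0.8 * sizes))
    arm <- pmin(pmax(arm, 1L), sizes - 1L)
    seqs <- Biostrings::DNAStringSet(vapply(sizes, random_dna, "", gc = gc))
    names(seqs) <- as.character(seq_len(n))
    structure(list(
      chromosomes = data.frame(label = seq_len(n), length = as.integer(sizes),
                               arm_boundary = as.integer(arm), type = type,
                               stringsAsFactors = FALSE),
      seqs = seqs, species = species), class = "TruthGenome")
  })
}

#' @export
print.TruthGenome <- function(x, ...) {
  cat(sprintf("TruthGenome '%s': %d chromosomes (%d macro, %d micro), %s bp\n",
              x$species, nrow(x$chromosomes),
              sum(x$chromosomes$type == "macro"),
              sum(x$chromosomes$type == "micro"),
              format(sum(x$chromosomes$length), big.mark = ",")))
  invisible(x)
}

#' Fragment a truth genome into scaffolds and induce chimeric misjoins
#'
#' Cuts every chromosome at random internal positions, then joins
#' `n_chimeras` randomly chosen fragment pairs drawn from *different*
#' chromosomes into single scaffolds, emulating assembly misjoins. The
#' exact provenance of every scaffold base is recorded in a truth map, and
#' the deliberately misjoined scaffolds are listed in a chimera registry so
#' that downstream detection can be scored against ground truth.
#'
#' @param truth A `TruthGenome`.
#' @param n_breaks_per_chrom Random internal breakpoints per chromosome.
#' @param n_chimeras Number of cross-chromosome fragment pairs to join.
#' @param seed Integer seed.
#' @return An object of class `AssemblyWithTruth`: list with `scaffolds`
#'   (named DNAStringSet), `truth_map` (data.frame: `scaffold`, `s_start`,
#'   `s_end`, `chrom`, `c_start`, `c_end`, `orientation`; 0-based
#'   half-open), and `chimera_registry` (character vector of scaffold ids).
#' @details The truth-map intervals tile each scaffold exactly (no overlap,
#'   no gap). The second fragment of a chimeric join is inserted in reverse
#'   complement with probability 1/2, mirroring how misjoins arise in
#'   either orientation.
#' @examples
#' g <- make_truth_genome(2, 2, c(30e3, 40e3), c(10e3, 15e3), seed = 1)
#' a <- fragment_and_misjoin(g, n_breaks_per_chrom = 1, n_chimeras = 2, seed = 2)
#' a$chimera_registry
#' @export
fragment_and_misjoin <- function(truth, n_breaks_per_chrom = 0L,
                                 n_chimeras = 0L, seed = NULL) {
  stopifnot(inherits(truth, "TruthGenome"))
  n_breaks_per_chrom <- stopifnot_scalar_count(n_breaks_per_chrom, "n_breaks_per_chrom")
  n_chimeras <- stopifnot_scalar_count(n_chimeras, "n_chimeras")

  with_seed(seed, {
    # fragment every chromosome; fragments carry provenance
    frags <- list()
    for (i in seq_len(nrow(truth$chromosomes))) {
      L <- truth$chromosomes$length[i]
      lab <- truth$chromosomes$label[i]
      nb <- min(n_breaks_per_chrom, L - 1L)
      cuts <- sort(unique(if (nb > 0) sample(seq_len(L - 1L), nb) else integer()))
      bounds <- c(0L, cuts, L)
      for (j in seq_len(length(bounds) - 1L))
        frags[[length(frags) + 1L]] <- list(chrom = lab,
                                            start = bounds[j], end = bounds[j + 1L])
    }
    fchrom <- vapply(frags, `[[`, integer(1), "chrom")

    # feasible cross-chromosome pairs: limited by the largest per-chromosome
    # fragment count (matching bound) and by floor(n/2)
    tab <- table(fchrom)
    feasible <- min(length(frags) %/% 2L, length(frags) - max(tab))
    if (n_chimeras > feasible)
      stop(sprintf("requested %d chimeras but only %d cross-chromosome joins are feasible",
                   n_chimeras, feasible), call. = FALSE)

    # greedily pair fragments from distinct chromosomes
    avail <- sample(seq_along(frags))
    pairs <- list()
    while (length(pairs) < n_chimeras) {
      a <- avail[1L]
      partner_pool <- avail[fchrom[avail] != fchrom[a]]
      if (length(partner_pool) == 0L) {
        # rotate: put a at the end and retry with another lead fragment
        avail <- c(avail[-1L], a)
        next
      }
      b <- partner_pool[1L]
      pairs[[length(pairs) + 1L]] <- c(a, b)
      avail <- setdiff(avail, c(a, b))
    }

    getseq <- function(f) Biostrings::subseq(truth$seqs[[as.character(f$chrom)]],
                                             f$start + 1L, f$end)
    scafs <- list(); tm <- list(); registry <- character()
    sid <- 0L
    new_id <- function() { sid <<- sid + 1L; sprintf("scaffold_%d", sid) }

    for (p in pairs) {
      f1 <- frags[[p[1]]]; f2 <- frags[[p[2]]]
      id <- new_id()
      flip <- runif(1) < 0.5
      s1 <- getseq(f1)
      s2 <- if (flip) Biostrings::reverseComplement(getseq(f2)) else getseq(f2)
      scafs[[id]] <- Biostrings::xscat(s1, s2)
      l1 <- f1$end - f1$start; l2 <- f2$end - f2$start
      tm[[length(tm) + 1L]] <- data.frame(
        scaffold = id, s_start = c(0L, l1), s_end = c(l1, l1 + l2),
        chrom = c(f1$chrom, f2$chrom),
        c_start = c(f1$start, f2$start), c_end = c(f1$end, f2$end),
        orientation = c("+", if (flip) "-" else "+"),
        stringsAsFactors = FALSE)
      registry <- c(registry, id)
    }
    for (k in avail) {
      f <- frags[[k]]
      id <- new_id()
      scafs[[id]] <- getseq(f)
      tm[[length(tm) + 1L]] <- data.frame(
        scaffold = id, s_start = 0L, s_end = f$end - f$start,
        chrom = f$chrom, c_start = f$start, c_end = f$end,
        orientation = "+", stringsAsFactors = FALSE)
    }

    scaffolds <- Biostrings::DNAStringSet(scafs)
    truth_map <- do.call(rbind, tm)
    rownames(truth_map) <- NULL
    structure(list(scaffolds = scaffolds, truth_map = truth_map,
                   chimera_registry = registry),
              class = "AssemblyWithTruth")
  })
}

#' @export
print.AssemblyWithTruth <- function(x, ...) {
  cat(sprintf("AssemblyWithTruth: %d scaffolds, %s bp, %d registered chimeras\n",
              length(x$scaffolds),
              format(sum(Biostrings::width(x$scaffolds)), big.mark = ","),
              length(x$chimera_registry)))
  invisible(x)
}

#' Sample BAC clones with FISH-truth chromosome and arm assignments
#'
#' Draws `n` clone inserts at uniform random genome positions (chromosome
#' chosen proportionally to its length), recording each clone's true
#' chromosome and arm as the FISH truth. Clone sequences are verbatim
#' substrings of their chromosome, optionally degraded by point
#' substitutions; indels are never introduced, so exact window matching
#' remains a valid oracle.
#'
#' @param truth A `TruthGenome`.
#' @param n Number of clones.
#' @param insert_len Insert length in bp (nominally ~150,000 for real BAC
#'   libraries; use smaller values at desk scale). Must not exceed the
#'   shortest chromosome.
#' @param mutation_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Object of class `BacSet`: list with `clones` (data.frame:
#'   `clone_id`, `chromosome`, `arm`, `start`, `end`; 0-based half-open),
#'   `seqs` (named DNAStringSet) and `insert_len`.
#' @details The arm is called from the clone midpoint relative to the
#'   stored arm boundary: midpoint left of the boundary records `"p"`,
#'   right records `"q"`.
#' @export
sample_bac_clones <- function(truth, n, insert_len = 150000L,
                              mutation_rate = 0, seed = NULL) {
  stopifnot(inherits(truth, "TruthGenome"))
  n <- stopifnot_scalar_count(n, "n", min = 1L)
  if (insert_len > min(truth$chromosomes$length))
    stop(sprintf("insert_len (%d) exceeds the shortest chromosome (%d bp)",
                 insert_len, min(truth$chromosomes$length)), call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must lie in [0, 1)", call. = FALSE)

  with_seed(seed, {
    ch <- truth$chromosomes
    idx <- sample(nrow(ch), n, replace = TRUE, prob = ch$length)
    start <- vapply(idx, function(i)
      as.integer(floor(runif(1, 0, ch$length[i] - insert_len + 1))), integer(1))
    mid <- start + insert_len %/% 2L
    arm <- ifelse(mid < ch$arm_boundary[idx], "p", "q")
    ids <- sprintf("bac%03d", seq_len(n))
    seqs <- vector("list", n)
    for (k in seq_len(n)) {
      s <- Biostrings::subseq(truth$seqs[[idx[k]]], start[k] + 1L,
                              start[k] + insert_len)
      if (mutation_rate > 0) {
        v <- strsplit(as.character(s), "")[[1]]
        hit <- which(runif(insert_len) < mutation_rate)
        for (h in hit) v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1)
        s <- Biostrings::DNAString(paste(v, collapse = ""))
      }
      seqs[[k]] <- s
    }
    seqs <- Biostrings::DNAStringSet(seqs)
    names(seqs) <- ids
    structure(list(
      clones = data.frame(clone_id = ids, chromosome = ch$label[idx],
                          arm = arm, start = start,
                          end = start + as.integer(insert_len),
                          stringsAsFactors = FALSE),
      seqs = seqs, insert_len = as.integer(insert_len)), class = "BacSet")
  })
}

# ---- genome rearrangement ---------------------------------------------------

# Segment lists describe each derived chromosome as an ordered run of
# (source chromosome, interval, strand) pieces; all sequence operations are
# performed on these lists and sequences are materialised at the end.

seg_len <- function(segs) sum(segs$end - segs$start)

# Split a segment run at derived-coordinate pos; returns list(before, after).
seg_split <- function(segs, pos) {
  off <- 0L; before <- list(); after <- list()
  for (i in seq_len(nrow(segs))) {
    w <- segs$end[i] - segs$start[i]
    if (off + w <= pos) before[[length(before) + 1L]] <- segs[i, ]
    else if (off >= pos) after[[length(after) + 1L]] <- segs[i, ]
    else {
      cut <- pos - off
      s <- segs[i, ]
      a <- s; b <- s
      if (s$strand == "+") { a$end <- s$start + cut; b$start <- s$start + cut }
      else                 { a$start <- s$end - cut; b$end <- s$end - cut }
      before[[length(before) + 1L]] <- a
      after[[length(after) + 1L]] <- b
    }
    off <- off + w
  }
  rb <- function(x) if (length(x)) do.call(rbind, x) else
    segs[0, , drop = FALSE]
  list(before = rb(before), after = rb(after))
}

seg_revcomp <- function(segs) {
  if (nrow(segs) == 0L) return(segs)
  segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  segs$strand <- ifelse(segs$strand == "+", "-", "+")
  rownames(segs) <- NULL
  segs
}

seg_materialise <- function(segs, seqs) {
  pieces <- lapply(seq_len(nrow(segs)), function(i) {
    s <- Biostrings::subseq(seqs[[as.character(segs$chrom[i])]],
                            segs$start[i] + 1L, segs$end[i])
    if (segs$strand[i] == "-") Biostrings::reverseComplement(s) else s
  })
  do.call(Biostrings::xscat, pieces)
}

validate_rearrangement_ops <- function(truth, ops) {
  labels <- truth$chromosomes$label
  lens <- setNames(truth$chromosomes$length, labels)
  ivs <- list()  # per-chromosome list of touched intervals, source coordinates
  for (op in ops) {
    kind <- op$kind
    if (!kind %in% c("inversion", "translocation", "fusion", "fission"))
      stop("unknown rearrangement kind: ", kind, call. = FALSE)
    check_iv <- function(chrom, start, end) {
      if (!chrom %in% labels)
        stop("rearrangement names unknown chromosome ", chrom, call. = FALSE)
      if (start < 0 || end > lens[[as.character(chrom)]] || start >= end)
        stop(sprintf("invalid interval [%d,%d) on chromosome %s",
                     start, end, chrom), call. = FALSE)
      key <- as.character(chrom)
      for (prev in ivs[[key]])
        if (start < prev[2] && prev[1] < end)
          stop(sprintf("overlapping rearrangement requests on chromosome %s: [%d,%d) vs [%d,%d)",
                       chrom, prev[1], prev[2], start, end), call. = FALSE)
      ivs[[key]] <<- c(ivs[[key]], list(c(start, end)))
    }
    switch(kind,
      inversion = check_iv(op$chrom, op$start, op$end),
      translocation = check_iv(op$from_chrom, op$start, op$end),
      fission = {
        if (!op$chrom %in% labels)
          stop("fission names unknown chromosome ", op$chrom, call. = FALSE)
        if (op$pos <= 0 || op$pos >= lens[[as.character(op$chrom)]])
          stop("fission position must be strictly internal", call. = FALSE)
      },
      fusion = {
        if (!op$chrom_a %in% labels || !op$chrom_b %in% labels ||
            op$chrom_a == op$chrom_b)
          stop("fusion requires two distinct existing chromosomes", call. = FALSE)
      })
  }
  invisible(TRUE)
}

apply_rearrangement_ops <- function(truth, ops) {
  ops <- lapply(ops, function(op) {
    for (f in intersect(names(op), c("start", "end", "pos", "at")))
      op[[f]] <- as.integer(op[[f]])
    op
  })
  segmap <- lapply(seq_len(nrow(truth$chromosomes)), function(i)
    data.frame(chrom = truth$chromosomes$label[i], start = 0L,
               end = truth$chromosomes$length[i], strand = "+",
               stringsAsFactors = FALSE))
  names(segmap) <- as.character(truth$chromosomes$label)
  next_label <- max(truth$chromosomes$label) + 1L

  for (op in ops) {
    switch(op$kind,
      inversion = {
        key <- as.character(op$chrom)
        sp1 <- seg_split(segmap[[key]], op$start)
        sp2 <- seg_split(sp1$after, op$end - op$start)
        segmap[[key]] <- rbind(sp1$before, seg_revcomp(sp2$before), sp2$after)
      },
      translocation = {
        from <- as.character(op$from_chrom); to <- as.character(op$to_chrom)
        sp1 <- seg_split(segmap[[from]], op$start)
        sp2 <- seg_split(sp1$after, op$end - op$start)
        segmap[[from]] <- rbind(sp1$before, sp2$after)
        at <- min(op$at, seg_len(segmap[[to]]))
        spt <- seg_split(segmap[[to]], at)
        segmap[[to]] <- rbind(spt$before, sp2$before, spt$after)
      },
      fusion = {
        a <- as.character(op$chrom_a); b <- as.character(op$chrom_b)
        segmap[[a]] <- rbind(segmap[[a]], segmap[[b]])
        segmap[[b]] <- NULL
      },
      fission = {
        key <- as.character(op$chrom)
        sp <- seg_split(segmap[[key]], op$pos)
        segmap[[key]] <- sp$before
        segmap[[as.character(next_label)]] <- sp$after
        next_label <- next_label + 1L
      })
  }
  segmap <- segmap[vapply(segmap, nrow, 1L) > 0L]
  segmap
}

#' Derive a rearranged genome and an exact rearrangement log
#'
#' Applies an ordered list of chromosomal rearrangements (inversions,
#' translocations, fusions, fissions) to a truth genome, returning the
#' derived genome together with a log that records the operations and the
#' complete derived-to-source segment map. Replaying the log on the source
#' genome reproduces the derived genome byte-for-byte
#' (see [replay_rearrangements()]).
#'
#' @param truth A `TruthGenome` (the source genome).
#' @param ops List of operations. Each is a list with a `kind` field:
#'   \describe{
#'     \item{inversion}{`chrom`, `start`, `end` (0-based half-open).}
#'     \item{translocation}{`from_chrom`, `start`, `end`, `to_chrom`, `at`
#'       (insertion offset on the destination).}
#'     \item{fusion}{`chrom_a`, `chrom_b`; the fused chromosome keeps
#'       label `chrom_a`.}
#'     \item{fission}{`chrom`, `pos`; the distal part receives a fresh
#'       label.}
#'   }
#'   Two operations naming overlapping intervals on the same chromosome
#'   are rejected.
#' @param species Species tag for the derived genome.
#' @return A list with `genome` (`TruthGenome`, carrying the segment map as
#'   `$segment_map`) and `log` (class `RearrangementLog`: `ops`,
#'   `segment_map`, `source_species`).
#' @examples
#' g <- make_truth_genome(2, 1, c(30e3, 40e3), c(10e3, 15e3), seed = 3)
#' d <- rearrange_genome(g, list(
#'   list(kind = "inversion", chrom = 1, start = 1000, end = 5000),
#'   list(kind = "fusion", chrom_a = 2, chrom_b = 3)))
#' nrow(d$genome$chromosomes)  # one fewer than the source
#' @export
rearrange_genome <- function(truth, ops, species = paste0(truth$species, "_derived")) {
  stopifnot(inherits(truth, "TruthGenome"))
  validate_rearrangement_ops(truth, ops)
  segmap <- apply_rearrangement_ops(truth, ops)

  labs <- names(segmap)
  lens <- vapply(segmap, seg_len, integer(1))
  seqs <- Biostrings::DNAStringSet(lapply(segmap, seg_materialise, seqs = truth$seqs))
  names(seqs) <- labs
  segdf <- do.call(rbind, lapply(labs, function(k) {
    s <- segmap[[k]]
    w <- s$end - s$start
    off <- cumsum(c(0L, w))[seq_len(nrow(s))]
    data.frame(derived = k, d_start = off, d_end = off + w,
               chrom = s$chrom, c_start = s$start, c_end = s$end,
               strand = s$strand, stringsAsFactors = FALSE)
  }))
  rownames(segdf) <- NULL

  genome <- structure(list(
    chromosomes = data.frame(label = as.integer(labs), length = as.integer(lens),
                             arm_boundary = pmax(1L, as.integer(lens) %/% 2L),
                             type = ifelse(as.integer(labs) %in%
                                             truth$chromosomes$label,
                                           truth$chromosomes$type[
                                             match(as.integer(labs),
                                                   truth$chromosomes$label)],
                                           "micro"),
                             stringsAsFactors = FALSE),
    seqs = seqs, species = species,
    segment_map = segdf), class = "TruthGenome")
  log <- structure(list(ops = ops, segment_map = segdf,
                        source_species = truth$species),
                   class = "RearrangementLog")
  list(genome = genome, log = log)
}

#' Replay a rearrangement log on its source genome
#'
#' @param truth The source `TruthGenome` the log was produced from.
#' @param log A `RearrangementLog`.
#' @return The derived `TruthGenome`, byte-identical to the one returned by
#'   the original [rearrange_genome()] call.
#' @export
replay_rearrangements <- function(truth, log) {
  stopifnot(inherits(log, "RearrangementLog"))
  rearrange_genome(truth, log$ops)$genome
}

#' True chromosome-homology pairs implied by a rearrangement log
#'
#' @param log A `RearrangementLog`.
#' @return data.frame with columns `source_chrom` and `derived_chrom`: every
#'   (source, derived) chromosome pair that shares at least one bp.
#' @export
homology_pairs_from_log <- function(log) {
  stopifnot(inherits(log, "RearrangementLog"))
  u <- unique(log$segment_map[, c("chrom", "derived")])
  out <- data.frame(source_chrom = as.character(u$chrom),
                    derived_chrom = as.character(u$derived),
                    stringsAsFactors = FALSE)
  out <- out[order(out$source_chrom, out$derived_chrom), ]
  rownames(out) <- NULL
  out
}
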