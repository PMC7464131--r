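# Fuse BAC placements with FISH assignments: scaffold-to-chromosome
# anchoring, chimera detection, and contiguity/anchoring statistics.

#' Anchor scaffolds to chromosomes using clone FISH assignments
#'
#' Joins clone-to-scaffold placements with clone-to-chromosome FISH
#' assignments and produces one anchor record per scaffold that carries at
#' least one FISH-assigned clone. Conflict is defined on chromosome
#' *numbers* only: clones on the p and q arms of the same chromosome never
#' conflict, and the arm is recorded only when all clones agree on it.
#'
#' @param placements data.frame with `clone_id` and `scaffold` columns
#'   (e.g. accepted placements from [call_placements()], or a direct
#'   clone-to-scaffold table). If a `multi` column is present, multi-mapped
#'   placements are excluded unless `include_multi = TRUE`. An optional
#'   `scaffold_size` column is carried through.
#' @param fish data.frame with `clone_id`, `chromosome` (integer) and
#'   optionally `arm` (`"p"`, `"q"` or `NA`).
#' @param include_multi Keep multi-flagged placements (default FALSE).
#' @return data.frame of anchor records: `scaffold`, `scaffold_length`
#'   (NA when unknown), `chromosome` (NA when the conflict set has more
#'   than one element), `arm`, `n_clones`, `n_chromosomes`, `clones` and
#'   `conflict_chroms` (comma-separated). Attribute `n_no_fish` counts
#'   placed clones absent from the FISH table.
#' @details A clone appearing twice in `fish` with conflicting chromosomes
#'   is an error; duplicated concordant records are collapsed.
#' @examples
#' tabs <- load_paper_tables()
#' pl <- data.frame(clone_id = tabs$table1$bac_id,
#'                  scaffold = tabs$table1$bionano_scaffold,
#'                  scaffold_size = tabs$table1$scaffold_size)
#' an <- anchor_scaffolds(pl, tabs$table1[, c("bac_id", "chromosome", "arm")] |>
#'                              setNames(c("clone_id", "chromosome", "arm")))
#' length(unique(an$chromosome[!is.na(an$chromosome)]))
#' @export
anchor_scaffolds <- function(placements, fish, include_multi = FALSE) {
  stopifnot(all(c("clone_id", "scaffold") %in% names(placements)),
            all(c("clone_id", "chromosome") %in% names(fish)))
  if (!is.null(placements$unplaced))
    placements <- placements[!placements$unplaced, , drop = FALSE]
  if (!include_multi && !is.null(placements$multi))
    placements <- placements[!placements$multi, , drop = FALSE]
  if (is.null(fish$arm)) fish$arm <- NA_character_

  fish <- unique(fish[, c("clone_id", "chromosome", "arm")])
  dup <- fish$clone_id[duplicated(fish$clone_id)]
  if (length(dup)) {
    bad <- unique(dup[vapply(dup, function(cl)
      length(unique(fish$chromosome[fish$clone_id == cl])) > 1L, logical(1))])
    if (length(bad))
      stop("conflicting FISH records for clone(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    # same chromosome, differing arm detail: keep the arm-specific record
    fish <- fish[order(fish$clone_id, is.na(fish$arm)), ]
    fish <- fish[!duplicated(fish$clone_id), ]
  }

  m <- merge(placements, fish, by = "clone_id")
  n_no_fish <- length(setdiff(unique(placements$clone_id), fish$clone_id))

  if (is.null(m$scaffold_size)) m$scaffold_size <- NA_integer_
  recs <- lapply(split(m, m$scaffold), function(g) {
    chroms <- sort(unique(g$chromosome))
    arms <- unique(g$arm[!is.na(g$arm)])
    data.frame(
      scaffold = g$scaffold[1],
      scaffold_length = g$scaffold_size[1],
      chromosome = if (length(chroms) == 1L) chroms else NA_integer_,
      arm = if (length(chroms) == 1L && length(arms) == 1L) arms else NA_character_,
      n_clones = length(unique(g$clone_id)),
      n_chromosomes = length(chroms),
      clones = paste(unique(g$clone_id), collapse = ","),
      conflict_chroms = paste(chroms, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  suppressWarnings(num <- as.numeric(out$scaffold))
  out <- out[if (anyNA(num)) order(out$scaffold) else order(num), ]
  rownames(out) <- NULL
  attr(out, "n_no_fish") <- n_no_fish
  out
}

#' Detect chimeric scaffolds from anchoring conflicts
#'
#' A scaffold is chimeric when two or more clones placed on it were FISHed
#' to two or more different chromosomes (chromosome numbers; arms never
#' create conflicts). Reports all such scaffolds with their evidence and
#' totals.
#'
#' @param anchors Anchor records from [anchor_scaffolds()].
#' @return list of class `ChimeraReport`: `report` (the conflicted anchor
#'   rows, sorted by scaffold id), `n_chimeric`, `total_bp` (sum of the
#'   listed scaffold lengths; NA-lengths contribute 0 and are counted in
#'   `n_unknown_length`).
#' @export
detect_chimeric_scaffolds <- function(anchors) {
  rep <- anchors[anchors$n_chromosomes >= 2L, , drop = FALSE]
  rownames(rep) <- NULL
  structure(list(
    report = rep,
    n_chimeric = nrow(rep),
    total_bp = sum(rep$scaffold_length, na.rm = TRUE),
    n_unknown_length = sum(is.na(rep$scaffold_length))),
    class = "ChimeraReport")
}

#' @export
print.ChimeraReport <- function(x, ...) {
  cat(sprintf("ChimeraReport: %d chimeric scaffold(s), %s bp impacted\n",
              x$n_chimeric, format(x$total_bp, big.mark = ",")))
  if (x$n_chimeric > 0)
    print(x$report[, c("scaffold", "scaffold_length", "conflict_chroms",
                       "clones")], row.names = FALSE)
  invisible(x)
}

#' Assembly N50
#'
#' Sorts lengths in decreasing order and returns the first length at which
#' the cumulative sum reaches at least half the total (the `>=` tie rule is
#' applied at exactly half). The returned value is always one of the input
#' lengths.
#'
#' @param lengths Numeric vector of positive scaffold lengths.
#' @return The N50 length in bp.
#' @examples
#' n50(c(50, 40, 30, 20, 10))  # 40
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("lengths must all be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' L50: number of scaffolds needed to reach half the assembly
#' @inheritParams n50
#' @return Integer count.
#' @export
l50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  which(cumsum(s) >= sum(s) / 2)[1]
}

#' Contiguity improvement ratio between two N50 values
#'
#' @param old_n50,new_n50 N50 values in bp; `old_n50` must be positive.
#' @return The ratio `new/old` expressed as a percentage, rounded to the
#'   nearest integer (e.g. 16 Mbp over 6.6 Mbp gives 242).
#' @examples
#' improvement_ratio(6.6e6, 16e6)
#' @export
improvement_ratio <- function(old_n50, new_n50) {
  if (length(old_n50) != 1L || is.na(old_n50) || old_n50 <= 0)
    stop("old_n50 must be a single positive value", call. = FALSE)
  round(100 * new_n50 / old_n50)
}

#' Anchoring and contiguity statistics for an assembly
#'
#' Computes scaffold count, total bp, N50/L50, and the anchored bp and
#' fraction implied by a set of anchor records. Chimeric scaffolds stay in
#' the anchored totals by default (they are physically anchored, just to
#' more than one chromosome) but are flagged and can be excluded.
#'
#' @param anchors Anchor records from [anchor_scaffolds()], or NULL for a
#'   pure contiguity summary.
#' @param scaffold_table data.frame with `scaffold` and `length` columns
#'   covering (at least) every anchored scaffold.
#' @param total_bp Optional denominator override for the anchored
#'   fraction; defaults to the sum of `scaffold_table$length`. The
#'   denominator actually used is echoed in the result.
#' @param exclude_chimeric Drop scaffolds with conflicting chromosome
#'   evidence from the anchored totals (default FALSE).
#' @return list of class `ContiguityStats`: `n_scaffolds`, `total_bp`,
#'   `n50`, `l50`, `anchored_bp`, `anchored_fraction`,
#'   `n_anchored_scaffolds`, `n_chimeric_flagged`, `denominator_bp`.
#' @export
anchored_statistics <- function(anchors, scaffold_table, total_bp = NULL,
                                exclude_chimeric = FALSE) {
  stopifnot(all(c("scaffold", "length") %in% names(scaffold_table)))
  denom <- if (is.null(total_bp)) sum(as.numeric(scaffold_table$length)) else total_bp
  anchored_bp <- 0; n_anch <- 0L; n_chim <- 0L
  if (!is.null(anchors) && nrow(anchors) > 0L) {
    unknown <- setdiff(anchors$scaffold, scaffold_table$scaffold)
    if (length(unknown))
      stop("anchor references unknown scaffold(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    n_chim <- sum(anchors$n_chromosomes >= 2L)
    keep <- if (exclude_chimeric) anchors$n_chromosomes == 1L else
      rep(TRUE, nrow(anchors))
    sel <- unique(anchors$scaffold[keep])
    anchored_bp <- sum(as.numeric(
      scaffold_table$length[match(sel, scaffold_table$scaffold)]))
    n_anch <- length(sel)
  }
  structure(list(
    n_scaffolds = nrow(scaffold_table),
    total_bp = sum(as.numeric(scaffold_table$length)),
    n50 = n50(scaffold_table$length),
    l50 = l50(scaffold_table$length),
    anchored_bp = anchored_bp,
    anchored_fraction = if (denom > 0) anchored_bp / denom else 0,
    n_anchored_scaffolds = n_anch,
    n_chimeric_flagged = n_chim,
    denominator_bp = denom), class = "ContiguityStats")
}

#' @export
print.ContiguityStats <- function(x, ...) {
  cat(sprintf(paste0(
    "ContiguityStats: %d scaffolds, %s bp total, N50 %s bp (L50 %d)\n",
    "  anchored: %s bp (%.1f%% of %s bp) over %d scaffolds, %d chimeric\n"),
    x$n_scaffolds, format(x$total_bp, big.mark = ","),
    format(x$n50, big.mark = ","), x$l50,
    format(x$anchored_bp, big.mark = ","), 100 * x$anchored_fraction,
    format(x$denominator_bp, big.mark = ","),
    x$n_anchored_scaffolds, x$n_chimeric_flagged))
  invisible(x)
}

#' Count genes lying on anchored scaffolds
#'
#' @param annotation Either a data.frame with `gene` and `scaffold`
#'   columns, or a path to a GFF3/BED file (imported with
#'   [rtracklayer::import()]; for GFF3 only `type == "gene"` records are
#'   used and the gene symbol is taken from `Name`, falling back to
#'   `gene_id`/`ID`; for BED the `name` column is the gene).
#' @param anchors Anchor records from [anchor_scaffolds()].
#' @param target_genes Optional character vector (e.g. a sexual-development
#'   panel); a per-gene found/missing report is returned for it.
#' @return list: `n_genes` (distinct gene symbols on anchored scaffolds),
#'   `genes`, and `target_report` (NULL unless `target_genes` given).
#' @export
count_anchored_genes <- function(annotation, anchors, target_genes = NULL) {
  if (is.character(annotation) && length(annotation) == 1L) {
    gr <- rtracklayer::import(annotation)
    md <- as.data.frame(gr)
    if (!is.null(md$type) && any(md$type == "gene"))
      md <- md[md$type == "gene", , drop = FALSE]
    sym <- md$Name
    if (is.null(sym)) sym <- md$gene_id
    if (is.null(sym)) sym <- md$ID
    if (is.null(sym)) sym <- md$name
    annotation <- data.frame(gene = as.character(sym),
                             scaffold = as.character(md$seqnames),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "scaffold") %in% names(annotation)))
  if (nrow(annotation) > 0L &&
      !any(annotation$scaffold %in% anchors$scaffold) && nrow(anchors) > 0L)
    stop("no scaffold ids shared between annotation and anchors; ",
         "likely a naming mismatch", call. = FALSE)
  on_anchored <- annotation[annotation$scaffold %in% anchors$scaffold, , drop = FALSE]
  genes <- sort(unique(on_anchored$gene))
  rep <- NULL
  if (!is.null(target_genes))
    rep <- data.frame(gene = target_genes,
                      found = target_genes %in% genes,
                      stringsAsFactors = FALSE)
  list(n_genes = length(genes), genes = genes, target_report = rep)
}

#' Localise chimeric breakpoints as inter-clone gaps
#'
#' The breakpoint of a misjoin cannot be resolved to the nucleotide from
#' FISH evidence alone; what the evidence supports is the gap between the
#' two nearest clone placements that disagree on chromosome. This reports
#' that gap for every chimeric scaffold.
#'
#' @param placements Placements with `clone_id`, `scaffold`, `start`,
#'   `end`.
#' @param fish FISH table with `clone_id`, `chromosome`.
#' @return data.frame: `scaffold`, `left_clone`, `right_clone`,
#'   `left_chrom`, `right_chrom`, `gap_start`, `gap_end` (0-based
#'   half-open interval between the discordant placements).
#' @export
chimeric_breakpoint_windows <- function(placements, fish) {
  m <- merge(placements, fish[, c("clone_id", "chromosome")], by = "clone_id")
  m <- m[!is.na(m$scaffold) & !is.na(m$start), , drop = FALSE]
  out <- list()
  for (sc in unique(m$scaffold)) {
    g <- m[m$scaffold == sc, , drop = FALSE]
    if (length(unique(g$chromosome)) < 2L) next
    g <- g[order(g$start), , drop = FALSE]
    for (i in seq_len(nrow(g) - 1L)) {
      if (g$chromosome[i] != g$chromosome[i + 1L])
        out[[length(out) + 1L]] <- data.frame(
          scaffold = sc,
          left_clone = g$clone_id[i], right_clone = g$clone_id[i + 1L],
          left_chrom = g$chromosome[i], right_chrom = g$chromosome[i + 1L],
          gap_start = g$end[i], gap_end = g$start[i + 1L],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(scaffold = character(), left_clone = character(),
               right_clone = character(), left_chrom = integer(),
               right_chrom = integer(), gap_start = integer(),
               gap_end = integer(), stringsAsFactors = FALSE)
}
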