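# Marker gene-order comparison along homologous chromosomes: unsigned
# breakpoint distance and conservation verdicts.

#' Order the genes of one species/chromosome panel
#'
#' @param anchors data.frame with a `gene` column and either `position`
#'   (bp) or `rank` (ordinal, usable when bp positions are unknown, as
#'   with gene orders read off a published figure or table).
#' @return Character vector of genes sorted by position/rank.
#' @export
build_order <- function(anchors) {
  stopifnot("gene" %in% names(anchors), nrow(anchors) >= 1L)
  pos <- if (!is.null(anchors$position)) anchors$position else anchors$rank
  if (is.null(pos)) stop("need a 'position' or 'rank' column", call. = FALSE)
  if (anyDuplicated(anchors$gene))
    stop("duplicate gene on one chromosome: ",
         paste(unique(anchors$gene[duplicated(anchors$gene)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(pos)) stop("tied positions/ranks", call. = FALSE)
  as.character(anchors$gene[order(pos)])
}

#' Unsigned breakpoint distance between two gene orders
#'
#' Counts the gene adjacencies of `a` that are absent from `b`, treating
#' adjacencies as unordered pairs (orientation-agnostic) and appending a
#' shared endpoint marker at both ends so that terminal relocations count.
#' With the shared end marker, reversing a list costs zero breakpoints,
#' making the distance a measure of order disruption rather than of
#' reading direction. The distance is symmetric in its arguments.
#'
#' @param a,b Character vectors over the same gene set.
#' @return Integer breakpoint count.
#' @examples
#' breakpoint_distance(c("Fhl2", "Dax1", "Fgf9"), c("Dax1", "Fhl2", "Fgf9"))
#' @export
breakpoint_distance <- function(a, b) {
  if (!setequal(a, b) || length(a) != length(b))
    stop("orders must contain the same genes", call. = FALSE)
  adj <- function(x) {
    x <- c(".END.", x, ".END.")
    pairs <- cbind(x[-length(x)], x[-1])
    apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
  }
  sum(!(adj(a) %in% adj(b)))
}

#' Compare gene order between two homologous chromosomes
#'
#' Genes shared by both lists but residing on different chromosomes
#' (according to the optional chromosome maps) are set aside as
#' *relocated*; the remaining shared genes are compared as a permutation.
#' The verdict is `identical` when the orders match exactly (breakpoint
#' distance 0, same orientation), `reversed` when one list is the exact
#' reverse of the other, `rearranged` otherwise, and `unassessable` when
#' no genes are shared.
#'
#' @param list_a,list_b Ordered gene vectors (from [build_order()]).
#' @param chrom_map_a,chrom_map_b Optional named vectors gene -> chromosome
#'   label for each species, used to identify relocated genes.
#' @return list of class `OrderComparison`: `shared_a`, `shared_b`
#'   (orders restricted to comparable genes), `relocated`, `distance`
#'   (unsigned breakpoint distance, see [breakpoint_distance()]),
#'   `verdict`.
#' @examples
#' compare_gene_order(c("Aco1", "Dmrt1", "Dmrt2", "Rps6"),
#'                    c("Dmrt1", "Dmrt2", "Rps6", "Aco1"))
#' @export
compare_gene_order <- function(list_a, list_b,
                               chrom_map_a = NULL, chrom_map_b = NULL) {
  relocated <- character()
  if (!is.null(chrom_map_a) && !is.null(chrom_map_b)) {
    # chromosome labels are species-specific (e.g. one species' 7 is the
    # other's Z), so "relocated" means: not on the partner chromosome of
    # THIS comparison. The partner labels are read off the lists' own
    # genes via the maps (modal label per list).
    modal <- function(x) if (length(x)) names(sort(table(x), decreasing = TRUE))[1]
      else NA_character_
    chrom_a <- modal(as.character(chrom_map_a[list_a]))
    chrom_b <- modal(as.character(chrom_map_b[list_b]))
    mb <- as.character(chrom_map_b[union(list_a, list_b)])
    ma <- as.character(chrom_map_a[union(list_a, list_b)])
    cand <- union(list_a, list_b)
    rel_b <- if (is.na(chrom_b)) rep(FALSE, length(cand)) else
      !is.na(mb) & mb != chrom_b
    rel_a <- if (is.na(chrom_a)) rep(FALSE, length(cand)) else
      !is.na(ma) & ma != chrom_a
    relocated <- cand[rel_b | rel_a]
  }
  shared <- setdiff(intersect(list_a, list_b), relocated)
  a <- list_a[list_a %in% shared]
  b <- list_b[list_b %in% shared]
  if (length(a) == 0L)
    return(structure(list(shared_a = character(), shared_b = character(),
                          relocated = relocated, distance = NA_integer_,
                          verdict = "unassessable"),
                     class = "OrderComparison"))
  d <- breakpoint_distance(a, b)
  verdict <-
    if (identical(a, b)) "identical"
    else if (length(a) >= 2L && identical(a, rev(b))) "reversed"
    else "rearranged"
  structure(list(shared_a = a, shared_b = b, relocated = relocated,
                 distance = d, verdict = verdict),
            class = "OrderComparison")
}

#' @export
print.OrderComparison <- function(x, ...) {
  cat(sprintf("OrderComparison: %s (breakpoint distance %s)\n",
              x$verdict, x$distance))
  cat("  A:", paste(x$shared_a, collapse = "-"), "\n")
  cat("  B:", paste(x$shared_b, collapse = "-"), "\n")
  if (length(x$relocated))
    cat("  relocated:", paste(x$relocated, collapse = ", "), "\n")
  invisible(x)
}

#' Compare all chromosome gene orders between two species
#'
#' For each chromosome of species A carrying at least one shared gene, the
#' partner chromosome of species B is the one holding the majority of the
#' shared genes; the two orders are then compared with
#' [compare_gene_order()] using the full per-species chromosome maps, so
#' minority genes appear as relocated.
#'
#' @param orders data.frame with columns `species`, `chromosome`, `rank`
#'   (or `position`), `gene` - e.g. `load_paper_tables()$table3_orders`.
#' @param species_a,species_b Species tags to compare.
#' @return data.frame: `chrom_a`, `chrom_b`, `n_shared`, `distance`,
#'   `verdict`, `order_a`, `order_b`, `relocated`.
#' @export
compare_species_orders <- function(orders, species_a, species_b) {
  oa <- orders[orders$species == species_a, , drop = FALSE]
  ob <- orders[orders$species == species_b, , drop = FALSE]
  map_a <- setNames(as.character(oa$chromosome), oa$gene)
  map_b <- setNames(as.character(ob$chromosome), ob$gene)
  out <- list()
  for (ch in unique(oa$chromosome)) {
    ga <- build_order(oa[oa$chromosome == ch, , drop = FALSE])
    shared <- ga[ga %in% names(map_b)]
    if (length(shared) == 0L) next
    partner <- names(sort(table(map_b[shared]), decreasing = TRUE))[1]
    gb <- build_order(ob[ob$chromosome == partner, , drop = FALSE])
    cmp <- compare_gene_order(ga, gb, map_a, map_b)
    out[[length(out) + 1L]] <- data.frame(
      chrom_a = as.character(ch), chrom_b = partner,
      n_shared = length(cmp$shared_a), distance = cmp$distance,
      verdict = cmp$verdict,
      order_a = paste(cmp$shared_a, collapse = "-"),
      order_b = paste(cmp$shared_b, collapse = "-"),
      relocated = paste(cmp$relocated, collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
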