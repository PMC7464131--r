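# Reconcile chromosome naming between a chromosome-level assembly and
# FISH-based karyotype labels by per-chromosome consensus voting.

#' Consensus FISH label for one assembly chromosome
#'
#' @param labels Vector of FISH chromosome labels observed for the clones
#'   assigned to one assembly chromosome.
#' @return list: `label` (modal label; NA on a tie), `support` (clones for
#'   the consensus), `dissent` (clones against), `distinct` (sorted unique
#'   labels). `support + dissent` equals the number of clones.
#' @examples
#' consensus_label(c(1, 1, 1, 4))
#' consensus_label(c(21, 25))  # tie -> unresolved (NA)
#' @export
consensus_label <- function(labels) {
  if (length(labels) == 0L) stop("need at least one label", call. = FALSE)
  tab <- sort(table(labels), decreasing = TRUE)
  tied <- length(tab) > 1L && tab[1] == tab[2]
  lab <- if (tied) NA else type.convert(names(tab)[1], as.is = TRUE)
  list(label = lab,
       support = if (tied) 0L else as.integer(tab[1]),
       dissent = if (tied) length(labels) else
         as.integer(length(labels) - tab[1]),
       distinct = sort(unique(labels)))
}

#' Reconcile assembly chromosome names against FISH assignments
#'
#' Votes the FISH labels of the clones carried by each assembly chromosome
#' and classifies the label:
#' \describe{
#'   \item{chimeric}{clones split across two or more distinct FISH
#'     chromosomes - the assembly chromosome mixes material that FISH
#'     places apart. Takes precedence over every other status (a
#'     majority-correct chromosome with discordant clones is still
#'     chimeric).}
#'   \item{rename}{all clones agree on a FISH chromosome that differs from
#'     the assembly label's number.}
#'   \item{consistent}{all clones agree with the assembly label.}
#'   \item{unresolved}{reserved for a consensus tie that involves no
#'     cross-chromosome split (unreachable when every tie implies two
#'     distinct labels, which are reported chimeric).}
#' }
#' Renames are reported as a two-phase old-to-new map and never
#' auto-applied, since cascades (e.g. 14 renamed to 13 while 13 is renamed
#' to 15) would transiently collide.
#'
#' @param assignments data.frame with `clone_id`, `assembly_chromosome`
#'   (integer) and optionally `assembly_scaffold`.
#' @param fish data.frame with `clone_id` and `chromosome` (the FISH-based
#'   true location). May be omitted if `assignments` already carries a
#'   `fish_chromosome` column.
#' @return list of class `NomenclatureReport`:
#'   `proposals` (data.frame sorted by assembly label:
#'   `assembly_chromosome`, `consensus`, `support`, `dissent`,
#'   `n_distinct`, `fish_labels`, `status`, `discrepant_clones`),
#'   `rename_map` (data.frame `old`, `new`), and `orphans` (FISH clones
#'   with no assembly assignment).
#' @examples
#' tabs <- load_paper_tables()
#' rec <- reconcile_nomenclature(
#'   data.frame(clone_id = tabs$table4$bac_id,
#'              assembly_scaffold = tabs$table4$tse_scaffold,
#'              assembly_chromosome = tabs$table4$tse_chromosome),
#'   data.frame(clone_id = tabs$table4$bac_id,
#'              chromosome = tabs$table4$tsc_chromosome))
#' rec$rename_map
#' @export
reconcile_nomenclature <- function(assignments, fish = NULL) {
  stopifnot(all(c("clone_id", "assembly_chromosome") %in% names(assignments)))
  if (is.null(fish)) {
    stopifnot("fish_chromosome" %in% names(assignments))
    fish <- data.frame(clone_id = assignments$clone_id,
                       chromosome = assignments$fish_chromosome,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("clone_id", "chromosome") %in% names(fish)))
  fish <- unique(fish[, c("clone_id", "chromosome")])
  if (anyDuplicated(fish$clone_id))
    stop("conflicting FISH records for clone(s): ",
         paste(unique(fish$clone_id[duplicated(fish$clone_id)]),
               collapse = ", "), call. = FALSE)

  m <- merge(assignments, fish, by = "clone_id")
  orphans <- fish[!fish$clone_id %in% assignments$clone_id, , drop = FALSE]

  groups <- split(m, m$assembly_chromosome)
  rows <- lapply(groups, function(g) {
    cons <- consensus_label(g$chromosome)
    lab <- g$assembly_chromosome[1]
    status <-
      if (length(cons$distinct) >= 2L) "chimeric"
      else if (is.na(cons$label)) "unresolved"
      else if (cons$label != lab) "rename"
      else "consistent"
    disc <- g$clone_id[is.na(cons$label) | g$chromosome != cons$label]
    data.frame(
      assembly_chromosome = lab,
      consensus = if (is.na(cons$label)) NA_integer_ else cons$label,
      support = cons$support, dissent = cons$dissent,
      n_distinct = length(cons$distinct),
      fish_labels = paste(cons$distinct, collapse = ","),
      status = status,
      discrepant_clones = paste(disc, collapse = ","),
      stringsAsFactors = FALSE)
  })
  proposals <- do.call(rbind, rows)
  proposals <- proposals[order(proposals$assembly_chromosome), ]
  rownames(proposals) <- NULL

  ren <- proposals[proposals$status == "rename", , drop = FALSE]
  rename_map <- data.frame(old = ren$assembly_chromosome, new = ren$consensus,
                           stringsAsFactors = FALSE)
  structure(list(proposals = proposals, rename_map = rename_map,
                 orphans = orphans), class = "NomenclatureReport")
}

#' @export
print.NomenclatureReport <- function(x, ...) {
  p <- x$proposals
  cat(sprintf("NomenclatureReport: %d labels (%d consistent, %d rename, %d chimeric, %d unresolved)\n",
              nrow(p), sum(p$status == "consistent"),
              sum(p$status == "rename"), sum(p$status == "chimeric"),
              sum(p$status == "unresolved")))
  if (nrow(x$rename_map))
    cat("  renames:",
        paste(sprintf("%s->%s", x$rename_map$old, x$rename_map$new),
              collapse = ", "), "\n")
  chim <- p$assembly_chromosome[p$status == "chimeric"]
  if (length(chim))
    cat("  chimeric labels:", paste(chim, collapse = ", "), "\n")
  if (nrow(x$orphans))
    cat("  orphan FISH clones:", nrow(x$orphans), "\n")
  invisible(x)
}
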