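# Shared synthetic fixtures and independent oracles used across tests.

# Small karyotype reused by several suites (built once per test run).
small_genome <- function(seed = 11) {
  make_truth_genome(4, 4, macro_size_range = c(40e3, 60e3),
                    micro_size_range = c(15e3, 25e3), seed = seed)
}

# Independent N50 oracle: explicit loop over prefix sums of the
# descending-sorted lengths, no vectorised shortcuts.
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= half) return(x)
  }
}

# Independent breakpoint-distance oracle: for every consecutive pair of
# the endpoint-extended first order, decide adjacency in the second order
# by positional lookup (positions differing by one; an end-marker pair is
# present iff the partner gene sits at either end of the second order).
breakpoint_oracle <- function(a, b) {
  n <- length(a)
  d <- 0L
  ext <- c("$", a, "$")
  for (i in seq_len(n + 1L)) {
    x <- ext[i]; y <- ext[i + 1L]
    present <- if (x == "$" && y == "$") {
      TRUE
    } else if (x == "$" || y == "$") {
      g <- if (x == "$") y else x
      g == b[1] || g == b[length(b)]
    } else {
      abs(match(x, b) - match(y, b)) == 1L
    }
    if (!present) d <- d + 1L
  }
  d
}

# Clone-to-scaffold placements plus FISH truth derived directly from an
# assembly truth map: one clone per truth-map segment, so every misjoin
# junction is spanned by clones on both constituent chromosomes.
placements_from_truth <- function(assembly) {
  tm <- assembly$truth_map
  ids <- sprintf("tm%03d", seq_len(nrow(tm)))
  list(
    placements = data.frame(clone_id = ids, scaffold = tm$scaffold,
                            scaffold_size = as.integer(
                              Biostrings::width(assembly$scaffolds)[
                                match(tm$scaffold, names(assembly$scaffolds))]),
                            stringsAsFactors = FALSE),
    fish = data.frame(clone_id = ids, chromosome = tm$chrom,
                      arm = NA_character_, stringsAsFactors = FALSE))
}

# Table 1/2 evidence assembled into the placement + FISH form used by the
# anchoring module.
tables_evidence <- function(tabs) {
  list(
    placements = rbind(
      data.frame(clone_id = tabs$table1$bac_id,
                 scaffold = tabs$table1$bionano_scaffold,
                 scaffold_size = tabs$table1$scaffold_size,
                 stringsAsFactors = FALSE),
      data.frame(clone_id = tabs$table2$bac_id,
                 scaffold = tabs$table2$bionano_scaffold,
                 scaffold_size = tabs$table2$scaffold_size,
                 stringsAsFactors = FALSE)),
    fish = rbind(
      data.frame(clone_id = tabs$table1$bac_id,
                 chromosome = tabs$table1$chromosome,
                 arm = tabs$table1$arm, stringsAsFactors = FALSE),
      data.frame(clone_id = tabs$table2$bac_id,
                 chromosome = tabs$table2$chromosome,
                 arm = tabs$table2$arm, stringsAsFactors = FALSE)))
}
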