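test_that("sliding windows enumerate the expected offsets", {
  w <- split_windows(strrep("A", 150))
  expect_equal(nrow(w), 1)
  expect_equal(w$offset, 0)

  w <- split_windows(strrep("A", 250))
  expect_equal(w$offset, c(0, 50, 100))

  # brute-force offset enumeration for a clone of 163,122 bp (the size of
  # clone 424K2 in the packaged Table 1)
  L <- 163122L
  offsets <- integer(); o <- 0L
  while (o + 150L <= L) { offsets <- c(offsets, o); o <- o + 50L }
  expect_length(offsets, 3260)
  s <- substr(strrep("ACGT", ceiling(L / 4)), 1, L)
  w <- split_windows(s)
  expect_equal(nrow(w), 3260)
  expect_equal(w$offset, offsets)
  expect_equal(w$offset, w$index * 50L)

  # neighbouring windows overlap by exactly window - step
  expect_true(all(diff(w$offset) == 50L))
  expect_true(all(w$length == 150L))

  ws <- split_windows("ACGTACGT")
  expect_true(ws$short)
  expect_equal(ws$length, 8)

  expect_error(split_windows("ACGT", window = 10, step = 20), "window >= step")
})

test_that("window mapping finds exact loci on both strands", {
  g <- small_genome()
  asm <- g$seqs  # chromosomes as 'scaffolds'
  win <- as.character(Biostrings::subseq(asm[[2]], 1001, 1150))
  wdf <- data.frame(index = 0L, offset = 0L, length = 150L, sequence = win,
                    short = FALSE, clone_id = "w")

  hits <- map_windows(wdf, asm, min_identity = 0.95)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$scaffold, "2")
  expect_equal(hits$offset, 1000)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
  wdf$sequence <- rc
  hits_rc <- map_windows(wdf, asm, min_identity = 0.95)
  expect_equal(hits_rc$scaffold, "2")
  expect_equal(hits_rc$offset, 1000)
  expect_equal(hits_rc$strand, "-")

  # raising min_identity never increases the hit count
  v <- strsplit(win, "")[[1]]
  v[c(10, 60, 110)] <- vapply(v[c(10, 60, 110)], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], "")
  wdf$sequence <- paste(v, collapse = "")
  counts <- vapply(c(0.90, 0.95, 0.98, 1.0), function(mi)
    nrow(map_windows(wdf, asm, min_identity = mi)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[4], 0L)  # 3 mismatches in 150 bp: identity 0.98

  # ambiguous-base windows are skipped, not matched
  wdf$sequence <- paste(c(rep("N", 20), substr(win, 21, 150)), collapse = "")
  h <- map_windows(wdf, asm)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "n_skipped"), 1L)

  expect_error(map_windows(wdf, Biostrings::DNAStringSet()), "empty assembly")
})

test_that("placement calls follow support fraction and margin rules", {
  hits <- data.frame(
    clone_id = "c1", window_index = 0:9, scaffold = "s1",
    offset = (0:9) * 50L, length = 150L, strand = "+", identity = 1,
    stringsAsFactors = FALSE)
  pl <- call_placements(hits, c(c1 = 10L))
  expect_equal(nrow(pl), 1)
  expect_equal(pl$support_fraction, 1.0)
  expect_false(pl$multi)
  expect_equal(pl$start, 0)
  expect_equal(pl$end, 9 * 50 + 150)

  # clone straddling a junction: half the windows on each scaffold with no
  # 2x margin -> both placements flagged multi, together covering all windows
  h2 <- rbind(hits[1:5, ],
              transform(hits[6:10, ], scaffold = "s2"))
  pl2 <- call_placements(h2, c(c1 = 10L))
  expect_equal(nrow(pl2), 2)
  expect_true(all(pl2$multi))
  expect_equal(sum(pl2$support), 10)

  # zero-hit clone appears as an unplaced record
  pl3 <- call_placements(hits, c(c1 = 10L, c2 = 8L))
  expect_true(pl3$unplaced[pl3$clone_id == "c2"])

  # raising min_support_fraction never increases accepted placements
  acc <- vapply(c(0.2, 0.5, 0.8, 0.95), function(th)
    sum(!call_placements(h2, c(c1 = 10L), min_support_fraction = th)$multi),
    integer(1))
  expect_true(all(diff(acc) <= 0))

  # support counts distinct window indices, not raw hits
  hdup <- rbind(hits, transform(hits, offset = offset + 5000L))
  pld <- call_placements(hdup, c(c1 = 10L))
  expect_equal(pld$support, 10)

  expect_error(call_placements(hits, c(other = 3L)), "missing from the totals")
})

test_that("mutation-free clones map back to their truth scaffolds", {
  g <- small_genome()
  a <- fragment_and_misjoin(g, n_breaks_per_chrom = 1, n_chimeras = 2, seed = 21)
  b <- sample_bac_clones(g, n = 10, insert_len = 3000, mutation_rate = 0,
                         seed = 22)
  mw <- map_bac_windows(b, a, min_identity = 0.95)
  pl <- call_placements(mw$hits, mw$totals)
  tm <- a$truth_map
  for (i in seq_len(nrow(b$clones))) {
    cl <- b$clones[i, ]
    p <- pl[pl$clone_id == cl$clone_id & !pl$multi & !pl$unplaced, ]
    # the clone's true source interval must overlap a truth-map segment of
    # the reported scaffold from the same chromosome
    for (sc in p$scaffold) {
      seg <- tm[tm$scaffold == sc & tm$chrom == cl$chromosome &
                  tm$c_start < cl$end & cl$start < tm$c_end, ]
      expect_gte(nrow(seg), 1)
    }
  }
  # every clone fully inside a single truth segment is recovered uniquely
  inside <- vapply(seq_len(nrow(b$clones)), function(i) {
    cl <- b$clones[i, ]
    any(tm$chrom == cl$chromosome & tm$c_start <= cl$start &
          cl$end <= tm$c_end & tm$orientation == "+")
  }, logical(1))
  rec <- vapply(which(inside), function(i) {
    cl <- b$clones[i, ]
    p <- pl[pl$clone_id == cl$clone_id & !pl$unplaced & !pl$multi, ]
    nrow(p) == 1L
  }, logical(1))
  expect_true(all(rec))
})

test_that("reverse-complementing a clone flips strands but not placements", {
  g <- small_genome()
  a <- fragment_and_misjoin(g, 0, 0, seed = 31)
  b <- sample_bac_clones(g, n = 3, insert_len = 2000, mutation_rate = 0,
                         seed = 32)
  fwd <- map_bac_windows(b$seqs, a)
  rev <- map_bac_windows(Biostrings::reverseComplement(b$seqs), a)
  plf <- call_placements(fwd$hits, fwd$totals)
  plr <- call_placements(rev$hits, rev$totals)
  expect_equal(plf[, c("clone_id", "scaffold", "start", "end")],
               plr[, c("clone_id", "scaffold", "start", "end")])
  key <- function(h) paste(h$clone_id, h$scaffold, h$offset)
  m <- match(key(fwd$hits), key(rev$hits))
  expect_false(anyNA(m))
  expect_true(all(fwd$hits$strand != rev$hits$strand[m]))
})

test_that("SAM and PAF window alignments yield identical placements", {
  dir <- withr::local_tempdir()
  # two clones: c1 with 4 windows on scafA (+), c2 with 2 windows on scafB,
  # one of them minus-strand, plus one unmapped and one secondary record
  seqs <- strrep("ACGT", 38)  # 152 bp placeholder read sequence
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:scafA\tLN:10000",
    "@SQ\tSN:scafB\tLN:8000",
    sprintf("c1:%d\t0\tscafA\t%d\t60\t150M\t*\t0\t0\t%s\t*", 0:3,
            c(101, 151, 201, 251), substr(seqs, 1, 150)),
    sprintf("c2:0\t0\tscafB\t501\t60\t150M\t*\t0\t0\t%s\t*", substr(seqs, 1, 150)),
    sprintf("c2:1\t16\tscafB\t551\t60\t150M\t*\t0\t0\t%s\t*", substr(seqs, 1, 150)),
    sprintf("c2:2\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", substr(seqs, 1, 150)),
    sprintf("c2:0\t256\tscafA\t901\t0\t150M\t*\t0\t0\t%s\t*", substr(seqs, 1, 150)))
  paf <- c(
    sprintf("c1:%d\t150\t0\t150\t+\tscafA\t10000\t%d\t%d\t150\t150\t60", 0:3,
            c(100, 150, 200, 250), c(250, 300, 350, 400)),
    "c2:0\t150\t0\t150\t+\tscafB\t8000\t500\t650\t150\t150\t60",
    "c2:1\t150\t0\t150\t-\tscafB\t8000\t550\t700\t150\t150\t60",
    "c2:0\t150\t0\t150\t+\tscafA\t10000\t900\t1050\t150\t150\t0\ttp:A:S")
  writeLines(sam, file.path(dir, "aln.sam"))
  writeLines(paf, file.path(dir, "aln.paf"))

  hs <- read_window_alignments(file.path(dir, "aln.sam"))
  hp <- read_window_alignments(file.path(dir, "aln.paf"))
  expect_equal(attr(hs, "n_unmapped"), 1L)
  expect_equal(hs[, c("clone_id", "window_index", "scaffold", "offset",
                      "strand", "secondary")],
               hp[, c("clone_id", "window_index", "scaffold", "offset",
                      "strand", "secondary")])
  expect_equal(hp$strand[hp$clone_id == "c2" & hp$window_index == 1], "-")

  totals <- c(c1 = 4L, c2 = 3L)
  pls <- call_placements(hs[!hs$secondary, ], totals)
  plp <- call_placements(hp[!hp$secondary, ], totals)
  expect_equal(pls, plp)

  # empty file
  writeLines(character(), file.path(dir, "empty.paf"))
  he <- read_window_alignments(file.path(dir, "empty.paf"))
  expect_equal(nrow(he), 0)
  expect_equal(attr(he, "n_unmapped"), 0L)

  # malformed records warn, and fail the file above the tolerated fraction
  writeLines(c(paf[1], "garbage line"), file.path(dir, "bad.paf"))
  expect_warning(
    expect_error(read_window_alignments(file.path(dir, "bad.paf"),
                                        max_malformed = 0.2), "malformed"),
    "malformed")
})
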