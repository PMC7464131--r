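test_that("PAF and MAF readers normalise coordinates identically", {
  dir <- withr::local_tempdir()

  writeLines(character(), file.path(dir, "empty.paf"))
  expect_equal(nrow(read_alignments(file.path(dir, "empty.paf"))), 0)

  # one 1 kb block, query on the reverse strand.
  # MAF convention: '-' s-line coordinates count from the reverse strand,
  # so a query segment at rev-start 200, size 1000 of a 5000 bp sequence
  # spans forward-strand [3800, 4800).
  maf <- c("##maf version=1",
           "a score=950",
           "s refA 1000 1000 + 20000 ACGT",
           "s qryB  200 1000 - 5000 ACGT",
           "")
  writeLines(maf, file.path(dir, "one.maf"))
  bm <- read_alignments(file.path(dir, "one.maf"))
  expect_equal(nrow(bm), 1)
  expect_equal(bm$ref_start, 1000)
  expect_equal(bm$ref_end, 2000)
  expect_equal(bm$strand, "-")
  expect_equal(bm$query_start, 3800)
  expect_equal(bm$query_end, 4800)
  expect_equal(bm$length, 1000)

  # the same alignment as PAF (PAF query coordinates are already
  # forward-strand): block lists must agree
  paf <- "qryB\t5000\t3800\t4800\t-\trefA\t20000\t1000\t2000\t950\t1000\t60"
  writeLines(paf, file.path(dir, "one.paf"))
  bp <- read_alignments(file.path(dir, "one.paf"))
  cols <- c("ref_chrom", "ref_start", "ref_end", "query_chrom",
            "query_start", "query_end", "strand", "length")
  expect_equal(bm[, cols], bp[, cols])

  expect_warning(b2 <- read_alignments(
    {writeLines(c(paf, "bad"), file.path(dir, "two.paf"));
     file.path(dir, "two.paf")}), "malformed")
  expect_equal(nrow(b2), 1)
  expect_equal(attr(b2, "n_malformed"), 1L)
})

mkblocks <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(ref_chrom = r[[1]], ref_start = as.integer(r[[2]]),
               ref_end = as.integer(r[[3]]), query_chrom = r[[4]],
               query_start = as.integer(r[[5]]), query_end = as.integer(r[[6]]),
               strand = r[[7]],
               length = as.integer(r[[3]]) - as.integer(r[[2]]),
               score = NA_real_, stringsAsFactors = FALSE)))
}

test_that("block filtering respects thresholds and monotonicity", {
  b <- mkblocks(list("r1", 0, 11999, "q1", 0, 11999, "+"),
                list("r1", 20000, 32000, "q1", 20000, 32000, "+"))
  expect_equal(nrow(filter_blocks(b, 0)), 2)
  f <- filter_blocks(b, 12000)
  expect_equal(nrow(f), 1)
  expect_equal(f$length, 12000)

  expect_equal(filter_blocks(b, "close"),
               filter_blocks(b, 12000))

  set.seed(5)
  rb <- mkblocks(list("r1", 0, 1, "q1", 0, 1, "+"))[0, ]
  for (i in 1:200) {
    st <- sample(1:10^6, 1); len <- sample(1:20000, 1)
    rb <- rbind(rb, mkblocks(list("r1", st, st + len, "q1", st, st + len, "+")))
  }
  surv <- vapply(c(1000, 7000, 12000), function(th)
    sum(filter_blocks(rb, th)$length), numeric(1))
  expect_true(all(diff(surv) <= 0))
})

test_that("chaining merges collinear blocks and is idempotent", {
  b <- mkblocks(list("r1", 0, 1000, "q1", 5000, 6000, "+"),
                list("r1", 1000, 2000, "q1", 6000, 7000, "+"))
  ch <- chain_blocks(b, max_gap = 0)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$length, 2000)
  expect_equal(ch$ref_start, 0); expect_equal(ch$ref_end, 2000)
  expect_equal(ch$query_start, 5000); expect_equal(ch$query_end, 7000)

  # opposite strands never merge
  b2 <- b; b2$strand[2] <- "-"
  expect_equal(nrow(chain_blocks(b2, max_gap = 0)), 2)

  # minus-strand collinearity: query runs backwards along the reference
  bm <- mkblocks(list("r1", 0, 1000, "q1", 6000, 7000, "-"),
                 list("r1", 1000, 2000, "q1", 5000, 6000, "-"))
  chm <- chain_blocks(bm, max_gap = 0)
  expect_equal(nrow(chm), 1)
  expect_equal(chm$query_start, 5000); expect_equal(chm$query_end, 7000)
  # but a '+'-order query arrangement on '-' strand is NOT collinear
  expect_equal(nrow(chain_blocks(mkblocks(
    list("r1", 0, 1000, "q1", 5000, 6000, "-"),
    list("r1", 1000, 2000, "q1", 6000, 7000, "-")), max_gap = 0)), 2)

  # idempotence and conservation of aligned bp
  set.seed(8)
  frag <- mkblocks(list("r1", 0, 1, "q1", 0, 1, "+"))[0, ]
  pos <- 0L
  for (i in 1:30) {
    len <- sample(500:1500, 1)
    frag <- rbind(frag, mkblocks(list("r1", pos, pos + len, "q1",
                                      pos + 100, pos + 100 + len, "+")))
    pos <- pos + len + sample(0:400, 1)
  }
  ch1 <- chain_blocks(frag, max_gap = 500)
  ch2 <- chain_blocks(ch1, max_gap = 500)
  expect_equal(ch1, ch2)
  expect_equal(sum(ch1$length), sum(frag$length))
})

test_that("fragmented identity alignments chain to full length", {
  g <- make_truth_genome(2, 0, c(30e3, 40e3), seed = 51)
  bl <- align_exact(g, g, k = 64)
  # self-alignment of repeat-free sequence: strictly diagonal, one chain
  # per chromosome at (near) full length
  expect_equal(nrow(bl[bl$strand == "+", ]), 2)
  for (i in 1:2) {
    ch <- bl[bl$query_chrom == as.character(i) & bl$strand == "+", ]
    expect_equal(ch$ref_chrom, as.character(i))
    # non-overlapping k-mers cover all but < 2k trailing/boundary bp
    expect_gte(ch$length, g$chromosomes$length[i] - 2 * 64)
  }
})

test_that("homology matrices partition aligned bp and expose marginals", {
  b <- mkblocks(list("r1", 0, 1000, "q1", 0, 1000, "+"),
                list("r1", 3000, 4000, "q2", 0, 1000, "+"),
                list("r2", 0, 2000, "q2", 5000, 7000, "-"))
  hm <- homology_matrix(b)
  expect_equal(sum(hm$matrix), sum(b$length))
  expect_equal(hm$matrix["r1", "q1"], 1000)
  expect_equal(hm$matrix["r1", "q2"], 1000)
  expect_equal(hm$matrix["r2", "q2"], 2000)
  expect_equal(unname(hm$ref_marginals["r1"]), 2000)
  expect_equal(unname(hm$query_marginals["q2"]), 3000)

  # scaffold-to-chromosome relabelling, unmatched binned as unplaced
  hm2 <- homology_matrix(b, ref_map = c(r1 = "chr1"))
  expect_setequal(rownames(hm2$matrix), c("chr1", "unplaced"))

  # dedupe merges overlapping reference coverage; raw sum still reported
  bo <- mkblocks(list("r1", 0, 1000, "q1", 0, 1000, "+"),
                 list("r1", 500, 1500, "q1", 500, 1500, "+"))
  hd <- homology_matrix(bo, dedupe = TRUE)
  expect_equal(hd$matrix["r1", "q1"], 1500)
  expect_equal(attr(hd, "raw_bp")["r1", "q1"], 2000)
})

test_that("correspondence patterns follow dominant/minor thresholds", {
  m <- diag(c(100, 200, 300))
  dimnames(m) <- list(c("r1", "r2", "r3"), c("q1", "q2", "q3"))
  cc <- classify_correspondence(m)
  expect_true(all(cc$pattern == "one-to-one"))

  m2 <- matrix(c(50, 50), 1, dimnames = list("r1", c("q1", "q2")))
  expect_equal(classify_correspondence(m2)$pattern, "one-to-many")

  m3 <- rbind(m2 * 0)
  expect_equal(classify_correspondence(m3)$pattern, "unassigned")

  expect_error(classify_correspondence(m, dominant_fraction = 1.2),
               "strictly in")
})

test_that("alignment of a rearranged genome recovers the true homology set", {
  g <- make_truth_genome(3, 2, c(40e3, 60e3), c(15e3, 25e3), seed = 61)
  res <- rearrange_genome(g, list(
    list(kind = "inversion", chrom = 1, start = 5000, end = 12000),
    list(kind = "inversion", chrom = 3, start = 1000, end = 3000),
    list(kind = "inversion", chrom = 2, start = 20000, end = 30000),
    list(kind = "translocation", from_chrom = 1, start = 30000, end = 38000,
         to_chrom = 4, at = 2000),
    list(kind = "translocation", from_chrom = 2, start = 1000, end = 7000,
         to_chrom = 5, at = 0)))
  bl <- align_exact(g, res$genome, k = 64)
  hm <- homology_matrix(bl)
  got <- which(hm$matrix > 0, arr.ind = TRUE)
  got_pairs <- sort(paste(rownames(hm$matrix)[got[, 1]],
                          colnames(hm$matrix)[got[, 2]]))
  truth <- homology_pairs_from_log(res$log)
  expect_equal(got_pairs,
               sort(paste(truth$source_chrom, truth$derived_chrom)))
  # the two translocations appear as off-diagonal homologies
  expect_true(all(c("1 4", "2 5") %in% got_pairs))

  # a fission shows up as a one-to-many correspondence of the source
  fis <- rearrange_genome(g, list(list(kind = "fission", chrom = 2, pos = 25000)))
  hmf <- homology_matrix(align_exact(g, fis$genome, k = 64))
  ccf <- classify_correspondence(hmf)
  expect_equal(ccf$pattern[ccf$ref_chrom == "2"], "one-to-many")
  expect_equal(ccf$n_partners[ccf$ref_chrom == "2"], 2)
})

test_that("circos links and dot-plot tables round-trip block geometry", {
  b <- mkblocks(list("r1", 100, 1100, "q1", 200, 1200, "+"),
                list("r1", 5000, 6000, "q2", 0, 1000, "-"))
  dir <- withr::local_tempdir()
  lf <- file.path(dir, "links.txt")
  write_circos_links(b, lf)
  lines <- readLines(lf)
  expect_length(lines, 2)
  expect_match(lines[1], "^r1 100 1100 q1 200 1200 strand=\\+")

  rb <- read_circos_links(lf)
  cols <- c("ref_chrom", "ref_start", "ref_end", "query_chrom",
            "query_start", "query_end", "strand", "length")
  expect_equal(rb[, cols], b[, cols])

  dp <- file.path(dir, "dot.tsv")
  write_dotplot_table(b, dp)
  d <- read.delim(dp)
  expect_equal(d$orientation, c("diag", "anti"))
  expect_true(d$y1[2] > d$y2[2])  # anti-diagonal rows descend

  expect_error(write_circos_links(b[0, ], lf), "no blocks")
})
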