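# hand-built SAM on a toy reference for cleavage-calling checks
toy_sam <- function() {
  genome <- c(ref = paste0(strrep("C", 10), "ACGTACGT",
                           strrep("G", 12), strrep("C", 70)))
  path <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:ref\tLN:%d", nchar(genome)),
             # + read covering 0-based 10..17 (1-based POS 11, 8M)
             "rplus\t0\tref\t11\t60\t8M\t*\t0\t0\tACGTACGT\t*",
             # - read covering 0-based 30..37
             sprintf("rminus\t16\tref\t31\t60\t8M\t*\t0\t0\t%s\t*",
                     substr(genome, 31, 38)),
             # + read with a 3'-clipped end (clip on the right for +)
             "rclip\t0\tref\t11\t60\t6M2S\t*\t0\t0\tACGTACGT\t*",
             # - read with its 3' end clipped (left side for -)
             sprintf("rclipm\t16\tref\t33\t60\t2S6M\t*\t0\t0\t%s\t*",
                     substr(genome, 31, 38)))
  writeLines(lines, path)
  list(genome = genome, path = path)
}

test_that("cleavage position is the tail-adjacent aligned base, per strand", {
  ts <- toy_sam()
  gal <- read_alignment_file(ts$path)
  called <- call_cleavage_events(gal)
  ev <- called$events[order(called$events$read_id), ]
  expect_identical(ev$read_id, c("rminus", "rplus"))
  expect_identical(ev$position, c(30L, 17L))
  expect_identical(ev$strand, c("-", "+"))
  expect_setequal(called$rejected$read_id, c("rclip", "rclipm"))
  expect_true(all(called$rejected$reason == "clipped-end"))
})

test_that("clipping on the 5' read end does not reject the record", {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:ref\tLN:100",
               # 5' clip for a + read is on the left: keep
               "r1\t0\tref\t11\t60\t2S6M\t*\t0\t0\tACGTACGT\t*"), path)
  called <- call_cleavage_events(read_alignment_file(path))
  expect_identical(nrow(called$rejected), 0L)
  expect_identical(called$events$position, 15L) # 6M from POS 11 -> 0-based 15
})

test_that("the priming filter applies the published window and run rules", {
  mk_genome <- function(window) c(chr = paste0(strrep("G", 50), window,
                                               strrep("G", 50)))
  ev <- data.frame(chrom = "chr", strand = "+", position = 49L,
                   read_id = "r", source_tag = "x")
  cases <- list(
    # 9 A: window rule fires; the 9-run also trips the run rule
    list(win = "AAAAAAAAAC", window = FALSE, run = FALSE, either = FALSE),
    list(win = "CAAAAAAAAG", window = TRUE, run = FALSE, either = FALSE),
    list(win = "ACGTACGTAC", window = TRUE, run = TRUE, either = TRUE))
  # expected 'keep' per mode
  for (cs in cases) {
    g <- mk_genome(cs$win)
    for (mode in c("window", "run", "either")) {
      f <- internal_priming_filter(ev, g, filter_config(mode = mode))
      expect_identical(f$keep, cs[[mode]],
                       label = paste(cs$win, mode))
    }
  }
})

test_that("minus-strand windows count sense A (reference T) downstream", {
  # event on -, cleavage at 60; transcript-downstream = reference 50..59
  g <- c(chr = paste0(strrep("G", 50), "TTTTTTTTTC", strrep("G", 40)))
  ev <- data.frame(chrom = "chr", strand = "-", position = 60L,
                   read_id = "r", source_tag = "x")
  f <- internal_priming_filter(ev, g, filter_config(mode = "either"))
  expect_false(f$keep)   # 9 T in the window and a T-run of 8
  f2 <- internal_priming_filter(ev, g, filter_config(mode = "window"))
  expect_false(f2$keep)
})

test_that("the filter matches direct window counting on a random 100-kb genome", {
  g <- c(chr = random_genome(100000, seed = 91))
  pos <- seq(0L, 99988L, by = 7L)
  ev <- data.frame(chrom = "chr", strand = "+", position = pos,
                   read_id = as.character(seq_along(pos)), source_tag = "x")
  f <- internal_priming_filter(ev, g, filter_config(mode = "either"))
  # independent oracle: per-base vector and cumulative sums
  v <- strsplit(g[[1]], "")[[1]] == "A"
  cum <- cumsum(v)
  n_a <- cum[pos + 11L] - cum[pos + 1L]          # bases pos+1..pos+10 (0-based)
  runlen <- function(x) { r <- rle(x); max(c(0, r$lengths[r$values])) }
  max_run <- vapply(pos, function(p) runlen(v[(p + 2):(p + 11)]), numeric(1))
  oracle_discard <- n_a >= 9 | max_run >= 8
  expect_identical(f$keep, !oracle_discard)
})

test_that("missing contigs are reported by name", {
  ev <- data.frame(chrom = "nope", strand = "+", position = 1L,
                   read_id = "r", source_tag = "x")
  expect_error(internal_priming_filter(ev, c(chr = "ACGT")), "nope")
})

test_that("single-linkage clustering merges gaps <= 20 and splits at 21", {
  mk <- function(pos) data.frame(chrom = "c", strand = "+", position = pos,
                                 read_id = as.character(seq_along(pos)),
                                 source_tag = "x")
  one <- cluster_events(mk(100L))
  expect_identical(nrow(one), 1L)
  expect_identical(one$representative_position, 100L)

  cl <- cluster_events(mk(c(100L, 115L, 140L)))
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$n_members, c(2L, 1L))

  chained <- cluster_events(mk(c(100L, 120L, 140L)))
  expect_identical(nrow(chained), 1L)
  expect_identical(chained$end - chained$start, 40L)

  split21 <- cluster_events(mk(c(100L, 121L)))
  expect_identical(nrow(split21), 2L)
})

test_that("the representative is the best-supported member, ties 5'-most", {
  ev <- data.frame(chrom = "c", strand = "+",
                   position = c(10L, 10L, 15L), read_id = c("a", "b", "c"),
                   source_tag = "x")
  expect_identical(cluster_events(ev)$representative_position, 10L)
  tie <- data.frame(chrom = "c", strand = "+", position = c(10L, 15L),
                    read_id = c("a", "b"), source_tag = "x")
  expect_identical(cluster_events(tie)$representative_position, 10L)
  tie$strand <- "-"
  expect_identical(cluster_events(tie)$representative_position, 15L)
})

test_that("clustering is idempotent, permutation-invariant, and matches a graph oracle", {
  skip_if_not_installed("igraph")
  oracle_sizes <- function(pos, d = 20L) {
    u <- unique(pos)
    if (length(u) == 1L) return(1L)
    adj <- abs(outer(u, u, "-")) <= d
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    length(unique(igraph::components(g)$membership))
  }
  set.seed(92)
  for (trial in 1:60) {
    pos <- sample.int(2000L, sample(1:200, 1), replace = TRUE)
    ev <- data.frame(chrom = "c", strand = "+", position = pos,
                     read_id = as.character(seq_along(pos)), source_tag = "x")
    cl <- cluster_events(ev)
    expect_identical(nrow(cl), oracle_sizes(pos))
    # permutation invariance
    ev2 <- ev[sample.int(nrow(ev)), ]
    expect_identical(cluster_events(ev2)$representative_position,
                     cl$representative_position)
    # idempotence: representatives are > merge_distance apart, so clustering
    # them reproduces them as singletons
    reps <- data.frame(chrom = "c", strand = "+",
                       position = cl$representative_position,
                       read_id = as.character(seq_len(nrow(cl))),
                       source_tag = "x")
    recl <- cluster_events(reps)
    expect_identical(recl$representative_position,
                     cl$representative_position)
    expect_true(all(recl$n_members == 1L))
    expect_identical(sum(cl$total_support), length(pos))
  }
})

test_that("reverse-complementing the world mirrors the clusters", {
  sim <- small_sim()
  run <- small_run()
  g <- sim$genome
  glen <- nchar(g)
  mirror_g <- setNames(revcomp_chr(g), names(g))
  ev <- run$events[run$events$keep, ]
  mev <- ev
  mev$position <- glen[ev$chrom] - 1L - ev$position
  mev$strand <- ifelse(ev$strand == "+", "-", "+")
  cl <- cluster_events(ev)
  mcl <- cluster_events(mev)
  # representatives map under the coordinate mirror
  mapped <- data.frame(chrom = cl$chrom,
                       strand = ifelse(cl$strand == "+", "-", "+"),
                       pos = glen[cl$chrom] - 1L - cl$representative_position)
  expect_identical(sort(paste(mapped$chrom, mapped$strand, mapped$pos)),
                   sort(paste(mcl$chrom, mcl$strand,
                              mcl$representative_position)))
})

test_that("sources are clustered separately and totals add", {
  ev <- data.frame(chrom = "c", strand = "+",
                   position = c(10L, 10L, 12L, 500L),
                   read_id = as.character(1:4),
                   source_tag = c("EST", "long_read", "EST", "long_read"))
  cl <- cluster_events(ev)
  s <- summarize_sites(cl)
  per <- s$per_source
  expect_identical(per$n_clusters[per$source_tag == "EST"], 1L)
  expect_identical(per$n_clusters[per$source_tag == "long_read"], 2L)
  expect_identical(per$n_clusters[per$source_tag == "total"], 3L)
  merged <- cluster_events(ev, merge_sources = TRUE)
  expect_identical(nrow(merged), 2L)
})

test_that("member-count fractions are reported over all clusters", {
  cl <- data.frame(source_tag = "x", n_members = c(1L, 2L, 5L))
  s <- summarize_sites(cl)
  expect_equal(unname(s$member_fractions), c(1, 1, 1) / 3)
  run <- noiseless_run()
  expect_equal(unname(run$report$member_fractions["one"]), 1)
})

test_that("the naive exact aligner reproduces simulated alignments", {
  cfg <- sim_config(seed = 31L, n_genes = 6L, n_chromosomes = 1L,
                    chrom_length = 30000L, cs_jitter_sd = 0,
                    decoy_fraction = 0, reads_per_site = 2L)
  sim <- simulate_pa_dataset(cfg)
  prep <- prepare_reads(data.frame(read_id = sim$reads$read_id,
                                   sequence = sim$reads$sequence))
  aln <- align_reads_naive(prep$calls$sense_sequence, sim$genome,
                           read_id = prep$calls$read_id)
  truth <- sim$alignments[match(aln$read_id, sim$alignments$read_id), ]
  expect_identical(aln$start, truth$start)
  expect_identical(aln$end, truth$end)
  expect_identical(aln$strand, truth$strand)
  expect_gt(nrow(aln), 0.8 * nrow(prep$calls)) # nearly all reads place uniquely
})
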