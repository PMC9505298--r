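mk_clusters <- function(chrom, strand, pos)
  data.frame(cluster_id = sprintf("c%03d", seq_along(pos)), chrom = chrom,
             strand = strand, representative_position = pos,
             stringsAsFactors = FALSE)

test_that("flank extraction is centred on the cleavage base", {
  g <- c(chr = random_genome(300, seed = 11))
  fl <- extract_flanks(mk_clusters("chr", "+", 150L), g)
  expect_identical(nchar(fl$flank), 201L)
  expect_identical(fl$flank, unname(substr(g, 51, 251)))  # 0-based 50..250
  expect_identical(substr(fl$flank, 101, 101),
                   unname(substr(g, 151, 151)))
})

test_that("minus-strand flanks are reverse complemented, hand-checked", {
  g <- c(chr = "AACGTAGGCT")  # 10 nt toy
  fl <- extract_flanks(mk_clusters("chr", "-", 5L), g, halfwidth = 3L)
  # genomic [2..8] = CGTAGGC; sense = revcomp = GCCTACG; position 0 = base 5 (A)
  expect_identical(fl$flank, "GCCTACG")
  expect_identical(substr(fl$flank, 4, 4), "T")  # complement of genomic A at 5
  # position -1 holds the complement of genomic base 6 (G -> C)
  expect_identical(substr(fl$flank, 3, 3), "C")
})

test_that("out-of-contig flank positions are N-masked", {
  g <- c(chr = random_genome(300, seed = 12))
  fl <- extract_flanks(mk_clusters("chr", "+", 40L), g)
  expect_identical(substr(fl$flank, 1, 60), strrep("N", 60)) # -100..-41 masked
  expect_false(grepl("N", substr(fl$flank, 61, 201)))
  mono <- nucleotide_profile(fl)
  expect_identical(mono$count[mono$positions < -40], rep(0L, 60))
})

test_that("nucleotide profiles equal a hand tally on four 11-nt flanks", {
  fl <- data.frame(cluster_id = letters[1:4], chrom = "c", strand = "+",
                   position = 0L,
                   flank = c("AAAAAAAAAAA", "CCCCCACCCCC",
                             "GGGGGAGGGGG", "TTTTTATTTTT"))
  attr(fl, "halfwidth") <- 5L
  mono <- nucleotide_profile(fl)
  expect_equal(unname(mono$freq[, "0"]), c(1, 0, 0, 0))  # all A at centre
  expect_equal(unname(mono$freq["A", "1"]), 0.25)
  expect_equal(unname(mono$freq["C", "-5"]), 0.25)
  expect_true(all(abs(colSums(mono$freq)[mono$count > 0] - 1) < 1e-9))
  di <- nucleotide_profile(fl, order = 2L)
  # at position -1 the dinucleotides are AA, CA, GA, TA
  expect_equal(unname(di$freq[c("AA", "CA", "GA", "UA"), "-1"]),
               rep(0.25, 4))
  expect_true(all(abs(colSums(di$freq)[di$count > 0] - 1) < 1e-9))
})

test_that("profile row sums hold at every unmasked position on real flanks", {
  run <- small_run()
  for (prof in list(run$mono_profile, run$di_profile)) {
    ok <- prof$count > 0
    expect_true(all(abs(colSums(prof$freq)[ok] - 1) < 1e-9))
  }
})

test_that("hexamer scan counts exact occurrences by 5'-base position", {
  base <- strrep("C", 201)
  f1 <- base
  substr(f1, -16 + 101, -16 + 106) <- "AATAAA"   # 5' base at -16
  fl <- data.frame(cluster_id = c("a", "b"), chrom = "c", strand = "+",
                   position = 0L, flank = c(f1, f1))
  attr(fl, "halfwidth") <- 100L
  scan <- hexamer_position_scan(fl)
  hit <- scan$counts[scan$counts$hexamer == "AAUAAA", ]
  expect_identical(hit$position, -16L)
  expect_identical(hit$count, 2L)
  expect_identical(unname(scan$sites_with["AAUAAA"]), 2L)
})

test_that("overlapping occurrences all count (poly-U run)", {
  f <- strrep("C", 201)
  substr(f, -20 + 101, -12 + 101) <- strrep("T", 9)  # U9 at -20..-12
  fl <- data.frame(cluster_id = "a", chrom = "c", strand = "+",
                   position = 0L, flank = f)
  attr(fl, "halfwidth") <- 100L
  scan <- hexamer_position_scan(fl)
  uu <- scan$counts[scan$counts$hexamer == "UUUUUU", ]
  expect_identical(uu$position, c(-20L, -19L, -18L, -17L))
  expect_identical(uu$count, rep(1L, 4))
})

test_that("an empty scan range yields an all-zero table", {
  fl <- data.frame(cluster_id = "a", chrom = "c", strand = "+",
                   position = 0L, flank = strrep("A", 21))
  attr(fl, "halfwidth") <- 10L
  scan <- hexamer_position_scan(fl, scan_range = c(-50L, -40L))
  expect_identical(nrow(scan$counts), 0L)
})

test_that("the scan equals a naive substring-search oracle", {
  set.seed(21)
  flanks <- vapply(1:100, function(i)
    paste0(sample(c("A", "C", "G", "T"), 201, TRUE,
                  prob = c(.318, .182, .182, .318)), collapse = ""),
    character(1))
  fl <- data.frame(cluster_id = as.character(1:100), chrom = "c",
                   strand = "+", position = 0L, flank = flanks)
  attr(fl, "halfwidth") <- 100L
  scan <- hexamer_position_scan(fl)
  hexes <- unique(c(vapply(1:50, function(i)
    paste0(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""),
    character(1)), "AATAAA"))
  for (hx in hexes) {
    oracle <- setNames(integer(0), character(0))
    for (x in -50:-6) {
      cnt <- sum(substr(flanks, x + 101, x + 106) == hx)
      if (cnt > 0) oracle[as.character(x)] <- cnt
    }
    got <- scan$counts[scan$counts$hexamer == chartr("T", "U", hx), ]
    expect_identical(setNames(got$count, as.character(got$position)),
                     oracle, label = hx)
  }
})

test_that("signal/noise classification separates peaks from flat noise", {
  flat <- list(counts = data.frame(hexamer = "UUUUUU",
                                   position = -50:-6,
                                   count = rep(7L, 45)),
               sites_with = c(UUUUUU = 45L), positions = -50:-6,
               n_flanks = 100L)
  class(flat) <- "hexamer_scan"
  expect_identical(classify_hexamer_signal(flat, "UUUUUU")$class, "noise")

  delta <- flat
  delta$counts <- data.frame(hexamer = "AAUAAA", position = -16L,
                             count = 40L)
  cl <- classify_hexamer_signal(delta, "AAUAAA")
  expect_identical(cl$class, "signal")
  expect_identical(cl$peak_position, -16L)
})

test_that("PAS assignment follows canonical priority and the whole-hexamer window", {
  mkflank <- function(edit) {
    f <- strrep("C", 201)
    for (e in edit) substr(f, e$pos + 101, e$pos + 106) <- e$hex
    fl <- data.frame(cluster_id = "a", chrom = "c", strand = "+",
                     position = 0L, flank = f)
    attr(fl, "halfwidth") <- 100L
    fl
  }
  both <- mkflank(list(list(pos = -20, hex = "ATTAAA"),
                       list(pos = -28, hex = "AATAAA")))
  call <- assign_pas(both)
  expect_identical(call$pas, "AAUAAA")
  expect_identical(call$offset, -28L)

  scrubbed <- mkflank(list())
  expect_identical(assign_pas(scrubbed)$pas, "none")

  # a hexamer overlapping the cleavage base is not eligible
  late <- mkflank(list(list(pos = -3, hex = "AATAAA")))
  expect_identical(assign_pas(late)$pas, "none")

  # multiple occurrences: the largest offset <= -11 wins, else nearest -11
  multi <- mkflank(list(list(pos = -35, hex = "AATAAA"),
                        list(pos = -15, hex = "AATAAA")))
  expect_identical(assign_pas(multi)$offset, -15L)
  only_late <- mkflank(list(list(pos = -9, hex = "AATAAA")))
  expect_identical(assign_pas(only_late)$offset, -9L)
})

test_that("adding a higher-priority hexamer never downgrades the call", {
  set.seed(22)
  pr <- pas_hexamers("DNA")
  for (i in 1:50) {
    f <- paste0(sample(c("C", "G", "T"), 201, TRUE), collapse = "")
    lowpos <- sample(seq(-38, -8), 1)
    low <- sample(pr[-1], 1)
    substr(f, lowpos + 101, lowpos + 106) <- low
    fl <- data.frame(cluster_id = "a", chrom = "c", strand = "+",
                     position = 0L, flank = f)
    attr(fl, "halfwidth") <- 100L
    before <- assign_pas(fl)$pas
    # write AAUAAA somewhere else in the eligible window
    hipos <- sample(setdiff(seq(-40, -6), seq(lowpos - 5, lowpos + 5)), 1)
    f2 <- f
    substr(f2, hipos + 101, hipos + 106) <- "AATAAA"
    fl$flank <- f2
    after <- assign_pas(fl)$pas
    rank <- function(h) match(h, c(pas_hexamers(), "none"))
    expect_lte(rank(after), rank(before))
  }
})

test_that("usage tables cover Other and sum to 100", {
  calls <- data.frame(cluster_id = as.character(1:4),
                      pas = c("AAUAAA", "AAUAAA", "AUUAAA", "none"),
                      offset = c(-20L, -21L, -15L, NA))
  u <- usage_frequency_table(calls)
  expect_equal(u$percent[u$hexamer == "AAUAAA"], 50)
  expect_equal(u$percent[u$hexamer == "AUUAAA"], 25)
  expect_equal(u$percent[u$hexamer == "Other"], 25)
  expect_equal(sum(u$percent), 100)

  allnone <- data.frame(cluster_id = "x", pas = "none", offset = NA)
  expect_equal(usage_frequency_table(allnone)$percent[15], 100)
})

test_that("chi-square against background matches the closed form", {
  expect_equal(unname(background_freqs(0.364)["A"]), 0.318)
  expect_equal(unname(background_freqs(0.364)["G"]), 0.182)

  # hand case: n = 100, 50 A observed vs expected 31.8
  hand <- (50 - 31.8)^2 / 31.8 + (50 - 68.2)^2 / 68.2
  prof <- list(freq = matrix(c(0.5, 0.2, 0.15, 0.15), ncol = 1,
                             dimnames = list(c("A", "C", "G", "U"), "0")),
               count = 100L, positions = 0L, order = 1L, n_flanks = 100L)
  class(prof) <- "profile_matrix"
  res <- chisq_vs_background(prof, 0L, "A", gc = 0.364)
  expect_equal(res$statistic, hand, tolerance = 1e-6)
  expect_equal(res$statistic, 15.27, tolerance = 1e-2 / 15)

  # observed equal to expected: statistic 0, p 1 (n chosen so the observed
  # count is integral: 0.318 * 500 = 159)
  prof0 <- prof
  prof0$freq["A", 1] <- 0.318
  prof0$count <- 500L
  res0 <- chisq_vs_background(prof0, 0L, "A", gc = 0.364)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)

  # n = 0 yields an undefined-result marker, not an error
  profn <- prof
  profn$count <- 0L
  resn <- chisq_vs_background(profn, 0L, "A")
  expect_true(is.na(resn$statistic) && is.na(resn$p_value))
})

test_that("downstream U enrichment is reported against background", {
  # flanks that are pure U downstream, background-ish upstream
  f <- paste0(strrep("C", 101), strrep("T", 100))
  fl <- data.frame(cluster_id = "a", chrom = "c", strand = "+",
                   position = 0L, flank = f)
  attr(fl, "halfwidth") <- 100L
  mono <- nucleotide_profile(fl)
  d <- dse_enrichment(mono, gc = 0.364)
  expect_equal(d$mean_u_window, 1)
  expect_equal(d$expected_u, 0.318)

  # background-composition flanks: window mean near (1-gc)/2
  set.seed(23)
  flanks <- vapply(1:400, function(i)
    paste0(sample(c("A", "C", "G", "T"), 201, TRUE,
                  prob = c(.318, .182, .182, .318)), collapse = ""),
    character(1))
  flb <- data.frame(cluster_id = as.character(1:400), chrom = "c",
                    strand = "+", position = 0L, flank = flanks)
  attr(flb, "halfwidth") <- 100L
  db <- dse_enrichment(nucleotide_profile(flb), gc = 0.364)
  n_eff <- 400 * 25
  expect_within_3se(db$mean_u_window, 0.318, n_eff, "background U")
})
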