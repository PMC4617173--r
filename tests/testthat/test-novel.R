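test_that("tag mapping finds forward and reverse loci exactly", {
  set.seed(61)
  g <- random_dna_seq(3000)
  fwd_tag <- substr(g, 500, 520)
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  rev_tag <- rc(substr(g, 1500, 1520))
  tags <- data.frame(sequence = c(fwd_tag, rev_tag),
                     count_control = c(1L, 1L), count_cms = c(0L, 0L))
  loci <- map_tags_to_genome(tags, c(chr1 = g))
  f <- loci[loci$sequence == fwd_tag, ]
  expect_true(any(f$start == 500 & f$strand == "+"))
  r <- loci[loci$sequence == rev_tag, ]
  expect_true(any(r$start == 1500 & r$strand == "-"))
})

test_that("tag mapping equals the naive string-scan oracle", {
  set.seed(62)
  g <- random_dna_seq(5000)
  tags <- data.frame(
    sequence = c(vapply(sample(4000, 30), function(s) substr(g, s, s + 19),
                        character(1)),
                 replicate(20, random_dna_seq(20))),
    count_control = 1L, count_cms = 0L, stringsAsFactors = FALSE)
  tags <- tags[!duplicated(tags$sequence), ]
  loci <- map_tags_to_genome(tags, c(chr1 = g))
  for (tg in tags$sequence) {
    mine <- loci[loci$sequence == tg, c("start", "strand")]
    mine <- mine[order(mine$start, mine$strand), ]
    orc <- oracle_tag_loci(tg, g)
    orc <- orc[order(orc$start, orc$strand), ]
    expect_equal(unname(as.matrix(mine)), unname(as.matrix(orc)), info = tg)
  }
})

test_that("repetitive tags beyond the locus cutoff are dropped and flagged", {
  unit <- "ACGTACGTACGTACGTACGTA"
  g <- paste(rep(paste0(unit, "TTTTT"), 25), collapse = "")
  tags <- data.frame(sequence = unit, count_control = 1L, count_cms = 0L)
  loci <- map_tags_to_genome(tags, c(chr1 = g), max_loci = 20)
  expect_equal(nrow(loci), 0)
  expect_equal(attr(loci, "repetitive"), unit)
})

novel_fixture <- function(seed = 31, counts = NULL) {
  cfg <- small_sim_config(seed = seed, background_fraction = 0)
  gen <- make_genome(cfg)
  nov <- gen$precursors[gen$precursors$novel, ]
  tags <- data.frame(sequence = nov$mature,
                     count_control = if (is.null(counts)) rep(60L, nrow(nov))
                                     else counts,
                     count_cms = 40L, stringsAsFactors = FALSE)
  list(gen = gen, nov = nov, tags = tags)
}

test_that("abundant planted matures are called with correct arm and locus", {
  fx <- novel_fixture()
  loci <- map_tags_to_genome(fx$tags, fx$gen$genome)
  calls <- call_novel(loci, fx$gen$genome, fx$tags)
  expect_equal(sort(calls$mature_sequence), sort(fx$nov$mature))
  for (i in seq_len(nrow(calls))) {
    truth <- fx$nov[match(calls$mature_sequence[i], fx$nov$mature), ]
    expect_equal(calls$arm[i], "5p")  # matures sit on the 5' arm by construction
    expect_equal(calls$chrom[i], truth$chrom)
    # excised precursor must lie within the planted locus's neighbourhood
    expect_lte(abs(calls$start[i] - truth$start), 160)
    expect_lte(calls$energy[i], -18)
    expect_gt(calls$copy_number[i], 5)
  }
})

test_that("the copy-number threshold is strictly greater than five", {
  fx <- novel_fixture(counts = rep(0L, 4))
  fx$tags$count_control <- c(5L, 6L, 0L, 60L)
  fx$tags$count_cms <- 0L
  loci <- map_tags_to_genome(fx$tags, fx$gen$genome)
  calls <- call_novel(loci, fx$gen$genome, fx$tags)
  expect_false(fx$tags$sequence[1] %in% calls$mature_sequence)  # copy 5
  expect_true(fx$tags$sequence[2] %in% calls$mature_sequence)   # copy 6
  expect_false(fx$tags$sequence[3] %in% calls$mature_sequence)  # copy 0
})

test_that("abundant tags at non-hairpin loci are rejected", {
  fx <- novel_fixture()
  g <- fx$gen$genome[[1]]
  pos <- 300L
  while (any(abs(fx$gen$precursors$start - pos) < 400)) pos <- pos + 500L
  tag <- substr(g, pos, pos + 20L)
  tags <- data.frame(sequence = tag, count_control = 100L, count_cms = 0L)
  loci <- map_tags_to_genome(tags, fx$gen$genome)
  expect_gte(nrow(loci), 1)
  calls <- call_novel(loci, fx$gen$genome, tags)
  expect_equal(nrow(calls), 0)
})

test_that("identical matures from several loci merge with n_precursors > 1", {
  fx <- novel_fixture(seed = 37)
  p <- fx$gen$precursors[fx$gen$precursors$novel, ][1, ]
  g <- fx$gen$genome[[1]]
  # plant a second copy of the same precursor far away
  insert_at <- 1000L
  while (any(abs(fx$gen$precursors$start - insert_at) < 600)) {
    insert_at <- insert_at + 700L
  }
  substr(g, insert_at, insert_at + nchar(p$sequence) - 1L) <- p$sequence
  genome2 <- c(chr1 = g)
  tags <- data.frame(sequence = p$mature, count_control = 80L,
                     count_cms = 10L)
  loci <- map_tags_to_genome(tags, genome2)
  expect_equal(nrow(loci), 2)
  calls <- call_novel(loci, genome2, tags)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$n_precursors, 2)
  # merging is order-independent
  calls_rev <- call_novel(loci[2:1, ], genome2, tags)
  expect_equal(calls$mature_sequence, calls_rev$mature_sequence)
  expect_equal(calls$n_precursors, calls_rev$n_precursors)
})

test_that("star-arm tags are detected as 5p/3p pairs", {
  fx <- novel_fixture(seed = 41)
  p <- fx$gen$precursors[fx$gen$precursors$novel, ][1, ]
  cand <- hairpin_candidate(p$sequence, c(p$mature_start, p$mature_end))
  star <- substr(p$sequence, cand$star_span[1], cand$star_span[2])
  tags <- data.frame(sequence = c(p$mature, star),
                     count_control = c(60L, 8L), count_cms = c(40L, 2L),
                     stringsAsFactors = FALSE)
  loci <- map_tags_to_genome(tags, fx$gen$genome)
  calls <- call_novel(loci, fx$gen$genome, tags)
  expect_true(calls$has_star[calls$mature_sequence == p$mature])
})

test_that("isomiR counting keeps end-tolerant tags and drops core mismatches", {
  fx <- novel_fixture(seed = 43)
  p <- fx$nov[1, ]
  mat <- p$mature
  trimmed <- substr(mat, 1, nchar(mat) - 2L)        # 3' trim by 2 -> counted
  core_mut <- mat
  substr(core_mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                      substr(mat, 11, 11))[1]
  end_mut <- mat
  substr(end_mut, nchar(mat), nchar(mat)) <-
    setdiff(c("A", "C", "G", "T"), substr(mat, nchar(mat), nchar(mat)))[1]
  tags <- data.frame(
    sequence = c(mat, trimmed, core_mut, end_mut),
    count_control = c(60L, 10L, 7L, 3L), count_cms = c(40L, 5L, 7L, 2L),
    stringsAsFactors = FALSE)
  loci <- map_tags_to_genome(tags[1, , drop = FALSE], fx$gen$genome)
  calls <- call_novel(loci, fx$gen$genome, tags)
  calls <- count_novel_expression(calls, tags)
  i <- match(mat, calls$mature_sequence)
  # exact + trimmed + end substitution, but never the core mismatch
  expect_equal(calls$expr_control[i], 60 + 10 + 3)
  expect_equal(calls$expr_cms[i], 40 + 5 + 2)
})

test_that("no call exists without a passing hairpin and copy number", {
  cfg <- small_sim_config(seed = 47)
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  srna <- simulate_srna(cfg, trs$truth, gen)
  loci <- map_tags_to_genome(srna, gen$genome)
  calls <- call_novel(loci, gen$genome, srna)
  counts <- setNames(srna$count_control + srna$count_cms, srna$sequence)
  for (i in seq_len(nrow(calls))) {
    expect_gt(calls$copy_number[i], 5)
    expect_equal(unname(counts[calls$mature_sequence[i]]),
                 calls$copy_number[i])
    cand <- hairpin_candidate(calls$precursor[i],
                              regexpr(calls$mature_sequence[i],
                                      calls$precursor[i], fixed = TRUE) +
                                c(0L, nchar(calls$mature_sequence[i]) - 1L))
    expect_lte(cand$fold$energy, -18)
  }
})
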