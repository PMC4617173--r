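rc_dna <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(x)), "")[[1]]),
        collapse = "")
}

test_that("alignment scoring follows the plant penalty scheme", {
  set.seed(71)
  mir <- random_dna_seq(21)
  expect_equal(score_alignment(mir, rc_dna(mir))$score, 0)

  # G:U wobble outside the core costs 0.5, inside the core 1.0
  wobble_at <- function(mir, pos) {
    stopifnot(substr(mir, pos, pos) %in% c("G", "T"))
    site <- strsplit(rc_dna(mir), "")[[1]]
    site[nchar(mir) + 1 - pos] <- if (substr(mir, pos, pos) == "G") "T" else "G"
    paste(site, collapse = "")
  }
  mir2 <- mir
  substr(mir2, 15, 15) <- "G"; substr(mir2, 5, 5) <- "G"
  expect_equal(score_alignment(mir2, wobble_at(mir2, 15))$score, 0.5)
  expect_equal(score_alignment(mir2, wobble_at(mir2, 5))$score, 1.0)

  # mismatches: 1.0 outside positions 2-13, 2.0 inside
  mm_at <- function(mir, pos) {
    site <- strsplit(rc_dna(mir), "")[[1]]
    site[nchar(mir) + 1 - pos] <- substr(mir, pos, pos)  # same base: no pair
    paste(site, collapse = "")
  }
  expect_equal(score_alignment(mir, mm_at(mir, 16))$score, 1.0)
  expect_equal(score_alignment(mir, mm_at(mir, 7))$score, 2.0)
})

test_that("single-bulge alignments match the brute-force oracle on 17-mers", {
  set.seed(72)
  for (i in 1:40) {
    mir <- random_dna_seq(17)
    for (dl in c(-1L, 0L, 1L)) {
      site <- random_dna_seq(17L + dl)
      expect_equal(score_alignment(mir, site, core = c(2L, 13L))$score,
                   oracle_align_score(mir, site),
                   info = paste(mir, site))
    }
    # near-complementary site with a bulge
    site <- rc_dna(mir)
    ins_at <- sample(17, 1)
    site2 <- paste0(substr(site, 1, ins_at), "A",
                    substr(site, ins_at + 1, 17))
    expect_equal(score_alignment(mir, site2)$score,
                 oracle_align_score(mir, site2))
  }
})

test_that("the vectorized site scorer agrees with the reference scorer", {
  set.seed(73)
  mir <- random_dna_seq(21)
  tr <- random_dna_seq(300)
  starts <- 1:(300 - 20)
  sites <- substring(tr, starts, starts + 20)
  v <- mircms:::score_sites_gapless(mir, sites)
  p <- mircms:::score_positions_gapless(
    mir, strsplit(chartr("T", "U", tr), "")[[1]], starts)
  s <- vapply(sites, function(x) score_alignment(mir, x)$score, numeric(1))
  expect_equal(v, unname(s))
  expect_equal(p, unname(s))
})

test_that("degradome profiles accumulate 5' ends and enforce the 20-21 nt rule", {
  set.seed(74)
  tr <- c(t1 = random_dna_seq(400))
  tag20 <- substr(tr, 101, 120)
  tag21 <- substr(tr, 101, 121)
  tag19 <- substr(tr, 200, 218)
  tags <- data.frame(sequence = c(tag20, tag21, tag19),
                     count = c(7, 2, 5), stringsAsFactors = FALSE)
  prof <- build_profiles(tags, tr)
  expect_equal(prof$t1[101], 9)  # both qualifying tags start at 101
  expect_equal(prof$t1[200], 0)  # 19-nt tag excluded
  expect_equal(sum(prof$t1), 9)
})

test_that("profiles equal a naive substring-scan oracle", {
  set.seed(75)
  tr <- c(a = random_dna_seq(200), b = random_dna_seq(250))
  tags <- data.frame(
    sequence = c(substr(tr[["a"]], 50, 69), substr(tr[["b"]], 10, 30),
                 random_dna_seq(20)),
    count = c(3, 4, 9), stringsAsFactors = FALSE)
  prof <- build_profiles(tags, tr)
  for (nm in names(tr)) {
    expected <- numeric(nchar(tr[[nm]]))
    for (i in seq_len(nrow(tags))) {
      w <- nchar(tags$sequence[i])
      if (!w %in% 20:21) next
      for (s in seq_len(nchar(tr[[nm]]) - w + 1)) {
        if (substr(tr[[nm]], s, s + w - 1) == tags$sequence[i]) {
          expected[s] <- expected[s] + tags$count[i]
        }
      }
    }
    expect_equal(prof[[nm]], expected, info = nm)
  }
})

target_fixture <- function(seed = 81, score = 0) {
  set.seed(seed)
  mir <- random_dna_seq(21)
  site <- if (score == 0) rc_dna(mir) else NULL
  tr <- random_dna_seq(300)
  s <- 120L
  substr(tr, s, s + 20L) <- if (is.null(site)) rc_dna(mir) else site
  cleav <- s + 11L  # transcript base paired to miRNA position 10
  tag <- substr(tr, cleav, cleav + 19L)
  list(mir = c(mirX = mir), tr = c(trX = tr), s = s, cleav = cleav, tag = tag)
}

test_that("a cleavage-coincident site yields a hit at the right position", {
  fx <- target_fixture()
  tags <- data.frame(sequence = fx$tag, count = 40)
  prof <- build_profiles(tags, fx$tr)
  hits <- find_targets(fx$mir, fx$tr, prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$cleavage_pos, fx$cleav)
  expect_equal(hits$mirna_cleavage_index, 10L)
  expect_equal(hits$align_score, 0)
  expect_equal(hits$site_start, fx$s)
})

test_that("signal away from positions 10/11 does not validate a site", {
  fx <- target_fixture()
  # tag 5' end opposite miRNA position 14: 4 nt upstream of the register
  off_tag <- substr(fx$tr, fx$cleav - 4L, fx$cleav - 4L + 19L)
  tags <- data.frame(sequence = off_tag, count = 40)
  prof <- build_profiles(tags, fx$tr)
  hits <- find_targets(fx$mir, fx$tr, prof)
  expect_equal(nrow(hits), 0)
})

test_that("position 11 is accepted as the alternative register", {
  fx <- target_fixture()
  # the base paired to miRNA position 11 is one nt 5' of the position-10 base
  tag11 <- substr(fx$tr, fx$cleav - 1L, fx$cleav + 18L)
  tags <- data.frame(sequence = tag11, count = 40)
  prof <- build_profiles(tags, fx$tr)
  hits <- find_targets(fx$mir, fx$tr, prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mirna_cleavage_index, 11L)
})

test_that("sites scoring above 4 are never retained", {
  set.seed(83)
  mir <- random_dna_seq(21)
  site <- strsplit(rc_dna(mir), "")[[1]]
  # two core mismatches (4.0) plus one outside (1.0) = 5 > 4
  for (pos in c(4, 6)) site[21 + 1 - pos] <- substr(mir, pos, pos)
  site[21 + 1 - 16] <- substr(mir, 16, 16)
  tr <- random_dna_seq(300)
  substr(tr, 120, 140) <- paste(site, collapse = "")
  trs <- c(trY = tr)
  tag <- substr(tr, 131, 150)
  prof <- build_profiles(data.frame(sequence = tag, count = 50), trs)
  hits <- find_targets(setNames(mir, "m"), trs, prof)
  expect_equal(nrow(hits), 0)
  # the same peak with a score-4 site is retained
  site4 <- strsplit(rc_dna(mir), "")[[1]]
  for (pos in c(4, 6)) site4[21 + 1 - pos] <- substr(mir, pos, pos)
  tr2 <- tr
  substr(tr2, 120, 140) <- paste(site4, collapse = "")
  trs2 <- c(trY = tr2)
  prof2 <- build_profiles(data.frame(sequence = substr(tr2, 131, 150),
                                     count = 50), trs2)
  hits2 <- find_targets(setNames(mir, "m"), trs2, prof2)
  expect_equal(nrow(hits2), 1)
  expect_equal(hits2$align_score, 4)
})

test_that("t-plot categories follow their definitions and the oracle", {
  prof <- numeric(200)
  prof[50] <- 90; prof[10] <- 3; prof[100] <- 2
  expect_equal(categorize(prof[50], prof), 0L)   # unique maximum
  prof2 <- prof; prof2[150] <- 90
  expect_equal(categorize(prof2[50], prof2), 1L) # shared maximum
  prof2[c(120, 130)] <- 2  # nonzero: 2,2,2,3,90,90 -> median 2.5
  expect_equal(categorize(prof2[10], prof2), 2L) # above median, below max
  prof3 <- prof; prof3[60] <- 2
  expect_equal(categorize(prof3[100], prof3), 3L) # at/below median, > 1 read
  prof4 <- prof; prof4[70] <- 1
  expect_equal(categorize(prof4[70], prof4), 4L)  # single read
  set.seed(85)
  for (i in 1:200) {
    p <- numeric(50)
    nz <- sample(50, sample(1:10, 1))
    p[nz] <- sample(1:20, length(nz), replace = TRUE)
    pos <- nz[sample.int(length(nz), 1)]
    expect_equal(categorize(p[pos], p), oracle_category(p[pos], p))
  }
})

test_that("the shuffle p-value is deterministic and near 1/(n+1) for perfect sites", {
  fx <- target_fixture()
  site <- substr(fx$tr, fx$s, fx$s + 20L)
  p1 <- target_pvalue(fx$mir[[1]], site, 0, n_shuffles = 100, seed = 7)
  p2 <- target_pvalue(fx$mir[[1]], site, 0, n_shuffles = 100, seed = 7)
  expect_identical(p1, p2)
  expect_equal(p1, 1 / 101)  # no shuffled miRNA reaches score 0
  expect_error(target_pvalue(fx$mir[[1]], site, 0, n_shuffles = 5), "20")
})

test_that("weaker sites get larger shuffle p-values on average", {
  set.seed(87)
  p0 <- numeric(6); p4 <- numeric(6)
  for (i in 1:6) {
    mir <- random_dna_seq(21)
    site0 <- rc_dna(mir)
    s4 <- strsplit(rc_dna(mir), "")[[1]]
    for (pos in c(4, 6)) s4[21 + 1 - pos] <- substr(mir, pos, pos)
    p0[i] <- target_pvalue(mir, site0, 0, n_shuffles = 60, seed = i)
    p4[i] <- target_pvalue(mir, paste(s4, collapse = ""), 4,
                           n_shuffles = 60, seed = i)
  }
  expect_lte(mean(p0), mean(p4))
})

test_that("every retained hit satisfies score, coincidence and p-value rules", {
  cfg <- small_sim_config(seed = 91)
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  deg <- simulate_degradome(cfg, trs$truth, trs$transcripts)
  mirnas <- setNames(gen$precursors$mature, gen$precursors$name)
  hits <- degradome_targets(mirnas, trs$transcripts, deg$control,
                            n_shuffles = 40, seed = 2)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$align_score <= 4))
  expect_true(all(hits$mirna_cleavage_index %in% c(10L, 11L)))
  expect_true(all(hits$p_value < 0.05))
  expect_true(all(hits$tag_count_at_site > 0))
  expect_true(all(hits$category %in% 0:4))
  # planted targets are recovered
  tg <- trs$truth$planted_targets
  found <- merge(hits, tg, by = c("transcript_id", "cleavage_pos"))
  expect_equal(nrow(found), nrow(tg))
})

test_that("t-plot data marks cleavage sites", {
  prof <- c(0, 5, 0, 9)
  hits <- data.frame(cleavage_pos = 4L)
  td <- tplot_data(prof, hits)
  expect_equal(td$count, prof)
  expect_equal(which(td$is_cleavage_site), 4L)
})
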