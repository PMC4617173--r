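ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

test_that("length and polyA filters remove the documented cases", {
  reads <- c("ACGTACGTACGTACGTACGT",              # 20 nt, kept
             "ACGTACGTACGTACGTA",                 # 17 nt -> too short
             "AAAAAAAAAAAAAAAAAAAA",              # 20 nt, 100% A -> polyA
             paste(rep("ACGT", 9), collapse = ""))  # 36 nt -> too long
  out <- clean_reads(reads)
  expect_equal(out$report$n_shorter_than_18, 1)
  expect_equal(out$report$n_polyA, 1)
  expect_equal(out$report$n_longer_than_30, 1)
  expect_equal(out$report$n_clean, 1)
  expect_equal(out$report$n_raw,
               out$report$n_clean + out$report$n_shorter_than_18 +
                 out$report$n_polyA + out$report$n_longer_than_30)
})

test_that("a spiked synthetic stream reproduces its composition exactly", {
  set.seed(33)
  insert <- function() random_dna_seq(sample(18:25, 1))
  good <- replicate(400, paste0(insert(), ADAPTER3))
  no_adapter <- replicate(25, random_dna_seq(40))
  contaminant <- replicate(20, paste0(ADAPTER5, insert(), ADAPTER3))
  short <- replicate(15, paste0(random_dna_seq(10), ADAPTER3))
  lowq <- replicate(10, paste0("ACGTN", insert(), ADAPTER3))
  polya <- replicate(5, paste0(strrep("A", 22), ADAPTER3))
  reads <- sample(c(good, no_adapter, contaminant, short, lowq, polya))
  out <- clean_reads(reads, adapter3 = ADAPTER3, adapter5 = ADAPTER5)
  expect_equal(out$report$n_raw, 475)
  expect_equal(out$report$n_low_quality, 10)
  expect_equal(out$report$n_3adapter_null, 25)
  expect_equal(out$report$n_5adapter_contaminant, 20)
  expect_equal(out$report$n_shorter_than_18, 15)
  expect_equal(out$report$n_polyA, 5)
  expect_equal(out$report$n_clean, 400)
  expect_true(all(nchar(out$tags) >= 18 & nchar(out$tags) <= 30))
})

test_that("empty input yields an empty stream and a zeroed report", {
  out <- clean_reads(character(0))
  expect_length(out$tags, 0)
  expect_true(all(unlist(out$report) == 0))
})

test_that("malformed records are skipped with a count", {
  out <- clean_reads(c("ACGTACGTACGTACGTACGT", NA, ""))
  expect_equal(out$report$n_malformed, 2)
  expect_equal(out$report$n_clean, 1)
})

test_that("collapse matches a brute-force dictionary count and keeps sharing", {
  set.seed(44)
  pool <- replicate(120, random_dna_seq(21))
  ctrl <- sample(pool, 1000, replace = TRUE)
  cms <- sample(pool, 800, replace = TRUE)
  tab <- collapse_tags(ctrl, cms)
  # oracle: environment-based tally
  dict <- new.env()
  for (s in ctrl) assign(s, c(get0(s, dict, ifnotfound = c(0, 0))[1] + 1,
                              get0(s, dict, ifnotfound = c(0, 0))[2]), dict)
  for (s in cms) assign(s, c(get0(s, dict, ifnotfound = c(0, 0))[1],
                             get0(s, dict, ifnotfound = c(0, 0))[2] + 1), dict)
  expect_equal(nrow(tab), length(ls(dict)))
  for (i in seq_len(nrow(tab))) {
    expect_equal(unname(get(tab$sequence[i], dict)),
                 c(tab$count_control[i], tab$count_cms[i]))
  }
  sh <- attr(tab, "sharing")
  expect_equal(sh$total$tags, 1800)
  expect_equal(sh$total$shared + sh$total$control_specific +
                 sh$total$cms_specific, 1800)
  expect_equal(sh$unique$shared + sh$unique$control_specific +
                 sh$unique$cms_specific, nrow(tab))
})

test_that("a tag present in both samples is shared with counts preserved", {
  tab <- collapse_tags(c("ACGTACGTACGTACGTAC", "ACGTACGTACGTACGTAC"),
                       c("ACGTACGTACGTACGTAC"))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$count_control, 2)
  expect_equal(tab$count_cms, 1)
  expect_equal(attr(tab, "sharing")$unique$shared, 1)
})

make_reference <- function() {
  set.seed(55)
  mat <- random_dna_seq(21)
  prec <- paste0(random_dna_seq(15), mat, random_dna_seq(40))
  list(mature = setNames(mat, "ref-miR-1"),
       precursor = setNames(prec, "ref-MIR-1"), mat = mat, prec = prec)
}

test_that("exact mature tags match with the full count assigned", {
  r <- make_reference()
  tags <- data.frame(sequence = r$mat, count_control = 10L, count_cms = 7L)
  rec <- match_known(tags, r$precursor, r$mature)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$count_control, 10)
  expect_equal(rec$count_cms, 7)
  expect_true(attr(rec, "matched"))
})

test_that("offset tags match when the mature overlap reaches 16 nt", {
  r <- make_reference()
  # shift +3 within the precursor: 18-nt overlap with the 21-nt mature
  shifted <- substr(r$prec, 19, 39)
  # shift +6: 15-nt overlap, below the rule
  shifted_far <- substr(r$prec, 22, 42)
  tags <- data.frame(sequence = c(shifted, shifted_far),
                     count_control = c(5L, 5L), count_cms = c(0L, 0L))
  rec <- match_known(tags, r$precursor, r$mature)
  expect_equal(attr(rec, "matched"), c(TRUE, FALSE))
  expect_equal(rec$count_control, 5)
})

test_that("one mismatch against the precursor blocks the match", {
  r <- make_reference()
  mut <- r$mat
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 11, 11))[1]
  tags <- data.frame(sequence = mut, count_control = 10L, count_cms = 0L)
  rec <- match_known(tags, r$precursor, r$mature)
  expect_equal(nrow(rec), 0)
  expect_false(attr(rec, "matched"))
})

test_that("matures shared by several precursors collapse into one record", {
  r <- make_reference()
  precs <- c(`ref-MIR-1a` = r$prec,
             `ref-MIR-1b` = paste0(random_dna_seq(10), r$mat,
                                   random_dna_seq(30)))
  mats <- c(`ref-miR-1a` = r$mat, `ref-miR-1b` = r$mat)
  tags <- data.frame(sequence = r$mat, count_control = 4L, count_cms = 6L)
  rec <- match_known(tags, precs, mats)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$count_control, 4)  # counted once, not per precursor
  expect_equal(sort(strsplit(rec$precursor_ids, ",")[[1]]),
               c("ref-MIR-1a", "ref-MIR-1b"))
})

test_that("empty or malformed references are rejected", {
  tags <- data.frame(sequence = "ACGT", count_control = 1L, count_cms = 0L)
  expect_error(match_known(tags, character(0), c(a = "ACGT")), "non-empty")
  expect_error(match_known(tags, c(p = "ACGT", p = "ACGG"), c(a = "ACGT")),
               "duplicate")
})

test_that("match_known is order-independent over tag input order", {
  cfg <- small_sim_config(seed = 12, background_fraction = 0)
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  srna <- simulate_srna(cfg, trs$truth, gen)
  r1 <- match_known(srna, gen$known_reference$precursor,
                    gen$known_reference$mature)
  perm <- srna[rev(seq_len(nrow(srna))), ]
  r2 <- match_known(perm, gen$known_reference$precursor,
                    gen$known_reference$mature)
  expect_equal(r1[order(r1$name), -match("precursor_ids", names(r1))],
               r2[order(r2$name), -match("precursor_ids", names(r2))],
               ignore_attr = TRUE)
})

test_that("planted known miRNAs are recovered with exact counts without noise", {
  cfg <- small_sim_config(seed = 12, background_fraction = 0)
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  srna <- simulate_srna(cfg, trs$truth, gen)
  rec <- match_known(srna, gen$known_reference$precursor,
                     gen$known_reference$mature)
  known <- gen$precursors[!gen$precursors$novel, ]
  for (i in seq_len(nrow(known))) {
    ri <- match(known$mature[i], rec$mature_sequence)
    expect_false(is.na(ri))
    ti <- match(known$mature[i], srna$sequence)
    # the star tag overlaps no mature, so the record count is exactly the
    # mature tag count
    expect_equal(rec$count_control[ri], srna$count_control[ti])
  }
})

test_that("family expansion accepts 2-edit relatives with valid hairpins only", {
  cfg <- small_sim_config(seed = 14)
  gen <- make_genome(cfg)
  mat <- gen$precursors$mature[1]
  mutate <- function(s, k) {
    chars <- strsplit(s, "")[[1]]
    for (pos in seq(2, by = 3, length.out = k)) {
      chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
    }
    paste(chars, collapse = "")
  }
  foreign2 <- mutate(mat, 2)   # reference differing by 2 substitutions
  foreign3 <- mutate(mat, 3)   # differing by 3: out of budget
  tags <- data.frame(sequence = mat, count_control = 50L, count_cms = 40L,
                     stringsAsFactors = FALSE)
  hit <- expand_families(tags, c(famA = foreign2), gen$genome)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$family, "famA")
  expect_equal(hit$mature_sequence, mat)
  expect_lte(hit$energy, -18)
  miss <- expand_families(tags, c(famB = foreign3), gen$genome)
  expect_equal(nrow(miss), 0)
})

test_that("relatives whose loci do not fold are discarded as pseudo-miRNAs", {
  cfg <- small_sim_config(seed = 14)
  gen <- make_genome(cfg)
  # a background tag: present in the genome, matches itself (0 edits),
  # but its locus is not a hairpin (taken well away from any precursor)
  g <- gen$genome[[1]]
  pos <- 100L
  while (any(abs(gen$precursors$start - pos) < 400)) pos <- pos + 500L
  tag <- substr(g, pos, pos + 20L)
  tags <- data.frame(sequence = tag, count_control = 50L, count_cms = 40L)
  out <- expand_families(tags, c(famX = tag), gen$genome)
  expect_equal(nrow(out), 0)
})

test_that("family expansion without a genome is skipped with a warning", {
  tags <- data.frame(sequence = "ACGTACGTACGTACGTACGTA",
                     count_control = 9L, count_cms = 9L)
  expect_warning(out <- expand_families(tags, c(f = "ACGTACGTACGTACGTACGTA"),
                                        NULL),
                 "skipped")
  expect_equal(nrow(out), 0)
})

test_that("annotation priority resolves overlaps and forwards the right classes", {
  decoys <- c(rRNA_synth = paste0("CCCC", "ACGTACGTACGTACGTACGTA", "GGGG"))
  tags <- data.frame(
    sequence = c("ACGTACGTACGTACGTACGTA",   # in rRNA decoy AND in intron
                 "TTTTTTTTTTGGGGGGGGGG",    # maps nowhere
                 "CATCATCATCATCATCATCAT"),  # known miRNA
    count_control = c(1L, 1L, 1L), count_cms = c(0L, 0L, 0L),
    stringsAsFactors = FALSE)
  loci <- data.frame(sequence = "ACGTACGTACGTACGTACGTA", chrom = "chr1",
                     start = 500L, end = 520L, strand = "+",
                     stringsAsFactors = FALSE)
  annotation <- data.frame(chrom = "chr1", start = 400L, end = 700L,
                           strand = "+", type = "intron",
                           stringsAsFactors = FALSE)
  ann <- annotate_hierarchy(tags, loci, annotation, decoys,
                            known_mask = c(FALSE, FALSE, TRUE))
  expect_equal(ann$annotation,
               c("rRNA", "unannotated", "known_miRNA"))
  expect_equal(ann$forwarded, c(FALSE, TRUE, FALSE))
})

test_that("every tag receives exactly one category and counts add up", {
  cfg <- small_sim_config(seed = 16)
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  srna <- simulate_srna(cfg, trs$truth, gen)
  known <- match_known(srna, gen$known_reference$precursor,
                       gen$known_reference$mature)
  loci <- map_tags_to_genome(srna, gen$genome)
  ann <- annotate_hierarchy(srna, loci, gen$annotation, gen$decoys,
                            known_mask = attr(known, "matched"))
  expect_false(any(is.na(ann$annotation)))
  expect_equal(sum(table(ann$annotation)), nrow(srna))
  expect_false(any(ann$annotation == "known_miRNA" & ann$forwarded))
})
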