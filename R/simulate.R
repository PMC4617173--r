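# Synthetic two-condition (CMS vs maintainer) sRNA / degradome / RNA-seq
# data with recorded ground truth. All fixtures are synthetic, generated
# deterministically from a root seed through named substreams.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions the pipeline is tested under:
#' two unreplicated libraries (maintainer control vs CMS), one million
#' small-RNA tags per sample, 10 planted known and 10 planted novel
#' miRNAs, 5 planted degradome-validated targets, planted log2 fold
#' changes of magnitude 1, and Poisson count noise (matching a
#' single-library-per-condition design; negative binomial is available
#' for robustness checks).
#'
#' @param seed root integer seed; all stage substreams derive from it.
#' @param genome_length toy genome size in nt.
#' @param n_known_mirnas,n_novel_mirnas planted miRNAs with/without a
#'   reference entry.
#' @param n_transcripts,transcript_length_range toy transcriptome shape.
#' @param n_planted_targets planted cleavage-validated target sites
#'   (<= n_transcripts).
#' @param target_scores complementarity scores the planted sites are
#'   mutated to (recycled over targets; each must be reachable and <= 4).
#' @param planted_log2fc true log2 fold changes (CMS vs control) recycled
#'   over planted miRNAs and over planted target genes.
#' @param srna_depth,degradome_depth,rnaseq_depth total tags per sample.
#' @param degradome_site_count degradome tag abundance planted at each
#'   cleavage site (>= 5x the per-position background by default).
#' @param background_fraction proportion of sRNA/degradome tags drawn from
#'   background (genome windows + rRNA/tRNA decoys) rather than planted
#'   features.
#' @param n_background_tags distinct background sRNA tag sequences.
#' @param noise_model `"poisson"` or `"nbinom"`.
#' @param nb_dispersion negative-binomial dispersion (1/size) when
#'   `noise_model = "nbinom"`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 100000L,
                              n_known_mirnas = 10L,
                              n_novel_mirnas = 10L,
                              n_transcripts = 50L,
                              transcript_length_range = c(500L, 1500L),
                              n_planted_targets = 5L,
                              target_scores = c(0, 0, 1, 2, 3),
                              planted_log2fc = c(-1, 1),
                              srna_depth = 1e6,
                              degradome_depth = 2e4,
                              rnaseq_depth = 5e6,
                              degradome_site_count = 50L,
                              background_fraction = 0.5,
                              n_background_tags = 500L,
                              noise_model = c("poisson", "nbinom"),
                              nb_dispersion = 0.1) {
  noise_model <- match.arg(noise_model)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_transcripts = as.integer(n_transcripts),
              transcript_length_range = as.integer(transcript_length_range),
              n_planted_targets = as.integer(n_planted_targets),
              target_scores = target_scores,
              planted_log2fc = planted_log2fc,
              srna_depth = srna_depth, degradome_depth = degradome_depth,
              rnaseq_depth = rnaseq_depth,
              degradome_site_count = as.integer(degradome_site_count),
              background_fraction = background_fraction,
              n_background_tags = as.integer(n_background_tags),
              noise_model = noise_model, nb_dispersion = nb_dispersion)
  stopifnot(cfg$background_fraction >= 0, cfg$background_fraction <= 1,
            cfg$n_planted_targets <= cfg$n_transcripts,
            cfg$srna_depth > 0, cfg$degradome_depth > 0, cfg$rnaseq_depth > 0,
            all(cfg$transcript_length_range > 0),
            cfg$n_known_mirnas >= 0, cfg$n_novel_mirnas >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

draw_counts <- function(cfg, mu) {
  if (cfg$noise_model == "poisson") {
    rpois(length(mu), mu)
  } else {
    rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  }
}

# build one precursor: unpaired flank + mature arm + loop + star arm + flank.
# The stem is a fully paired duplex (>= 26 bp) carrying two G:U wobbles, so
# the fold energy sits far below the -18 kcal/mol ceiling under the bundled
# model and under ViennaRNA alike, the mature/star duplex carries 2-nt 3'
# overhangs by the Dicer geometry, and (as in real hairpins) the star arm is
# not the exact reverse complement of the mature, keeping genome mapping
# unambiguous.
build_precursor <- function(mature) {
  ext <- random_dna(5)
  loop_len <- sample(8:15, 1)
  # low-complementarity loop: A/C alphabet only, cannot extend the stem
  loop <- paste(sample(c("A", "C"), loop_len, TRUE, prob = c(.6, .4)),
                collapse = "")
  arm5 <- paste0(mature, ext)
  arm3 <- strsplit(revcomp(arm5), "")[[1]]
  m_chars <- strsplit(mature, "")[[1]]
  # both wobbles on one side of the mature, leaving a clean >= 11-nt
  # perfectly paired stretch on the other side
  eligible <- which(m_chars %in% c("G", "T"))
  five_side <- eligible[eligible >= 4 & eligible <= 10]
  three_side <- eligible[eligible >= 12 & eligible <= 18]
  wobble_sites <- if (length(five_side) >= 2) head(five_side, 2)
                  else if (length(three_side) >= 2) head(three_side, 2)
                  else head(eligible[eligible >= 4 & eligible <= 18], 1)
  for (k in unique(wobble_sites)) {
    # star base pairing mature position k sits at arm3 index len - k + 1;
    # G:C -> G:U and A:U -> G:U keep the position paired
    arm3[length(arm3) - k + 1L] <- if (m_chars[k] == "G") "T" else "G"
  }
  flank5 <- random_dna(4); flank3 <- random_dna(4)
  seqc <- paste0(flank5, arm5, loop, paste(arm3, collapse = ""), flank3)
  list(sequence = seqc, mature_start = 5L, mature_end = 4L + nchar(mature),
       arm = "5p")
}

#' Generate the toy genome with planted miRNA precursor loci
#'
#' Embeds the planted known and novel precursors at non-overlapping
#' positions (random strand) in a random background genome, together with
#' a synthetic rRNA/tRNA decoy set and a toy exon/intron/repeat annotation
#' that never overlaps the precursor loci. Every planted precursor passes
#' [validate_hairpin()] by construction.
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (named character, one chromosome),
#'   `precursors` (data.frame of loci and relative mature spans),
#'   `known_reference` (precursor + mature sets for the known subset),
#'   `decoys` (named synthetic rRNA/tRNA sequences), `annotation`
#'   (1-based inclusive interval table) and `truth` (started truth table).
#' @export
make_genome <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "genome"))
  n_mir <- cfg$n_known_mirnas + cfg$n_novel_mirnas
  matures <- character(0)
  while (length(matures) < n_mir) {
    m <- random_dna(21)
    if (!m %in% matures) matures <- c(matures, m)
  }
  prec <- lapply(matures, build_precursor)
  total_prec <- sum(vapply(prec, function(p) nchar(p$sequence), numeric(1)))
  if (cfg$genome_length < 10 * max(total_prec, 1)) {
    stop("genome too short: genome_length must be >= 10x total precursor length")
  }
  genome <- random_dna(cfg$genome_length)
  # place precursors non-overlapping with 50 nt spacing
  taken <- IRanges::IRanges()
  rows <- list()
  for (i in seq_len(n_mir)) {
    len <- nchar(prec[[i]]$sequence)
    repeat {
      s <- sample.int(cfg$genome_length - len - 1L, 1)
      cand <- IRanges::IRanges(start = s - 50L, end = s + len + 49L)
      if (!length(IRanges::findOverlaps(cand, taken))) break
    }
    taken <- c(taken, IRanges::IRanges(start = s - 50L, end = s + nchar(prec[[i]]$sequence) + 49L))
    strand <- sample(c("+", "-"), 1)
    ins <- if (strand == "+") prec[[i]]$sequence else revcomp(prec[[i]]$sequence)
    substr(genome, s, s + len - 1L) <- ins
    is_novel <- i > cfg$n_known_mirnas
    name <- if (is_novel) sprintf("nov-miR-%02d", i - cfg$n_known_mirnas)
            else sprintf("kno-miR-%02d", i)
    rows[[i]] <- data.frame(
      name = name, chrom = "chr1", start = s, end = s + len - 1L,
      strand = strand, sequence = prec[[i]]$sequence,
      mature_start = prec[[i]]$mature_start, mature_end = prec[[i]]$mature_end,
      arm = prec[[i]]$arm, mature = matures[i], novel = is_novel,
      stringsAsFactors = FALSE)
  }
  precursors <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), sequence = character(0),
               mature_start = integer(0), mature_end = integer(0),
               arm = character(0), mature = character(0), novel = logical(0),
               stringsAsFactors = FALSE)

  # synthetic rRNA/tRNA decoys (not placed in the genome)
  decoys <- c(rRNA_synth_1 = random_dna(600), rRNA_synth_2 = random_dna(400),
              tRNA_synth_1 = random_dna(80), tRNA_synth_2 = random_dna(75))

  # toy annotation intervals avoiding precursor loci
  ann <- list()
  types <- c("exon", "intron", "repeat")
  for (t in types) {
    for (k in 1:5) {
      len <- sample(200:600, 1)
      repeat {
        s <- sample.int(cfg$genome_length - len, 1)
        cand <- IRanges::IRanges(start = s, end = s + len - 1L)
        if (!length(IRanges::findOverlaps(cand, taken))) break
      }
      taken <- c(taken, IRanges::IRanges(start = s, end = s + len - 1L))
      ann[[length(ann) + 1L]] <- data.frame(
        chrom = "chr1", start = s, end = s + len - 1L,
        strand = sample(c("+", "-"), 1), type = t, stringsAsFactors = FALSE)
    }
  }
  annotation <- do.call(rbind, ann)

  known <- precursors[!precursors$novel, , drop = FALSE]
  known_reference <- if (nrow(known)) {
    list(precursor = setNames(known$sequence, paste0(known$name, "-prec")),
         mature = setNames(known$mature, known$name))
  } else {
    list(precursor = setNames(character(0), character(0)),
         mature = setNames(character(0), character(0)))
  }

  fc <- rep_len(cfg$planted_log2fc, n_mir)
  truth <- list(
    planted_mirnas = precursors[, c("name", "mature", "chrom", "start", "end",
                                    "strand", "arm", "novel")],
    planted_targets = NULL,
    planted_fc = setNames(fc, precursors$name))
  list(genome = c(chr1 = genome), precursors = precursors,
       known_reference = known_reference, decoys = decoys,
       annotation = annotation, truth = truth)
}

# mutate a perfect reverse-complement site to a requested Allen-type score;
# cleavage-register positions (miRNA 9-11) stay complementary
make_site <- function(mirna, score) {
  m <- nchar(mirna)
  mi <- strsplit(mirna, "")[[1]]            # DNA alphabet
  site <- strsplit(revcomp(mirna), "")[[1]] # site position m+1-k pairs miRNA k
  site_idx <- function(k) m + 1L - k
  remaining <- score
  core_slots <- setdiff(2:8, integer(0))    # core, away from positions 9-13? keep 2-8
  noncore_mm <- setdiff(14:(m - 1L), integer(0))
  wob_slots <- c(setdiff(14:m, integer(0)), 1L)
  used <- integer(0)
  while (remaining >= 2 && length(setdiff(core_slots, used))) {
    k <- setdiff(core_slots, used)[1]
    site[site_idx(k)] <- mi[k]              # same base never pairs
    used <- c(used, k); remaining <- remaining - 2
  }
  while (remaining >= 1 && length(setdiff(noncore_mm, used))) {
    k <- setdiff(noncore_mm, used)[1]
    site[site_idx(k)] <- mi[k]
    used <- c(used, k); remaining <- remaining - 1
  }
  if (remaining >= 0.5 - 1e-9 && remaining > 1e-9) {
    ks <- setdiff(wob_slots, used)
    ks <- ks[mi[ks] %in% c("G", "T")]       # only G or U miRNA bases wobble
    if (!length(ks)) stop("requested score unreachable for this miRNA")
    k <- ks[1]
    site[site_idx(k)] <- if (mi[k] == "G") "T" else "G"
    used <- c(used, k); remaining <- remaining - 0.5
  }
  if (abs(remaining) > 1e-9) stop("requested score unreachable for this miRNA")
  paste(site, collapse = "")
}

#' Generate the toy transcriptome with planted target sites
#'
#' Plants one cleavage-validated site per target: the reverse complement of
#' the chosen miRNA, mutated to the requested complementarity score, at a
#' position leaving room for a 20-nt degradome tag downstream of the
#' cleavage position. Site coordinates are recorded 1-based inclusive on
#' the sense strand.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth table started by [make_genome()].
#' @return list with `transcripts` (named character vector),
#'   `gene_lengths`, and the updated `truth` (planted_targets filled,
#'   planted_fc extended over target genes).
#' @export
make_transcriptome <- function(cfg, truth) {
  set.seed(substream_seed(cfg$seed, "transcriptome"))
  stopifnot(cfg$n_planted_targets <= cfg$n_transcripts)
  lens <- sample(seq(cfg$transcript_length_range[1],
                     cfg$transcript_length_range[2]), cfg$n_transcripts,
                 replace = TRUE)
  ids <- sprintf("gene%03d", seq_len(cfg$n_transcripts))
  transcripts <- setNames(vapply(lens, random_dna, character(1)), ids)

  targets <- NULL
  if (cfg$n_planted_targets > 0) {
    mir <- truth$planted_mirnas
    # spread targets over miRNAs, preferring novel ones first
    donors <- c(mir$name[mir$novel], mir$name[!mir$novel])
    donors <- rep_len(donors, cfg$n_planted_targets)
    scores <- rep_len(cfg$target_scores, cfg$n_planted_targets)
    rows <- list()
    for (i in seq_len(cfg$n_planted_targets)) {
      gene <- ids[i]
      mirna <- mir$mature[match(donors[i], mir$name)]
      m <- nchar(mirna)
      site <- make_site(mirna, scores[i])
      len <- nchar(transcripts[[gene]])
      # cleavage pos = start + m - 10; need 20-nt tag to fit: pos + 19 <= len
      smax <- len - m - 25L
      if (smax < 30L) stop("transcript too short for a planted site")
      s <- sample(30:smax, 1)
      substr(transcripts[[gene]], s, s + m - 1L) <- site
      rows[[i]] <- data.frame(mirna_name = donors[i], transcript_id = gene,
                              site_start = s, site_end = s + m - 1L,
                              expected_score = scores[i],
                              cleavage_pos = s + m - 10L,
                              stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, rows)
  }
  truth$planted_targets <- targets
  # planted fold changes for the target genes
  if (!is.null(targets)) {
    gene_fc <- setNames(rep_len(cfg$planted_log2fc, nrow(targets)),
                        targets$transcript_id)
    truth$planted_fc <- c(truth$planted_fc, gene_fc)
  }
  list(transcripts = transcripts, gene_lengths = setNames(lens, ids),
       truth = truth)
}

#' Simulate the two-sample small-RNA tag-count table
#'
#' Planted mature (and low-abundance star) tags receive expected counts
#' honouring the planted fold changes; background tags are drawn from
#' genome windows outside the precursor loci and from the rRNA/tRNA decoy
#' set, with equal expected abundance in both samples. Counts are drawn
#' under the configured noise model. Columns: `sequence`,
#' `count_control`, `count_cms`.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth table (for names and fold changes).
#' @param genome output of [make_genome()].
#' @return data.frame of collapsed tags with per-sample counts.
#' @export
simulate_srna <- function(cfg, truth, genome) {
  set.seed(substream_seed(cfg$seed, "srna"))
  mir <- truth$planted_mirnas
  fc <- truth$planted_fc[mir$name]
  bg <- cfg$background_fraction
  n_mir <- nrow(mir)
  w <- exp(runif(n_mir, log(1), log(60)))
  w <- w / sum(w)
  e_ctrl <- cfg$srna_depth * (1 - bg) * w
  e_cms <- e_ctrl * 2^fc

  seqs <- mir$mature
  mu_c <- e_ctrl; mu_m <- e_cms
  # star strands at 5% of the mature abundance (below the copy threshold
  # at typical weights, but exercising 5p/3p detection at high weights)
  prec_rows <- genome$precursors
  star <- vapply(seq_len(nrow(prec_rows)), function(i) {
    p <- prec_rows[i, ]
    cand <- hairpin_candidate(p$sequence, c(p$mature_start, p$mature_end))
    if (is.null(cand$star_span)) return(NA_character_)
    rna_to_dna(substr(p$sequence, cand$star_span[1], cand$star_span[2]))
  }, character(1))
  ok <- !is.na(star)
  seqs <- c(seqs, star[ok])
  mu_c <- c(mu_c, 0.05 * e_ctrl[ok])
  mu_m <- c(mu_m, 0.05 * e_cms[ok])

  if (bg > 0 && cfg$n_background_tags > 0) {
    n_bg <- cfg$n_background_tags
    n_dec <- round(n_bg * 0.3)
    n_gen <- n_bg - n_dec
    g <- genome$genome[[1]]
    prec_iv <- IRanges::IRanges(start = genome$precursors$start,
                                end = genome$precursors$end)
    bg_seqs <- character(0)
    while (length(bg_seqs) < n_gen) {
      len <- sample(18:30, 1)
      s <- sample.int(nchar(g) - len, 1)
      if (length(IRanges::findOverlaps(
            IRanges::IRanges(s, s + len - 1L), prec_iv))) next
      strand <- sample(c("+", "-"), 1)
      tag <- substr(g, s, s + len - 1L)
      if (strand == "-") tag <- revcomp(tag)
      bg_seqs <- c(bg_seqs, tag)
    }
    dec_seqs <- vapply(seq_len(n_dec), function(i) {
      d <- genome$decoys[[sample.int(length(genome$decoys), 1)]]
      len <- sample(18:30, 1)
      s <- sample.int(nchar(d) - len, 1)
      substr(d, s, s + len - 1L)
    }, character(1))
    bg_all <- c(bg_seqs, dec_seqs)
    keep <- !duplicated(bg_all) & !(bg_all %in% seqs)
    bg_all <- bg_all[keep]
    wbg <- stats::rexp(length(bg_all))
    wbg <- wbg / sum(wbg)
    bg_ctrl_total <- cfg$srna_depth - sum(mu_c)
    bg_cms_total <- cfg$srna_depth - sum(mu_m)
    if (bg_ctrl_total < 0 || bg_cms_total < 0) {
      stop("background_fraction too small for the planted fold changes")
    }
    seqs <- c(seqs, bg_all)
    mu_c <- c(mu_c, bg_ctrl_total * wbg)
    mu_m <- c(mu_m, bg_cms_total * wbg)
  }
  data.frame(sequence = seqs,
             count_control = draw_counts(cfg, mu_c),
             count_cms = draw_counts(cfg, mu_m),
             stringsAsFactors = FALSE)
}

#' Simulate per-sample degradome tag tables
#'
#' Each planted target emits a 20-nt tag whose 5' end sits at the
#' transcript base paired to miRNA position 10, at an abundance at least
#' five times the per-position background; background tags of 20-21 nt are
#' laid uniformly along the transcripts.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth table with planted targets.
#' @param transcripts named transcript sequences.
#' @return list of two data.frames (`control`, `cms`), columns
#'   `sequence`, `count`.
#' @export
simulate_degradome <- function(cfg, truth, transcripts) {
  set.seed(substream_seed(cfg$seed, "degradome"))
  one_sample <- function() {
    seqs <- character(0); cnts <- numeric(0)
    tg <- truth$planted_targets
    if (!is.null(tg) && nrow(tg)) {
      for (i in seq_len(nrow(tg))) {
        tr <- transcripts[[tg$transcript_id[i]]]
        p <- tg$cleavage_pos[i]
        if (p + 19L > nchar(tr)) {
          stop("planted site too close to the transcript 3' end for a 20-nt tag")
        }
        seqs <- c(seqs, substr(tr, p, p + 19L))
        cnts <- c(cnts, cfg$degradome_site_count)
      }
    }
    bg_reads <- cfg$degradome_depth * cfg$background_fraction
    if (bg_reads >= 1) {
      n_pos <- max(1L, round(bg_reads / 2))
      tr_idx <- sample.int(length(transcripts), n_pos, replace = TRUE)
      for (t in unique(tr_idx)) {
        tr <- transcripts[[t]]
        k <- sum(tr_idx == t)
        len <- nchar(tr)
        widths <- sample(20:21, k, replace = TRUE)
        starts <- sample.int(len - 21L, k, replace = TRUE)
        seqs <- c(seqs, substring(tr, starts, starts + widths - 1L))
        cnts <- c(cnts, sample(1:3, k, replace = TRUE))
      }
    }
    agg <- tapply(cnts, seqs, sum)
    data.frame(sequence = names(agg), count = as.numeric(agg),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(control = one_sample(), cms = one_sample())
}

#' Simulate the two-sample RNA-seq gene count table
#'
#' Gene expression is log-normal; planted target genes carry the planted
#' fold changes; expected read counts are proportional to expression times
#' gene length, scaled to the configured depth; counts follow the noise
#' model.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth table (planted_fc holds gene fold changes).
#' @param transcriptome output of [make_transcriptome()].
#' @return list with `counts` (data.frame feature/count_control/count_cms)
#'   and `gene_lengths`.
#' @export
simulate_rnaseq <- function(cfg, truth, transcriptome) {
  set.seed(substream_seed(cfg$seed, "rnaseq"))
  lens <- transcriptome$gene_lengths
  ids <- names(lens)
  expr <- exp(stats::rnorm(length(ids), mean = 3, sd = 1))
  fc <- truth$planted_fc[ids]
  fc[is.na(fc)] <- 0
  w_ctrl <- expr * lens
  w_cms <- expr * 2^fc * lens
  # both libraries sequenced to the same depth; the small compositional
  # shift induced by the planted genes is part of the realism
  mu_c <- cfg$rnaseq_depth * w_ctrl / sum(w_ctrl)
  mu_m <- cfg$rnaseq_depth * w_cms / sum(w_cms)
  counts <- data.frame(feature = ids,
                       count_control = draw_counts(cfg, mu_c),
                       count_cms = draw_counts(cfg, mu_m),
                       stringsAsFactors = FALSE)
  list(counts = counts, gene_lengths = lens)
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_genome()], [make_transcriptome()], [simulate_srna()],
#' [simulate_degradome()] and [simulate_rnaseq()] under one root seed and
#' returns everything with the final truth table.
#'
#' @param cfg a [simulation_config()].
#' @return object of class `cms_simulation`.
#' @export
simulate_dataset <- function(cfg) {
  gen <- make_genome(cfg)
  trs <- make_transcriptome(cfg, gen$truth)
  srna <- simulate_srna(cfg, trs$truth, gen)
  deg <- simulate_degradome(cfg, trs$truth, trs$transcripts)
  rna <- simulate_rnaseq(cfg, trs$truth, trs)
  structure(list(config = cfg, genome = gen$genome,
                 precursors = gen$precursors,
                 known_reference = gen$known_reference,
                 decoys = gen$decoys, annotation = gen$annotation,
                 transcripts = trs$transcripts,
                 gene_lengths = trs$gene_lengths,
                 srna_counts = srna, degradome = deg,
                 rnaseq = rna$counts, truth = trs$truth),
            class = "cms_simulation")
}

#' @export
print.cms_simulation <- function(x, ...) {
  cat(sprintf("synthetic CMS dataset (seed %d)\n", x$config$seed))
  cat(sprintf("  genome: %d nt, %d planted precursors (%d known, %d novel)\n",
              nchar(x$genome[[1]]), nrow(x$precursors),
              sum(!x$precursors$novel), sum(x$precursors$novel)))
  cat(sprintf("  transcripts: %d; planted targets: %d\n",
              length(x$transcripts),
              if (is.null(x$truth$planted_targets)) 0L
              else nrow(x$truth$planted_targets)))
  cat(sprintf("  sRNA tags: %d distinct; degradome tags: %d / %d distinct\n",
              nrow(x$srna_counts), nrow(x$degradome$control),
              nrow(x$degradome$cms)))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `genome.fasta`, `precursors.gff` (GFF3, 1-based inclusive),
#' `mature.fasta`, `transcripts.fasta`, `srna_counts.tsv`,
#' `degradome_control.tsv`, `degradome_cms.tsv`, `rnaseq_counts.tsv` and
#' `truth/*.tsv`. All TSVs have a one-line header and are UTF-8.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  # the miRBase-style reference holds the *known* subset only; novel
  # precursors are recorded in the GFF and the truth tables
  write_fasta(sim$known_reference$precursor,
              file.path(dir, "precursors.fasta"))
  gff <- data.frame(seqid = sim$precursors$chrom, source = "mircms",
                    type = "miRNA_primary_transcript",
                    start = sim$precursors$start, end = sim$precursors$end,
                    score = ".", strand = sim$precursors$strand, phase = ".",
                    attributes = paste0("ID=", sim$precursors$name, "-prec"))
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")),
             file.path(dir, "precursors.gff"))
  write_fasta(sim$known_reference$mature, file.path(dir, "mature.fasta"))
  write_fasta(sim$transcripts, file.path(dir, "transcripts.fasta"))
  write_tsv(sim$srna_counts, file.path(dir, "srna_counts.tsv"))
  write_tsv(sim$degradome$control, file.path(dir, "degradome_control.tsv"))
  write_tsv(sim$degradome$cms, file.path(dir, "degradome_cms.tsv"))
  write_tsv(sim$rnaseq, file.path(dir, "rnaseq_counts.tsv"))
  write_tsv(sim$truth$planted_mirnas, file.path(dir, "truth", "mirnas.tsv"))
  if (!is.null(sim$truth$planted_targets)) {
    write_tsv(sim$truth$planted_targets, file.path(dir, "truth", "targets.tsv"))
  }
  write_tsv(data.frame(feature = names(sim$truth$planted_fc),
                       log2fc = unname(sim$truth$planted_fc)),
            file.path(dir, "truth", "fold_changes.tsv"))
  invisible(dir)
}
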