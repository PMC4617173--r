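# Degradome (PARE) target validation: transcript profiles, Allen-type
# complementarity scoring, cleavage coincidence, t-plot categories and a
# shuffle p-value.

penalty_matrix <- function() {
  # miRNA base x target base (RNA alphabet): 0 = Watson-Crick,
  # 0.5 = G:U wobble, 1 = mismatch
  p <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  p["A", "U"] <- 0; p["U", "A"] <- 0; p["G", "C"] <- 0; p["C", "G"] <- 0
  p["G", "U"] <- 0.5; p["U", "G"] <- 0.5
  p
}

core_multiplier <- function(m, core = c(2L, 13L)) {
  mult <- rep(1, m)
  mult[seq(core[1], min(core[2], m))] <- 2
  mult
}

#' Score miRNA:target complementarity (plant rule)
#'
#' Scores an antiparallel alignment of a miRNA against a candidate target
#' site given on the transcript sense strand: each mismatch costs 1, each
#' G:U wobble 0.5, each gap/bulge 1, and every penalty is doubled at miRNA
#' positions 2-13 (1-based from the miRNA 5' end). Sites one base shorter
#' or longer than the miRNA are aligned with a single bulge; the minimum
#' score over all bulge placements is returned. Length differences beyond
#' one base admit no alignment (infinite score).
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param site candidate site on the transcript sense strand, 5'->3'.
#' @param core integer length-2, miRNA positions with doubled penalties.
#' @return list with `score` and `pairing` (one symbol per miRNA position:
#'   `|` Watson-Crick, `o` wobble, `.` mismatch, `-` bulged).
#' @export
score_alignment <- function(mirna, site, core = c(2L, 13L)) {
  pm <- penalty_matrix()
  mi <- strsplit(dna_to_rna(mirna), "")[[1]]
  ta <- strsplit(dna_to_rna(site), "")[[1]]
  m <- length(mi)
  ns <- length(ta)
  mult <- core_multiplier(m, core)
  rev_ta <- rev(ta)  # reversed target: index r pairs miRNA position r (gapless)
  sym <- function(pen) if (pen == 0) "|" else if (pen == 0.5) "o" else "."

  best <- list(score = Inf, pairing = strrep("-", m))
  consider <- function(score, pairing) {
    if (score < best$score) best <<- list(score = score, pairing = pairing)
  }

  if (ns == m) {
    pen <- pm[cbind(mi, rev_ta)] * mult
    consider(sum(pen), paste(vapply(pen / mult, sym, ""), collapse = ""))
  } else if (ns == m + 1L) {
    # one bulged target base at reversed index g, between miRNA g-1 and g
    for (g in seq_len(ns)) {
      tt <- rev_ta[-g]
      pen <- pm[cbind(mi, tt)] * mult
      gpos <- min(max(g, 1L), m)
      gap_pen <- 1 * (if (gpos >= core[1] && gpos <= core[2]) 2 else 1)
      consider(sum(pen) + gap_pen,
               paste(vapply(pen / mult, sym, ""), collapse = ""))
    }
  } else if (ns == m - 1L) {
    # one bulged miRNA base at position g
    for (g in seq_len(m)) {
      mm <- mi[-g]; mu <- mult[-g]
      pen <- pm[cbind(mm, rev_ta)] * mu
      gap_pen <- 1 * (if (g >= core[1] && g <= core[2]) 2 else 1)
      symb <- vapply(pen / mu, sym, "")
      pairing <- append(symb, "-", after = g - 1L)
      consider(sum(pen) + gap_pen, paste(pairing, collapse = ""))
    }
  }
  best
}

# vectorized gapless scorer: one miRNA vs many equal-length sites
score_sites_gapless <- function(mirna, sites, core = c(2L, 13L)) {
  if (!length(sites)) return(numeric(0))
  pm <- penalty_matrix()
  mi <- strsplit(dna_to_rna(mirna), "")[[1]]
  m <- length(mi)
  mult <- core_multiplier(m, core)
  mat <- do.call(rbind, strsplit(dna_to_rna(sites), ""))  # n x m
  stopifnot(ncol(mat) == m)
  total <- numeric(length(sites))
  for (k in seq_len(m)) {
    total <- total + pm[mi[k], ][mat[, m + 1L - k]] * mult[k]
  }
  unname(total)
}

# same scoring, but indexing a pre-split transcript character vector at
# given site start positions (no substring extraction; used by the scan)
score_positions_gapless <- function(mirna, tr_chars, starts,
                                    core = c(2L, 13L)) {
  if (!length(starts)) return(numeric(0))
  pm <- penalty_matrix()
  mi <- strsplit(dna_to_rna(mirna), "")[[1]]
  m <- length(mi)
  mult <- core_multiplier(m, core)
  total <- numeric(length(starts))
  for (k in seq_len(m)) {
    total <- total + pm[mi[k], ][tr_chars[starts + (m - k)]] * mult[k]
  }
  unname(total)
}

#' Build per-transcript degradome 5'-end profiles
#'
#' Filters degradome tags to 20-21 nt, matches each tag exactly against the
#' transcript sense strands, and accumulates the tag abundance at the
#' 1-based position of its 5' end. Antisense matches are discarded. Tags
#' matching more than one transcript contribute to every match and are
#' flagged multi-mapped.
#'
#' @param tags data.frame with columns `sequence` and `count`.
#' @param transcripts named character vector of transcript sequences
#'   (sense strand, DNA alphabet).
#' @return named list of numeric count vectors (one per transcript, length
#'   = transcript length), with attribute `multi_mapped` (character vector
#'   of multi-mapping tag sequences).
#' @export
build_profiles <- function(tags, transcripts) {
  stopifnot(all(c("sequence", "count") %in% names(tags)))
  keep <- nchar(tags$sequence) %in% c(20L, 21L)
  tags <- tags[keep, , drop = FALSE]
  subject <- Biostrings::DNAStringSet(transcripts)
  profiles <- lapply(transcripts, function(tr) numeric(nchar(tr)))
  names(profiles) <- names(transcripts)
  multi <- character(0)
  if (nrow(tags)) {
    for (w in unique(nchar(tags$sequence))) {
      idx <- which(nchar(tags$sequence) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(tags$sequence[idx]))
      n_tr_hits <- integer(length(idx))
      for (t in seq_along(transcripts)) {
        m <- Biostrings::matchPDict(pd, subject[[t]])
        starts_per_tag <- Biostrings::startIndex(m)
        for (ti in which(lengths(starts_per_tag) > 0L)) {
          n_tr_hits[ti] <- n_tr_hits[ti] + 1L
          st <- starts_per_tag[[ti]]
          profiles[[t]][st] <- profiles[[t]][st] + tags$count[idx[ti]]
        }
      }
      multi <- c(multi, tags$sequence[idx[n_tr_hits > 1L]])
    }
  }
  attr(profiles, "multi_mapped") <- unique(multi)
  profiles
}

#' Find degradome-supported miRNA target sites
#'
#' For every degradome 5'-end position with signal, tests whether a miRNA
#' aligns antiparallel over the window placing that position opposite
#' miRNA position 10 (canonical) or 11, with complementarity score not
#' exceeding `max_score` (4 by default, Allen-type scoring). Hits are
#' deduplicated by (miRNA, transcript, cleavage position), keeping the
#' better score and the canonical position-10 register on ties.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param profiles output of [build_profiles()].
#' @param max_score maximum retained alignment score.
#' @param cleavage_index miRNA positions accepted as the cleavage register.
#' @return data.frame of hits: `mirna_name`, `transcript_id`, `align_score`,
#'   `cleavage_pos`, `mirna_cleavage_index`, `tag_count_at_site`,
#'   `site_start`, `site_end`.
#' @export
find_targets <- function(mirnas, transcripts, profiles, max_score = 4,
                         cleavage_index = c(10L, 11L)) {
  rows <- list()
  for (tr_id in names(transcripts)) {
    prof <- profiles[[tr_id]]
    if (is.null(prof)) next
    pos <- which(prof > 0)
    if (!length(pos)) next
    tr_seq <- transcripts[[tr_id]]
    tr_chars <- strsplit(dna_to_rna(tr_seq), "")[[1]]
    len <- nchar(tr_seq)
    for (mn in names(mirnas)) {
      m <- nchar(mirnas[[mn]])
      for (k in cleavage_index) {
        s <- pos - (m - k)
        e <- pos + k - 1L
        ok <- s >= 1L & e <= len
        if (!any(ok)) next
        sc <- score_positions_gapless(mirnas[[mn]], tr_chars, s[ok])
        hit <- sc <= max_score
        if (!any(hit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_name = mn, transcript_id = tr_id,
          align_score = sc[hit], cleavage_pos = pos[ok][hit],
          mirna_cleavage_index = k,
          tag_count_at_site = prof[pos[ok][hit]],
          site_start = s[ok][hit], site_end = e[ok][hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_name = character(0), transcript_id = character(0),
                      align_score = numeric(0), cleavage_pos = integer(0),
                      mirna_cleavage_index = integer(0),
                      tag_count_at_site = numeric(0),
                      site_start = integer(0), site_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  # dedupe by (miRNA, transcript, cleavage position): best score first,
  # canonical register 10 preferred on ties
  ord <- order(hits$mirna_name, hits$transcript_id, hits$cleavage_pos,
               hits$align_score, hits$mirna_cleavage_index)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$mirna_name, hits$transcript_id, hits$cleavage_pos)
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify the degradome signal at a hit (t-plot category)
#'
#' Category 0: the site count is the unique maximum of the transcript
#' profile and exceeds 1 read; 1: it equals a maximum shared with other
#' positions (> 1 read); 2: above the median of nonzero positions but
#' below the maximum; 3: at or below the median, more than 1 read;
#' 4: exactly 1 read.
#'
#' @param site_count degradome count at the cleavage position.
#' @param profile numeric profile vector of the transcript.
#' @return integer category in 0..4.
#' @export
categorize <- function(site_count, profile) {
  stopifnot(site_count > 0)
  mx <- max(profile)
  med <- median(profile[profile > 0])
  if (site_count == 1) return(4L)
  if (site_count == mx) {
    if (sum(profile == mx) == 1L) return(0L) else return(1L)
  }
  if (site_count > med) return(2L)
  3L
}

#' Shuffle p-value for a degradome target hit
#'
#' Permutation null: the miRNA sequence is shuffled `n_shuffles` times
#' (seeded Fisher-Yates) and re-scored against the same cleavage-coincident
#' site; the p-value is `(1 + #better-or-equal) / (1 + n_shuffles)`
#' (add-one smoothing, so p is never 0). Hits with p >= 0.05 are dropped
#' from the retained set by [degradome_targets()].
#'
#' @param mirna miRNA sequence.
#' @param site site sequence the hit was scored on.
#' @param observed_score the hit's alignment score.
#' @param n_shuffles number of permutations (>= 20).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
target_pvalue <- function(mirna, site, observed_score, n_shuffles = 100,
                          seed = 1) {
  stopifnot(n_shuffles >= 20)
  chars <- strsplit(dna_to_rna(mirna), "")[[1]]
  hits <- 0L
  set.seed(substream_seed(seed, "target_shuffle"))
  for (i in seq_len(n_shuffles)) {
    shuf <- paste(sample(chars), collapse = "")
    if (score_alignment(shuf, site)$score <= observed_score) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_shuffles)
}

#' Run the full degradome target-validation stage
#'
#' Builds profiles, finds score/coincidence-qualified sites, categorizes
#' each hit and computes the shuffle p-value; only hits with p below
#' `p_max` (0.05) are retained. Every retained hit therefore satisfies
#' score <= 4, positional coincidence at miRNA position 10/11, and
#' p < 0.05.
#'
#' @param mirnas named character vector of mature miRNAs.
#' @param transcripts named character vector of transcripts.
#' @param tags degradome tag data.frame (`sequence`, `count`).
#' @param max_score,n_shuffles,seed,p_max stage parameters.
#' @return data.frame of retained hits with `category` and `p_value`
#'   columns appended; all scanned hits (pre-p-filter) in
#'   `attr(, "scanned")`.
#' @export
degradome_targets <- function(mirnas, transcripts, tags, max_score = 4,
                              n_shuffles = 100, seed = 1, p_max = 0.05) {
  profiles <- build_profiles(tags, transcripts)
  hits <- find_targets(mirnas, transcripts, profiles, max_score = max_score)
  if (!nrow(hits)) {
    hits$category <- integer(0)
    hits$p_value <- numeric(0)
    attr(hits, "scanned") <- hits
    return(hits)
  }
  hits$category <- vapply(seq_len(nrow(hits)), function(i) {
    categorize(hits$tag_count_at_site[i], profiles[[hits$transcript_id[i]]])
  }, integer(1))
  hits$p_value <- vapply(seq_len(nrow(hits)), function(i) {
    site <- substring(transcripts[[hits$transcript_id[i]]],
                      hits$site_start[i], hits$site_end[i])
    target_pvalue(mirnas[[hits$mirna_name[i]]], site, hits$align_score[i],
                  n_shuffles = n_shuffles,
                  seed = substream_seed(seed, paste0("hit", i)))
  }, numeric(1))
  scanned <- hits
  hits <- hits[hits$p_value < p_max, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "scanned") <- scanned
  hits
}

#' T-plot data for one transcript
#'
#' Per-position degradome 5'-end counts with cleavage-site markers,
#' suitable for plotting a cutting plot.
#'
#' @param profile numeric profile vector.
#' @param hits hit table (rows for this transcript).
#' @return data.frame `position`, `count`, `is_cleavage_site`.
#' @export
tplot_data <- function(profile, hits = NULL) {
  out <- data.frame(position = seq_along(profile), count = profile,
                    is_cleavage_site = FALSE)
  if (!is.null(hits) && nrow(hits)) {
    out$is_cleavage_site[hits$cleavage_pos] <- TRUE
  }
  out
}
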