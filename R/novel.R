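# Mireap-style novel miRNA discovery from forwarded tags.

#' Map tags to the genome by exact matching on both strands
#'
#' Reports every exact occurrence of each tag on either strand of the
#' genome (1-based inclusive coordinates on the forward strand). Tags
#' with more than `max_loci` occurrences are flagged repetitive and
#' dropped from the returned loci.
#'
#' @param tags tag table (`sequence` column).
#' @param genome named character vector of chromosome sequences.
#' @param max_loci repetitive-locus cutoff (20).
#' @return data.frame `sequence`, `chrom`, `start`, `end`, `strand`, with
#'   attribute `repetitive` (sequences dropped for exceeding the cutoff).
#' @export
map_tags_to_genome <- function(tags, genome, max_loci = 20L) {
  chroms <- lapply(genome, Biostrings::DNAString)
  rows <- list()
  repetitive <- character(0)
  for (tg in unique(tags$sequence)) {
    found <- list()
    for (cn in names(chroms)) {
      fwd <- Biostrings::matchPattern(tg, chroms[[cn]])
      if (length(fwd)) {
        found[[length(found) + 1L]] <- data.frame(
          sequence = tg, chrom = cn, start = Biostrings::start(fwd),
          end = Biostrings::end(fwd), strand = "+", stringsAsFactors = FALSE)
      }
      rev <- Biostrings::matchPattern(revcomp(tg), chroms[[cn]])
      if (length(rev)) {
        found[[length(found) + 1L]] <- data.frame(
          sequence = tg, chrom = cn, start = Biostrings::start(rev),
          end = Biostrings::end(rev), strand = "-", stringsAsFactors = FALSE)
      }
    }
    if (!length(found)) next
    found <- do.call(rbind, found)
    if (nrow(found) > max_loci) {
      repetitive <- c(repetitive, tg)
    } else {
      rows[[length(rows) + 1L]] <- found
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "repetitive") <- repetitive
  out
}

# Anchor prefilter: a window can only host a hairpin whose stem carries the
# tag if the reverse complement of some `anchor_len`-mer of the tag occurs in
# the window (the star arm must pair a substantial stretch of the mature).
# Saves folding the overwhelmingly non-hairpin background windows.
window_has_anchor <- function(window, tag, anchor_len = 10L) {
  w <- nchar(tag)
  if (w < anchor_len) return(TRUE)
  rc <- revcomp(tag)
  for (s in seq_len(w - anchor_len + 1L)) {
    if (regexpr(substr(rc, s, s + anchor_len - 1L), window,
                fixed = TRUE) > 0) {
      return(TRUE)
    }
  }
  FALSE
}

# Fold windows around one tag locus and return the best valid hairpin
# candidate (lowest energy), or NULL. `windows` is a list of
# c(upstream, downstream) extents relative to the tag, in the tag's
# strand orientation. Window overruns at chromosome ends are truncated.
best_hairpin_at_locus <- function(genome, locus, tag,
                                  criteria = hairpin_criteria(),
                                  windows = list(c(150L, 150L),
                                                 c(20L, 200L),
                                                 c(200L, 20L)),
                                  engine = "nn") {
  chrom_seq <- if (is.list(genome)) genome$genome[[locus$chrom]]
               else genome[[locus$chrom]]
  clen <- nchar(chrom_seq)
  best <- NULL
  # windows are consulted in order; once one yields a valid candidate the
  # remaining variants are skipped (they would excise the same stem-loop;
  # the asymmetric variants exist for placements the symmetric window
  # truncates, e.g. near chromosome ends)
  for (wn in windows) {
    if (!is.null(best)) break
    up <- wn[1]; down <- wn[2]
    if (locus$strand == "+") {
      ws <- max(1L, locus$start - up)
      we <- min(clen, locus$end + down)
      wseq <- substr(chrom_seq, ws, we)
      tag_rel <- c(locus$start - ws + 1L, locus$end - ws + 1L)
    } else {
      ws <- max(1L, locus$start - down)
      we <- min(clen, locus$end + up)
      wseq <- revcomp(substr(chrom_seq, ws, we))
      tag_rel <- c(we - locus$end + 1L, we - locus$start + 1L)
    }
    if (nchar(wseq) < 40L) next
    if (!window_has_anchor(wseq, substr(wseq, tag_rel[1], tag_rel[2]))) next
    fr <- fold(wseq, engine = engine)
    loops <- hairpin_loops(fr$pairs)
    if (!nrow(loops)) next
    for (lp in seq_len(nrow(loops))) {
      stem <- excise_stem(fr$pairs, loops$start[lp], loops$end[lp])
      if (is.null(stem)) next
      # keep 2 flanking nt so the star's 3' overhang stays inside the
      # excised precursor
      stem <- c(max(1L, stem[1] - 2L), min(nchar(wseq), stem[2] + 2L))
      if (tag_rel[1] < stem[1] || tag_rel[2] > stem[2]) next
      prec_seq <- substr(wseq, stem[1], stem[2])
      if (nchar(prec_seq) < 40L || nchar(prec_seq) > 400L) next
      cand <- hairpin_candidate(prec_seq,
                                tag_rel - stem[1] + 1L,
                                engine = engine)
      v <- validate_hairpin(cand, criteria)
      if (!v$pass) next
      if (is.null(best) || cand$fold$energy < best$candidate$fold$energy) {
        # genomic coordinates of the excised precursor
        if (locus$strand == "+") {
          gs <- ws + stem[1] - 1L; ge <- ws + stem[2] - 1L
        } else {
          gs <- we - stem[2] + 1L; ge <- we - stem[1] + 1L
        }
        best <- list(candidate = cand,
                     locus = c(chrom = locus$chrom, start = gs, end = ge,
                               strand = locus$strand))
      }
    }
  }
  best
}

#' Call novel miRNAs from forwarded tags
#'
#' For every genomic locus of a forwarded tag, windows around the tag
#' (+/-150 nt plus the asymmetric 20/200 and 200/20 variants) are folded;
#' the mature-bearing stem-loop is excised and the lowest-energy candidate
#' passing [validate_hairpin()] is retained. A call additionally requires
#' the copy number of the mature tag to exceed `copy_min` (5): with the
#' default, at least 6 aligned copies. Identical matures found at several
#' loci merge into one record with `n_precursors` incremented; the copy
#' threshold applies to the merged mature. A 5p/3p pair is reported when a
#' tag matching the star arm is observed with nonzero count.
#'
#' @param loci output of [map_tags_to_genome()] for the forwarded tags.
#' @param genome named chromosome sequences (or a [make_genome()] result).
#' @param tags the tag count table (for copy numbers and star detection).
#' @param criteria hairpin acceptance criteria.
#' @param copy_min copy-number threshold (strictly greater than).
#' @param engine folding engine.
#' @return data.frame of novel calls: `name`, `mature_sequence`, `arm`,
#'   `energy`, `copy_number`, `count_control`, `count_cms`, `has_star`,
#'   `n_precursors`, `chrom`, `start`, `end`, `strand`, `precursor`.
#' @export
call_novel <- function(loci, genome, tags, criteria = hairpin_criteria(),
                       copy_min = 5L, engine = "nn") {
  empty <- data.frame(name = character(0), mature_sequence = character(0),
                      arm = character(0), energy = numeric(0),
                      copy_number = numeric(0), count_control = numeric(0),
                      count_cms = numeric(0), has_star = logical(0),
                      n_precursors = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(loci)) return(empty)
  counts <- setNames(tags$count_control + tags$count_cms, tags$sequence)
  by_seq <- list()
  for (tg in unique(loci$sequence)) {
    copy <- counts[tg]
    if (is.na(copy) || copy <= copy_min) next
    tl <- loci[loci$sequence == tg, , drop = FALSE]
    found <- list()
    for (li in seq_len(nrow(tl))) {
      hp <- best_hairpin_at_locus(genome, tl[li, ], tg, criteria = criteria,
                                  engine = engine)
      if (!is.null(hp)) found[[length(found) + 1L]] <- hp
    }
    if (!length(found)) next
    # best-energy candidate represents the mature; extra loci increment
    # the precursor count
    energies <- vapply(found, function(h) h$candidate$fold$energy, numeric(1))
    best <- found[[which.min(energies)]]
    star_seq <- NA_character_
    if (!is.null(best$candidate$star_span)) {
      star_seq <- rna_to_dna(substr(best$candidate$sequence,
                                    best$candidate$star_span[1],
                                    best$candidate$star_span[2]))
    }
    has_star <- !is.na(star_seq) && star_seq %in% tags$sequence &&
      counts[star_seq] > 0
    i <- match(tg, tags$sequence)
    by_seq[[tg]] <- data.frame(
      name = NA_character_, mature_sequence = tg,
      arm = best$candidate$arm, energy = best$candidate$fold$energy,
      copy_number = unname(copy),
      count_control = tags$count_control[i], count_cms = tags$count_cms[i],
      has_star = has_star, n_precursors = length(found),
      chrom = unname(best$locus["chrom"]),
      start = as.integer(best$locus["start"]),
      end = as.integer(best$locus["end"]),
      strand = unname(best$locus["strand"]),
      precursor = rna_to_dna(best$candidate$sequence),
      stringsAsFactors = FALSE)
  }
  if (!length(by_seq)) return(empty)
  out <- do.call(rbind, by_seq)
  # deterministic naming by genomic position
  out <- out[order(out$chrom, out$start, out$mature_sequence), , drop = FALSE]
  out$name <- sprintf("novel-miR-%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# does `tag` align to `mature` under the isomiR counting rule?
# Up to `max_edits` total deviations (substitutions, trims or overhangs),
# all confined to the terminal `end_window` nt of each end; the core must
# match exactly at some end-offset |shift| <= end_window.
tag_matches_mature <- function(tag, mature, max_edits = 3L, end_window = 3L) {
  Tn <- nchar(tag); L <- nchar(mature)
  tg <- strsplit(tag, "")[[1]]; mt <- strsplit(mature, "")[[1]]
  core <- seq(end_window + 1L, L - end_window)
  for (d in -end_window:end_window) {
    # tag position i aligns mature position i + d
    mpos <- seq_len(Tn) + d
    edits <- 0L
    ok <- TRUE
    # core coverage and exactness
    for (k in core) {
      i <- k - d
      if (i < 1L || i > Tn || tg[i] != mt[k]) { ok <- FALSE; break }
    }
    if (!ok) next
    # end-zone positions of the mature: mismatch or missing = 1 edit
    for (k in setdiff(seq_len(L), core)) {
      i <- k - d
      if (i < 1L || i > Tn) edits <- edits + 1L
      else if (tg[i] != mt[k]) edits <- edits + 1L
    }
    # tag bases overhanging the mature: 1 edit each (they sit at the ends)
    edits <- edits + sum(mpos < 1L | mpos > L)
    if (edits <= max_edits) return(TRUE)
  }
  FALSE
}

#' Count expression of novel miRNAs with the isomiR tolerance rule
#'
#' A tag contributes to a novel mature's expression iff it aligns with no
#' mismatches in the middle and at most three deviations (substitutions,
#' trims or extensions) confined to the terminal 3 nt of the 5' and 3'
#' ends. Counts are summed per sample.
#'
#' @param calls novel call table from [call_novel()].
#' @param tags tag count table.
#' @param max_edits,end_window rule parameters.
#' @return `calls` with `expr_control`, `expr_cms` columns appended.
#' @export
count_novel_expression <- function(calls, tags, max_edits = 3L,
                                   end_window = 3L) {
  if (!nrow(calls)) {
    calls$expr_control <- numeric(0)
    calls$expr_cms <- numeric(0)
    return(calls)
  }
  # only tags of compatible length carrying the exact core can qualify
  lens <- nchar(tags$sequence)
  for (ci in seq_len(nrow(calls))) {
    m <- calls$mature_sequence[ci]
    L <- nchar(m)
    core <- substr(m, end_window + 1L, L - end_window)
    idx <- which(abs(lens - L) <= 2L * end_window &
                 grepl(core, tags$sequence, fixed = TRUE))
    hit <- idx[vapply(idx, function(i) {
      tag_matches_mature(tags$sequence[i], m, max_edits, end_window)
    }, logical(1))]
    calls$expr_control[ci] <- sum(tags$count_control[hit])
    calls$expr_cms[ci] <- sum(tags$count_cms[hit])
  }
  calls
}
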