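# Small-RNA catalogue: read cleaning, tag collapsing, known-miRNA
# identification, family expansion and hierarchical annotation.

#' Clean raw small-RNA reads
#'
#' Applies the standard tag-library filters in order: low-quality reads
#' (reads containing N, or mean Phred below `min_qual` when qualities are
#' supplied), reads without the 3' adapter, empty inserts after trimming,
#' 5'-adapter contaminants, inserts shorter than 18 nt, polyA inserts
#' (>= 80% adenine), and inserts longer than 30 nt (the 18-30 nt window
#' applied symmetrically). Adapter detection uses the first `seed_len`
#' bases of each adapter. Without adapter sequences, cleaning is
#' restricted to the length and polyA filters.
#'
#' @param reads character vector of raw read sequences (NA entries are
#'   treated as malformed records and skipped with a count).
#' @param qualities optional numeric list/vector of mean Phred scores per
#'   read.
#' @param adapter3,adapter5 adapter sequences, or NULL.
#' @param min_qual mean-quality floor.
#' @param polyA_min adenine fraction defining a polyA insert.
#' @param seed_len adapter seed length.
#' @return list with `tags` (clean insert sequences, repeats retained) and
#'   `report` (one-row data.frame balancing `n_raw` against the removals
#'   and `n_clean`; skipped malformed records in `n_malformed`).
#' @export
clean_reads <- function(reads, qualities = NULL, adapter3 = NULL,
                        adapter5 = NULL, min_qual = 20, polyA_min = 0.8,
                        seed_len = 8L) {
  report <- data.frame(n_raw = 0L, n_low_quality = 0L, n_3adapter_null = 0L,
                       n_insert_null = 0L, n_5adapter_contaminant = 0L,
                       n_shorter_than_18 = 0L, n_polyA = 0L,
                       n_longer_than_30 = 0L, n_clean = 0L, n_malformed = 0L)
  if (!length(reads)) return(list(tags = character(0), report = report))
  bad <- is.na(reads) | !nzchar(reads)
  report$n_malformed <- sum(bad)
  if (!is.null(qualities)) qualities <- qualities[!bad]
  reads <- toupper(reads[!bad])
  report$n_raw <- length(reads) + report$n_malformed

  lowq <- grepl("N", reads, fixed = TRUE)
  if (!is.null(qualities)) lowq <- lowq | qualities < min_qual
  report$n_low_quality <- sum(lowq)
  reads <- reads[!lowq]

  if (!is.null(adapter3)) {
    seed <- substr(toupper(adapter3), 1L, seed_len)
    pos <- regexpr(seed, reads, fixed = TRUE)
    report$n_3adapter_null <- sum(pos < 0L)
    inserts <- substr(reads[pos > 0L], 1L, pos[pos > 0L] - 1L)
  } else {
    inserts <- reads
  }

  null_ins <- !nzchar(inserts)
  report$n_insert_null <- sum(null_ins)
  inserts <- inserts[!null_ins]

  if (!is.null(adapter5)) {
    seed5 <- substr(toupper(adapter5), 1L, seed_len)
    contam <- substr(inserts, 1L, seed_len) == seed5
    report$n_5adapter_contaminant <- sum(contam)
    inserts <- inserts[!contam]
  }

  short <- nchar(inserts) < 18L
  report$n_shorter_than_18 <- sum(short)
  inserts <- inserts[!short]

  a_frac <- vapply(strsplit(inserts, ""), function(x) mean(x == "A"),
                   numeric(1))
  polya <- a_frac >= polyA_min
  report$n_polyA <- sum(polya)
  inserts <- inserts[!polya]

  long <- nchar(inserts) > 30L
  report$n_longer_than_30 <- sum(long)
  inserts <- inserts[!long]

  report$n_clean <- length(inserts)
  list(tags = inserts, report = report)
}

#' Collapse clean tag streams into a unique-tag count table
#'
#' One row per distinct sequence with per-sample counts, plus sharing
#' statistics over both total tag counts and unique sequences
#' (sample-specific vs shared).
#'
#' @param control,cms character vectors of clean tags (repeats = reads).
#' @return data.frame `sequence`, `count_control`, `count_cms`, with
#'   attribute `sharing` (list of totals, specific and shared counts and
#'   their percentages).
#' @export
collapse_tags <- function(control, cms = character(0)) {
  tc <- table(control)
  tm <- table(cms)
  seqs <- union(names(tc), names(tm))
  out <- data.frame(sequence = seqs,
                    count_control = as.integer(tc[seqs]),
                    count_cms = as.integer(tm[seqs]),
                    stringsAsFactors = FALSE)
  out$count_control[is.na(out$count_control)] <- 0L
  out$count_cms[is.na(out$count_cms)] <- 0L
  attr(out, "sharing") <- tag_sharing_stats(out)
  out
}

#' Tag sharing statistics of a two-sample count table
#'
#' Splits the total tag counts and the unique sequences into
#' control-specific, CMS-specific and shared fractions.
#'
#' @param counts data.frame with `count_control` and `count_cms`.
#' @return list with `total` and `unique` components, each holding counts
#'   and percentages.
#' @export
tag_sharing_stats <- function(counts) {
  shared <- counts$count_control > 0 & counts$count_cms > 0
  ctrl_only <- counts$count_control > 0 & counts$count_cms == 0
  cms_only <- counts$count_control == 0 & counts$count_cms > 0
  tot <- sum(counts$count_control) + sum(counts$count_cms)
  tot_shared <- sum(counts$count_control[shared]) + sum(counts$count_cms[shared])
  tot_ctrl <- sum(counts$count_control[ctrl_only])
  tot_cms <- sum(counts$count_cms[cms_only])
  pct <- function(x, n) if (n > 0) 100 * x / n else NA_real_
  list(total = list(tags = tot, shared = tot_shared,
                    control_specific = tot_ctrl, cms_specific = tot_cms,
                    shared_pct = pct(tot_shared, tot),
                    control_specific_pct = pct(tot_ctrl, tot),
                    cms_specific_pct = pct(tot_cms, tot)),
       unique = list(tags = nrow(counts), shared = sum(shared),
                     control_specific = sum(ctrl_only),
                     cms_specific = sum(cms_only),
                     shared_pct = pct(sum(shared), nrow(counts))))
}

#' Identify known miRNAs by the two-step miRBase matching rule
#'
#' A tag is a known miRNA iff (a) it matches a reference precursor exactly
#' as a substring (no mismatches) and (b) its precursor placement overlaps
#' a reference mature miRNA by at least `min_overlap` nucleotides (16 by
#' default, allowing end offsets). The expression of a mature is the sum
#' of the counts of all tags satisfying both rules; matures sharing one
#' sequence across several precursors collapse into a single record.
#'
#' @param tags data.frame `sequence`, `count_control`, `count_cms`.
#' @param precursors named character vector of reference precursors.
#' @param matures named character vector of reference mature miRNAs.
#' @param min_overlap minimum overlap with the mature (nt).
#' @return data.frame of miRNA records (`name`, `mature_sequence`, `arm`,
#'   `precursor_ids`, `family`, `source`, `count_control`, `count_cms`)
#'   with attribute `matched` (logical per input tag).
#' @export
match_known <- function(tags, precursors, matures, min_overlap = 16L) {
  if (!length(precursors) || !length(matures)) {
    stop("reference precursors and matures must be non-empty")
  }
  if (anyDuplicated(names(precursors))) stop("duplicate precursor ids")
  matched <- rep(FALSE, nrow(tags))
  # locate each mature on each precursor (exact substring)
  mature_loci <- list()
  for (mn in names(matures)) {
    for (pn in names(precursors)) {
      at <- regexpr(matures[[mn]], precursors[[pn]], fixed = TRUE)
      if (at > 0) {
        mature_loci[[length(mature_loci) + 1L]] <- list(
          mature = mn, precursor = pn, start = as.integer(at),
          end = as.integer(at) + nchar(matures[[mn]]) - 1L)
      }
    }
  }
  counts_c <- setNames(numeric(length(matures)), names(matures))
  counts_m <- counts_c
  prec_of <- setNames(vector("list", length(matures)), names(matures))
  seen <- new.env(parent = emptyenv())  # (tag, mature) pairs already counted
  for (i in seq_len(nrow(tags))) {
    tg <- tags$sequence[i]
    w <- nchar(tg)
    for (loc in mature_loci) {
      at <- regexpr(tg, precursors[[loc$precursor]], fixed = TRUE)
      if (at < 0) next
      ov <- min(at + w - 1L, loc$end) - max(as.integer(at), loc$start) + 1L
      if (ov >= min_overlap) {
        matched[i] <- TRUE
        mn <- loc$mature
        if (!loc$precursor %in% prec_of[[mn]]) {
          prec_of[[mn]] <- c(prec_of[[mn]], loc$precursor)
        }
        # a tag matching one mature via several precursors counts once
        key <- paste(i, mn)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          counts_c[mn] <- counts_c[mn] + tags$count_control[i]
          counts_m[mn] <- counts_m[mn] + tags$count_cms[i]
        }
      }
    }
  }
  expressed <- names(matures)[counts_c + counts_m > 0]
  # collapse matures with identical sequence: keep one record each
  seqs <- matures[expressed]
  keep <- expressed[!duplicated(seqs)]
  if (!length(keep)) {
    rec <- data.frame(name = character(0), mature_sequence = character(0),
                      arm = character(0), precursor_ids = character(0),
                      family = character(0), source = character(0),
                      count_control = numeric(0), count_cms = numeric(0),
                      stringsAsFactors = FALSE)
    attr(rec, "matched") <- matched
    return(rec)
  }
  rec <- data.frame(
    name = keep,
    mature_sequence = unname(matures[keep]),
    arm = ifelse(grepl("-5p$", keep), "5p",
                 ifelse(grepl("-3p$", keep), "3p", "unknown")),
    precursor_ids = vapply(keep, function(m) paste(prec_of[[m]], collapse = ","), ""),
    family = sub("-(5p|3p)$", "", keep),
    source = "brapa_known",
    count_control = unname(counts_c[keep]),
    count_cms = unname(counts_m[keep]),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  attr(rec, "matched") <- matched
  rec
}

# edit distance with free end offsets: the sequences may be shifted
# against each other by up to `max_offset` nt for free; within the
# overlapping region (>= min_overlap nt) substitutions and internal gap
# columns each cost 1 (Levenshtein). Returns the minimal edit count.
semi_global_edits <- function(a, b, max_offset = 3L, min_overlap = 16L) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  lev <- function(x, y) {
    nx <- length(x); ny <- length(y)
    prev <- 0:ny
    for (i in seq_len(nx)) {
      cur <- c(i, integer(ny))
      for (j in seq_len(ny)) {
        cur[j + 1L] <- min(prev[j] + (x[i] != y[j]),
                           prev[j + 1L] + 1L, cur[j] + 1L)
      }
      prev <- cur
    }
    prev[ny + 1L]
  }
  best <- Inf
  for (d in -max_offset:max_offset) {
    # b shifted by d relative to a; overlap on a: [max(1, 1+d), min(na, nb+d)]
    a1 <- max(1L, 1L + d); a2 <- min(length(A), length(B) + d)
    if (a2 - a1 + 1L < min_overlap) next
    best <- min(best, lev(A[a1:a2], B[(a1 - d):(a2 - d)]))
  }
  best
}

#' Expand miRNA families from foreign-species matures
#'
#' Tags left unmatched by [match_known()] are aligned to the mature
#' miRNAs of other plant species allowing at most two edits
#' (substitutions or internal gap columns; end offsets free). Per family,
#' the highest-expressed matching tag forms the temporary database entry;
#' its genomic loci are folded in +/-150 nt windows (both orientations)
#' and kept only when the hairpin passes [validate_hairpin()] — failures
#' are pseudo-miRNAs and are discarded. Survivors become new family
#' members.
#'
#' @param tags unmatched tag table (`sequence`, `count_control`,
#'   `count_cms`).
#' @param plant_matures named character vector of foreign matures; names
#'   are family identifiers.
#' @param genome named character vector of chromosome sequences (NULL
#'   skips the stage with a warning).
#' @param max_edits edit budget (2).
#' @param criteria hairpin acceptance criteria.
#' @return data.frame of new family-member records (source =
#'   `family_expansion`), possibly empty.
#' @export
expand_families <- function(tags, plant_matures, genome, max_edits = 2L,
                            criteria = hairpin_criteria()) {
  empty <- data.frame(name = character(0), mature_sequence = character(0),
                      arm = character(0), family = character(0),
                      source = character(0), count_control = numeric(0),
                      count_cms = numeric(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), energy = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(genome)) {
    warning("no genome supplied; family expansion skipped")
    return(empty)
  }
  if (!nrow(tags) || !length(plant_matures)) return(empty)
  rows <- list()
  for (fam in unique(names(plant_matures))) {
    fam_seqs <- plant_matures[names(plant_matures) == fam]
    hit <- vapply(tags$sequence, function(tg) {
      any(vapply(fam_seqs, function(ref) {
        semi_global_edits(tg, ref) <= max_edits
      }, logical(1)))
    }, logical(1))
    if (!any(hit)) next
    cand <- tags[hit, , drop = FALSE]
    best <- cand[which.max(cand$count_control + cand$count_cms), , drop = FALSE]
    loci <- map_tags_to_genome(best, genome)
    if (!nrow(loci)) next
    found <- NULL
    for (li in seq_len(nrow(loci))) {
      hp <- best_hairpin_at_locus(genome, loci[li, ], best$sequence,
                                  criteria = criteria,
                                  windows = list(c(150L, 150L)))
      if (!is.null(hp)) { found <- hp; break }
    }
    if (is.null(found)) next  # pseudo-miRNA: no valid hairpin at any locus
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(fam, "-like"), mature_sequence = best$sequence,
      arm = found$candidate$arm, family = fam, source = "family_expansion",
      count_control = best$count_control, count_cms = best$count_cms,
      chrom = found$locus["chrom"], start = as.integer(found$locus["start"]),
      end = as.integer(found$locus["end"]), strand = found$locus["strand"],
      energy = found$candidate$fold$energy, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate tags hierarchically into small-RNA categories
#'
#' Each tag receives exactly one category by priority:
#' known_miRNA > rRNA > scRNA > snRNA > snoRNA > tRNA > repeat >
#' exon (sense/antisense) > intron (sense/antisense) > unannotated.
#' rRNA/scRNA/snRNA/snoRNA/tRNA membership is substring matching against
#' the decoy sequence set (decoy names must start with the category);
#' repeat/exon/intron come from interval overlap of the tag's genomic
#' loci (1-based inclusive, stranded). Tags in categories exon_antisense,
#' intron_sense, intron_antisense and unannotated are forwarded to novel
#' miRNA prediction.
#'
#' @param tags tag table (`sequence`, counts).
#' @param loci genomic loci from [map_tags_to_genome()].
#' @param annotation interval data.frame `chrom`, `start`, `end`,
#'   `strand`, `type` (types `repeat`, `exon`, `intron`).
#' @param decoys named character vector of structural-RNA decoy sequences.
#' @param known_mask logical per tag: already identified as known miRNA.
#' @return the tag table with `annotation` and `forwarded` columns.
#' @export
annotate_hierarchy <- function(tags, loci, annotation = NULL, decoys = NULL,
                               known_mask = NULL) {
  n <- nrow(tags)
  if (is.null(known_mask)) known_mask <- rep(FALSE, n)
  cat_levels <- c("known_miRNA", "rRNA", "scRNA", "snRNA", "snoRNA", "tRNA",
                  "repeat", "exon_sense", "exon_antisense", "intron_sense",
                  "intron_antisense", "unannotated")
  prio <- setNames(seq_along(cat_levels), cat_levels)
  best <- rep(prio["unannotated"], n)
  best[known_mask] <- prio["known_miRNA"]

  if (!is.null(decoys) && length(decoys)) {
    dec_cat <- sub("_.*$", "", names(decoys))
    for (i in which(best > prio["known_miRNA"])) {
      for (d in seq_along(decoys)) {
        if (!dec_cat[d] %in% cat_levels) next
        if (regexpr(tags$sequence[i], decoys[[d]], fixed = TRUE) > 0) {
          best[i] <- min(best[i], prio[dec_cat[d]])
        }
      }
    }
  }

  if (!is.null(annotation) && nrow(annotation) && nrow(loci)) {
    iv <- IRanges::IRanges(start = annotation$start, end = annotation$end)
    tag_index <- setNames(seq_len(n), tags$sequence)
    for (li in seq_len(nrow(loci))) {
      i <- tag_index[loci$sequence[li]]
      if (is.na(i) || best[i] <= prio["tRNA"]) next
      same_chrom <- annotation$chrom == loci$chrom[li]
      if (!any(same_chrom)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(loci$start[li], loci$end[li]), iv[same_chrom])
      for (a in which(same_chrom)[S4Vectors::subjectHits(hits)]) {
        type <- annotation$type[a]
        if (type == "repeat") {
          best[i] <- min(best[i], prio["repeat"])
        } else if (type %in% c("exon", "intron")) {
          rel <- if (annotation$strand[a] == loci$strand[li]) "sense" else "antisense"
          best[i] <- min(best[i], prio[paste(type, rel, sep = "_")])
        }
      }
    }
  }

  tags$annotation <- cat_levels[best]
  tags$forwarded <- tags$annotation %in%
    c("exon_antisense", "intron_sense", "intron_antisense", "unannotated")
  tags
}
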