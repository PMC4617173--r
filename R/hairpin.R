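#' Construct a hairpin precursor candidate
#'
#' Bundles a (putative) precursor sequence, its fold, and the placement of
#' the mature miRNA on the hairpin. When `star_span` is not supplied it is
#' inferred from the pairing table using the Dicer duplex geometry: the
#' miRNA* spans the bases pairing the mature interior, offset so that both
#' strands of the excised duplex carry 2-nt 3' overhangs
#' (`star = [partner(mature_end - 2), partner(mature_start) + 2]`).
#'
#' @param sequence precursor sequence (DNA or RNA alphabet).
#' @param mature_span integer length-2, 1-based inclusive span of the mature
#'   miRNA within `sequence`.
#' @param locus optional list/vector `(chrom, start, end, strand)`,
#'   1-based inclusive.
#' @param star_span optional explicit miRNA* span.
#' @param fold_result optional precomputed [fold()] result for `sequence`.
#' @param engine folding engine, see [fold()].
#' @return An object of class `hairpin_candidate`.
#' @export
hairpin_candidate <- function(sequence, mature_span, locus = NULL,
                              star_span = NULL, fold_result = NULL,
                              engine = "nn") {
  stopifnot(length(mature_span) == 2L, mature_span[1] <= mature_span[2])
  if (mature_span[1] < 1L || mature_span[2] > nchar(sequence)) {
    stop("mature_span outside the precursor sequence")
  }
  if (is.null(fold_result)) fold_result <- fold(sequence, engine = engine)
  pairs <- fold_result$pairs
  mb <- mature_span[1]; me <- mature_span[2]
  if (is.null(star_span)) {
    a <- pairs[me - 2L]; b <- pairs[mb]
    if (!is.na(a) && !is.na(b)) star_span <- sort(c(a, b + 2L))
  }
  loops <- hairpin_loops(pairs)
  arm <- "unknown"
  if (nrow(loops) == 1L) {
    if (me < loops$start[1]) arm <- "5p" else if (mb > loops$end[1]) arm <- "3p"
  }
  structure(list(sequence = dna_to_rna(sequence), mature_span = c(mb, me),
                 star_span = star_span, locus = locus, fold = fold_result,
                 arm = arm),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("hairpin candidate (%d nt, %.2f kcal/mol, arm %s)\n",
              nchar(x$sequence), x$fold$energy, x$arm))
  cat(x$sequence, "\n", x$fold$structure, "\n", sep = "")
  cat(sprintf("mature: %d-%d", x$mature_span[1], x$mature_span[2]))
  if (!is.null(x$star_span)) {
    cat(sprintf("  star: %d-%d", x$star_span[1], x$star_span[2]))
  }
  cat("\n")
  invisible(x)
}

# terminal (hairpin) loops of a pairing table: innermost pairs (i, j)
# with no paired base strictly between them. Loop interval is (i+1, j-1).
hairpin_loops <- function(pairs) {
  n <- length(pairs)
  out <- data.frame(start = integer(0), end = integer(0))
  for (i in seq_len(n)) {
    j <- pairs[i]
    if (is.na(j) || j <= i) next
    inner <- if (j - i > 1) pairs[(i + 1):(j - 1)] else integer(0)
    if (!any(!is.na(inner))) {
      out <- rbind(out, data.frame(start = i + 1L, end = j - 1L))
    }
  }
  out
}

#' Default hairpin acceptance criteria
#'
#' Thresholds used by [validate_hairpin()]: energy ceiling -18 kcal/mol,
#' maximum asymmetric bulge 4 nt and maximum total internal loop 6 nt
#' within the mature:star duplex, and whether a miRNA* duplex is required
#' to show 2-nt 3' overhangs when present.
#'
#' @param max_energy energy ceiling (kcal/mol); candidates must fold at or
#'   below it.
#' @param max_bulge largest tolerated one-sided bulge inside the duplex (nt).
#' @param max_internal largest tolerated total internal loop inside the
#'   duplex (nt).
#' @return A list of criteria.
#' @export
hairpin_criteria <- function(max_energy = -18, max_bulge = 4,
                             max_internal = 6) {
  list(max_energy = max_energy, max_bulge = max_bulge,
       max_internal = max_internal)
}

#' Test a hairpin candidate against miRNA precursor criteria
#'
#' A candidate passes only if all of the following hold: the folded stem
#' carries a single terminal loop; the mature miRNA lies entirely on one arm
#' (it may not straddle the loop); when a miRNA* is present the mature:star
#' duplex shows 2-nt 3' overhangs at both ends; the duplex contains no large
#' internal loop or bulge; and the fold energy is at or below the ceiling
#' (-18 kcal/mol by default). Every violated criterion is reported as a
#' reason code, so a rejection always carries at least one code.
#'
#' @param candidate a [hairpin_candidate()].
#' @param criteria a [hairpin_criteria()] list.
#' @return list with `pass` (logical) and `reasons` (character vector drawn
#'   from `"loop"`, `"arm"`, `"overhang"`, `"bulge"`, `"energy"`).
#' @export
validate_hairpin <- function(candidate, criteria = hairpin_criteria()) {
  stopifnot(inherits(candidate, "hairpin_candidate"))
  pairs <- candidate$fold$pairs
  n <- length(pairs)
  mb <- candidate$mature_span[1]; me <- candidate$mature_span[2]
  if (mb < 1L || me > n) stop("mature_span outside the precursor sequence")
  reasons <- character(0)

  loops <- hairpin_loops(pairs)
  if (nrow(loops) != 1L) {
    reasons <- c(reasons, "loop")
  }
  on_one_arm <- FALSE
  if (nrow(loops) >= 1L) {
    # the mature-bearing stem must have a single terminal loop and the
    # mature must sit entirely 5' or 3' of it
    l1 <- loops$start[1]; l2 <- loops$end[1]
    on_one_arm <- (me < l1) || (mb > l2)
  }
  if (!on_one_arm) reasons <- c(reasons, "arm")

  if (!is.null(candidate$star_span)) {
    a <- pairs[me - 2L]; b <- pairs[mb]
    ok <- !is.na(a) && !is.na(b) &&
      identical(sort(c(a, b + 2L)), sort(as.integer(candidate$star_span)))
    if (!ok) reasons <- c(reasons, "overhang")
    if (ok && duplex_has_large_loop(pairs, mb, me, criteria)) {
      reasons <- c(reasons, "bulge")
    }
  }

  if (candidate$fold$energy > criteria$max_energy) {
    reasons <- c(reasons, "energy")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# scan the mature-side duplex region (excluding the 2-nt 3' overhang) for
# bulges / internal loops exceeding the configured maxima
duplex_has_large_loop <- function(pairs, mb, me, criteria) {
  region <- mb:(me - 2L)
  paired <- region[!is.na(pairs[region])]
  if (length(paired) < 2L) return(TRUE)
  # leading/trailing unpaired stretches inside the duplex count as bulges
  lead <- paired[1] - mb
  trail <- (me - 2L) - paired[length(paired)]
  if (lead > criteria$max_bulge || trail > criteria$max_bulge) return(TRUE)
  for (k in seq_len(length(paired) - 1L)) {
    p <- paired[k]; q <- paired[k + 1L]
    gap_m <- q - p - 1L
    gap_s <- abs(pairs[p] - pairs[q]) - 1L
    if (gap_m == 0L && gap_s == 0L) next
    if (min(gap_m, gap_s) == 0L) {
      if (max(gap_m, gap_s) > criteria$max_bulge) return(TRUE)
    } else if (gap_m + gap_s > criteria$max_internal) {
      return(TRUE)
    }
  }
  FALSE
}

# Excise the stem-loop around one terminal loop from a folded window:
# follow enclosing pairs outward from the loop-closing pair while the
# enclosing loop contains no other branch; returns span of the outermost
# such pair, or NULL.
excise_stem <- function(pairs, loop_start, loop_end) {
  i <- loop_start - 1L; j <- loop_end + 1L
  if (i < 1L || j > length(pairs) || is.na(pairs[i]) || pairs[i] != j) {
    return(NULL)
  }
  repeat {
    # direct parent pair: nearest (a, b) with a < i, b > j, pairs[a] == b,
    # and no other paired base between a..i or j..b
    a <- i - 1L; found <- FALSE
    while (a >= 1L) {
      if (!is.na(pairs[a])) {
        if (pairs[a] > j && all(is.na(pairs[seq2(j + 1L, pairs[a] - 1L)]))) {
          i <- a; j <- pairs[a]; found <- TRUE
        }
        break
      }
      a <- a - 1L
    }
    if (!found) break
  }
  c(i, j)
}

seq2 <- function(from, to) if (from > to) integer(0) else seq(from, to)
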