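# Independent oracles used across the suite. Each reimplements the model
# definition from first principles, without reusing the package's
# computational path.

# ---- exhaustive structure enumeration + scoring (fold oracle) ----------

orc_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# enumerate every pseudoknot-free structure of chars[i..j] (>= 3 nt hairpin
# loops) as a list of pair matrices (2 columns: i, j)
orc_enum <- function(chars, i, j) {
  if (j - i < 4L) return(list(matrix(integer(0), ncol = 2)))
  out <- list()
  # i unpaired
  for (s in orc_enum(chars, i + 1L, j)) out[[length(out) + 1L]] <- s
  # i paired with k (loop >= 3 between)
  for (k in seq(i + 4L, j)) {
    if (!orc_can_pair(chars[i], chars[k])) next
    inner <- orc_enum(chars, i + 1L, k - 1L)
    outer <- orc_enum(chars, k + 1L, j)
    for (si in inner) for (so in outer) {
      out[[length(out) + 1L]] <- rbind(c(i, k), si, so)
    }
  }
  out
}

# score a pair set by loop decomposition under the published model;
# written independently of mircms::structure_energy
orc_score <- function(chars, pairs_mat) {
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  if (nrow(pairs_mat)) {
    partner[pairs_mat[, 1]] <- pairs_mat[, 2]
    partner[pairs_mat[, 2]] <- pairs_mat[, 1]
  }
  stack_e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  total <- 0
  for (r in seq_len(nrow(pairs_mat))) {
    i <- pairs_mat[r, 1]; j <- pairs_mat[r, 2]
    # contents of the loop closed by (i, j)
    k <- i + 1L; branches <- 0L; unp <- 0L
    first_branch <- NULL
    while (k < j) {
      if (!is.na(partner[k]) && partner[k] > k) {
        branches <- branches + 1L
        if (is.null(first_branch)) first_branch <- k
        k <- partner[k] + 1L
      } else {
        unp <- unp + 1L
        k <- k + 1L
      }
    }
    if (branches == 0L) {
      if (unp < 3L) return(Inf)
      total <- total + 4
    } else if (branches == 1L && unp == 0L) {
      total <- total + stack_e[[paste0(chars[i], chars[j])]]
    } else if (branches == 1L) {
      if (unp > 15L) return(Inf)
      total <- total + 3 + 0.5 * unp
    } else {
      total <- total + 3 + 0.5 * unp
    }
  }
  total
}

# minimum energy over every structure (the brute-force folding oracle)
oracle_fold_energy <- function(sequence) {
  chars <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  structs <- orc_enum(chars, 1L, length(chars))
  min(c(0, vapply(structs, function(s) orc_score(chars, s), numeric(1))))
}

# ---- brute-force target alignment oracle -------------------------------

orc_pair_penalty <- function(mb, tb) {
  key <- paste0(mb, tb)
  if (key %in% c("AU", "UA", "GC", "CG")) return(0)
  if (key %in% c("GU", "UG")) return(0.5)
  1
}

# minimal Allen-type score over the gapless and all single-bulge
# alignments of miRNA (5'->3') vs site (sense strand, 5'->3')
oracle_align_score <- function(mirna, site, core = 2:13) {
  mi <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  ta <- rev(strsplit(chartr("T", "U", toupper(site)), "")[[1]])
  m <- length(mi); n <- length(ta)
  weigh <- function(pos) if (pos %in% core) 2 else 1
  gapless <- function(mv, tv) {
    sum(vapply(seq_along(mv), function(k) {
      orc_pair_penalty(mv[k], tv[k]) * weigh(k)
    }, numeric(1)))
  }
  best <- Inf
  if (n == m) {
    best <- gapless(mi, ta)
  } else if (n == m + 1L) {
    for (g in seq_len(n)) {
      pos <- min(max(g, 1L), m)
      best <- min(best, gapless(mi, ta[-g]) + weigh(pos))
    }
  } else if (n == m - 1L) {
    for (g in seq_len(m)) {
      mv <- mi[-g]
      # positions keep their original miRNA index for core weighting
      idx <- seq_len(m)[-g]
      sc <- sum(vapply(seq_along(mv), function(k) {
        orc_pair_penalty(mv[k], ta[k]) * weigh(idx[k])
      }, numeric(1)))
      best <- min(best, sc + weigh(g))
    }
  }
  best
}

# ---- Audic-Claverie direct-summation oracle ----------------------------

# literal posterior mass p(y | x) for library sizes N1, N2
orc_ac_mass <- function(y, x, N1, N2) {
  exp(y * log(N2 / N1) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log(1 + N2 / N1))
}

oracle_ac_pvalue <- function(x, y, N1, N2, y_max = 500L) {
  masses <- orc_ac_mass(0:y_max, x, N1, N2)
  obs <- orc_ac_mass(y, x, N1, N2)
  min(1, sum(masses[masses <= obs * (1 + 1e-12)]))
}

# ---- textbook Benjamini-Hochberg step-up -------------------------------

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (r in n:1) {
    i <- o[r]
    prev <- min(prev, p[i] * n / r)
    q[i] <- prev
  }
  q
}

# ---- t-plot category predicate (direct re-evaluation) ------------------

oracle_category <- function(site_count, profile) {
  mx <- max(profile)
  med <- stats::median(profile[profile > 0])
  if (site_count == 1) return(4L)
  if (site_count == mx && sum(profile == mx) == 1) return(0L)
  if (site_count == mx) return(1L)
  if (site_count > med) return(2L)
  3L
}

# ---- misc helpers ------------------------------------------------------

random_rna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive genome substring scan (both strands), oracle for tag mapping
oracle_tag_loci <- function(tag, genome_str) {
  revcomp_str <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  hits <- data.frame(start = integer(0), strand = character(0))
  w <- nchar(tag)
  for (s in seq_len(nchar(genome_str) - w + 1L)) {
    sub <- substr(genome_str, s, s + w - 1L)
    if (sub == tag) hits <- rbind(hits, data.frame(start = s, strand = "+"))
    if (sub == revcomp_str(tag)) hits <- rbind(hits, data.frame(start = s, strand = "-"))
  }
  hits
}

# tiny default simulation for fast tests
small_sim_config <- function(seed = 1, ...) {
  args <- list(seed = seed, genome_length = 30000, n_known_mirnas = 3,
               n_novel_mirnas = 4, n_transcripts = 12,
               transcript_length_range = c(300, 600),
               n_planted_targets = 3, srna_depth = 1e5,
               degradome_depth = 4e3, rnaseq_depth = 5e5,
               n_background_tags = 80)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}
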