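# Joint miRNA/target expression clustering and the final report.

#' Pair miRNAs with validated targets and classify expression clusters
#'
#' One pair per retained degradome hit whose miRNA and target gene both
#' have a defined log2 fold change. Clusters follow the joint regulation
#' pattern (CMS vs maintainer): I miRNA down / target up, II both down,
#' III both up, IV miRNA up / target down. A zero fold change on either
#' side is assigned by the sign rule with the tie broken toward the
#' smaller cluster index and flagged. Tier thresholds apply to the
#' magnitudes of BOTH members: `1.5fold` requires |log2fc| >= log2(1.5),
#' `2fold` requires |log2fc| >= 1; tiers are nested (2fold within 1.5fold
#' within any).
#'
#' @param mirna_de miRNA DE table (`feature`, `log2fc`).
#' @param gene_de gene DE table (`feature`, `log2fc`).
#' @param hits retained degradome hit table (`mirna_name`,
#'   `transcript_id`).
#' @param annotation optional data.frame (`feature`, `description`) joined
#'   onto the target gene.
#' @return data.frame of pairs (`mirna_name`, `target_gene`,
#'   `mirna_log2fc`, `target_log2fc`, `cluster`, `tier`, `zero_flagged`,
#'   `annotation`), with attribute `proportions` (cluster proportions per
#'   tier) and attribute `skipped` (hits with unknown features).
#' @export
pair_and_classify <- function(mirna_de, gene_de, hits, annotation = NULL) {
  empty <- data.frame(mirna_name = character(0), target_gene = character(0),
                      mirna_log2fc = numeric(0), target_log2fc = numeric(0),
                      cluster = character(0), tier = character(0),
                      zero_flagged = logical(0), annotation = character(0),
                      stringsAsFactors = FALSE)
  skipped <- character(0)
  rows <- list()
  if (nrow(hits)) {
    key <- unique(hits[, c("mirna_name", "transcript_id")])
    for (i in seq_len(nrow(key))) {
      mi <- match(key$mirna_name[i], mirna_de$feature)
      gi <- match(key$transcript_id[i], gene_de$feature)
      if (is.na(mi) || is.na(gi) ||
          is.na(mirna_de$log2fc[mi]) || is.na(gene_de$log2fc[gi])) {
        skipped <- c(skipped,
                     paste(key$mirna_name[i], key$transcript_id[i], sep = ":"))
        next
      }
      mfc <- mirna_de$log2fc[mi]; gfc <- gene_de$log2fc[gi]
      cl <- classify_cluster(mfc, gfc)
      tier <- if (abs(mfc) >= 1 && abs(gfc) >= 1) "2fold"
              else if (abs(mfc) >= log2(1.5) && abs(gfc) >= log2(1.5)) "1.5fold"
              else "any"
      desc <- NA_character_
      if (!is.null(annotation)) {
        ai <- match(key$transcript_id[i], annotation$feature)
        if (!is.na(ai)) desc <- annotation$description[ai]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_name = key$mirna_name[i], target_gene = key$transcript_id[i],
        mirna_log2fc = mfc, target_log2fc = gfc,
        cluster = cl$cluster, tier = tier, zero_flagged = cl$flagged,
        annotation = desc, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "proportions") <- cluster_proportions(out)
  attr(out, "skipped") <- skipped
  if (length(skipped)) {
    message("skipped ", length(skipped), " hit(s) with unknown features")
  }
  out
}

classify_cluster <- function(mfc, gfc) {
  flagged <- mfc == 0 || gfc == 0
  # I: mir down / target up; II: both down; III: both up; IV: mir up / down.
  # zeros may take either sign; the smallest consistent cluster index wins
  msign <- if (mfc == 0) c(-1, 1) else sign(mfc)
  gsign <- if (gfc == 0) c(-1, 1) else sign(gfc)
  idx <- 5L
  for (m in msign) for (g in gsign) {
    k <- if (m < 0 && g > 0) 1L else if (m < 0 && g < 0) 2L
         else if (m > 0 && g > 0) 3L else 4L
    idx <- min(idx, k)
  }
  list(cluster = c("I", "II", "III", "IV")[idx], flagged = flagged)
}

cluster_proportions <- function(pairs) {
  tiers <- list(any = rep(TRUE, nrow(pairs)),
                `1.5fold` = pairs$tier %in% c("1.5fold", "2fold"),
                `2fold` = pairs$tier == "2fold")
  lapply(tiers, function(sel) {
    sub <- pairs$cluster[sel]
    if (!length(sub)) {
      return(setNames(rep(NA_real_, 4), c("I", "II", "III", "IV")))
    }
    tab <- table(factor(sub, levels = c("I", "II", "III", "IV")))
    as.numeric(tab) / length(sub) -> p
    setNames(p, names(tab))
  })
}

#' Assemble the final structured pipeline report
#'
#' Summary counts for every stage (known/novel miRNAs, DE calls up/down,
#' validated targets, pairs per cluster and tier), a provenance block
#' (seed, thresholds, package version), and the per-stage tables.
#' Deterministic given its inputs.
#'
#' @param pairs output of [pair_and_classify()].
#' @param mirna_de,gene_de DE tables with `call` columns.
#' @param known_mirnas,novel_calls catalogue tables (may be NULL).
#' @param hits retained degradome hits.
#' @param config list of thresholds/seeds recorded as provenance.
#' @return list of class `mircms_report` with `summary` (JSON-ready) and
#'   `tables`.
#' @export
integration_report <- function(pairs, mirna_de, gene_de,
                               known_mirnas = NULL, novel_calls = NULL,
                               hits = NULL, config = list()) {
  tally <- function(de) {
    if (is.null(de) || !nrow(de)) return(list(up = 0L, down = 0L, ns = 0L))
    as.list(table(factor(de$call, levels = c("up", "down", "ns"))))
  }
  cluster_counts <- as.list(table(factor(pairs$cluster,
                                         levels = c("I", "II", "III", "IV"))))
  tier_counts <- list(
    any = nrow(pairs),
    `1.5fold` = sum(pairs$tier %in% c("1.5fold", "2fold")),
    `2fold` = sum(pairs$tier == "2fold"))
  summary <- list(
    n_known_mirnas = if (is.null(known_mirnas)) 0L else nrow(known_mirnas),
    n_novel_mirnas = if (is.null(novel_calls)) 0L else nrow(novel_calls),
    mirna_de = tally(mirna_de),
    gene_de = tally(gene_de),
    n_target_hits = if (is.null(hits)) 0L else nrow(hits),
    n_target_genes = if (is.null(hits)) 0L else
      length(unique(hits$transcript_id)),
    n_pairs = nrow(pairs),
    pairs_per_cluster = cluster_counts,
    pairs_per_tier = tier_counts,
    cluster_proportions = attr(pairs, "proportions"),
    n_pairs_skipped = length(attr(pairs, "skipped")),
    provenance = c(list(package_version = as.character(
      utils::packageVersion("mircms"))), config))
  structure(list(summary = summary,
                 tables = list(pairs = pairs, mirna_de = mirna_de,
                               gene_de = gene_de)),
            class = "mircms_report")
}

#' @export
print.mircms_report <- function(x, ...) {
  s <- x$summary
  cat("miRNA-target integration report\n")
  cat(sprintf("  known miRNAs: %d  novel miRNAs: %d\n",
              s$n_known_mirnas, s$n_novel_mirnas))
  cat(sprintf("  miRNA DE: %d up / %d down; gene DE: %d up / %d down\n",
              s$mirna_de$up, s$mirna_de$down, s$gene_de$up, s$gene_de$down))
  cat(sprintf("  validated targets: %d hits on %d genes; %d pairs\n",
              s$n_target_hits, s$n_target_genes, s$n_pairs))
  cl <- unlist(s$pairs_per_cluster)
  cat(sprintf("  clusters I/II/III/IV: %s\n", paste(cl, collapse = "/")))
  invisible(x)
}

#' Write a report to disk (pairs.tsv + summary.json)
#'
#' @param report a [integration_report()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$tables$pairs, file.path(dir, "pairs.tsv"))
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
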