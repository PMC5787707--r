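#' Exon regions eligible for guide placement
#'
#' An exon region is excluded when it is the first or last exon in more
#' than `max_terminal_fraction` (strictly) of the transcripts that contain
#' it: terminal exons are poor CRISPR targets (truncations there often
#' leave function intact). The fraction's denominator is the number of
#' transcripts containing the region.
#'
#' @param gene_model Data.frame for one gene: `transcript_id`, `exon_rank`
#'   (1 = 5'-most), `exon_region_id`.
#' @param max_terminal_fraction Exclusion threshold (default 0.25).
#' @return Character vector of eligible `exon_region_id`s.
#' @export
eligible_regions <- function(gene_model, max_terminal_fraction = 0.25) {
  if (!nrow(gene_model)) stop("gene model has no transcripts")
  tx_list <- split(gene_model, gene_model$transcript_id)
  all_regions <- lapply(tx_list, function(tx) {
    tx$exon_region_id[order(tx$exon_rank)]
  })
  term_regions <- lapply(all_regions, function(r) {
    unique(c(r[1], r[length(r)]))
  })
  regions <- unique(gene_model$exon_region_id)
  keep <- vapply(regions, function(reg) {
    containing <- vapply(all_regions, function(r) reg %in% r, logical(1))
    terminal <- vapply(term_regions, function(r) reg %in% r, logical(1))
    frac <- sum(terminal & containing) / sum(containing)
    frac <= max_terminal_fraction
  }, logical(1))
  unname(regions[keep])
}

#' Select guides for a gene
#'
#' Rule-based selection mirroring arrayed-library design practice:
#' candidates are restricted to eligible exon regions
#' ([eligible_regions()]) and on-target score >= `min_score` (inclusive),
#' then up to `n_guides` are picked greedily, one per exon region,
#' preferring (1) guides hitting more transcripts, (2) higher score,
#' (3) lexicographic guide id. If fewer than `n_guides` candidates pass
#' the score filter, the remaining slots are filled with the
#' highest-scoring eligible-region candidates regardless of transcript
#' coverage, still one per region; any remaining shortfall is reported.
#'
#' @param gene_model Data.frame for one gene (see [eligible_regions()]).
#' @param candidates Data.frame: `guide_id`, `gene`, `exon_region_id`,
#'   `on_target_score`. Transcript coverage is derived from the gene model
#'   (all transcripts containing the guide's region).
#' @param n_guides Guides to select (default 3).
#' @param min_score Minimum on-target score (default 0.7, inclusive).
#' @param max_terminal_fraction Passed to [eligible_regions()].
#' @return A list: `selection` (data.frame with `rank`, `guide_id`,
#'   `exon_region_id`, `on_target_score`, `n_transcripts_hit`, `fallback`)
#'   and `shortfall` (count of unfilled slots).
#' @export
select_guides <- function(gene_model, candidates, n_guides = 3,
                          min_score = 0.7, max_terminal_fraction = 0.25) {
  elig <- eligible_regions(gene_model, max_terminal_fraction)
  cand <- candidates[candidates$exon_region_id %in% elig, , drop = FALSE]
  tx_per_region <- tapply(gene_model$transcript_id, gene_model$exon_region_id,
                          function(x) length(unique(x)))
  cand$n_transcripts_hit <- as.integer(tx_per_region[cand$exon_region_id])

  pick <- function(pool, used_regions, slots, by_coverage) {
    ord <- if (by_coverage) {
      order(-pool$n_transcripts_hit, -pool$on_target_score, pool$guide_id)
    } else {
      order(-pool$on_target_score, pool$guide_id)
    }
    pool <- pool[ord, , drop = FALSE]
    sel <- list()
    for (i in seq_len(nrow(pool))) {
      if (length(sel) >= slots) break
      if (pool$exon_region_id[i] %in% used_regions) next
      sel[[length(sel) + 1L]] <- pool[i, , drop = FALSE]
      used_regions <- c(used_regions, pool$exon_region_id[i])
    }
    if (length(sel)) do.call(rbind, sel) else pool[0, , drop = FALSE]
  }

  primary_pool <- cand[cand$on_target_score >= min_score, , drop = FALSE]
  primary <- pick(primary_pool, character(), n_guides, by_coverage = TRUE)
  primary$fallback <- rep(FALSE, nrow(primary))
  sel <- primary
  if (nrow(sel) < n_guides) {
    rest <- cand[!cand$guide_id %in% sel$guide_id, , drop = FALSE]
    fb <- pick(rest, sel$exon_region_id, n_guides - nrow(sel),
               by_coverage = FALSE)
    if (nrow(fb)) {
      fb$fallback <- TRUE
      sel <- rbind(sel, fb)
    }
  }
  sel$rank <- seq_len(nrow(sel))
  if (!"fallback" %in% names(sel)) sel$fallback <- logical(0)
  sel <- sel[, c("rank", "guide_id", "exon_region_id", "on_target_score",
                 "n_transcripts_hit", "fallback"), drop = FALSE]
  rownames(sel) <- NULL
  list(selection = sel, shortfall = max(0L, n_guides - nrow(sel)))
}

#' Assign guides to wells from read counts
#'
#' Barcoded-colony deconvolution QC: a well is retained — and assigned its
#' most abundant guide — when (inclusive) at least `min_reads` mapped reads
#' were identified in it and (strictly) the most abundant guide was read
#' more than `ratio` times more often than the second most abundant (a
#' second count of zero passes whenever the total suffices). Everything
#' else is rejected with a reason.
#'
#' @param counts Data.frame: `plate_id`, `well_id`, `guide`, `count`.
#' @param min_reads Minimum total mapped reads per well (default 50).
#' @param ratio Required top/second abundance ratio (default 5).
#' @return A data.frame per well: plate_id, well_id, guide (top guide),
#'   top_count, second_count, total, retained, reason.
#' @export
deconvolve_wells <- function(counts, min_reads = 50, ratio = 5) {
  if (any(counts$count < 0)) stop("read counts must be >= 0")
  key <- paste(counts$plate_id, counts$well_id, sep = ":")
  rows <- lapply(unique(key), function(k) {
    sub <- counts[key == k, , drop = FALSE]
    ord <- order(-sub$count, sub$guide)
    top <- sub[ord[1], ]
    second <- if (nrow(sub) > 1) sub$count[ord[2]] else 0
    total <- sum(sub$count)
    enough <- total >= min_reads
    dominant <- top$count > ratio * second
    data.frame(
      plate_id = top$plate_id, well_id = top$well_id, guide = top$guide,
      top_count = top$count, second_count = second, total = total,
      retained = enough && dominant,
      reason = if (!enough) "fewer than minimum mapped reads" else
        if (!dominant) "top guide not dominant" else ""
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-array to one well per guide
#'
#' When a guide was assigned to several retained wells, keeps the well with
#' the highest top-guide read count (ties broken by the lexicographically
#' smaller `plate:well` key), producing an injective guide-to-well map for
#' the re-arrayed library.
#'
#' @param assignments Output of [deconvolve_wells()] (only retained rows
#'   are used).
#' @return A data.frame: guide, plate_id, well_id, top_count.
#' @export
rearray_unique <- function(assignments) {
  ret <- assignments[assignments$retained, , drop = FALSE]
  if (!nrow(ret)) {
    return(data.frame(guide = character(), plate_id = character(),
                      well_id = character(), top_count = integer()))
  }
  key <- paste(ret$plate_id, ret$well_id, sep = ":")
  ord <- order(ret$guide, -ret$top_count, key)
  ret <- ret[ord, , drop = FALSE]
  ret <- ret[!duplicated(ret$guide), c("guide", "plate_id", "well_id",
                                       "top_count")]
  rownames(ret) <- NULL
  ret
}
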