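#' Read a term-to-gene annotation table
#'
#' Two-column delimited text (`term_id`, `gene`), with an optional third
#' `label` column. GMT-style files (term, description, genes...) can be
#' converted with [gmt_to_annotations()].
#'
#' @param path Path to a CSV/TSV file.
#' @return A named list of character gene sets, with a `labels` attribute.
#' @export
read_annotations <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (ncol(df) < 2) stop("annotation file needs term_id and gene columns")
  names(df)[1:2] <- c("term_id", "gene")
  sets <- split(as.character(df$gene), df$term_id)
  sets <- lapply(sets, unique)
  labels <- if (ncol(df) >= 3) {
    tapply(as.character(df[[3]]), df$term_id, function(x) x[1])
  } else {
    setNames(names(sets), names(sets))
  }
  attr(sets, "labels") <- labels[names(sets)]
  sets
}

#' Convert GMT lines to an annotation list
#'
#' @param lines Character vector of GMT lines
#'   (`term<TAB>description<TAB>gene1<TAB>gene2...`).
#' @return A named list of gene sets with a `labels` attribute.
#' @export
gmt_to_annotations <- function(lines) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "labels") <- setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}

#' Hypergeometric over-representation test
#'
#' For each annotation term with `K` genes in the screened library universe
#' of size `N`, and `k` of them among the `n` hit genes, computes the
#' one-sided enrichment p-value `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, a Benjamini-Hochberg adjusted p-value
#' across tested terms, and the enrichment ratio `(k/n)/(K/N)`. Terms with
#' no gene in the universe are skipped.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe Character vector: all genes screened.
#' @param annotations Named list of gene sets (see [read_annotations()]).
#' @return A data.frame: term_id, label, k, K, n, N, enrichment, p_raw,
#'   p_adjusted, ordered by p_raw.
#' @export
hypergeom_enrichment <- function(hits, universe, annotations) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    stop("hit gene(s) not in the universe: ",
         paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(names(annotations), function(term) {
    set <- intersect(annotations[[term]], universe)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(set, hits))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               enrichment = if (n > 0 && K > 0) (k / n) / (K / N) else NA,
               p_raw = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), label = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), enrichment = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  }
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  labels <- attr(annotations, "labels")
  out$label <- if (!is.null(labels)) {
    unname(labels[out$term_id])
  } else {
    out$term_id
  }
  out <- out[order(out$p_raw), c("term_id", "label", "k", "K", "n", "N",
                                 "enrichment", "p_raw", "p_adjusted")]
  rownames(out) <- NULL
  out
}
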