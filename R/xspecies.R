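#' Prefilter genes on mean raw count
#'
#' Removes genes whose mean raw count across samples is below `min_mean`
#' before differential expression: the boundary is strict on the low side,
#' so a mean of exactly `min_mean` is retained.
#'
#' @param count_table numeric matrix or data frame, genes x samples.
#' @param min_mean minimum mean raw count to retain (default 10).
#' @return The filtered table, same type as the input.
#' @export
prefilter_counts <- function(count_table, min_mean = 10) {
  mat <- as.matrix(count_table)
  if (ncol(mat) == 0L) stop("count table has zero samples")
  if (any(mat < 0)) stop("counts must be non-negative")
  keep <- rowMeans(mat) >= min_mean
  count_table[keep, , drop = FALSE]
}

#' Validate a differential-expression result table
#'
#' @param de data frame with columns `gene`, `log2fc`, `pvalue` and
#'   (optionally) `padj`.
#' @return The table, checked.
#' @export
validate_de_table <- function(de) {
  required <- c("gene", "log2fc", "pvalue")
  missing_cols <- setdiff(required, names(de))
  if (length(missing_cols) > 0L) {
    stop("DE table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- de$gene[duplicated(de$gene)]
  if (length(dup) > 0L) {
    stop("duplicate gene symbols: ", paste(unique(dup), collapse = ", "))
  }
  if (any(!is.finite(de$log2fc))) stop("non-finite log2fc values")
  de
}

#' Filter a DE table to significant genes with direction
#'
#' Keeps rows passing both the significance and the fold-change cut, with
#' strict inequalities: adjusted p (or raw p when `use_padj = FALSE`) below
#' `alpha`, and |log2fc| strictly greater than `lfc_cut`. Adds a `direction`
#' column (`up` / `down`). Two printed threshold conventions are common for
#' this procedure -- adjusted p < 0.1 and raw p < 0.05 -- so both the column
#' and the level are parameters.
#'
#' @param de DE table (`gene`, `log2fc`, `pvalue`, `padj`).
#' @param alpha significance level (default 0.1).
#' @param lfc_cut |log2fc| must exceed this (default 1).
#' @param use_padj test `padj` (default) rather than `pvalue`.
#' @return The significant subset with a `direction` column.
#' @export
filter_deg <- function(de, alpha = 0.1, lfc_cut = 1, use_padj = TRUE) {
  de <- validate_de_table(de)
  stopifnot(alpha > 0, alpha < 1, lfc_cut > 0)
  if (use_padj && !("padj" %in% names(de))) {
    stop("DE table has no padj column; set use_padj = FALSE to filter on pvalue")
  }
  p <- if (use_padj) de$padj else de$pvalue
  keep <- !is.na(p) & p < alpha & abs(de$log2fc) > lfc_cut
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Read an ortholog map from TSV
#'
#' @param path TSV with header columns `mouse_symbol`, `human_symbol`.
#' @return Validated ortholog map data frame (possibly many-to-many).
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  validate_ortholog_map(map)
}

validate_ortholog_map <- function(map) {
  required <- c("mouse_symbol", "human_symbol")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0L) {
    stop("ortholog map is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(map$mouse_symbol == "" | map$human_symbol == "")) {
    stop("ortholog map contains empty symbols")
  }
  if (any(map$mouse_symbol == map$human_symbol)) {
    stop("ortholog map contains self-loops")
  }
  map[!duplicated(map[, required]), required]
}

#' Cross-species overlap of significant orthologous DEGs
#'
#' A mouse/human gene pair contributes to the overlap when the two genes are
#' orthologs, both passed [filter_deg()], and their directions agree. Pairs
#' significant in both species but in opposite directions are reported
#' separately as discordant and excluded from the overlap count. Under
#' many-to-many orthology each mouse gene contributes at most one pair,
#' tie-broken to the lexicographically smallest concordant human symbol and
#' flagged, so the tallies count genes rather than ortholog edges.
#'
#' @param de_mouse_sig,de_human_sig significant subsets from [filter_deg()]
#'   (must carry `direction`).
#' @param map ortholog map with `mouse_symbol`, `human_symbol` columns.
#' @return An `overlap_result`: list with `overlapping_genes` (data frame
#'   `mouse_symbol`, `human_symbol`, `direction`, `collapsed`), `n_overlap`,
#'   `n_up`, `n_down`, and `discordant`.
#' @export
overlap_orthologs <- function(de_mouse_sig, de_human_sig, map) {
  map <- validate_ortholog_map(map)
  for (de in list(de_mouse_sig, de_human_sig)) {
    if (!("direction" %in% names(de))) {
      stop("inputs must come from filter_deg (direction column missing)")
    }
  }
  pairs <- map[map$mouse_symbol %in% de_mouse_sig$gene &
                 map$human_symbol %in% de_human_sig$gene, , drop = FALSE]
  pairs$dir_mouse <-
    de_mouse_sig$direction[match(pairs$mouse_symbol, de_mouse_sig$gene)]
  pairs$dir_human <-
    de_human_sig$direction[match(pairs$human_symbol, de_human_sig$gene)]

  concord <- pairs[pairs$dir_mouse == pairs$dir_human, , drop = FALSE]
  discord <- pairs[pairs$dir_mouse != pairs$dir_human, , drop = FALSE]

  # one pair per mouse gene: smallest concordant human symbol wins
  concord <- concord[order(concord$mouse_symbol, concord$human_symbol), ,
                     drop = FALSE]
  n_alt <- table(concord$mouse_symbol)
  concord <- concord[!duplicated(concord$mouse_symbol), , drop = FALSE]
  overlapping <- data.frame(
    mouse_symbol = concord$mouse_symbol,
    human_symbol = concord$human_symbol,
    direction = concord$dir_mouse,
    collapsed = as.integer(n_alt[concord$mouse_symbol]) > 1L,
    stringsAsFactors = FALSE, row.names = NULL)

  discordant <- data.frame(
    mouse_symbol = discord$mouse_symbol,
    human_symbol = discord$human_symbol,
    dir_mouse = discord$dir_mouse,
    dir_human = discord$dir_human,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(overlapping_genes = overlapping,
                 n_overlap = nrow(overlapping),
                 n_up = sum(overlapping$direction == "up"),
                 n_down = sum(overlapping$direction == "down"),
                 discordant = discordant),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Ortholog DEG overlap: %d genes (%d up, %d down), %d discordant\n",
              x$n_overlap, x$n_up, x$n_down, nrow(x$discordant)))
  invisible(x)
}

#' Generate paired synthetic DE tables with planted overlap structure
#'
#' Emits finished mouse and human DE result tables plus a 1:1 ortholog map
#' (mouse title-case vs human upper-case symbol conventions) in which a
#' chosen number of genes are concordantly up, concordantly down, or
#' significant in one species only; all remaining genes are null. Planted
#' significant genes satisfy |log2fc| > 1 with adjusted p < 0.1 and raw
#' p < 0.05 in the relevant species, so the planted structure is recovered
#' under either threshold convention.
#'
#' @param n_genes total genes per species (default 2000).
#' @param n_up_concordant planted concordant upregulated genes (default 25).
#' @param n_down_concordant planted concordant downregulated genes
#'   (default 83).
#' @param n_mouse_only,n_human_only species-specific significant distractors
#'   (default 40 each).
#' @param effect_size mean |log2fc| of planted genes (default 2.5; planted
#'   values never fall below 1.2).
#' @param seed RNG seed.
#' @return List with `mouse`, `human` (DE tables), `map` (ortholog map) and
#'   `truth` (data frame of planted classes).
#' @export
generate_synthetic_de <- function(n_genes = 2000L, n_up_concordant = 25L,
                                  n_down_concordant = 83L,
                                  n_mouse_only = 40L, n_human_only = 40L,
                                  effect_size = 2.5, seed = 1L) {
  n_planted <- n_up_concordant + n_down_concordant + n_mouse_only +
    n_human_only
  stopifnot(n_planted <= n_genes, effect_size > 1.2)
  set.seed(seed)

  base <- sprintf("Gene%04d", seq_len(n_genes))
  mouse_sym <- paste0(substr(base, 1L, 1L), tolower(substr(base, 2L, 99L)))
  human_sym <- toupper(base)
  classes <- rep("null", n_genes)
  planted <- sample.int(n_genes, n_planted)
  classes[planted] <- rep(c("up_concordant", "down_concordant",
                            "mouse_only", "human_only"),
                          times = c(n_up_concordant, n_down_concordant,
                                    n_mouse_only, n_human_only))

  sig_lfc <- function(n, sign) {
    sign * pmax(1.2, stats::rnorm(n, mean = effect_size, sd = 0.4))
  }
  null_lfc <- function(n) stats::runif(n, -0.8, 0.8)
  sig_p <- function(n) stats::runif(n, 1e-8, 0.04)
  null_p <- function(n) stats::runif(n, 0.15, 1)

  one_species <- function(active_up, active_down) {
    lfc <- null_lfc(n_genes)
    pv <- null_p(n_genes)
    lfc[active_up] <- sig_lfc(sum(active_up), +1)
    lfc[active_down] <- sig_lfc(sum(active_down), -1)
    pv[active_up | active_down] <- sig_p(sum(active_up | active_down))
    padj <- pmin(1, pv * stats::runif(n_genes, 1, 2))
    padj[active_up | active_down] <-
      pmin(0.09, padj[active_up | active_down] * 2)
    list(log2fc = lfc, pvalue = pv, padj = padj)
  }

  # species-specific distractors split evenly between up and down
  m_only_up <- classes == "mouse_only" & seq_len(n_genes) %% 2L == 0L
  m_only_dn <- classes == "mouse_only" & !m_only_up
  h_only_up <- classes == "human_only" & seq_len(n_genes) %% 2L == 0L
  h_only_dn <- classes == "human_only" & !h_only_up

  m <- one_species(classes == "up_concordant" | m_only_up,
                   classes == "down_concordant" | m_only_dn)
  h <- one_species(classes == "up_concordant" | h_only_up,
                   classes == "down_concordant" | h_only_dn)

  mouse <- data.frame(gene = mouse_sym, log2fc = m$log2fc,
                      pvalue = m$pvalue, padj = m$padj,
                      stringsAsFactors = FALSE)
  human <- data.frame(gene = human_sym, log2fc = h$log2fc,
                      pvalue = h$pvalue, padj = h$padj,
                      stringsAsFactors = FALSE)
  map <- data.frame(mouse_symbol = mouse_sym, human_symbol = human_sym,
                    stringsAsFactors = FALSE)
  truth <- data.frame(mouse_symbol = mouse_sym, human_symbol = human_sym,
                      class = classes, stringsAsFactors = FALSE)
  list(mouse = mouse, human = human, map = map, truth = truth)
}
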