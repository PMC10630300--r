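#' Relative shRNA abundances per sample
#'
#' Converts raw counts to per-sample frequencies over library shRNAs. A
#' pseudocount is added to every cell before normalization so that shRNAs
#' depleted to zero reads keep a finite fold change downstream. Unassigned
#' and undemultiplexed reads are excluded from the denominator: abundances
#' are relative among detected library shRNAs.
#'
#' @param cm a `count_matrix`.
#' @param pseudocount non-negative value added to each raw count
#'   (default 0.5).
#' @return An `abundance_table`: list with `freq` (matrix, columns sum to 1)
#'   and `pseudocount`.
#' @export
relative_abundance <- function(cm, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  shifted <- cm$counts + pseudocount
  tot <- colSums(shifted)
  zero <- tot == 0
  if (any(zero)) {
    stop("sample(s) with zero total counts and pseudocount 0: ",
         paste(colnames(cm$counts)[zero], collapse = ", "))
  }
  freq <- sweep(shifted, 2L, tot, "/")
  structure(list(freq = freq, pseudocount = pseudocount),
            class = "abundance_table")
}

#' Per-replicate log2 fold change versus the starting pool
#'
#' For every shRNA and liver replicate, computes
#' `log2(freq_replicate / freq_pool)` where the pool is the manifest's
#' `reference_pool` sample, then averages over replicates with the arithmetic
#' mean of the per-replicate log2 values.
#'
#' @param ab an `abundance_table`.
#' @param manifest a `sample_manifest` whose samples are columns of `ab`.
#' @return A `fold_change_table`: list with `lfc` (shRNA x replicate matrix),
#'   `mean_lfc`, `n_replicates` and (once [replicate_consistency()] has run)
#'   `consistency`.
#' @export
log2_fold_change <- function(ab, manifest) {
  pool <- pool_sample(manifest)
  reps <- replicate_samples(manifest)
  missing <- setdiff(c(pool, reps), colnames(ab$freq))
  if (length(missing) > 0L) {
    stop("sample(s) absent from abundance table: ",
         paste(missing, collapse = ", "))
  }
  f_pool <- ab$freq[, pool]
  if (any(f_pool == 0)) {
    stop("zero pool frequency for: ",
         paste(rownames(ab$freq)[f_pool == 0], collapse = ", "),
         " (use pseudocount > 0)")
  }
  lfc <- log2(ab$freq[, reps, drop = FALSE] / f_pool)
  structure(list(lfc = lfc,
                 mean_lfc = rowMeans(lfc),
                 n_replicates = length(reps),
                 consistency = NULL),
            class = "fold_change_table")
}

#' Replicate sign-consistency score
#'
#' The screen's prioritization favours shRNAs enriched consistently across
#' all biological replicates. This formalizes that as, per shRNA, the
#' fraction of replicates whose log2 fold change agrees in sign with the
#' mean and has magnitude at least `consistency_floor`. Where the mean is
#' exactly zero the score is 0.
#'
#' @param fc a `fold_change_table`.
#' @param consistency_floor minimum per-replicate |lfc| to count as agreeing
#'   (default 0: sign agreement only).
#' @return `fc` with the `consistency` field filled.
#' @export
replicate_consistency <- function(fc, consistency_floor = 0) {
  agree <- sweep(sign(fc$lfc), 1L, sign(fc$mean_lfc), "==") &
    abs(fc$lfc) >= consistency_floor
  cons <- rowSums(agree) / fc$n_replicates
  cons[fc$mean_lfc == 0] <- 0
  fc$consistency <- cons
  fc
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("Fold-change table: %d shRNAs x %d replicates; mean lfc range [%.2f, %.2f]\n",
              nrow(x$lfc), x$n_replicates,
              min(x$mean_lfc), max(x$mean_lfc)))
  invisible(x)
}

#' Write per-shRNA fold changes to TSV
#'
#' One row per shRNA: gene and control class from the library, one lfc column
#' per replicate, `mean_lfc` and `consistency`.
#'
#' @param fc a `fold_change_table` with consistency filled.
#' @param library the matching `shrna_library`.
#' @param path output path.
#' @return The written data frame, invisibly.
#' @export
write_fold_changes <- function(fc, library, path) {
  idx <- match(rownames(fc$lfc), library$shrna_id)
  if (anyNA(idx)) stop("fold-change rows not present in library")
  out <- data.frame(shrna_id = rownames(fc$lfc),
                    gene = library$gene[idx],
                    control_class = library$control_class[idx],
                    fc$lfc,
                    mean_lfc = fc$mean_lfc,
                    consistency = if (is.null(fc$consistency)) NA
                                  else fc$consistency,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
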