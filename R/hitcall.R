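#' Classify shRNAs as enriched, depleted or neutral
#'
#' An shRNA is `enriched` when its mean log2 fold change is at least
#' `+lfc_threshold` (two-fold by default, inclusive boundary) and its
#' replicate consistency reaches `min_consistency`; `depleted` symmetrically
#' at `-lfc_threshold`; otherwise `neutral`.
#'
#' @param fc a `fold_change_table`; [replicate_consistency()] is applied with
#'   floor 0 if `consistency` is not yet filled.
#' @param library the matching `shrna_library`.
#' @param lfc_threshold positive log2 threshold (default 1 = two-fold).
#' @param min_consistency minimum replicate consistency for a non-neutral
#'   call (default 0.8, i.e. at least 4 of 5 replicates agreeing in sign).
#' @return Data frame of per-shRNA calls (`shrna_id`, `gene`,
#'   `control_class`, `mean_lfc`, `consistency`, `call`).
#' @export
classify_shrnas <- function(fc, library, lfc_threshold = 1.0,
                            min_consistency = 0.8) {
  if (lfc_threshold <= 0) stop("lfc_threshold must be > 0")
  if (is.null(fc$consistency)) fc <- replicate_consistency(fc)
  idx <- match(rownames(fc$lfc), library$shrna_id)
  if (anyNA(idx)) stop("fold-change rows not present in library")
  consistent <- fc$consistency >= min_consistency
  call <- ifelse(fc$mean_lfc >= lfc_threshold & consistent, "enriched",
          ifelse(fc$mean_lfc <= -lfc_threshold & consistent, "depleted",
                 "neutral"))
  data.frame(shrna_id = rownames(fc$lfc),
             gene = library$gene[idx],
             control_class = library$control_class[idx],
             mean_lfc = fc$mean_lfc,
             consistency = fc$consistency,
             call = unname(call),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-level hit calls under the independent-shRNA rule
#'
#' A gene is a hit only when at least `min_shrnas_per_gene` independent
#' shRNAs targeting it score in the same direction; single strong shRNAs are
#' never hits, guarding against off-target effects. Non-targeting controls
#' are excluded from gene aggregation. A gene reaching the rule in both
#' directions simultaneously is called `none` and flagged discordant.
#'
#' @param calls per-shRNA call table from [classify_shrnas()].
#' @param library the matching `shrna_library`.
#' @param min_shrnas_per_gene minimum same-direction shRNAs (default 2).
#' @return Data frame, one row per gene, ranked by `n_enriched` then mean
#'   supporting lfc (descending): `gene`, `n_shrnas_total`, `n_enriched`,
#'   `n_depleted`, `gene_call`, `discordant`, `supporting_shrnas`.
#' @export
call_gene_hits <- function(calls, library, min_shrnas_per_gene = 2L) {
  missing <- setdiff(library$shrna_id, calls$shrna_id)
  if (length(missing) > 0L) {
    stop("calls do not cover the library; missing: ",
         paste(missing, collapse = ", "))
  }
  targeting <- calls[calls$control_class != "non_targeting" &
                       calls$gene != "", , drop = FALSE]
  genes <- unique(targeting$gene)
  rows <- lapply(genes, function(g) {
    sub <- targeting[targeting$gene == g, , drop = FALSE]
    enr <- sub[sub$call == "enriched", , drop = FALSE]
    dep <- sub[sub$call == "depleted", , drop = FALSE]
    hit_enr <- nrow(enr) >= min_shrnas_per_gene
    hit_dep <- nrow(dep) >= min_shrnas_per_gene
    discordant <- hit_enr && hit_dep
    gene_call <- if (discordant) "none"
      else if (hit_enr) "hit_enriched"
      else if (hit_dep) "hit_depleted"
      else "none"
    supporting <- if (gene_call == "hit_enriched") enr
      else if (gene_call == "hit_depleted") dep
      else sub[0L, , drop = FALSE]
    data.frame(gene = g,
               n_shrnas_total = nrow(sub),
               n_enriched = nrow(enr),
               n_depleted = nrow(dep),
               gene_call = gene_call,
               discordant = discordant,
               supporting_shrnas = paste(supporting$shrna_id, collapse = ","),
               support_mean_lfc = if (nrow(supporting) > 0L)
                 mean(supporting$mean_lfc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_enriched,
                   -ifelse(is.na(out$support_mean_lfc), -Inf,
                           out$support_mean_lfc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Control-based screen QC
#'
#' Non-targeting controls are expected neutral (|mean lfc| below the
#' threshold); depletion sentinels target a gene essential for the selected
#' phenotype and are expected to drop out (mean lfc at or below the negative
#' threshold), which validates that selection pressure acted. A QC failure is
#' reported but never aborts hit calling; screens are exploratory and
#' controls are confidence checks.
#'
#' @param calls per-shRNA call table from [classify_shrnas()].
#' @param library the matching `shrna_library`.
#' @param lfc_threshold log2 threshold used for the pass rules (default 1).
#' @return A `control_qc_report`: list with data frames `non_targeting` and
#'   `sentinels` (each `shrna_id`, `mean_lfc`, `pass`) and `overall_pass`.
#' @export
control_qc <- function(calls, library, lfc_threshold = 1.0) {
  nt_ids <- library$shrna_id[library$control_class == "non_targeting"]
  se_ids <- library$shrna_id[library$control_class == "sentinel_depletion"]
  if (length(nt_ids) == 0L && length(se_ids) == 0L) {
    warning("library annotates no control shRNAs; QC is trivially empty-pass")
  }
  ctrl_rows <- function(ids, pass_fun) {
    sub <- calls[match(ids, calls$shrna_id), , drop = FALSE]
    data.frame(shrna_id = ids,
               mean_lfc = sub$mean_lfc,
               pass = pass_fun(sub$mean_lfc),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  nt <- ctrl_rows(nt_ids, function(m) abs(m) < lfc_threshold)
  se <- ctrl_rows(se_ids, function(m) m <= -lfc_threshold)
  structure(list(non_targeting = nt,
                 sentinels = se,
                 overall_pass = all(nt$pass) && all(se$pass)),
            class = "control_qc_report")
}

#' @export
print.control_qc_report <- function(x, ...) {
  cat(sprintf("Control QC: %d/%d non-targeting neutral, %d/%d sentinels depleted -> %s\n",
              sum(x$non_targeting$pass), nrow(x$non_targeting),
              sum(x$sentinels$pass), nrow(x$sentinels),
              if (x$overall_pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Run counts through enrichment, classification, hit calling and QC
#'
#' Convenience wrapper chaining [relative_abundance()],
#' [log2_fold_change()], [replicate_consistency()], [classify_shrnas()],
#' [call_gene_hits()] and [control_qc()] with the screen's defaults.
#'
#' @param cm a `count_matrix`.
#' @param library an `shrna_library`.
#' @param manifest a `sample_manifest`.
#' @param pseudocount added to counts before normalization (default 0.5).
#' @param consistency_floor per-replicate |lfc| floor for consistency
#'   (default 0).
#' @param lfc_threshold log2 fold-change threshold (default 1 = two-fold).
#' @param min_consistency consistency gate for calls (default 0.8).
#' @param min_shrnas_per_gene independent-shRNA rule (default 2).
#' @return List with `fold_changes`, `shrna_calls`, `gene_hits`, `qc`.
#' @export
screen_pipeline <- function(cm, library, manifest,
                            pseudocount = 0.5,
                            consistency_floor = 0,
                            lfc_threshold = 1.0,
                            min_consistency = 0.8,
                            min_shrnas_per_gene = 2L) {
  ab <- relative_abundance(cm, pseudocount = pseudocount)
  fc <- log2_fold_change(ab, manifest)
  fc <- replicate_consistency(fc, consistency_floor = consistency_floor)
  calls <- classify_shrnas(fc, library, lfc_threshold = lfc_threshold,
                           min_consistency = min_consistency)
  hits <- call_gene_hits(calls, library,
                         min_shrnas_per_gene = min_shrnas_per_gene)
  qc <- control_qc(calls, library, lfc_threshold = lfc_threshold)
  list(fold_changes = fc, shrna_calls = calls, gene_hits = hits, qc = qc)
}
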