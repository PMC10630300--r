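# Small in-code fixtures and an independent brute-force counting oracle.

tiny_library <- function() {
  shrna_library(data.frame(
    shrna_id = c("shA_1", "shA_2", "shNC_1", "shMet_1"),
    gene = c("geneA", "geneA", "", "Met"),
    guide_seq = c("ACGTAC", "TTGGCC", "GGGTTT", "CCCAAA"),
    control_class = c("targeting", "targeting", "non_targeting",
                      "sentinel_depletion"),
    stringsAsFactors = FALSE))
}

tiny_manifest <- function(n_reps = 2L) {
  barcodes <- c("AACCGGTT", "TTGGCCAA", "ACACACAC", "GTGTGTGT",
                "AAGGTTCC", "CCTTGGAA")[seq_len(n_reps + 1L)]
  sample_manifest(data.frame(
    barcode = barcodes,
    sample_id = c("pool", paste0("rep", seq_len(n_reps))),
    role = c("reference_pool", rep("replicate", n_reps)),
    stringsAsFactors = FALSE))
}

# Independent oracle: nested-loop scan comparing every read against every
# barcode and every guide with character-wise substring equality. Never
# shares code with count_read_vector.
brute_force_count <- function(reads, library, manifest, guide_offset) {
  L <- attr(library, "guide_length")
  bl <- attr(manifest, "barcode_length")
  counts <- matrix(0, nrow(library), nrow(manifest),
                   dimnames = list(library$shrna_id, manifest$sample_id))
  unassigned <- stats::setNames(rep(0, nrow(manifest)), manifest$sample_id)
  undemuxed <- 0
  for (rd in reads) {
    s <- NA_character_
    for (k in seq_len(nrow(manifest))) {
      if (nchar(rd) >= bl && substr(rd, 1, bl) == manifest$barcode[k]) {
        s <- manifest$sample_id[k]
        break
      }
    }
    if (is.na(s)) {
      undemuxed <- undemuxed + 1
      next
    }
    g <- NA_character_
    region <- if (nchar(rd) >= guide_offset + L) {
      substr(rd, guide_offset + 1, guide_offset + L)
    } else ""
    for (k in seq_len(nrow(library))) {
      if (region == library$guide_seq[k]) {
        g <- library$shrna_id[k]
        break
      }
    }
    if (is.na(g)) {
      unassigned[s] <- unassigned[s] + 1
    } else {
      counts[g, s] <- counts[g, s] + 1
    }
  }
  count_matrix(counts, unassigned, undemuxed)
}

# Random test instance: reads drawn from planted (guide, sample) pairs with
# occasional corrupted barcodes, corrupted guides and short reads.
random_read_instance <- function(library, manifest, n_reads, guide_offset) {
  L <- attr(library, "guide_length")
  bl <- attr(manifest, "barcode_length")
  spacer <- strrep("T", guide_offset - bl)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    kind <- sample(c("clean", "bad_barcode", "bad_guide", "short"), 1,
                   prob = c(0.6, 0.15, 0.15, 0.1))
    bc <- sample(manifest$barcode, 1)
    gd <- sample(library$guide_seq, 1)
    if (kind == "bad_barcode") {
      p <- sample(bl, 1)
      substr(bc, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(bc, p, p)), 1)
    }
    if (kind == "bad_guide") {
      p <- sample(L, 1)
      substr(gd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(gd, p, p)), 1)
    }
    rd <- paste0(bc, spacer, gd, "AA")
    if (kind == "short") rd <- substr(rd, 1, sample(0:(bl + 2), 1))
    reads[i] <- rd
  }
  reads
}

random_small_library <- function(n_guides, guide_len = 8L) {
  repeat {
    seqs <- vapply(seq_len(n_guides), function(i) {
      paste(sample(c("A", "C", "G", "T"), guide_len, replace = TRUE),
            collapse = "")
    }, "")
    if (!anyDuplicated(seqs)) break
  }
  shrna_library(data.frame(
    shrna_id = paste0("sh", seq_len(n_guides)),
    gene = paste0("g", rep(seq_len(max(1, n_guides %/% 2)),
                           each = 2)[seq_len(n_guides)]),
    guide_seq = seqs,
    control_class = "targeting",
    stringsAsFactors = FALSE))
}

expect_conservation <- function(cm, n_reads) {
  expect_equal(sum(cm$counts) + sum(cm$unassigned) + cm$undemuxed, n_reads)
  expect_equal(cm$total_reads, n_reads)
}
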