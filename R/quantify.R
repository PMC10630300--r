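#' Count matrix constructor
#'
#' Holds exact-match read counts per shRNA and sample, together with the
#' per-sample tally of demultiplexed reads whose guide region matched no
#' library guide (`unassigned`) and the count of reads whose leading bases
#' matched no sample barcode (`undemuxed`). The conservation invariant
#' `sum(counts) + sum(unassigned) + undemuxed == total_reads` always holds.
#'
#' @param counts integer matrix, rows = shRNA ids, columns = sample ids.
#' @param unassigned named integer vector, one entry per sample.
#' @param undemuxed single non-negative integer.
#' @return A `count_matrix`.
#' @export
count_matrix <- function(counts, unassigned = NULL, undemuxed = 0) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(unassigned)) {
    unassigned <- rep(0, ncol(counts))
  }
  if (is.null(names(unassigned))) {
    names(unassigned) <- colnames(counts)
  }
  unassigned <- unassigned[colnames(counts)]
  if (anyNA(unassigned)) stop("unassigned names must match sample columns")
  if (any(counts < 0) || any(unassigned < 0) || undemuxed < 0) {
    stop("counts must be non-negative")
  }
  structure(list(counts = counts,
                 unassigned = unassigned,
                 undemuxed = as.double(undemuxed),
                 total_reads = sum(counts) + sum(unassigned) + undemuxed),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d shRNAs x %d samples, %s reads (%s unassigned, %s undemuxed)\n",
              nrow(x$counts), ncol(x$counts),
              format(x$total_reads, big.mark = ",", scientific = FALSE),
              format(sum(x$unassigned), big.mark = ",", scientific = FALSE),
              format(x$undemuxed, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Demultiplex reads by exact barcode prefix
#'
#' Assigns each read to the sample whose barcode equals the read's first
#' `barcode_length` bases with zero mismatches; reads that match no barcode
#' (including reads shorter than the barcode) get `NA`.
#'
#' @param read_seq character vector of read sequences.
#' @param manifest a `sample_manifest`.
#' @return Character vector of sample ids, `NA` where undemultiplexed.
#' @export
demultiplex_read <- function(read_seq, manifest) {
  bl <- attr(manifest, "barcode_length")
  prefix <- substr(read_seq, 1L, bl)
  prefix[nchar(read_seq) < bl] <- NA_character_
  manifest$sample_id[match(prefix, manifest$barcode)]
}

#' Count exact guide matches per shRNA and sample
#'
#' Demultiplexes a FASTQ file by 8-bp sample barcode and counts reads whose
#' guide region is a 100% match to a library guide. No mismatches are
#' tolerated anywhere: a read either increments exactly one `(shRNA, sample)`
#' cell, or its sample's `unassigned` tally, or the global `undemuxed` tally.
#' Base qualities are ignored (exact matching subsumes quality filtering).
#'
#' @param fastq path to a FASTQ or FASTQ.gz file.
#' @param library an `shrna_library`.
#' @param manifest a `sample_manifest`.
#' @param guide_offset 0-based offset of the guide region from the read start
#'   (i.e. the guide occupies bases `guide_offset + 1 ... guide_offset + L`),
#'   or `"scan"` to search each read for any exact guide occurrence
#'   (leftmost occurrence wins).
#' @param match_revcomp also match the reverse complement of each read
#'   (default `FALSE`; amplicon sequencing is single-orientation).
#' @return A `count_matrix`.
#' @export
count_shrnas <- function(fastq, library, manifest, guide_offset = 0L,
                         match_revcomp = FALSE) {
  reads <- read_fastq_seqs(fastq)
  count_read_vector(reads, library, manifest, guide_offset, match_revcomp)
}

read_fastq_seqs <- function(fastq) {
  if (!file.exists(fastq)) stop("FASTQ file not found: ", fastq)
  lines <- readLines(fastq)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", length(lines),
         " lines is not a multiple of 4 (record ",
         length(lines) %/% 4L + 1L, " incomplete)")
  }
  if (length(lines) == 0L) return(character(0))
  headers <- lines[seq(1L, length(lines), by = 4L)]
  bad <- which(!startsWith(headers, "@"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record at index ", bad[1L])
  }
  toupper(lines[seq(2L, length(lines), by = 4L)])
}

#' Count guide matches in an in-memory read vector
#'
#' Workhorse behind [count_shrnas()]; useful in tests and simulations where
#' reads never touch disk.
#'
#' @inheritParams count_shrnas
#' @param reads character vector of read sequences.
#' @return A `count_matrix`.
#' @export
count_read_vector <- function(reads, library, manifest, guide_offset = 0L,
                              match_revcomp = FALSE) {
  L <- attr(library, "guide_length")
  bl <- attr(manifest, "barcode_length")
  samples <- manifest$sample_id

  counts <- matrix(0, nrow = nrow(library), ncol = length(samples),
                   dimnames = list(library$shrna_id, samples))
  unassigned <- stats::setNames(rep(0, length(samples)), samples)

  # guide lookup, optionally extended with reverse complements mapping back
  # to the same shRNA (forward orientation wins on the rare collision)
  guide_tab <- library$guide_seq
  guide_idx <- seq_len(nrow(library))
  if (match_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(library$guide_seq)))
    keep <- !(rc %in% guide_tab)
    guide_tab <- c(guide_tab, rc[keep])
    guide_idx <- c(guide_idx, seq_len(nrow(library))[keep])
  }

  assign_guides <- function(rd) {
    hit <- if (identical(guide_offset, "scan")) {
      scan_guides(rd, guide_tab)
    } else {
      region <- substr(rd, guide_offset + 1L, guide_offset + L)
      region[nchar(rd) < guide_offset + L] <- NA_character_
      match(region, guide_tab)
    }
    guide_idx[hit]
  }

  sample_idx <- match(demultiplex_read(reads, manifest), samples)
  undemuxed <- sum(is.na(sample_idx))

  demuxed <- !is.na(sample_idx)
  if (any(demuxed)) {
    gi <- assign_guides(reads[demuxed])
    si <- sample_idx[demuxed]
    hit <- !is.na(gi)
    if (any(hit)) {
      tab <- table(factor(gi[hit], levels = seq_len(nrow(library))),
                   factor(si[hit], levels = seq_along(samples)))
      counts <- counts + unclass(tab)
    }
    if (any(!hit)) {
      ua <- table(factor(si[!hit], levels = seq_along(samples)))
      unassigned <- unassigned + as.double(ua)
    }
  }

  cm <- count_matrix(counts, unassigned, undemuxed)
  stopifnot(cm$total_reads == length(reads))
  cm
}

# Leftmost exact occurrence of any guide in each read; among guides starting
# at the same position only one can match (guides are distinct, equal length).
scan_guides <- function(reads, guides) {
  best_pos <- rep(Inf, length(reads))
  best_guide <- rep(NA_integer_, length(reads))
  for (g in seq_along(guides)) {
    pos <- regexpr(guides[g], reads, fixed = TRUE)
    found <- pos > 0L & pos < best_pos
    best_pos[found] <- pos[found]
    best_guide[found] <- g
  }
  best_guide
}

#' Write a count matrix to TSV
#'
#' Emits one row per shRNA with one column per sample, a trailing
#' `__unassigned__` row with the per-sample unassigned tallies, and a final
#' `# undemuxed=N` metadata line. [read_counts()] reproduces the matrix
#' exactly.
#'
#' @param cm a `count_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  body <- rbind(cm$counts, `__unassigned__` = cm$unassigned)
  tab <- data.frame(shrna_id = rownames(body), body, check.names = FALSE,
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# undemuxed=%s",
                     format(cm$undemuxed, scientific = FALSE)), con)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path counts TSV path.
#' @return A `count_matrix`.
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# undemuxed=", lines, value = TRUE)
  undemuxed <- if (length(meta) == 1L) {
    as.double(sub("^# undemuxed=", "", meta))
  } else 0
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab$shrna_id
  ua_row <- rownames(mat) == "__unassigned__"
  ua <- if (any(ua_row)) {
    stats::setNames(as.double(mat[ua_row, , drop = FALSE]), colnames(mat))
  }
  count_matrix(mat[!ua_row, , drop = FALSE], unassigned = ua,
               undemuxed = undemuxed)
}
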