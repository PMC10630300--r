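#' shRNA library objects
#'
#' An `shrna_library` is a validated data frame of guide records with one row
#' per shRNA and columns `shrna_id`, `gene`, `guide_seq` and `control_class`,
#' plus a `guide_length` attribute. Guides are the constant-length unique
#' subsequences used for exact-match quantification; `control_class` marks
#' each record as `targeting`, `non_targeting` (no transcript target, expected
#' neutral) or `sentinel_depletion` (targets a gene required for the selected
#' phenotype, expected to drop out).
#'
#' @param records data frame with columns `shrna_id`, `gene`, `guide_seq`,
#'   `control_class`.
#' @return A validated `shrna_library`.
#' @export
shrna_library <- function(records) {
  required <- c("shrna_id", "gene", "guide_seq", "control_class")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)[, required]
  records$shrna_id <- as.character(records$shrna_id)
  records$gene <- as.character(records$gene)
  records$gene[is.na(records$gene)] <- ""
  records$guide_seq <- toupper(as.character(records$guide_seq))
  records$control_class <- as.character(records$control_class)
  validate_library(records)
  rownames(records) <- NULL
  structure(records,
            guide_length = nchar(records$guide_seq[1L]),
            class = c("shrna_library", "data.frame"))
}

validate_library <- function(records) {
  if (nrow(records) == 0L) stop("library is empty")
  dup_id <- records$shrna_id[duplicated(records$shrna_id)]
  if (length(dup_id) > 0L) {
    stop("duplicate shrna_id: ", paste(unique(dup_id), collapse = ", "))
  }
  dup_guide <- records$guide_seq[duplicated(records$guide_seq)]
  if (length(dup_guide) > 0L) {
    offenders <- records$shrna_id[records$guide_seq %in% dup_guide]
    stop("duplicate guide sequence shared by: ",
         paste(offenders, collapse = ", "))
  }
  lens <- unique(nchar(records$guide_seq))
  if (length(lens) != 1L) {
    stop("mixed guide lengths: ", paste(sort(lens), collapse = ", "))
  }
  bad_seq <- grepl("[^ACGT]", records$guide_seq)
  if (any(bad_seq)) {
    stop("guide sequences with non-ACGT characters: ",
         paste(records$shrna_id[bad_seq], collapse = ", "))
  }
  classes <- c("targeting", "non_targeting", "sentinel_depletion")
  bad_class <- !(records$control_class %in% classes)
  if (any(bad_class)) {
    stop("unknown control_class for: ",
         paste(records$shrna_id[bad_class], collapse = ", "))
  }
  nt_with_gene <- records$control_class == "non_targeting" & records$gene != ""
  if (any(nt_with_gene)) {
    stop("non_targeting records must have empty gene: ",
         paste(records$shrna_id[nt_with_gene], collapse = ", "))
  }
  invisible(records)
}

#' Read an shRNA library from TSV or FASTA
#'
#' The canonical format is a tab-separated table with header columns
#' `shrna_id`, `gene`, `guide_seq`, `control_class`. FASTA is accepted for
#' convenience; record ids must encode `shrna_id|gene|control_class` and the
#' sequence is the guide.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"fasta"`.
#' @return An `shrna_library`.
#' @export
read_library <- function(path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (nrow(tab) == 0L) stop("library is empty")
    return(shrna_library(tab))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("library is empty")
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("FASTA ids must encode shrna_id|gene|control_class")
  }
  shrna_library(data.frame(
    shrna_id = vapply(parts, `[`, "", 1L),
    gene = vapply(parts, `[`, "", 2L),
    guide_seq = as.character(seqs),
    control_class = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  ))
}

#' Write an shRNA library to TSV
#'
#' @param library an `shrna_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample manifests
#'
#' A `sample_manifest` maps fixed-length sample barcodes (8 nt by default) to
#' sample ids and roles. Exactly one sample carries the `reference_pool` role:
#' the starting plasmid pool sequenced alongside the liver samples, which is
#' the denominator of every fold change. All other samples are `replicate`s.
#'
#' @param entries data frame with columns `barcode`, `sample_id`, `role`.
#' @param barcode_length expected barcode length (default 8).
#' @return A validated `sample_manifest`.
#' @export
sample_manifest <- function(entries, barcode_length = 8L) {
  required <- c("barcode", "sample_id", "role")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)[, required]
  entries$barcode <- toupper(as.character(entries$barcode))
  entries$sample_id <- as.character(entries$sample_id)
  entries$role <- as.character(entries$role)
  if (nrow(entries) == 0L) stop("manifest is empty")
  bad_len <- nchar(entries$barcode) != barcode_length
  if (any(bad_len)) {
    stop("barcode(s) not of length ", barcode_length, ": ",
         paste(entries$barcode[bad_len], collapse = ", "))
  }
  dup_bc <- entries$barcode[duplicated(entries$barcode)]
  if (length(dup_bc) > 0L) {
    stop("duplicate barcode: ", paste(unique(dup_bc), collapse = ", "))
  }
  dup_id <- entries$sample_id[duplicated(entries$sample_id)]
  if (length(dup_id) > 0L) {
    stop("duplicate sample_id: ", paste(unique(dup_id), collapse = ", "))
  }
  if (!all(entries$role %in% c("reference_pool", "replicate"))) {
    stop("role must be 'reference_pool' or 'replicate'")
  }
  n_pool <- sum(entries$role == "reference_pool")
  if (n_pool != 1L) {
    stop("manifest must have exactly one reference_pool sample, found ", n_pool)
  }
  structure(entries,
            barcode_length = as.integer(barcode_length),
            class = c("sample_manifest", "data.frame"))
}

#' Read a sample manifest from TSV
#'
#' @param path TSV with header columns `barcode`, `sample_id`, `role`.
#' @param barcode_length expected barcode length (default 8).
#' @return A `sample_manifest`.
#' @export
read_manifest <- function(path, barcode_length = 8L) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  sample_manifest(tab, barcode_length = barcode_length)
}

#' Write a sample manifest to TSV
#'
#' @param manifest a `sample_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shRNA library: %d guides (%d nt), %d genes; %d non-targeting, %d sentinel\n",
              nrow(x), attr(x, "guide_length"),
              length(unique(x$gene[x$gene != ""])),
              sum(x$control_class == "non_targeting"),
              sum(x$control_class == "sentinel_depletion")))
  invisible(x)
}

#' @export
print.sample_manifest <- function(x, ...) {
  cat(sprintf("Sample manifest: %d samples (%d replicates + reference pool), %d-nt barcodes\n",
              nrow(x), sum(x$role == "replicate"), attr(x, "barcode_length")))
  invisible(x)
}

pool_sample <- function(manifest) {
  manifest$sample_id[manifest$role == "reference_pool"]
}

replicate_samples <- function(manifest) {
  manifest$sample_id[manifest$role == "replicate"]
}
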