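#' Simulator configuration
#'
#' Parameters of the clonal-competition simulator that emulates a pooled
#' shRNA screen in a chimeric liver under repeated damage-regeneration
#' cycles. Defaults describe the emulated experiment: 253 shRNAs, 5
#' biological replicates plus the sequenced starting pool, roughly 10% of
#' hepatocytes carrying a stable integration (only this transduced
#' compartment is modeled, since sequencing sees only integrated cassettes),
#' 24 damage cycles (3 hepatotoxin doses per week for 8 weeks), and deep
#' sequencing at 10^6 reads per sample. The default planted scenario gives
#' one 4-shRNA gene a per-cycle fitness of 1.1, keeps 2 non-targeting
#' controls neutral, and handicaps a 3-shRNA sentinel gene at 0.9.
#'
#' @param n_shrnas library size (default 253).
#' @param n_replicates biological replicates, i.e. mice (default 5).
#' @param n_cells transduced hepatocytes per mouse (default 1e5).
#' @param transduced_fraction fraction of hepatocytes transduced (default
#'   0.10; documentation of the emulated compartment, not used in dynamics).
#' @param n_cycles damage-regeneration cycles (default 24).
#' @param kill_fraction fraction of each clone killed per cycle (default 0.3).
#' @param hit_fitness per-cycle fitness of the planted advantaged shRNAs
#'   (default 1.1).
#' @param sentinel_fitness per-cycle fitness of sentinel shRNAs (default 0.9).
#' @param n_hit_shrnas shRNAs in the planted advantaged gene (default 4).
#' @param n_nontargeting neutral non-targeting controls (default 2).
#' @param n_sentinels shRNAs in the depleting sentinel gene (default 3).
#' @param pool_depth,replicate_depth sequencing reads per sample
#'   (default 1e6 each).
#' @param guide_length guide length in nt (default 22).
#' @param barcode_length sample barcode length in nt (default 8).
#' @param guide_offset 0-based guide offset within emitted reads (default 20:
#'   8 nt barcode + 12 nt constant spacer).
#' @param error_rate per-base substitution rate in emitted reads (default 0).
#' @param mode `"stochastic"` (default) or `"deterministic"` (expected-value
#'   dynamics and largest-remainder sequencing; exists to give closed-form
#'   oracles).
#' @param seed integer seed for all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_shrnas = 253L, n_replicates = 5L, n_cells = 1e5,
                       transduced_fraction = 0.10, n_cycles = 24L,
                       kill_fraction = 0.3, hit_fitness = 1.1,
                       sentinel_fitness = 0.9, n_hit_shrnas = 4L,
                       n_nontargeting = 2L, n_sentinels = 3L,
                       pool_depth = 1e6, replicate_depth = 1e6,
                       guide_length = 22L, barcode_length = 8L,
                       guide_offset = 20L, error_rate = 0,
                       mode = c("stochastic", "deterministic"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(transduced_fraction > 0, transduced_fraction <= 1,
            kill_fraction >= 0, kill_fraction < 1,
            pool_depth > 0, replicate_depth > 0,
            n_shrnas >= n_hit_shrnas + n_nontargeting + n_sentinels,
            guide_offset >= barcode_length)
  structure(list(n_shrnas = as.integer(n_shrnas),
                 n_replicates = as.integer(n_replicates),
                 n_cells = n_cells,
                 transduced_fraction = transduced_fraction,
                 n_cycles = as.integer(n_cycles),
                 kill_fraction = kill_fraction,
                 hit_fitness = hit_fitness,
                 sentinel_fitness = sentinel_fitness,
                 n_hit_shrnas = as.integer(n_hit_shrnas),
                 n_nontargeting = as.integer(n_nontargeting),
                 n_sentinels = as.integer(n_sentinels),
                 pool_depth = pool_depth,
                 replicate_depth = replicate_depth,
                 guide_length = as.integer(guide_length),
                 barcode_length = as.integer(barcode_length),
                 guide_offset = as.integer(guide_offset),
                 error_rate = error_rate,
                 mode = mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

distinct_dna <- function(n, len) {
  out <- unique(random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), len)))
  }
  out
}

#' Build the simulated shRNA library
#'
#' Generates the planted library: one advantaged gene with `n_hit_shrnas`
#' guides, non-targeting controls, one sentinel gene, and background genes
#' carrying 2-4 guides each until `n_shrnas` is reached. Guide sequences are
#' random distinct DNA of `guide_length`; fitness values are attached as the
#' `fitness` attribute (the planted ground truth).
#'
#' @param cfg a `sim_config`. Uses the current RNG state; seed via
#'   [sim_screen()] or `set.seed()`.
#' @return An `shrna_library` with a `fitness` attribute (named numeric).
#' @export
sim_library <- function(cfg) {
  n_special <- cfg$n_hit_shrnas + cfg$n_nontargeting + cfg$n_sentinels
  n_bg <- cfg$n_shrnas - n_special

  bg_sizes <- integer(0)
  cyc <- c(2L, 3L, 4L)
  while (sum(bg_sizes) < n_bg) {
    bg_sizes <- c(bg_sizes, cyc[(length(bg_sizes) %% 3L) + 1L])
  }
  if (sum(bg_sizes) > n_bg) {
    bg_sizes[length(bg_sizes)] <- bg_sizes[length(bg_sizes)] -
      (sum(bg_sizes) - n_bg)
    bg_sizes <- bg_sizes[bg_sizes > 0L]
  }
  bg_genes <- rep(sprintf("gene%03d", seq_along(bg_sizes)), bg_sizes)

  gene <- c(rep("advgene", cfg$n_hit_shrnas),
            rep("", cfg$n_nontargeting),
            rep("Met", cfg$n_sentinels),
            bg_genes)
  class_ <- c(rep("targeting", cfg$n_hit_shrnas),
              rep("non_targeting", cfg$n_nontargeting),
              rep("sentinel_depletion", cfg$n_sentinels),
              rep("targeting", length(bg_genes)))
  shrna_id <- c(sprintf("sh_advgene_%d", seq_len(cfg$n_hit_shrnas)),
                sprintf("shNC_%d", seq_len(cfg$n_nontargeting)),
                sprintf("sh_Met_%d", seq_len(cfg$n_sentinels)),
                paste0("sh_", bg_genes, "_",
                       unlist(lapply(bg_sizes, seq_len))))
  lib <- shrna_library(data.frame(
    shrna_id = shrna_id, gene = gene,
    guide_seq = distinct_dna(cfg$n_shrnas, cfg$guide_length),
    control_class = class_, stringsAsFactors = FALSE))
  fitness <- rep(1, nrow(lib))
  fitness[lib$control_class == "sentinel_depletion"] <- cfg$sentinel_fitness
  fitness[lib$gene == "advgene"] <- cfg$hit_fitness
  attr(lib, "fitness") <- stats::setNames(fitness, lib$shrna_id)
  lib
}

#' Build the simulated sample manifest
#'
#' One reference-pool sample plus `n_replicates` liver replicates, with
#' random distinct barcodes of `barcode_length`.
#'
#' @param cfg a `sim_config`. Uses the current RNG state.
#' @return A `sample_manifest`.
#' @export
sim_manifest <- function(cfg) {
  n <- cfg$n_replicates + 1L
  sample_manifest(data.frame(
    barcode = distinct_dna(n, cfg$barcode_length),
    sample_id = c("pool", sprintf("mouse%d", seq_len(cfg$n_replicates))),
    role = c("reference_pool", rep("replicate", cfg$n_replicates)),
    stringsAsFactors = FALSE), barcode_length = cfg$barcode_length)
}

#' Initialize the transduced clone population of one mouse
#'
#' Distributes `n_cells` transduced hepatocytes over library clones according
#' to the pool frequencies: multinomially in stochastic mode, exactly
#' proportionally in deterministic mode.
#'
#' @param cfg a `sim_config`.
#' @param library an `shrna_library`.
#' @param pool_freq starting pool frequencies (default uniform over guides).
#' @return A `clone_population`: list with `cell_counts` (named numeric) and
#'   `cycle_index`.
#' @export
initialize_population <- function(cfg, library,
                                  pool_freq = rep(1 / nrow(library),
                                                  nrow(library))) {
  stopifnot(length(pool_freq) == nrow(library),
            abs(sum(pool_freq) - 1) < 1e-9)
  cells <- if (cfg$mode == "stochastic") {
    as.double(stats::rmultinom(1L, size = cfg$n_cells, prob = pool_freq))
  } else {
    cfg$n_cells * pool_freq
  }
  structure(list(cell_counts = stats::setNames(cells, library$shrna_id),
                 cycle_index = 0L),
            class = "clone_population")
}

#' Run damage-regeneration cycles on a clone population
#'
#' Each cycle (i) kills `kill_fraction` of every clone's cells -- binomial
#' thinning in stochastic mode, exact scaling in deterministic mode; damage
#' is nonselective -- and (ii) regrows the liver back to its pre-kill total,
#' clone `s` receiving a share proportional to `survivors_s * w_s`, so
#' selection acts at the compensatory-regeneration step. In deterministic
#' mode the dynamics have the closed form
#' `freq_s(c) = freq_s(0) * w_s^c / sum_j freq_j(0) * w_j^c`.
#'
#' @param pop a `clone_population`.
#' @param cfg a `sim_config` carrying `kill_fraction`, `n_cycles`, `mode`
#'   and the fitness scenario.
#' @param fitness named per-shRNA fitness vector (defaults to the `fitness`
#'   attribute planted by [sim_library()], or all 1).
#' @param n_cycles number of cycles to run (default `cfg$n_cycles`).
#' @return The evolved `clone_population`.
#' @export
run_damage_cycles <- function(pop, cfg, fitness = NULL,
                              n_cycles = cfg$n_cycles) {
  cells <- pop$cell_counts
  if (is.null(fitness)) fitness <- rep(1, length(cells))
  if (!is.null(names(fitness))) {
    stopifnot(all(names(cells) %in% names(fitness)))
    fitness <- fitness[names(cells)]
  }
  stopifnot(all(fitness >= 0))
  for (cycle in seq_len(n_cycles)) {
    total <- sum(cells)
    survivors <- if (cfg$mode == "stochastic") {
      stats::rbinom(length(cells), size = round(cells),
                    prob = 1 - cfg$kill_fraction)
    } else {
      cells * (1 - cfg$kill_fraction)
    }
    weight <- survivors * fitness
    if (sum(weight) <= 0) {
      stop("all clones extinct at cycle ", pop$cycle_index + cycle,
           "; increase n_cells or lower kill_fraction")
    }
    cells <- if (cfg$mode == "stochastic") {
      as.double(stats::rmultinom(1L, size = round(total),
                                 prob = weight / sum(weight)))
    } else {
      total * weight / sum(weight)
    }
    names(cells) <- names(pop$cell_counts)
  }
  pop$cell_counts <- cells
  pop$cycle_index <- pop$cycle_index + n_cycles
  pop
}

clone_frequencies <- function(pop) {
  pop$cell_counts / sum(pop$cell_counts)
}

#' Sample sequencing reads from clone frequencies
#'
#' Deep sequencing of the amplicon pool: multinomial with `depth` trials in
#' stochastic mode; in deterministic mode the rounded expectation, with
#' rounding resolved by largest remainder so the counts always sum to
#' `depth`.
#'
#' @param freq frequency vector (sums to 1).
#' @param depth total reads.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return Integer-valued count vector summing to `depth`.
#' @export
sample_sequencing <- function(freq, depth, mode = "stochastic") {
  stopifnot(abs(sum(freq) - 1) < 1e-9, depth >= 0)
  if (depth == 0) return(stats::setNames(rep(0, length(freq)), names(freq)))
  if (mode == "stochastic") {
    return(stats::setNames(
      as.double(stats::rmultinom(1L, size = depth, prob = freq)),
      names(freq)))
  }
  expect <- depth * freq
  base <- floor(expect)
  short <- round(depth - sum(base))
  if (short > 0) {
    extra <- order(expect - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(base, names(freq))
}

#' Emit amplicon FASTQ reads for a counts table
#'
#' Writes one read per count: the sample barcode, a constant spacer up to
#' `guide_offset`, the guide, and a constant 3' filler, all at Phred quality
#' 'I'. Optional uniform per-base substitution errors at `error_rate`. A
#' truth table records the exact emitted composition.
#'
#' @param counts matrix of reads to emit, shRNA ids x sample ids.
#' @param library an `shrna_library`.
#' @param manifest a `sample_manifest` covering the count columns.
#' @param cfg a `sim_config` (layout and `error_rate`).
#' @param path output FASTQ path; `.gz` suffix writes gzip.
#' @return Invisibly, a data frame of the emitted composition
#'   (`shrna_id`, `sample_id`, `reads`).
#' @export
emit_fastq <- function(counts, library, manifest, cfg, path) {
  stopifnot(all(rownames(counts) %in% library$shrna_id),
            all(colnames(counts) %in% manifest$sample_id))
  spacer <- paste(rep("T", cfg$guide_offset - cfg$barcode_length),
                  collapse = "")
  filler <- paste(rep("A", 10L), collapse = "")
  guide <- library$guide_seq[match(rownames(counts), library$shrna_id)]
  barcode <- manifest$barcode[match(colnames(counts), manifest$sample_id)]

  seqs <- character(0)
  truth <- list()
  for (j in seq_len(ncol(counts))) {
    n_per <- counts[, j]
    keep <- n_per > 0
    if (!any(keep)) next
    seqs <- c(seqs, rep(paste0(barcode[j], spacer, guide[keep], filler),
                        times = n_per[keep]))
    truth[[length(truth) + 1L]] <- data.frame(
      shrna_id = rownames(counts)[keep],
      sample_id = colnames(counts)[j],
      reads = as.double(n_per[keep]),
      stringsAsFactors = FALSE)
  }
  if (cfg$error_rate > 0 && length(seqs) > 0L) {
    seqs <- inject_errors(seqs, cfg$error_rate)
  }
  qual <- strrep("I", nchar(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(seqs) > 0L) {
    writeLines(paste0("@read", seq_along(seqs), "\n", seqs, "\n+\n", qual),
               con)
  }
  invisible(if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(shrna_id = character(0), sample_id = character(0),
               reads = double(0)))
}

inject_errors <- function(seqs, error_rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    chars <- strsplit(s, "")[[1L]]
    hit <- stats::runif(length(chars)) < error_rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, "")
    }
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate a full screen
#'
#' End-to-end generator: builds the planted library and manifest, initializes
#' one clone population per mouse, runs the damage-regeneration cycles,
#' sequences the starting pool and every replicate, and returns the counts
#' plus ground truth. With `fastq = TRUE` the reads are additionally emitted
#' as FASTQ so the exact-match quantifier can be exercised end to end.
#'
#' @param cfg a `sim_config`.
#' @param fitness optional named fitness override (default: the planted
#'   scenario from [sim_library()]).
#' @param fastq if `TRUE`, also write FASTQ under `out_dir`.
#' @param out_dir directory for FASTQ/truth output (required when
#'   `fastq = TRUE`).
#' @return List with `library`, `manifest`, `counts` (a `count_matrix`),
#'   `truth` (fitness, final clone frequencies per replicate, pool
#'   frequencies) and, when written, `fastq` (path).
#' @export
sim_screen <- function(cfg = sim_config(), fitness = NULL, fastq = FALSE,
                       out_dir = NULL) {
  set.seed(cfg$seed)
  library <- sim_library(cfg)
  manifest <- sim_manifest(cfg)
  if (is.null(fitness)) fitness <- attr(library, "fitness")

  pool_freq <- rep(1 / nrow(library), nrow(library))
  pool_counts <- sample_sequencing(
    stats::setNames(pool_freq, library$shrna_id),
    cfg$pool_depth, cfg$mode)

  rep_freqs <- matrix(NA_real_, nrow(library), cfg$n_replicates,
                      dimnames = list(library$shrna_id,
                                      replicate_samples(manifest)))
  counts <- matrix(0, nrow(library), nrow(manifest),
                   dimnames = list(library$shrna_id, manifest$sample_id))
  counts[, pool_sample(manifest)] <- pool_counts
  for (r in replicate_samples(manifest)) {
    pop <- initialize_population(cfg, library, pool_freq)
    pop <- run_damage_cycles(pop, cfg, fitness = fitness)
    rep_freqs[, r] <- clone_frequencies(pop)
    counts[, r] <- sample_sequencing(clone_frequencies(pop),
                                     cfg$replicate_depth, cfg$mode)
  }

  cm <- count_matrix(counts)
  out <- list(library = library, manifest = manifest, counts = cm,
              truth = list(fitness = fitness, pool_freq = pool_freq,
                           replicate_freqs = rep_freqs))
  if (fastq) {
    if (is.null(out_dir)) stop("out_dir required when fastq = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq <- file.path(out_dir, "reads.fastq.gz")
    emitted <- emit_fastq(counts, library, manifest, cfg, fq)
    write_library(library, file.path(out_dir, "library.tsv"))
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    utils::write.table(
      data.frame(shrna_id = library$shrna_id,
                 fitness = unname(fitness[library$shrna_id]),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    out$fastq <- fq
    out$emitted <- emitted
  }
  out
}

#' Closed-form deterministic enrichment
#'
#' Expected final clone frequencies after `c` cycles of deterministic
#' selection: `freq_s(c) = freq_s(0) * w_s^c / sum_j freq_j(0) * w_j^c`.
#' Used as the independent oracle for the pipeline's measured fold changes.
#'
#' @param freq0 starting frequencies.
#' @param fitness per-clone fitness.
#' @param n_cycles number of cycles.
#' @return Frequency vector after selection.
#' @export
closed_form_frequencies <- function(freq0, fitness, n_cycles) {
  w <- freq0 * fitness^n_cycles
  w / sum(w)
}
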