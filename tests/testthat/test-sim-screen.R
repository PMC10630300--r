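test_that("population initialization splits cells by pool frequency", {
  set.seed(2)
  cfg <- sim_config(n_shrnas = 10L, n_cells = 100, mode = "deterministic")
  lib <- sim_library(cfg)

  two <- sim_config(n_shrnas = 10L, n_cells = 100, mode = "deterministic")
  pop <- initialize_population(two, lib,
                               pool_freq = c(0.5, 0.5, rep(0, 8)))
  expect_equal(unname(pop$cell_counts[1:2]), c(50, 50))

  skewed <- initialize_population(
    sim_config(n_shrnas = 10L, n_cells = 1000, mode = "deterministic"), lib,
    pool_freq = c(0.9, 0.1, rep(0, 8)))
  expect_equal(unname(skewed$cell_counts[1:2]), c(900, 100))

  # stochastic mode is reproducible under a fixed seed
  stoch_cfg <- sim_config(n_shrnas = 10L, n_cells = 1000)
  set.seed(33); a <- initialize_population(stoch_cfg, lib)
  set.seed(33); b <- initialize_population(stoch_cfg, lib)
  expect_identical(a$cell_counts, b$cell_counts)
  expect_equal(sum(a$cell_counts), 1000)
})

test_that("deterministic cycles follow the closed form freq0 * w^c", {
  set.seed(4)
  cfg <- sim_config(n_shrnas = 6L, n_hit_shrnas = 2L, n_nontargeting = 1L,
                    n_sentinels = 1L, n_cells = 1e4, n_cycles = 1L,
                    kill_fraction = 0.3, mode = "deterministic")
  lib <- sim_library(cfg)

  # 2 clones at 0.5/0.5 with w = (2, 1): one cycle -> (2/3, 1/3)
  pop <- initialize_population(cfg, lib, c(0.5, 0.5, rep(0, 4)))
  w <- stats::setNames(c(2, 1, 1, 1, 1, 1), lib$shrna_id)
  pop1 <- run_damage_cycles(pop, cfg, fitness = w, n_cycles = 1L)
  f <- pop1$cell_counts / sum(pop1$cell_counts)
  expect_equal(unname(f[1:2]), c(2 / 3, 1 / 3), tolerance = 1e-12)

  # neutrality: w = 1 leaves frequencies unchanged over many cycles
  popn <- run_damage_cycles(pop, cfg, fitness = NULL, n_cycles = 15L)
  expect_equal(popn$cell_counts / sum(popn$cell_counts),
               pop$cell_counts / sum(pop$cell_counts), tolerance = 1e-12)

  # general closed form over random fitness, checked to 1e-12
  freq0 <- c(0.3, 0.25, 0.2, 0.15, 0.07, 0.03)
  wr <- stats::setNames(c(1.2, 1.1, 1.0, 0.95, 0.9, 1.05), lib$shrna_id)
  for (cycles in c(1L, 5L, 24L)) {
    p <- initialize_population(cfg, lib, freq0)
    p <- run_damage_cycles(p, cfg, fitness = wr, n_cycles = cycles)
    expect_equal(unname(p$cell_counts / sum(p$cell_counts)),
                 unname(closed_form_frequencies(freq0, unname(wr), cycles)),
                 tolerance = 1e-12)
  }
})

test_that("extinction of all clones raises an advisory error", {
  set.seed(6)
  cfg <- sim_config(n_shrnas = 6L, n_hit_shrnas = 2L, n_nontargeting = 1L,
                    n_sentinels = 1L, n_cells = 3, kill_fraction = 0.99,
                    mode = "stochastic")
  lib <- sim_library(cfg)
  pop <- initialize_population(cfg, lib)
  expect_error(run_damage_cycles(pop, cfg, n_cycles = 50L),
               "extinct.*n_cells")
})

test_that("sequencing sampling conserves depth in both modes", {
  expect_equal(unname(sample_sequencing(c(0.5, 0.5), 10, "deterministic")),
               c(5, 5))
  expect_equal(sum(sample_sequencing(c(0.3, 0.3, 0.4), 0, "stochastic")),
               0)
  # largest-remainder rounding sums exactly to depth
  set.seed(8)
  for (i in 1:10) {
    f <- runif(20); f <- f / sum(f)
    depth <- sample(c(97, 1000, 12345), 1)
    cts <- sample_sequencing(f, depth, "deterministic")
    expect_equal(sum(cts), depth)
    expect_true(all(abs(cts - depth * f) <= 1))
  }
  set.seed(12); a <- sample_sequencing(rep(0.1, 10), 1e4, "stochastic")
  set.seed(12); b <- sample_sequencing(rep(0.1, 10), 1e4, "stochastic")
  expect_identical(a, b)
  expect_equal(sum(a), 1e4)
})

test_that("emitted FASTQ round-trips exactly through the quantifier", {
  cfg <- sim_config(n_shrnas = 12L, n_replicates = 2L, seed = 5,
                    pool_depth = 300, replicate_depth = 300,
                    n_cells = 1e4, n_cycles = 4L)
  out <- withr::local_tempdir()
  sim <- sim_screen(cfg, fastq = TRUE, out_dir = out)
  cm <- count_shrnas(sim$fastq, sim$library, sim$manifest,
                     guide_offset = cfg$guide_offset)
  expect_identical(cm$counts, sim$counts$counts)
  expect_equal(sum(cm$unassigned) + cm$undemuxed, 0)

  # truth and library files land next to the reads
  expect_true(file.exists(file.path(out, "library.tsv")))
  expect_true(file.exists(file.path(out, "truth.tsv")))
  lib2 <- read_library(file.path(out, "library.tsv"))
  expect_equal(nrow(lib2), 12L)
})

test_that("error_rate 1 makes every read unassignable under exact matching", {
  cfg <- sim_config(n_shrnas = 8L, n_hit_shrnas = 2L, n_nontargeting = 1L,
                    n_sentinels = 1L, n_replicates = 1L, seed = 5,
                    pool_depth = 50, replicate_depth = 50,
                    n_cells = 1e3, n_cycles = 2L, error_rate = 1)
  out <- withr::local_tempdir()
  sim <- sim_screen(cfg, fastq = TRUE, out_dir = out)
  cm <- count_shrnas(sim$fastq, sim$library, sim$manifest,
                     guide_offset = cfg$guide_offset)
  expect_equal(sum(cm$counts), 0)
  expect_equal(sum(cm$unassigned) + cm$undemuxed, 100)
})

test_that("neutral screens yield near-zero mean lfc up to clonal drift", {
  # with expected-value dynamics the only perturbations are sequencing
  # rounding and the pseudocount: mean lfc is essentially zero
  cfg_det <- sim_config(mode = "deterministic", seed = 1)
  sim_det <- sim_screen(cfg_det, fitness = rep(1, cfg_det$n_shrnas))
  res_det <- screen_pipeline(sim_det$counts, sim_det$library,
                             sim_det$manifest)
  expect_lt(max(abs(res_det$fold_changes$mean_lfc)), 1e-3)

  # stochastic screens at the default population size carry a small negative
  # compositional bias (Jensen effect of genetic drift over 24 cycles);
  # it shrinks towards zero as the per-mouse population grows
  drift_mean <- function(n_cells, seeds) {
    sapply(seeds, function(s) {
      cfg <- sim_config(n_cells = n_cells, seed = 100 + s)
      sim <- sim_screen(cfg, fitness = rep(1, cfg$n_shrnas))
      res <- screen_pipeline(sim$counts, sim$library, sim$manifest)
      mean(res$fold_changes$mean_lfc)
    })
  }
  default_bias <- drift_mean(1e5, 1:3)
  expect_true(all(default_bias < 0))
  expect_true(all(abs(default_bias) < 0.15))
  big_pop <- drift_mean(1e6, 1:3)
  expect_true(all(abs(big_pop) < 0.02))
  expect_lt(mean(abs(big_pop)), mean(abs(default_bias)))
})

test_that("higher planted fitness always yields higher measured mean lfc", {
  # graded distinct fitness values (no ties): rank agreement is near-perfect
  cfg <- sim_config(seed = 77)
  set.seed(77)
  graded <- seq(0.9, 1.1, length.out = cfg$n_shrnas)
  sim <- sim_screen(cfg, fitness = graded)
  res <- screen_pipeline(sim$counts, sim$library, sim$manifest)
  rho <- cor(log2(graded), res$fold_changes$mean_lfc, method = "spearman")
  expect_gt(rho, 0.95)

  # default planted scenario: the three fitness groups separate cleanly
  sim_d <- sim_screen(sim_config(seed = 78))
  res_d <- screen_pipeline(sim_d$counts, sim_d$library, sim_d$manifest)
  lfc <- res_d$fold_changes$mean_lfc
  lib <- sim_d$library
  adv <- lfc[lib$gene == "advgene"]
  sent <- lfc[lib$control_class == "sentinel_depletion"]
  neut <- lfc[lib$gene != "advgene" &
                lib$control_class != "sentinel_depletion"]
  expect_gt(min(adv), max(neut))
  expect_lt(max(sent), min(neut))
})

test_that("fixed seeds reproduce the stochastic screen exactly", {
  a <- sim_screen(sim_config(seed = 31))
  b <- sim_screen(sim_config(seed = 31))
  expect_identical(a$counts$counts, b$counts$counts)
  c <- sim_screen(sim_config(seed = 32))
  expect_false(identical(a$counts$counts, c$counts$counts))
})
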