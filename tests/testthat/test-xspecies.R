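test_that("count prefilter removes genes with mean raw count below ten, boundary retained", {
  counts <- rbind(at_nine  = c(9, 9, 9, 9),
                  at_ten   = c(10, 10, 10, 10),
                  at_9.9   = c(9, 10, 10, 10.6),  # mean 9.9
                  high     = c(100, 0, 0, 0))     # mean 25
  kept <- prefilter_counts(counts, min_mean = 10)
  expect_equal(rownames(kept), c("at_ten", "high"))

  empty <- counts[0, , drop = FALSE]
  expect_equal(nrow(prefilter_counts(empty)), 0L)
  expect_error(prefilter_counts(counts[, 0, drop = FALSE]), "zero samples")
})

test_that("DEG filter applies strict inequalities on significance and fold change", {
  de <- data.frame(
    gene = c("kept_up", "lfc_at_cut", "not_sig", "kept_down", "na_padj"),
    log2fc = c(1.5, 1.0, 3.0, -2.0, 2.0),
    pvalue = c(0.01, 0.01, 0.04, 0.001, 0.01),
    padj = c(0.05, 0.05, 0.2, 0.02, NA),
    stringsAsFactors = FALSE)
  sig <- filter_deg(de, alpha = 0.1, lfc_cut = 1, use_padj = TRUE)
  expect_equal(sig$gene, c("kept_up", "kept_down"))
  expect_equal(sig$direction, c("up", "down"))

  # padj exactly at alpha is dropped (strict <)
  at_alpha <- data.frame(gene = "g", log2fc = 2, pvalue = 0.01, padj = 0.1)
  expect_equal(nrow(filter_deg(at_alpha, alpha = 0.1)), 0L)

  # raw-p variant keeps what the padj variant drops
  sig_p <- filter_deg(de, alpha = 0.05, lfc_cut = 1, use_padj = FALSE)
  expect_true("not_sig" %in% sig_p$gene)

  no_padj <- de[, c("gene", "log2fc", "pvalue")]
  expect_error(filter_deg(no_padj, use_padj = TRUE), "padj")
  expect_silent(filter_deg(no_padj, use_padj = FALSE))
})

test_that("DEG filtering is idempotent", {
  set.seed(14)
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   log2fc = rnorm(200, 0, 2),
                   pvalue = runif(200),
                   padj = runif(200),
                   stringsAsFactors = FALSE)
  once <- filter_deg(de)
  twice <- filter_deg(once)
  expect_equal(twice, once)
})

test_that("ortholog overlap keeps concordant pairs and reports discordant ones", {
  m_sig <- data.frame(gene = c("Lrp8", "Dusp4", "Plat"),
                      log2fc = c(2, 1.5, -2), pvalue = 0.01, padj = 0.01,
                      direction = c("up", "up", "down"),
                      stringsAsFactors = FALSE)
  h_sig <- data.frame(gene = c("LRP8", "DUSP4", "PLAT"),
                      log2fc = c(1.8, -1.5, -2.5), pvalue = 0.01, padj = 0.01,
                      direction = c("up", "down", "down"),
                      stringsAsFactors = FALSE)
  map <- data.frame(mouse_symbol = c("Lrp8", "Dusp4", "Plat", "Slc7a5"),
                    human_symbol = c("LRP8", "DUSP4", "PLAT", "SLC7A5"),
                    stringsAsFactors = FALSE)
  ov <- overlap_orthologs(m_sig, h_sig, map)
  expect_equal(ov$n_overlap, 2L)
  expect_equal(ov$n_up, 1L)
  expect_equal(ov$n_down, 1L)
  expect_equal(ov$n_overlap, ov$n_up + ov$n_down)
  expect_equal(ov$discordant$mouse_symbol, "Dusp4")
  expect_true(all(paste(ov$overlapping_genes$mouse_symbol,
                        ov$overlapping_genes$human_symbol) %in%
                    paste(map$mouse_symbol, map$human_symbol)))
})

test_that("many-to-many orthology collapses to one pair per mouse gene", {
  m_sig <- data.frame(gene = "Gna12", log2fc = 2, pvalue = 0.01,
                      padj = 0.01, direction = "up",
                      stringsAsFactors = FALSE)
  h_sig <- data.frame(gene = c("GNA12B", "GNA12A"), log2fc = c(2, 2),
                      pvalue = 0.01, padj = 0.01,
                      direction = c("up", "up"), stringsAsFactors = FALSE)
  map <- data.frame(mouse_symbol = c("Gna12", "Gna12"),
                    human_symbol = c("GNA12B", "GNA12A"),
                    stringsAsFactors = FALSE)
  ov <- overlap_orthologs(m_sig, h_sig, map)
  expect_equal(ov$n_overlap, 1L)
  expect_equal(ov$overlapping_genes$human_symbol, "GNA12A")
  expect_true(ov$overlapping_genes$collapsed)
})

test_that("synthetic DE tables recover the planted overlap structure exactly", {
  for (seed in c(1, 7, 19)) {
    de <- generate_synthetic_de(seed = seed)
    ov <- overlap_orthologs(filter_deg(de$mouse), filter_deg(de$human),
                            de$map)
    expect_equal(ov$n_overlap, 108L)
    expect_equal(ov$n_up, 25L)
    expect_equal(ov$n_down, 83L)
    planted <- de$truth[de$truth$class %in% c("up_concordant",
                                              "down_concordant"), ]
    expect_setequal(ov$overlapping_genes$mouse_symbol,
                    planted$mouse_symbol)
    # raw-p threshold variant recovers the same planted structure
    ov_p <- overlap_orthologs(
      filter_deg(de$mouse, alpha = 0.05, use_padj = FALSE),
      filter_deg(de$human, alpha = 0.05, use_padj = FALSE), de$map)
    expect_equal(c(ov_p$n_overlap, ov_p$n_up, ov_p$n_down),
                 c(108L, 25L, 83L))
  }

  # empty planting gives an empty overlap
  de0 <- generate_synthetic_de(n_up_concordant = 0, n_down_concordant = 0,
                               seed = 2)
  ov0 <- overlap_orthologs(filter_deg(de0$mouse), filter_deg(de0$human),
                           de0$map)
  expect_equal(ov0$n_overlap, 0L)

  # same seed twice gives identical tables
  expect_identical(generate_synthetic_de(seed = 5),
                   generate_synthetic_de(seed = 5))
})

test_that("overlap is symmetric under species swap", {
  de <- generate_synthetic_de(seed = 9)
  m_sig <- filter_deg(de$mouse)
  h_sig <- filter_deg(de$human)
  fwd <- overlap_orthologs(m_sig, h_sig, de$map)
  rev_map <- data.frame(mouse_symbol = de$map$human_symbol,
                        human_symbol = de$map$mouse_symbol,
                        stringsAsFactors = FALSE)
  bwd <- overlap_orthologs(h_sig, m_sig, rev_map)
  expect_equal(bwd$n_overlap, fwd$n_overlap)
  expect_equal(bwd$n_up, fwd$n_up)
  expect_equal(bwd$n_down, fwd$n_down)
})

test_that("overlap is monotone non-increasing as thresholds tighten", {
  de <- generate_synthetic_de(seed = 13)
  n_at <- function(alpha, cut) {
    overlap_orthologs(filter_deg(de$mouse, alpha = alpha, lfc_cut = cut),
                      filter_deg(de$human, alpha = alpha, lfc_cut = cut),
                      de$map)$n_overlap
  }
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  expect_true(all(diff(sapply(alphas, n_at, cut = 1)) <= 0))
  cuts <- c(0.5, 1, 1.5, 2.5)
  expect_true(all(diff(sapply(cuts, function(ct) n_at(0.1, ct))) <= 0))
})
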