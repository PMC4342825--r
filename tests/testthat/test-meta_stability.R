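make_rpkm_tables <- function() {
  r1 <- rbind(ctrl = c(gA = 15, gB = 30, gC = 40),
              straw = c(gA = 30, gB = 30, gC = 0),
              heat = c(gA = 15, gB = 60, gC = 20))
  r2 <- rbind(ctrl = c(gA = 100, gB = 10, gC = 50),
              infection = c(gA = 100, gB = 20, gC = 50))
  list(ds1 = list(rpkm = r1, control_condition = "ctrl", organism = "fungusA"),
       ds2 = list(rpkm = r2, control_condition = "ctrl", organism = "fungusB"))
}

test_that("fold changes from RPKM are log2 ratios vs the control condition", {
  res <- fold_changes_from_rpkm(make_rpkm_tables())
  expect_equal(nrow(res$fc), 3)  # straw, heat, infection
  expect_equal(res$fc["ds1:straw", "gA"], 1)      # 30 vs 15
  expect_equal(res$fc["ds1:heat", "gA"], 0)       # equal RPKM
  expect_equal(res$fc["ds2:infection", "gB"], 1)  # 20 vs 10
  expect_true(is.na(res$fc["ds1:straw", "gC"]))   # zero RPKM -> missing
  expect_identical(res$row_info$organism, c("fungusA", "fungusA", "fungusB"))

  broken <- make_rpkm_tables()
  broken$ds2$control_condition <- "missing_ctrl"
  expect_error(fold_changes_from_rpkm(broken), "ds2")
})

test_that("swapping interest and control flips the sign of the fold change", {
  t <- make_rpkm_tables()["ds1"]
  fwd <- fold_changes_from_rpkm(t)
  t$ds1$control_condition <- "straw"
  rev_ <- fold_changes_from_rpkm(t)
  expect_equal(rev_$fc["ds1:ctrl", "gA"], -fwd$fc["ds1:straw", "gA"])
})

test_that("candidate pre-selection applies each filter with its reason code", {
  tabs <- list(ds = list(rpkm = rbind(ctrl = c(low = 10, anti = 50, ok = 50,
                                               wild = 50, spliced = 40),
                                      t1 = c(low = 60, anti = 50, ok = 52,
                                             wild = 200, spliced = 40)),
                         control_condition = "ctrl"))
  fc <- fold_changes_from_rpkm(tabs)$fc
  flags <- data.frame(gene = c("anti", "spliced"),
                      antisense = c(TRUE, FALSE),
                      alt_splicing = c(FALSE, TRUE))
  sel <- preselect_candidates(fc, tabs, flags)
  get <- function(g, col) sel[[col]][sel$gene == g]
  expect_identical(get("low", "reason"), "low_expression")  # RPKM 10 < 15
  expect_identical(get("anti", "reason"), "antisense")
  expect_identical(get("spliced", "reason"), "alternative_splicing")
  expect_identical(get("wild", "reason"), "unstable_fc")    # 4-fold change
  expect_true(get("ok", "retained"))
  expect_true(is.na(get("ok", "reason")))
})

test_that("gene fold-change summaries use interpolation quantiles", {
  fc <- cbind(flat = rep(0, 6), mix = c(-1, 0, 1, 2, NA, NA))
  s <- gene_fc_summary(fc)
  expect_equal(s$median[s$gene == "flat"], 0)
  expect_equal(s$iqr[s$gene == "flat"], 0)
  expect_equal(s$mean[s$gene == "flat"], 0)
  expect_equal(s$median[s$gene == "mix"], 0.5)
  expect_equal(s$iqr[s$gene == "mix"], 1.5)
  expect_equal(s$n[s$gene == "mix"], 4L)

  few <- gene_fc_summary(cbind(tiny = c(1, 2, NA, NA)))
  expect_true(few$too_few)
  expect_true(is.na(few$iqr))
})

test_that("normality flag behaves at the test level on normal draws", {
  flags <- vapply(1:50, function(s) {
    set.seed(s)
    fc <- cbind(g = rnorm(500))
    gene_fc_summary(fc)$normal
  }, logical(1))
  expect_gte(mean(flags), 0.9)
  # a clearly bimodal gene is flagged non-normal
  set.seed(1)
  fc <- cbind(g = c(rnorm(250, -3, 0.2), rnorm(250, 3, 0.2)))
  expect_false(gene_fc_summary(fc)$normal)
})

test_that("summaries are invariant to condition (row) order", {
  set.seed(6)
  fc <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("g", 1:5)))
  s1 <- gene_fc_summary(fc)
  s2 <- gene_fc_summary(fc[sample(12), ])
  expect_equal(s1, s2)
})

test_that("Ward clustering recovers planted classes and standardizes inputs", {
  # two (median, IQR) blobs separated by 2 log2 units with 0.1 spread:
  # exact recovery
  two <- simulate_fc_matrix(
    n_genes_per_class = c(8, 8),
    class_params = data.frame(median = c(0, 2), iqr = c(0.5, 2.5)),
    n_conditions = 200, blob_sd = 0.1, seed = 23)
  s2 <- gene_fc_summary(two$fc)
  c2 <- classify_genes(s2, k = 2)
  expect_equal(adjusted_rand_index(c2$classes[s2$gene],
                                   two$truth$class_labels[s2$gene]), 1)

  sim <- simulate_fc_matrix(
    n_genes_per_class = rep(8, 5),
    class_params = data.frame(median = c(-4, -2, 0, 2, 4),
                              iqr = c(0.5, 1.0, 1.5, 2.0, 2.5)),
    n_conditions = 200, blob_sd = 0.1, seed = 23)
  summ <- gene_fc_summary(sim$fc)
  cl <- classify_genes(summ, k = 5)
  expect_gte(adjusted_rand_index(cl$classes[summ$gene],
                                 sim$truth$class_labels[summ$gene]), 0.9)
  expect_false(cl$degenerate)
  # rescaling one input variable changes nothing after standardization
  summ_scaled <- summ
  summ_scaled$iqr <- summ_scaled$iqr * 10
  cl2 <- classify_genes(summ_scaled, k = 5)
  expect_equal(adjusted_rand_index(cl$classes, cl2$classes), 1)
})

test_that("adjusted Rand index agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("identical genes give a flagged degenerate classification", {
  summ <- data.frame(gene = paste0("g", 1:6), median = 0, iqr = 1)
  cl <- classify_genes(summ, k = 3)
  expect_true(cl$degenerate)
  expect_length(unique(cl$classes), 3)  # deterministic arbitrary split
  cl_again <- classify_genes(summ, k = 3)
  expect_identical(cl$classes, cl_again$classes)
  expect_error(classify_genes(summ, k = 7), "exceeds")
})

test_that("the most stable planted class owns the tight near-zero centroid", {
  sim <- simulate_fc_matrix(seed = 41)  # default five-class geometry
  summ <- gene_fc_summary(sim$fc)
  cl <- classify_genes(summ, k = 5)
  cent <- cl$centroids
  best_class <- cent$class[order(abs(cent$median) + cent$iqr)][1]
  truth_best <- names(sim$truth$class_labels)[sim$truth$class_labels == 1]
  got_best <- names(cl$classes)[cl$classes == best_class]
  expect_gte(length(intersect(got_best, truth_best)) /
               length(union(got_best, truth_best)), 0.8)
})

test_that("heat-map clipping saturates at the display bound", {
  fc <- matrix(c(0, 4, log2(12), -5, 1.2, NA), 2, 3)
  hm <- heatmap_matrix(fc)
  expect_equal(hm$matrix[1, 1], 0)              # green anchor preserved
  expect_equal(hm$matrix[2, 1], 3.5)            # log2 FC 4 clips
  expect_equal(hm$matrix[1, 2], 3.5)            # 12-fold clips
  expect_equal(hm$matrix[2, 2], -3.5)
  expect_equal(hm$matrix[1, 3], 1.2)
  expect_true(is.na(hm$matrix[2, 3]))           # missing preserved
  expect_equal(hm$scale$extreme_values, c(-3.5, 3.5))
})
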