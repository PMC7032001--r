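test_that("FPKM matches its definition", {
  m <- matrix(c(0L, 200L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  f <- compute_fpkm(m, lengths = c(1000, 2000), library_sizes = 2e6)
  expect_equal(f["a", 1], 0)
  expect_equal(f["b", 1], 50)

  set.seed(1)
  counts <- matrix(rpois(60, 40), 10, 6)
  lens <- sample(200:3000, 10)
  libs <- sample(1e6:5e6, 6)
  expect_equal(compute_fpkm(counts, lens, libs),
               bf_fpkm(counts, lens, libs), tolerance = 1e-12)

  expect_equal(compute_fpkm(counts, lens, libs * 2),
               compute_fpkm(counts, lens, libs) / 2, tolerance = 1e-12)
  expect_error(compute_fpkm(counts, rep(0, 10), libs), "positive")
})

test_that("condition means average replicates and respect the design", {
  design <- data.frame(sample_id = c("s1", "s2", "s3"),
                       genotype = "tolerant", treatment = "DS",
                       replicate = 1:3)
  expr <- matrix(c(4, 6, 8), 1, 3, dimnames = list("g", design$sample_id))
  expect_equal(unname(condition_means(expr, design)[1, 1]), 6)
  # permuting samples leaves the mean unchanged
  perm <- c("s3", "s1", "s2")
  expect_equal(condition_means(expr[, perm, drop = FALSE],
                               design[match(perm, design$sample_id), ]),
               condition_means(expr, design))
  # single replicate is its own mean
  expect_equal(unname(condition_means(expr[, 1, drop = FALSE],
                                      design[1, ])[1, 1]), 4)
  # empty cell errors
  bad <- rbind(design, data.frame(sample_id = "s4", genotype = "tolerant",
                                  treatment = "RW", replicate = 1))
  expect_error(condition_means(expr, bad), "missing")
})

test_that("log2 ratio handles the pseudo-expression and degenerate cases", {
  expect_equal(log2_ratio(8, 2, epsilon = 0), 2)
  expect_equal(log2_ratio(0, 0, epsilon = 0.1), 0)
  expect_equal(log2_ratio(8, 2, epsilon = 0.1), log2(8.1 / 2.1))
  expect_equal(log2_ratio(0, 0, epsilon = 0), 0)
  expect_identical(log2_ratio(4, 0, epsilon = 0), Inf)
  expect_error(log2_ratio(-1, 2), ">= 0")
})

test_that("the NB Wald test behaves at its boundary cases", {
  sizes <- rep(1e6, 3)
  expect_equal(nb_test(c(10, 12, 11), c(10, 12, 11), sizes, sizes)$p, 1)
  strong <- nb_test(c(10, 12, 11), c(100, 110, 105), sizes, sizes)
  expect_lt(strong$p, 0.01)
  # two-sidedness: swapping groups leaves p unchanged
  expect_equal(nb_test(c(100, 110, 105), c(10, 12, 11), sizes, sizes)$p,
               strong$p, tolerance = 1e-12)
  allzero <- nb_test(c(0, 0, 0), c(0, 0, 0), sizes, sizes)
  expect_equal(allzero$p, 1)
  expect_true(allzero$degenerate)
  expect_error(nb_test(c(1, 2), c(3), c(1, 1), c(1)), "2 replicates")
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_identical(bh_adjust(numeric(0)), numeric(0))

  # exhaustive-definition oracle on all permutations of small p sets
  base_p <- c(0.001, 0.02, 0.04, 0.2, 0.6, 0.9)
  perms <- list(base_p, rev(base_p), base_p[c(3, 1, 5, 2, 6, 4)],
                c(0.5, 0.5, 0.01), c(0.2, 0.04, 0.9, 0.04))
  for (p in perms) {
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
  }
})

test_that("DE calls respect both thresholds and partition the features", {
  st <- test_study()
  de <- de_by_biotype(st, "tolerant")$all
  expect_setequal(de$call, c("up", "down", "not_de"))
  expect_equal(sum(de$call == "up") + sum(de$call == "down") +
                 sum(de$call == "not_de"), nrow(st$counts))
  up <- de[de$call == "up", ]
  dn <- de[de$call == "down", ]
  expect_true(all(up$q <= 0.05 & up$log2_ratio >= 1))
  expect_true(all(dn$q <= 0.05 & dn$log2_ratio <= -1))
  # features failing either threshold stay not_de
  near <- de[de$call == "not_de" & !de$degenerate, ]
  expect_true(all(near$q > 0.05 | abs(near$log2_ratio) < 1))
  expect_error(call_de(st$counts, st$design, "unknown",
                       setNames(st$annotation$length,
                                st$annotation$feature_id)),
               "unknown genotype")
})

test_that("planted DE features are recovered on the synthetic study", {
  st <- test_study()
  for (g in c("tolerant", "sensitive")) {
    de <- de_by_biotype(st, g)$all
    truth <- st$truth[st$truth$genotype == g, ]
    called <- de$feature_id[de$call != "not_de"]
    recall <- mean(truth$feature_id[truth$is_de] %in% called)
    expect_gt(recall, 0.85)
    # direction agrees with the planted sign for recovered features
    hits <- de[de$call != "not_de" &
                 de$feature_id %in% truth$feature_id[truth$is_de], ]
    planted_sign <- sign(truth$true_log2fc[match(hits$feature_id,
                                                 truth$feature_id)])
    expect_gt(mean(ifelse(hits$call == "up", 1, -1) == planted_sign), 0.99)
  }
})

test_that("genotype comparison partitions DE sets exactly", {
  mk <- function(ids, calls, universe) {
    data.frame(feature_id = universe,
               call = calls[match(universe, ids)] |>
                 (\(x) ifelse(is.na(x), "not_de", x))())
  }
  uni <- c("f1", "f2", "f3", "f4")
  a <- mk(c("f1", "f2"), c("up", "down"), uni)
  b <- mk(c("f1", "f2", "f3"), c("up", "up", "down"), uni)
  cmp <- compare_genotypes(a, b)
  expect_equal(cmp$classes$shared_up, "f1")
  expect_equal(cmp$classes$down_A_up_B, "f2")
  expect_equal(cmp$classes$B_only, "f3")
  expect_length(cmp$classes$A_only, 0)

  # identical inputs: everything shared, converse classes empty
  cmp2 <- compare_genotypes(a, a)
  expect_equal(cmp2$counts[["shared_total"]], 2)
  expect_equal(cmp2$counts[["up_A_down_B"]], 0)
  expect_equal(cmp2$counts[["down_A_up_B"]], 0)

  # disjoint DE sets: all shared classes empty
  c1 <- mk("f1", "up", uni); c2 <- mk("f2", "down", uni)
  cmp3 <- compare_genotypes(c1, c2)
  expect_equal(cmp3$counts[["shared_total"]], 0)

  # partition identity on a real study: class sizes rebuild |A| and |B|
  st <- test_study()
  da <- de_by_biotype(st, "tolerant")$lnc
  db <- de_by_biotype(st, "sensitive")$lnc
  cmp4 <- compare_genotypes(da, db)
  n <- cmp4$counts
  shared <- n[["shared_up"]] + n[["shared_down"]] +
    n[["up_A_down_B"]] + n[["down_A_up_B"]]
  expect_equal(shared, n[["shared_total"]])
  expect_equal(n[["A_only"]] + shared, n[["A_total"]])
  expect_equal(n[["B_only"]] + shared, n[["B_total"]])
})
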