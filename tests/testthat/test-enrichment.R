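test_that("hypergeometric enrichment matches exhaustive tail sums", {
  pop <- sprintf("g%02d", 1:20)
  tm <- data.frame(feature_id = pop[1:5], term_id = "T1")
  study <- pop[c(1:4, 6:9)]            # k = 4 of K = 5, n = 8, N = 20
  res <- hypergeom_enrich(study, pop, tm)
  expect_equal(res$k, 4)
  expect_equal(res$K, 5)
  expect_equal(res$p, 7280 / 125970, tolerance = 1e-12)
  expect_equal(res$rich_factor, 4 / 5)

  # k = 0 spans the whole support
  res0 <- hypergeom_enrich(pop[6:9], pop, tm)
  expect_equal(res0$p, 1)
  # K = N forces the study into the term
  tm_all <- data.frame(feature_id = pop, term_id = "ALL")
  expect_equal(hypergeom_enrich(study, pop, tm_all)$p, 1)
  expect_error(hypergeom_enrich(c(pop[1], "zz"), pop, tm), "subset")

  set.seed(4)
  for (i in 1:15) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    pop_i <- sprintf("x%03d", 1:N)
    tm_i <- data.frame(feature_id = pop_i[1:K], term_id = "T")
    st_i <- sample(pop_i, n)
    k <- length(intersect(st_i, pop_i[1:K]))
    expect_equal(hypergeom_enrich(st_i, pop_i, tm_i)$p,
                 bf_hyper_tail(k, N, K, n), tolerance = 1e-10)
  }
})

test_that("length weights recover planted bias and stay flat under the null", {
  set.seed(5)
  n <- 5000
  len <- exp(runif(n, log(300), log(8000)))
  # null: DE independent of length
  de0 <- runif(n) < 0.1
  w0 <- length_weights(len, de0)
  expect_equal(mean(w0), 1, tolerance = 1e-12)
  expect_lt(max(abs(w0 - 1)), 0.1 / mean(de0) * 0.1 + 0.6) # loose cap
  expect_lt(diff(range(tapply(w0, cut(len, 5), mean))), 0.35)
  # planted: P(DE) strictly increasing in length
  p_de <- (rank(len) / n) * 0.4
  de1 <- runif(n) < p_de
  w1 <- length_weights(len, de1)
  o <- order(len)
  expect_true(all(diff(w1[o]) >= -1e-12))        # monotone step function
  expect_gt(cor(w1, len, method = "spearman"), 0.9)
  # degenerate cases collapse to unit weights
  expect_equal(length_weights(len, rep(TRUE, n)), rep(1, n))
  expect_equal(length_weights(len, de1, n_bins = 1), rep(1, n))
})

test_that("Wallenius pmf is exact against enumeration and reduces centrally", {
  for (urn in list(c(10, 4, 3), c(8, 5, 4), c(12, 6, 5), c(7, 2, 6))) {
    N <- urn[1]; K <- urn[2]; n <- urn[3]
    for (w in c(0.5, 1, 2, 3.7)) {
      pmf <- wallenius_pmf(N, K, n, w)
      expect_equal(sum(pmf), 1, tolerance = 1e-12)
      expect_true(all(pmf >= 0))
      expect_equal(pmf, bf_wallenius_pmf(N, K, n, w), tolerance = 1e-12)
    }
    # w = 1 is the central hypergeometric
    ks <- 0:min(n, K)
    expect_equal(unname(wallenius_pmf(N, K, n, 1)),
                 dhyper(ks, K, N - K, n), tolerance = 1e-10)
    expect_equal(wallenius_tail(2, N, K, n, 1),
                 phyper(1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # E[k] increases with w
  means <- sapply(c(0.5, 1, 2, 4), function(w) {
    pmf <- wallenius_pmf(10, 4, 3, w)
    sum(as.integer(names(pmf)) * pmf)
  })
  expect_true(all(diff(means) > 0))
})

test_that("Wallenius pmf agrees with weighted urn sampling", {
  # R's sample() draws sequentially with probability proportional to the
  # remaining weights -- precisely the Wallenius urn process
  N <- 12; K <- 5; n <- 6
  is_succ <- c(rep(TRUE, K), rep(FALSE, N - K))
  set.seed(31)
  for (w in c(0.5, 1, 2)) {
    wt <- ifelse(is_succ, w, 1)
    draws <- replicate(20000, sum(is_succ[sample.int(N, n, prob = wt)]))
    pmf <- wallenius_pmf(N, K, n, w)
    for (k in 0:min(n, K)) {
      p_k <- pmf[as.character(k)]
      obs <- mean(draws == k)
      se <- sqrt(p_k * (1 - p_k) / length(draws))
      expect_lt(abs(obs - p_k), 3 * se + 1e-9)
    }
  }
})

test_that("Wallenius enrichment generalizes the central test", {
  pop <- sprintf("g%03d", 1:40)
  tm <- data.frame(feature_id = pop[1:8], term_id = "T1")
  study <- pop[c(1:5, 20:28)]
  unit <- setNames(rep(1, 40), pop)
  expect_equal(wallenius_enrich(study, pop, tm, unit)$p,
               hypergeom_enrich(study, pop, tm)$p, tolerance = 1e-10)
  # biased weights shift the p-value in the expected direction: if term
  # genes were easier to sample anyway (w > 1), the same k is less surprising
  biased <- unit; biased[1:8] <- 3
  expect_gt(wallenius_enrich(study, pop, tm, biased)$p,
            hypergeom_enrich(study, pop, tm)$p)
  expect_error(wallenius_enrich(study, pop, tm, unit[-1]), "one per")
})

test_that("a strongly enriched planted term ranks first", {
  set.seed(17)
  n <- 1000
  pop <- sprintf("g%04d", 1:n)
  term_members <- pop[1:50]
  tm <- rbind(data.frame(feature_id = term_members, term_id = "PLANTED"),
              do.call(rbind, lapply(1:10, function(t)
                data.frame(feature_id = sample(pop, 50),
                           term_id = sprintf("BG%02d", t)))))
  first <- logical(50)
  for (s in 1:50) {
    rr <- ifelse(pop %in% term_members, 5, 1)  # relative risk 5
    study <- pop[runif(n) < 0.05 * rr]
    res <- hypergeom_enrich(study, pop, tm)
    first[s] <- res$term_id[1] == "PLANTED"
  }
  expect_gte(mean(first), 0.95)
})
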