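test_that("pi matches hand-computed single-site values", {
  # one site, n = 4 copies, k = 2: 2*2*2/(4*3) / 10
  m <- geno_matrix("c", 1L, "A", "T", matrix(c(1L, 1L), 1, 2),
                   c("s1", "s2"))
  pm <- pop_map(c("s1", "s2"), c("p", "p"))
  expect_equal(pi_window(m, 1L, "p", pm, 10), (2 * 2 * 2) / (4 * 3) / 10)
  # two singleton sites at n = 4, denominator 100
  m2 <- geno_matrix(c("c", "c"), 1:2, c("A", "A"), c("T", "T"),
                    matrix(c(1L, 0L, 1L, 0L), 2, 2, byrow = TRUE),
                    c("s1", "s2"))
  expect_equal(pi_window(m2, 1:2, "p", pm, 100), 2 * (2 * 3 / 12) / 100)
  # no variant sites
  expect_equal(pi_window(m, integer(0), "p", pm, 10000), 0)
})

test_that("pi equals the brute-force mean pairwise difference oracle", {
  for (seed in 1:5) {
    toy <- toy_matrix(n_sites = 10, n_per_pop = 4, seed = seed,
                      miss_prob = 0.15)
    g <- toy$matrix$geno[, 1:4, drop = FALSE]
    expect_equal(
      pi_window(toy$matrix, 1:10, "popA", toy$popmap, 1),
      oracle_pi_sum(g), tolerance = 1e-12)
  }
})

test_that("Tajima constants match their defining sums", {
  cst <- tajima_constants(10)
  expect_equal(cst$a1, sum(1 / (1:9)), tolerance = 1e-12)
  expect_equal(cst$a1, 2.828968, tolerance = 1e-6)
  expect_equal(cst$a2, sum(1 / (1:9)^2), tolerance = 1e-12)
  expect_true(cst$e1 > 0 && cst$e2 > 0)
})

test_that("Tajima's D agrees with an independent first-principles evaluation", {
  for (seed in 1:5) {
    toy <- toy_matrix(n_sites = 20, n_per_pop = 5, seed = seed)
    g <- toy$matrix$geno[, 1:5, drop = FALSE]
    k <- rowSums(g)
    expect_equal(
      tajimas_d(toy$matrix, 1:20, "popA", toy$popmap),
      oracle_tajimas_d(k, 10), tolerance = 1e-12)
  }
  # S = 0 is undefined
  m <- geno_matrix("c", 1L, "A", "T", matrix(c(0L, 0L), 1, 2),
                   c("s1", "s2"))
  pm <- pop_map(c("s1", "s2"), c("p", "p"))
  expect_true(is.na(tajimas_d(m, 1L, "p", pm)))
  # n < 4 warns and is undefined
  m1 <- geno_matrix("c", 1L, "A", "T", matrix(1L, 1, 1), "s1")
  pm1 <- pop_map("s1", "p")
  expect_warning(d <- tajimas_d(m1, 1L, "p", pm1), "undefined")
  expect_true(is.na(d))
})

test_that("Tajima's D uses only fully-called sites", {
  geno <- matrix(c(1L, 0L, 1L, 0L,
                   1L, NA, 0L, 0L), 2, 4, byrow = TRUE)
  m <- geno_matrix(c("c", "c"), 1:2, c("A", "A"), c("T", "T"), geno,
                   paste0("s", 1:4))
  pm <- pop_map(paste0("s", 1:4), rep("p", 4))
  expect_equal(tajimas_d(m, 1:2, "p", pm),
               oracle_tajimas_d(2L, 8), tolerance = 1e-12)
})

test_that("Weir-Cockerham F_ST: fixed difference gives 1, identity gives <= 0", {
  geno <- matrix(c(2L, 2L, 0L, 0L), 1, 4)
  m <- geno_matrix("c", 1L, "A", "T", geno, paste0("s", 1:4))
  pm <- pop_map(paste0("s", 1:4), rep(c("pA", "pB"), each = 2))
  expect_equal(weir_cockerham_fst(m, 1L, "pA", "pB", pm)$fst, 1)
  geno2 <- matrix(rep(c(1L, 0L), 4), 2, 4, byrow = TRUE)
  m2 <- geno_matrix(c("c", "c"), 1:2, c("A", "A"), c("T", "T"), geno2,
                    paste0("s", 1:4))
  est <- weir_cockerham_fst(m2, 1:2, "pA", "pB", pm)
  expect_true(is.na(est$fst) || est$fst <= 0)
  expect_error(weir_cockerham_fst(m, 1L, "pA", "pA", pm), "differ")
})

test_that("Weir-Cockerham components match direct formula evaluation", {
  for (seed in 1:5) {
    toy <- toy_matrix(n_sites = 5, n_per_pop = 3, seed = seed)
    est <- weir_cockerham_fst(toy$matrix, 1:5, "popA", "popB",
                              toy$popmap)
    for (s in 1:5) {
      gA <- toy$matrix$geno[s, 1:3]; gB <- toy$matrix$geno[s, 4:6]
      o <- oracle_wc_site(3, sum(gA) / 6, mean(gA == 1),
                          3, sum(gB) / 6, mean(gB == 1))
      expect_equal(est$a[s], o[["a"]], tolerance = 1e-10)
      expect_equal(est$b[s], o[["b"]], tolerance = 1e-10)
      expect_equal(est$c[s], o[["c"]], tolerance = 1e-10)
    }
    # weighted estimate is invariant to swapping population labels
    swap <- weir_cockerham_fst(toy$matrix, 1:5, "popB", "popA",
                               toy$popmap)
    expect_equal(est$fst, swap$fst, tolerance = 1e-12)
    expect_true(is.na(est$fst) || est$fst <= 1)
  }
})

test_that("d_xy handles fixed, identical and intermediate frequencies", {
  geno <- matrix(c(2L, 2L, 0L, 0L), 1, 4)
  m <- geno_matrix("c", 1L, "A", "T", geno, paste0("s", 1:4))
  pm <- pop_map(paste0("s", 1:4), rep(c("pA", "pB"), each = 2))
  expect_equal(dxy_window(m, 1L, "pA", "pB", pm, 1), 1)
  geno2 <- matrix(0L, 1, 4)
  m2 <- geno_matrix("c", 1L, "A", "T", geno2, paste0("s", 1:4))
  expect_equal(dxy_window(m2, 1L, "pA", "pB", pm, 1), 0)
  # p_A = p_B = 0.5 -> 2 * 0.5 * 0.5 / 10
  geno3 <- matrix(c(1L, 1L, 1L, 1L), 1, 4)
  m3 <- geno_matrix("c", 1L, "A", "T", geno3, paste0("s", 1:4))
  expect_equal(dxy_window(m3, 1L, "pA", "pB", pm, 10), 0.05)
  expect_error(dxy_window(m3, 1L, "pA", "pA", pm, 10), "differ")
})

test_that("windowed_scan composes the per-window statistics", {
  toy <- toy_matrix(n_sites = 8, n_per_pop = 3, seed = 2)
  tab <- windowed_scan(toy$matrix, toy$popmap, size = 2000,
                       populations = c("popA", "popB"),
                       pairs = list(c("popA", "popB")))
  expect_equal(nrow(tab), 1L)
  w <- iter_windows(toy$matrix, 2000)[[1]]
  expect_equal(tab$pi_popA,
               pi_window(toy$matrix, w$idx, "popA", toy$popmap, 2000))
  expect_equal(tab$fst_popA_popB,
               weir_cockerham_fst(toy$matrix, w$idx, "popA", "popB",
                                  toy$popmap)$fst)
  expect_equal(tab$dxy_popA_popB,
               dxy_window(toy$matrix, w$idx, "popA", "popB",
                          toy$popmap, 2000))
  expect_equal(tab$n_sites, 8L)
})
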