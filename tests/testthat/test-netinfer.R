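test_that("unsigned soft-threshold adjacency matches analytic values", {
  # two perfectly correlated genes and one anti-correlated at -0.5
  s <- seq(-1, 1, length.out = 6)
  m <- rbind(g1 = s, g2 = 2 * s + 3, g3 = -0.5 * s + rep(c(1, -1), 3) * 0.662)
  colnames(m) <- paste0("s", 1:6)
  x <- expr_mat(m, "log2")
  cc <- cor(t(m))
  a <- correlation_adjacency(x, beta = 8)
  expect_equal(a["g1", "g2"], 1)
  expect_equal(a["g1", "g3"], abs(cc["g1", "g3"])^8, tolerance = 1e-12)
  expect_true(all(diag(a) == 0))
  # exact eighth power of a -0.5 correlation
  ym <- rbind(gA = c(1, 2, 3, 4, 5, 6), gB = c(4, 2, 6, 1, 5, 3))
  r <- cor(ym[1, ], ym[2, ])
  colnames(ym) <- paste0("s", 1:6)
  y <- expr_mat(ym, "log2")
  expect_equal(unname(correlation_adjacency(y, beta = 8)["gA", "gB"]),
               abs(r)^8, tolerance = 1e-12)
})

test_that("adjacency equals an element-wise pairwise-correlation loop", {
  x <- toy_expr(4, 6)
  for (method in c("pearson", "spearman")) {
    a <- correlation_adjacency(x, method, beta = 8)
    for (i in 1:4) for (j in 1:4) {
      want <- if (i == j) 0 else
        abs(cor(unclass(x)[i, ], unclass(x)[j, ], method = method))^8
      expect_equal(unname(a[i, j]), want, tolerance = 1e-12)
    }
  }
})

test_that("raising beta never increases adjacency and shrinks mean connectivity", {
  x <- toy_expr(10, 8, seed = 3)
  a2 <- correlation_adjacency(x, beta = 2)
  a5 <- correlation_adjacency(x, beta = 5)
  expect_true(all(a5 <= a2 + 1e-15))
  st <- pick_soft_threshold(x, betas = 1:6)
  expect_true(all(diff(st$table$mean_k) < 0))
})

test_that("soft-threshold fit table equals an independent recomputation", {
  sim <- simulate_expression(sim_config(n_genes = 150, seed = 4))
  x <- expr_log2(sim$expr)
  st <- pick_soft_threshold(x, betas = c(1, 4, 8))
  a1 <- correlation_adjacency(x, beta = 1)
  for (r in seq_len(nrow(st$table))) {
    k <- rowSums(a1^st$table$beta[r])
    lk <- log10(k[k > 0])
    br <- seq(min(lk), max(lk), length.out = 11)
    bin <- cut(lk, br, include.lowest = TRUE)
    freq <- tapply(lk, bin, length)
    km <- tapply(k[k > 0], bin, mean)
    ok <- !is.na(freq)
    fit <- lm(log10(freq[ok]) ~ log10(km[ok]))
    r2 <- summary(fit)$r.squared
    if (unname(coef(fit)[2]) > 0) r2 <- -r2
    expect_equal(st$table$r_squared[r], r2, tolerance = 1e-10)
    expect_equal(st$table$mean_k[r], mean(k), tolerance = 1e-10)
  }
  expect_true(st$chosen_beta %in% c(1, 4, 8))
})

test_that("TOM has unit diagonal, zero for empty graphs, and the 3-node path value", {
  a0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  t0 <- tom_transform(a0)
  expect_true(all(diag(t0) == 1))
  expect_true(all(t0[upper.tri(t0)] == 0))
  # path a-b-c: TOM(a, c) = (1*1 + 0) / (min(1, 1) + 1 - 0) = 0.5
  p <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p["a", "b"] <- p["b", "a"] <- 1
  p["b", "c"] <- p["c", "b"] <- 1
  expect_equal(tom_transform(p)["a", "c"], 0.5)
})

test_that("TOM of a full clique is 1 for every pair", {
  for (n in 3:6) {
    a <- matrix(1, n, n); diag(a) <- 0
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    tt <- tom_transform(a)
    expect_true(all(abs(tt - 1) < 1e-12))
  }
})

test_that("TOM equals the O(n^3) brute-force loop on random adjacencies", {
  for (seed in 1:3) {
    a <- random_adjacency(50, seed)
    expect_lt(max(abs(tom_transform(a) - tom_oracle(a))), 1e-10)
  }
  # asymmetric input is rejected
  bad <- random_adjacency(5, 1); bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(tom_transform(bad), "symmetric")
})

test_that("mutual information vanishes for independents and saturates for identity", {
  set.seed(10)
  xm <- rbind(a = runif(1000), b = runif(1000))
  colnames(xm) <- paste0("s", 1:1000)
  mi <- mutual_information_matrix(expr_mat(xm, "log2"), bins = 10)
  expect_lt(mi["a", "b"], 0.1)
  # identical uniform-grid genes isolate one diagonal cell per bin
  z <- 1:12
  ym <- rbind(a = z, b = z)
  colnames(ym) <- paste0("s", 1:12)
  suppressWarnings(mi2 <- mutual_information_matrix(expr_mat(ym, "log2"), bins = 3))
  expect_equal(mi2["a", "b"], log(3), tolerance = 1e-12)
})

test_that("MI matrix equals a naive per-pair histogram loop", {
  set.seed(11)
  m <- matrix(rnorm(3 * 12), 3, 12,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:12)))
  suppressWarnings(mi <- mutual_information_matrix(expr_mat(m, "log2"), bins = 3))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(unname(mi[i, j]), mi_pair_oracle(m[i, ], m[j, ], 3),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information_matrix(expr_mat(m, "log2"), bins = 1), "bins")
})

test_that("CLR zeroes constant backgrounds and flags the elevated pair", {
  cm <- matrix(0.5, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  diag(cm) <- 1
  expect_true(all(clr_scores(cm)$z == 0))
  cm["a", "b"] <- cm["b", "a"] <- 2
  z <- clr_scores(cm)$z
  top <- which(z == max(z), arr.ind = TRUE)
  expect_setequal(rownames(top), c("a", "b"))
})

test_that("CLR matches the element-wise oracle and is shift-invariant", {
  set.seed(12)
  mi <- matrix(runif(100), 10, 10)
  mi <- (mi + t(mi)) / 2
  dimnames(mi) <- list(paste0("g", 1:10), paste0("g", 1:10))
  z <- clr_scores(mi)$z
  expect_lt(max(abs(z - clr_oracle(mi))), 1e-12)
  z2 <- clr_scores(mi + 3)$z
  expect_lt(max(abs(z - z2)), 1e-12)
  expect_error(clr_scores(mi[1:2, 1:2]), "3 genes")
})

test_that("approximate MIC saturates on noiseless monotone dependence", {
  s <- seq_len(64)
  xm <- rbind(a = s, b = s^2)
  colnames(xm) <- paste0("s", s)
  expect_gte(mic_approx_matrix(expr_mat(xm, "log2"))["a", "b"], 0.99)
  set.seed(13)
  ym <- rbind(a = runif(200), b = runif(200))
  colnames(ym) <- paste0("s", 1:200)
  expect_lt(mic_approx_matrix(expr_mat(ym, "log2"))["a", "b"], 0.3)
})

test_that("MIC equals exhaustive enumeration over the restricted grid family", {
  set.seed(14)
  m <- matrix(rnorm(2 * 20), 2, 20,
              dimnames = list(c("a", "b"), paste0("s", 1:20)))
  got <- mic_approx_matrix(expr_mat(m, "log2"), max_grid = 6)["a", "b"]
  expect_equal(got, mic_pair_oracle(m[1, ], m[2, ], 6), tolerance = 1e-12)
  expect_error(mic_approx_matrix(expr_mat(m, "log2"), max_grid = 3), "max_grid")
})

test_that("edge thresholding keeps the top quantile, sorted by weight", {
  a <- random_adjacency(20, 5)
  e <- threshold_edges(a, quantile_frac = 0.1)
  expect_equal(nrow(e), sum(a[upper.tri(a)] >= quantile(a[upper.tri(a)], 0.9)))
  expect_true(all(diff(e$weight) <= 0))
  e2 <- threshold_edges(a, min_score = 0.9)
  expect_equal(nrow(e2), sum(a[upper.tri(a)] >= 0.9))
})

test_that("matrix TSV round-trips with gene ids intact", {
  a <- random_adjacency(8, 6)
  p <- tempfile(fileext = ".tsv")
  write_matrix_tsv(a, p)
  b <- read_matrix_tsv(p)
  expect_equal(b, a, tolerance = 1e-12)
})
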