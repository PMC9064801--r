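test_that("Fisher exact test reproduces the cohort-table p-values", {
  # vaginal delivery: 2/14 controls vs 4/9 cases
  expect_equal(round(fisher_exact_2x2(rbind(c(2, 12), c(4, 5)))$p_value, 2),
               0.16)
  # male sex: 5/14 controls vs 6/9 cases
  expect_equal(round(fisher_exact_2x2(rbind(c(5, 9), c(6, 3)))$p_value, 2),
               0.21)
  # human-milk exposure: 13/14 controls vs 8/9 cases
  expect_gt(fisher_exact_2x2(rbind(c(13, 1), c(8, 1)))$p_value, 0.99)
  expect_warning(res <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_equal(res$p_value, 1)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  res <- mann_whitney(x, y)
  expect_equal(unname(res$statistic), 0)
  # enumeration oracle: all C(6,3) assignments of the pooled ranks to x
  pooled <- c(x, y)
  u_stats <- apply(utils::combn(6, 3), 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, `>`))
  })
  u_obs <- sum(outer(x, y, `>`))
  p_exact <- mean(u_stats <= u_obs) + mean(u_stats >= length(x) * length(y) - u_obs)
  expect_equal(res$p_value, p_exact) # = 0.1
  expect_equal(res$p_value, 0.1)
  # symmetry: identical multisets
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # large shifted samples
  set.seed(9)
  expect_lt(mann_whitney(rnorm(60), rnorm(60) + 3)$p_value, 1e-6)
})

test_that("PCoA recovers collinear and planar configurations", {
  pts <- c(0, 1, 2)
  d <- abs(outer(pts, pts, `-`))
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  res <- pcoa(d, k = 1)
  rec <- abs(outer(res$coordinates[, 1], res$coordinates[, 1], `-`))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  # planar configuration: two positive eigenvalues, full reconstruction
  set.seed(5)
  xy <- matrix(rnorm(12), 6, 2)
  d2 <- as.matrix(dist(xy))
  dimnames(d2) <- list(paste0("s", 1:6), paste0("s", 1:6))
  res2 <- pcoa(d2, k = 2)
  expect_equal(sum(res2$eigenvalues > 1e-8), 2)
  rec2 <- as.matrix(dist(res2$coordinates))
  expect_lt(max(abs(rec2 - d2)), 1e-9)
  expect_true(all(diff(res2$eigenvalues) <= 1e-12)) # decreasing order
  # degenerate: all-zero distances give all-zero coordinates
  d0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_warning(res0 <- pcoa(d0, k = 2), "truncated")
  expect_equal(ncol(res0$coordinates), 0)
})

naive_pseudo_f <- function(d, x) {
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  g <- j %*% a %*% j
  x <- cbind(x - mean(x))
  h <- x %*% solve(t(x) %*% x) %*% t(x)
  m <- 1
  (sum(diag(h %*% g)) / m) /
    (sum(diag((diag(n) - h) %*% g)) / (n - m - 1))
}

test_that("PERMANOVA exhaustive p matches enumeration over label splits", {
  d <- matrix(0.9, 6, 6)
  within <- list(1:3, 4:6)
  for (g in within) d[g, g] <- 0.1
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  grp <- c(1, 1, 1, 0, 0, 0)
  res <- permanova(d, factor(grp), exhaustive = TRUE)
  # oracle: enumerate all choose(6,3) = 20 labelings, F computed naively
  f_all <- apply(utils::combn(6, 3), 2, function(ix) {
    g <- rep(0, 6); g[ix] <- 1
    naive_pseudo_f(d, g)
  })
  f_obs <- naive_pseudo_f(d, grp)
  expect_equal(res$statistic, f_obs, tolerance = 1e-10)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12)) # = 2/20
  expect_equal(res$p_value, 2 / 20)
})

test_that("PERMANOVA F is invariant to consistent sample reordering", {
  set.seed(6)
  x <- matrix(rnorm(40), 10, 4)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  cov <- rnorm(10)
  f1 <- permanova(d, cov, permutations = 99, seed = 1)$statistic
  perm <- sample(10)
  f2 <- permanova(d[perm, perm], cov[perm], permutations = 99,
                  seed = 1)$statistic
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_error(permanova(d, rep(1, 10)), "degenerate")
})

test_that("PERMANOVA agrees with vegan::adonis2 on observed pseudo-F and R2", {
  set.seed(8)
  x <- matrix(rnorm(60), 12, 5)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
  cov <- rnorm(12)
  mine <- permanova(d, cov, permutations = 99, seed = 2)
  ad <- vegan::adonis2(as.dist(d) ~ cov, permutations = 99)
  expect_equal(mine$statistic, ad$F[1], tolerance = 1e-8)
  expect_equal(mine$r_squared, ad$R2[1], tolerance = 1e-8)
})

test_that("within/between splits pairs correctly and uses the exact MWU", {
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        infant_id = c("i1", "i1", "i2", "i2"),
                        stringsAsFactors = FALSE)
  d <- matrix(0, 4, 4,
              dimnames = list(samples$sample_id, samples$sample_id))
  d[1, 2] <- 0.10; d[3, 4] <- 0.12             # within-infant pairs
  d[1, 3] <- 0.80; d[1, 4] <- 0.85             # between-infant pairs
  d[2, 3] <- 0.90; d[2, 4] <- 0.95
  d <- d + t(d)
  res <- within_between(d, samples)
  expect_equal(res$median_within, 0.11)
  expect_equal(res$median_between, 0.875)
  # exact two-sided MWU for 2 within vs 4 between, complete separation:
  # enumeration over C(6,2) assignments of the pooled ranks to "within"
  u_all <- apply(utils::combn(6, 2), 2, function(ix)
    sum(outer(ix, setdiff(1:6, ix), `>`)))
  u_obs <- 0
  p_exact <- mean(u_all <= u_obs) + mean(u_all >= 2 * 4 - u_obs)
  expect_equal(res$test$p_value, p_exact) # = 2/15
  expect_equal(res$test$p_value, 2 / 15)
  # every infant with a single sample: no within pairs
  one <- data.frame(sample_id = paste0("s", 1:3),
                    infant_id = c("i1", "i2", "i3"))
  d3 <- d[1:3, 1:3]
  expect_error(within_between(d3, one), "two or more samples")
})

test_that("alpha trend recovers a planted PMA slope with infant effects", {
  set.seed(10)
  ninf <- 10; nper <- 5
  smp <- data.frame(sample_id = paste0("s", seq_len(ninf * nper)),
                    infant_id = rep(paste0("i", 1:ninf), each = nper),
                    pma_weeks = 26 + runif(ninf * nper, 0, 10))
  u <- rep(rnorm(ninf, 0, 0.4), each = nper)
  alpha <- data.frame(sample_id = smp$sample_id,
                      value = 1 + 0.1 * smp$pma_weeks + u +
                        rnorm(ninf * nper, 0, 0.05))
  fit <- alpha_trend(alpha, smp)
  expect_equal(fit$model_type, "mixed")
  expect_lt(abs(fit$slope - 0.1) / 0.1, 0.2) # within 20% of the truth
  expect_lt(fit$p_value, 0.01)
  # constant response: zero slope
  alpha0 <- data.frame(sample_id = smp$sample_id, value = rep(2, nrow(smp)))
  expect_equal(alpha_trend(alpha0, smp)$slope, 0, tolerance = 1e-10)
})

test_that("Kruskal-Wallis/Dunn reproduces the closed-form rank example", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_dunn(vals, grp)
  expect_equal(unname(res$test$statistic), 7.2) # 12/(9*10)*(36+225+576)/3-30
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_unadjusted))
  # identical groups: statistic 0, p = 1
  res0 <- kruskal_dunn(c(1, 2, 1, 2, 1, 2), rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(res0$test$statistic), 0)
  expect_equal(res0$test$p_value, 1)
})
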