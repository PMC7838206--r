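test_that("a null between-only design gives F = 0 when cell means are identical", {
  set.seed(1)
  d <- expand.grid(subject_id = 1:10, a = c("x", "y"), b = c("u", "v"))
  d$subject_id <- seq_len(nrow(d))
  noise <- rnorm(nrow(d))
  ## center the noise within each cell so all cell means are exactly equal
  d$y <- stats::ave(noise, d$a, d$b, FUN = function(v) v - mean(v)) + 5
  out <- mixed_rm_anova(d, "y", between = c("a", "b"))
  expect_true(all(out$F < 1e-10))
  expect_true(all(out$p > 1 - 1e-6))
})

test_that("between-only degrees of freedom follow the design arithmetic", {
  set.seed(2)
  d <- data.frame(subject_id = 1:30, g = rep(c("a", "b", "c"), 10),
                  y = rnorm(30))
  out <- mixed_rm_anova(d, "y", between = "g")
  expect_equal(out$df_num, 2)
  expect_equal(out$df_den, 27)
})

test_that("mixed RM-ANOVA matches the brute-force summation oracle", {
  ## the 6-subject, 2-session design, checked term by term
  set.seed(3)
  d <- expand.grid(subject_id = sprintf("s%d", 1:6), session = c("s1", "s2"))
  d$g <- rep(rep(c("a", "b"), each = 3), 2)
  d$y <- rnorm(12, sd = 2) + (d$session == "s2") * 1.5
  mine <- mixed_rm_anova(d, "y", between = "g", within = "session")
  orac <- oracle_rm_anova(d, "y", between = "g", within = "session")
  for (tm in orac$term) {
    i <- match(tm, mine$term); j <- match(tm, orac$term)
    expect_equal(mine$SS[i], orac$SS[j], tolerance = 1e-10)
    expect_equal(mine$F[i], orac$F[j], tolerance = 1e-10)
    expect_equal(mine$df_num[i], orac$df_num[j])
    expect_equal(mine$df_den[i], orac$df_den[j])
  }
})

test_that("balanced designs decompose the total SS exactly across terms and strata", {
  set.seed(4)
  d <- expand.grid(subject_id = sprintf("s%d", 1:12),
                   w1 = c("p", "q"), w2 = c("k", "l", "m"))
  d$g <- rep(rep(c("a", "b"), each = 6), 6)
  d$y <- rnorm(nrow(d))
  out <- mixed_rm_anova(d, "y", between = "g", within = c("w1", "w2"))
  strata <- attr(out, "strata")
  expect_equal(sum(out$SS) + sum(strata$SS), attr(out, "ss_total"),
               tolerance = 1e-8)
  expect_true(all(out$eta_squared >= 0 & out$eta_squared <= 1))
  ## eta^2 over all terms cannot exceed 1
  expect_lte(sum(out$eta_squared), 1 + 1e-12)
})

test_that("F statistics are invariant to permuting factor-level labels", {
  set.seed(5)
  d <- expand.grid(subject_id = sprintf("s%d", 1:12), session = c("s1", "s2"))
  d$g <- rep(c("a", "b", "c"), 8)
  d$y <- rnorm(24) + (d$g == "b")
  f1 <- mixed_rm_anova(d, "y", between = "g", within = "session")
  d2 <- d
  d2$g <- c(a = "c", b = "a", c = "b")[d$g]
  f2 <- mixed_rm_anova(d2, "y", between = "g", within = "session")
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
})

test_that("subjects with a missing within level are excluded casewise", {
  set.seed(6)
  d <- expand.grid(subject_id = sprintf("s%d", 1:10), session = c("s1", "s2"))
  d$g <- rep(c("a", "b"), 10)
  d$y <- rnorm(20)
  d <- d[!(d$subject_id == "s3" & d$session == "s2"), ]
  out <- mixed_rm_anova(d, "y", between = "g", within = "session")
  expect_equal(attr(out, "n_excluded"), 1L)
  expect_equal(attr(out, "n_subjects"), 9L)
})

test_that("an unbalanced Type III analysis matches an independent implementation", {
  ## cross-check against car::Anova on the multivariate model
  set.seed(7)
  n <- c(a = 8, b = 14)
  d <- expand.grid(subject_id = sprintf("s%02d", 1:22), session = c("s1", "s2"))
  d$g <- rep(rep(names(n), n), 2)
  d$y <- rnorm(44) + (d$g == "b") * 0.8 + (d$session == "s2") * 0.5
  mine <- mixed_rm_anova(d, "y", between = "g", within = "session")

  wide <- reshape(d, idvar = c("subject_id", "g"), timevar = "session",
                  direction = "wide")
  mlm <- lm(cbind(y.s1, y.s2) ~ g, data = wide,
            contrasts = list(g = "contr.sum"))
  idata <- data.frame(session = factor(c("s1", "s2")))
  ca <- car::Anova(mlm, idata = idata, idesign = ~session, type = "III")
  cs <- summary(ca, multivariate = FALSE)$univariate.tests
  for (tm in c("g", "session", "g:session")) {
    expect_equal(mine$SS[mine$term == tm], unname(cs[tm, "Sum Sq"]),
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$term == tm], unname(cs[tm, "F value"]),
                 tolerance = 1e-8)
  }
})

test_that("Tukey HSD gives no false positives on identical groups and detects huge separations", {
  y <- rep(c(1.2, 3.4, 2.1, 0.7, 4.4, 2.8), 3)
  g <- rep(c("a", "b", "c"), each = 6)
  out <- tukey_hsd_groups(y, g)
  expect_equal(nrow(out), 3)
  expect_true(all(out$p_adj > 0.99))

  set.seed(8)
  y2 <- c(rnorm(10), rnorm(10, mean = 10))  # 10 pooled SDs apart
  out2 <- tukey_hsd_groups(y2, rep(c("a", "b"), each = 10))
  expect_lt(out2$p_adj, 0.001)

  expect_equal(nrow(tukey_hsd(c(a = 1), 5, 1, 4)), 0)
})

test_that("Tukey HSD agrees with the base TukeyHSD and a permutation oracle", {
  set.seed(9)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), c(8, 10, 6))))
  d$y <- rnorm(24) + c(a = 0, b = 0.9, c = 0.3)[as.character(d$g)]
  mine <- tukey_hsd_groups(d$y, d$g)
  base <- TukeyHSD(aov(y ~ g, d))$g
  expect_equal(mine$p_adj, unname(base[, "p adj"]), tolerance = 1e-8)
  expect_equal(mine$diff, unname(base[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$lwr, unname(base[, "lwr"]), tolerance = 1e-8)

  set.seed(10)
  p_perm <- oracle_tukey_perm(d$y, d$g, B = 100000)
  ## permutation of a normal null approximates the studentized-range law
  expect_true(all(abs(mine$p_adj - p_perm) < 0.02))
})

test_that("correlations match the direct covariance formula and flag degeneracies", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.1, 0.3, 2.9)
  y <- c(2.0, 3.1, 2.5, 4.9, 4.5, 1.1, 2.2)
  out <- pearson_with_r2(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_direct, tolerance = 1e-12)
  expect_equal(out$r_squared, r_direct^2, tolerance = 1e-12)

  lin <- pearson_with_r2(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$r_squared, 1)

  ## orthogonal by construction
  x0 <- c(-1, 1, -1, 1); y0 <- c(-1, -1, 1, 1)
  expect_equal(pearson_with_r2(x0, y0)$r, 0)

  expect_warning(z <- pearson_with_r2(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(z$r))
  expect_error(pearson_with_r2(1:2, 1:2), "at least 3")
})

test_that("correlation is invariant under positive affine maps and flips sign", {
  set.seed(11)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  r0 <- pearson_with_r2(x, y)$r
  expect_equal(pearson_with_r2(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_with_r2(x, -2 * y + 1)$r, -r0, tolerance = 1e-12)
})

test_that("PCA recovers a planted two-factor structure with clean salience", {
  set.seed(12)
  n <- 2000
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(v1 = 0.9 * f1, v2 = 0.9 * f1, v3 = 0.9 * f1,
             v4 = 0.9 * f2, v5 = 0.9 * f2, v6 = 0.9 * f2) +
    matrix(rnorm(6 * n, sd = 0.1), n, 6)
  p <- pca_varimax(x)
  expect_equal(p$n_retained, 2L)
  own <- unname(apply(abs(p$loadings), 1, which.max))
  expect_equal(own, rep(c(own[1], own[4]), each = 3))
  expect_true(all(abs(p$loadings)[cbind(1:6, own)] > 0.7))
  cross <- abs(p$loadings)[cbind(1:6, 3 - own)]
  expect_true(all(cross < 0.3))
})

test_that("rotation preserves communalities and independent variables stay unit-eigenvalue", {
  set.seed(13)
  x <- matrix(rnorm(5000 * 6), 5000, 6)
  colnames(x) <- paste0("v", 1:6)
  p <- pca_varimax(x, min_eigenvalue = 0.9)
  expect_true(all(abs(p$eigenvalues - 1) < 0.1))
  pre <- rowSums(p$unrotated^2)
  expect_equal(unname(p$communality), unname(pre), tolerance = 1e-8)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-8)
})

test_that("perfectly collinear duplicates collapse onto one retained factor", {
  set.seed(14)
  v <- rnorm(300)
  x <- data.frame(v1 = v, v2 = v)
  p <- pca_varimax(x)
  expect_equal(p$n_retained, 1L)
  expect_equal(p$eigenvalues[1], 2, tolerance = 1e-10)
  expect_true(all(p$salient))
})

test_that("the varimax rotation reproduces the reference implementation", {
  set.seed(15)
  for (i in 1:5) {
    A <- matrix(rnorm(7 * 2), 7, 2) %*% diag(c(1.5, 1))
    mine <- varimax_rotation(A)
    ref <- stats::varimax(A, normalize = TRUE, eps = 1e-8)
    expect_equal(varimax_criterion(mine$loadings),
                 varimax_criterion(unclass(ref$loadings)), tolerance = 1e-6)
    ## orthogonality of the accumulated rotation
    expect_equal(crossprod(mine$rotmat), diag(2), tolerance = 1e-12)
  }
})
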