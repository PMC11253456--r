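## small synthetic fits used by several blocks
fit_pair <- function(seed = 1, n = 600, spec = small_spec()) {
  gen <- generate_outcome_level(
    synthetic_config(n_insured = n, n_non_insured = n, seed = seed))
  dA <- build_design(gen$records, spec, group = "non_insured")
  dB <- build_design(gen$records, spec, group = "insured")
  list(fA = fit_logit(dA), fB = fit_logit(dB), gen = gen)
}

test_that("twofold identities hold on every run", {
  for (s in c(1, 2, 3)) {
    fp <- fit_pair(seed = s)
    res <- mvdecomp(fp$fA, fp$fB)
    expect_lt(abs(res$E$estimate + res$C$estimate - res$R$estimate), 1e-10)
    expect_lt(abs(sum(res$detailed$E) - res$E$estimate), 1e-10)
    expect_lt(abs(sum(res$detailed$C) - res$C$estimate), 1e-10)
    expect_equal(res$E$pct + res$C$pct, 100, tolerance = 1e-8)
  }
})

test_that("equal coefficients kill C exactly and equal designs kill E exactly", {
  fp <- fit_pair(seed = 4)
  resC <- mvdecomp(fp$fA, fp$fA)     # same fit (and design) on both sides
  expect_identical(resC$C$estimate, 0)
  expect_identical(resC$E$estimate, resC$R$estimate)
  expect_true(all(resC$detailed$C == 0))

  ## two different outcomes fitted over one shared design matrix
  X <- fp$fA$X
  y1 <- fp$fA$y
  y2 <- withr::with_seed(11, sample(y1))
  fA <- fit_logit(X, y1, group_label = "A")
  fB <- fit_logit(X, y2, group_label = "B")
  resE <- mvdecomp(fA, fB)
  expect_identical(resE$E$estimate, 0)
  expect_identical(resE$C$estimate, resE$R$estimate)
})

test_that("swapping comparison and reference negates the raw gap exactly", {
  fp <- fit_pair(seed = 5)
  r1 <- mvdecomp(fp$fA, fp$fB)
  r2 <- mvdecomp(fp$fB, fp$fA)
  expect_identical(r2$R$estimate, -r1$R$estimate)
})

test_that("Yun weights normalize within each family", {
  w <- yun_weights(beta_A = c(-1, 0.5), beta_B = c(-0.7, 0.2),
                   xbar_A = c(1, 0.6), xbar_B = c(1, 0.3))
  expect_equal(w$w_E, c(0, 1))          # single covariate takes all of E
  expect_equal(sum(w$w_C), 1)

  w0 <- yun_weights(c(-1, 0.5), c(-1, 0.5), c(1, 0.6), c(1, 0.3))
  expect_true(w0$unstable_C)
  expect_equal(w0$w_C, c(0, 0))
})

test_that("detailed endowment terms agree with a substitution oracle", {
  set.seed(42)
  n <- 4000
  XA <- cbind(1, runif(n) < 0.62, runif(n) < 0.35)
  XB <- cbind(1, runif(n) < 0.45, runif(n) < 0.25)
  colnames(XA) <- colnames(XB) <- c("(Intercept)", "x1", "x2")
  bA <- c(-0.9, 0.45, 0.35)
  terms <- data.frame(column = colnames(XA),
                      variable = c("(Intercept)", "x1", "x2"),
                      level = c(NA, "1", "1"))
  mk <- function(beta, X) structure(
    list(beta = stats::setNames(beta, colnames(X)),
         vcov = diag(1e-6, 3), terms = terms, X = X, y = NULL,
         n = nrow(X), group_label = NULL, spec = NULL),
    class = "che_logit")
  res <- mvdecomp(mk(bA, XA), mk(c(-1.2, 0.30, 0.30), XB))

  base <- mean(plogis(XA %*% bA))
  for (k in 2:3) {
    Xs <- XA
    Xs[, k] <- Xs[, k] + (mean(XB[, k]) - mean(XA[, k]))
    oracle_k <- base - mean(plogis(Xs %*% bA))
    est_k <- res$detailed$E[k]
    expect_lt(abs(est_k - oracle_k) / abs(oracle_k), 0.10)
  }
})

test_that("deviation normalization makes detailed terms reference-invariant", {
  gen <- generate_outcome_level(
    synthetic_config(n_insured = 800, n_non_insured = 800, seed = 29))
  refs <- c("self_employed", "government", "private_sector")
  out <- lapply(refs, function(ref) {
    res <- decompose_gap(gen$records,
                         c(occupation = ref, chronic_condition = "yes"),
                         normalization = "deviation")
    d <- res$detailed[res$detailed$variable == "occupation", ]
    list(agg = c(res$R$estimate, res$E$estimate, res$C$estimate),
         E = stats::setNames(d$E, d$level)[refs],
         C = stats::setNames(d$C, d$level)[refs])
  })
  for (i in 2:3) {
    expect_lt(max(abs(out[[i]]$agg - out[[1]]$agg)), 1e-8)
    expect_lt(max(abs(out[[i]]$E - out[[1]]$E)), 1e-6)
    expect_lt(max(abs(out[[i]]$C - out[[1]]$C)), 1e-6)
  }
  ## one detailed row per level, including the reference
  res <- decompose_gap(gen$records,
                       c(occupation = "self_employed",
                         chronic_condition = "yes"),
                       normalization = "deviation")
  expect_equal(sum(res$detailed$variable == "occupation"), 3)
})

test_that("confidence intervals are Wald by construction and respect a degenerate vcov", {
  fp <- fit_pair(seed = 7)
  res <- mvdecomp(fp$fA, fp$fB, conf_level = 0.95)
  z <- qnorm(0.975)
  expect_equal(res$E$ci[2] - res$E$estimate, z * res$E$se, tolerance = 1e-12)
  expect_equal(res$detailed$ci_hi_C - res$detailed$C,
               z * res$detailed$se_C, tolerance = 1e-12)

  ## with vcov_B = 0, se_C reflects only the first bracket (beta_A) term
  fB0 <- fp$fB
  fB0$vcov <- fp$fB$vcov * 0
  res0 <- mvdecomp(fp$fA, fB0)
  g <- sapply(seq_along(fp$fA$beta), function(j) {
    h <- 1e-6 * max(1, abs(fp$fA$beta[j]))
    bp <- fp$fA$beta; bp[j] <- bp[j] + h
    bm <- fp$fA$beta; bm[j] <- bm[j] - h
    (mean(plogis(fp$fB$X %*% bp)) - mean(plogis(fp$fB$X %*% bm))) / (2 * h)
  })
  se_expected <- sqrt(drop(t(g) %*% fp$fA$vcov %*% g))
  expect_equal(res0$C$se, se_expected, tolerance = 1e-6)
  expect_lt(res0$C$se, res$C$se)
})

test_that("bootstrap and delta-method standard errors agree at moderate n", {
  fp <- fit_pair(seed = 13, n = 1000)
  delta <- mvdecomp(fp$fA, fp$fB, se_method = "delta")
  boot <- mvdecomp(fp$fA, fp$fB, se_method = "bootstrap",
                   boot_reps = 200, boot_seed = 1234)
  for (comp in c("R", "C")) {
    ratio <- delta[[comp]]$se / boot[[comp]]$se
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.25)
  }
  ## for E the household bootstrap additionally propagates covariate-
  ## composition variability, which the X-conditional delta method excludes,
  ## so its SE can only be larger
  expect_lte(delta$E$se, boot$E$se)
  expect_gt(delta$E$se / boot$E$se, 0.3)
})

test_that("a zero gap leaves components defined but percentages undefined", {
  fp <- fit_pair(seed = 19)
  suppressMessages(res <- mvdecomp(fp$fA, fp$fA))
  ## same fit and same design on both sides: R = E = C = 0
  expect_identical(res$R$estimate, 0)
  expect_true(is.na(res$R$pct))
  expect_true(all(is.na(res$detailed$pct_E)))
})

test_that("mismatched term maps are refused", {
  fp <- fit_pair(seed = 3)
  other <- fit_pair(seed = 3, spec = c(head_sex = "male",
                                       chronic_condition = "yes"))
  expect_error(mvdecomp(fp$fA, other$fB), "term map")
})
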