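## one-factor asset sample used across several tests
factor_assets <- function(n = 2000, n_signal = 12, n_noise = 0,
                          loading = 2.0, seed = 99) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    cols <- list()
    for (i in seq_len(n_signal)) {
      b <- seq(0.2, 0.8, length.out = n_signal)[i]
      cols[[sprintf("sig_%02d", i)]] <- runif(n) < plogis(qlogis(b) + loading * z)
    }
    for (i in seq_len(n_noise)) {
      b <- seq(0.2, 0.8, length.out = max(n_noise, 1))[i]
      cols[[sprintf("noi_%02d", i)]] <- runif(n) < b
    }
    list(assets = as.data.frame(cols), latent = z)
  })
}

test_that("prevalence filter keeps the closed band [low, high]", {
  a <- data.frame(common = rep(c(TRUE, FALSE), c(97, 3)),
                  boundary = rep(c(TRUE, FALSE), c(95, 5)),
                  typical = rep(c(TRUE, FALSE), 50),
                  rare = rep(c(TRUE, FALSE), c(3, 97)))
  f <- filter_by_prevalence(a)
  expect_setequal(f$retained, c("boundary", "typical"))
  expect_equal(f$removal_log$reason[f$removal_log$variable == "common"],
               "prevalence>0.95")
  expect_equal(f$removal_log$reason[f$removal_log$variable == "rare"],
               "prevalence<0.05")
})

test_that("correlation filter removes one of a perfectly correlated pair", {
  fa <- factor_assets(n = 500, n_signal = 5, seed = 12)
  a <- fa$assets
  a$dup <- a$sig_01  # |r| = 1 with sig_01
  f <- filter_by_correlation(a)
  expect_equal(nrow(f$removal_log), 1)
  ## tie on violations broken by prevalence then name: exactly one survives
  expect_equal(sum(c("sig_01", "dup") %in% f$retained), 1)
})

test_that("variables whose correlations all sit inside the band are untouched", {
  fa <- factor_assets(n = 2000, n_signal = 8, seed = 5)
  r <- abs(cor(sapply(fa$assets, as.numeric)))
  diag(r) <- NA
  stopifnot(all(r[!is.na(r)] > 0.1 & r[!is.na(r)] < 0.9))
  f <- filter_by_correlation(fa$assets)
  expect_equal(f$retained, names(fa$assets))
  expect_equal(nrow(f$removal_log), 0)
})

test_that("the iterative rule prunes a 35-variable inventory down to the coherent 12", {
  fa <- factor_assets(n = 2000, n_signal = 12, n_noise = 23, seed = 99)
  assets <- fa$assets[sample(ncol(fa$assets))]
  f <- filter_by_correlation(assets)
  expect_equal(length(f$retained), 12)
  expect_setequal(f$retained, sprintf("sig_%02d", 1:12))
  expect_equal(nrow(f$removal_log), 23)
  expect_true(all(diff(f$removal_log$round) > 0))
})

test_that("the first component recovers a one-factor latent wealth score", {
  fa <- factor_assets(n = 2000, n_signal = 12, seed = 31)
  m <- fit_wealth_model(fa$assets)
  expect_equal(sum(m$loadings^2), 1, tolerance = 1e-12)
  s <- wealth_score(m, fa$assets)
  expect_gt(abs(cor(s, fa$latent)), 0.9)

  q <- assign_quintiles(m, fa$assets)
  expect_gt(cor(as.integer(q), fa$latent, method = "spearman"), 0.85)
})

test_that("orientation is anchored and flipping it negates scores and reverses quintiles", {
  fa <- factor_assets(n = 400, n_signal = 6, seed = 8)
  m <- fit_wealth_model(fa$assets)
  expect_gt(m$loadings[m$anchor], 0)

  m_flip <- m
  m_flip$loadings <- -m$loadings
  m_flip$cutpoints <- rev(-m$cutpoints)
  s <- wealth_score(m, fa$assets)
  expect_equal(wealth_score(m_flip, fa$assets), -s)
  q <- as.integer(assign_quintiles(m, fa$assets))
  q_flip <- as.integer(assign_quintiles(m_flip, fa$assets))
  expect_true(all(q + q_flip %in% 5:7))  # order reversed up to cutpoint ties
  expect_lt(cor(q, q_flip), -0.9)
})

test_that("loadings are invariant to duplicating every household", {
  fa <- factor_assets(n = 300, n_signal = 5, seed = 77)
  m1 <- fit_wealth_model(fa$assets)
  m2 <- fit_wealth_model(rbind(fa$assets, fa$assets))
  expect_equal(m2$loadings, m1$loadings, tolerance = 1e-12)
})

test_that("degenerate asset inputs are surfaced, not silently scored", {
  fa <- factor_assets(n = 100, n_signal = 4, seed = 2)
  a <- fa$assets
  a$flat <- TRUE
  expect_error(fit_wealth_model(a), "zero-variance.*flat")
  expect_error(fit_wealth_model(fa$assets[1:2]), ">= 3")
  m <- fit_wealth_model(fa$assets)
  expect_error(wealth_score(m, fa$assets[-1]), "absent")
})

test_that("quintile assignment is monotone in score and tie-preserving", {
  fa <- factor_assets(n = 500, n_signal = 6, seed = 44)
  m <- fit_wealth_model(fa$assets)
  s <- wealth_score(m, fa$assets)
  q <- as.integer(assign_quintiles(m, fa$assets))
  o <- order(s)
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(tapply(q, round(s, 12), function(x) length(unique(x))) == 1))

  ## five distinct scores -> one household per quintile
  five <- data.frame(a = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                     b = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     c = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  m5 <- fit_wealth_model(rbind(five, five)[1:10, ])
  s5 <- wealth_score(m5, five)
  if (length(unique(s5)) == 5) {
    expect_equal(sort(as.integer(assign_quintiles(m5, five))), 1:5)
  }

  ## all-identical asset vectors collapse to a single bin with a warning
  flat <- data.frame(a = TRUE, b = FALSE, c = TRUE)[rep(1, 20), ]
  suppressWarnings(mf <- fit_wealth_model(
    rbind(fa$assets[1:30, 1:3] |> stats::setNames(c("a", "b", "c")), flat)))
  expect_warning(q1 <- assign_quintiles(mf, flat), "single quintile")
  expect_equal(length(unique(q1)), 1)
})
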