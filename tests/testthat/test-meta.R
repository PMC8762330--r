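test_that("log odds ratios follow the 2x2 definition with Haldane fallback", {
  est <- log_or(10, 90, 5, 95)
  expect_equal(est$log_or, log((10 * 95) / (90 * 5))) # OR = 2.111...
  expect_equal(exp(est$log_or), 2.111, tolerance = 1e-3)
  expect_equal(est$se, sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95))

  expect_equal(log_or(7, 93, 7, 93)$log_or, 0) # a=c, b=d

  zeroed <- log_or(0, 100, 5, 95)
  expect_true(is.finite(zeroed$log_or)) # +0.5 on all cells engaged
  expect_equal(zeroed$log_or, log((0.5 * 95.5) / (100.5 * 5.5)))

  expect_error(log_or(0, 0, 5, 95), "empty case or control margin")
})

test_that("fixed-effect pooling obeys its identities and matches metafor", {
  one <- fixed_effect_meta(tibble::tibble(log_or = 0.31, se = 0.12))
  expect_equal(glance(one)$estimate, 0.31)
  expect_equal(glance(one)$se, 0.12)

  sym <- fixed_effect_meta(tibble::tibble(log_or = c(0.4, -0.4), se = 0.1))
  expect_equal(glance(sym)$estimate, 0)

  est <- tibble::tibble(
    label = c("disc", "repl", "array"),
    log_or = c(0.45, 0.12, 0.30), se = c(0.21, 0.16, 0.09)
  )
  m <- fixed_effect_meta(est)
  g <- glance(m)
  expect_gte(g$estimate, min(est$log_or))
  expect_lte(g$estimate, max(est$log_or))
  expect_lte(g$se, min(est$se)) # pooling never loses precision
  expect_gte(g$Q, 0)
  expect_gte(g$I2, 0)
  expect_lt(g$I2, 1)
  # order invariance
  m_rev <- fixed_effect_meta(est[3:1, ])
  expect_equal(glance(m_rev), glance(m))
  # independent oracle
  rma <- metafor::rma(yi = est$log_or, sei = est$se, method = "FE")
  expect_equal(g$estimate, as.numeric(rma$beta))
  expect_equal(g$se, rma$se)
  expect_equal(g$p, rma$pval)
  expect_equal(g$Q, rma$QE)
})

test_that("meta_2x2 chains the corrected log-ORs into the pooled estimate", {
  tables <- tibble::tibble(
    label = c("disc", "repl"),
    a = c(130L, 98L), b = c(1046L, 910L), c = c(70L, 81L), d = c(746L, 927L)
  )
  m <- meta_2x2(tables)
  est <- log_or(tables$a, tables$b, tables$c, tables$d)
  expect_equal(tidy(m)$log_or, est$log_or)
  expect_gt(exp(glance(m)$estimate), 1)
})

test_that("Hedges' g and DerSimonian-Laird pooling match metafor", {
  studies <- tibble::tibble(
    label = paste0("s", 1:5),
    mean_case = c(7.2, 7.5, 6.9, 7.0, 7.4),
    sd_case = c(1.1, 0.9, 1.3, 1.0, 1.2), n_case = c(30L, 60L, 45L, 80L, 25L),
    mean_control = c(7.5, 7.6, 7.3, 7.1, 7.2),
    sd_control = c(1.0, 1.1, 1.2, 0.9, 1.1),
    n_control = c(28L, 55L, 40L, 75L, 30L)
  )
  esc <- metafor::escalc(
    measure = "SMD",
    m1i = studies$mean_case, sd1i = studies$sd_case, n1i = studies$n_case,
    m2i = studies$mean_control, sd2i = studies$sd_control,
    n2i = studies$n_control
  )
  eff <- hedges_g(
    studies$mean_case, studies$sd_case, studies$n_case,
    studies$mean_control, studies$sd_control, studies$n_control
  )
  # metafor applies the exact gamma-function small-sample correction; ours is
  # the standard 1 - 3/(4 df - 1) approximation, identical to ~1e-5
  expect_equal(eff$g, as.numeric(esc$yi), tolerance = 1e-4)
  expect_equal(eff$var_g, as.numeric(esc$vi), tolerance = 1e-3)

  m <- random_effect_smd_meta(studies)
  rma <- metafor::rma(yi = eff$g, vi = eff$var_g, method = "DL")
  g <- glance(m)
  expect_equal(g$estimate, as.numeric(rma$beta))
  expect_equal(g$se, rma$se)
  expect_equal(g$tau2, rma$tau2)
  expect_equal(g$p, rma$pval)
})

test_that("random-effect pooling degenerates correctly", {
  # identical studies: tau^2 = 0 and pooled equals the common g
  same <- tibble::tibble(
    mean_case = 5.5, sd_case = 1, n_case = 50L,
    mean_control = 5.0, sd_control = 1, n_control = 50L
  )[rep(1, 4), ]
  m_same <- random_effect_smd_meta(same)
  expect_equal(glance(m_same)$tau2, 0)
  expect_equal(glance(m_same)$estimate, tidy(m_same)$g[1])

  # mirror-image studies pool to zero with heterogeneity
  mirror <- tibble::tibble(
    mean_case = c(5.8, 4.2), sd_case = 1, n_case = 50L,
    mean_control = c(5.0, 5.0), sd_control = 1, n_control = 50L
  )
  m_mirror <- random_effect_smd_meta(mirror)
  expect_equal(glance(m_mirror)$estimate, 0, tolerance = 1e-10)
  expect_gt(glance(m_mirror)$tau2, 0)

  # forcing tau^2 = 0 reproduces fixed-effect pooling exactly
  studies <- tibble::tibble(
    mean_case = c(7.2, 7.5, 6.9), sd_case = c(1.1, 0.9, 1.3),
    n_case = c(30L, 60L, 45L),
    mean_control = c(7.5, 7.6, 7.3), sd_control = c(1.0, 1.1, 1.2),
    n_control = c(28L, 55L, 40L)
  )
  eff <- hedges_g(
    studies$mean_case, studies$sd_case, studies$n_case,
    studies$mean_control, studies$sd_control, studies$n_control
  )
  fe <- fixed_effect_meta(tibble::tibble(
    log_or = eff$g, se = sqrt(eff$var_g)
  ))
  re0 <- random_effect_smd_meta(studies, tau2 = 0)
  expect_equal(glance(re0)$estimate, glance(fe)$estimate)
  expect_equal(glance(re0)$se, glance(fe)$se)

  expect_warning(random_effect_smd_meta(same[1, ]), "single study")
})

test_that("random-effect CIs cover a simulated SMD at nominal rate", {
  # five-study meta-analyses simulated from a true SMD of -0.15
  set.seed(2026)
  true_smd <- -0.15
  n_rep <- 1000
  covered <- logical(n_rep)
  n <- 50L
  for (r in seq_len(n_rep)) {
    studies <- purrr::map_dfr(1:5, function(k) {
      cases <- stats::rnorm(n, true_smd, 1)
      ctrls <- stats::rnorm(n, 0, 1)
      tibble::tibble(
        mean_case = mean(cases), sd_case = stats::sd(cases), n_case = n,
        mean_control = mean(ctrls), sd_control = stats::sd(ctrls),
        n_control = n
      )
    })
    g <- glance(random_effect_smd_meta(studies))
    covered[r] <- g$ci_low <= true_smd && true_smd <= g$ci_high
  }
  expect_gte(mean(covered), 0.93)
})
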