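test_that("RCBD ANOVA matches the hand-summation oracle on the tiny fixture", {
  an <- rcbd_anova(tiny_rcbd())
  expect_equal(an$term, c("replication", "families", "error"))
  expect_equal(an$df, c(1L, 2L, 2L))
  expect_equal(an$sumsq, c(6, 16, 0), tolerance = 1e-12)
  expect_equal(an$meansq[2], 8)
  # error SS is zero up to floating point, so F blows up and p vanishes
  expect_gt(an$statistic[2], 1e10)
  expect_lt(an$p.value[2], 1e-10)
})

test_that("ANOVA df and SS are additive on random balanced designs", {
  for (seed in 1:5) {
    g <- sample(3:8, 1); r <- sample(2:4, 1)
    ds <- random_trial(seed, g = g, r = r)
    an <- rcbd_anova(ds)
    for (key in split(an, interaction(an$trait, an$condition))) {
      expect_equal(key$df, c(r - 1L, g - 1L, (g - 1L) * (r - 1L)))
      m <- matrix(0, g, r)
      sub <- merge(
        expand.grid(family = unique(ds$family),
                    replicate = unique(ds$replicate)),
        ds[ds$trait == key$trait[1] & ds$condition == key$condition[1], ],
        sort = FALSE
      )
      m[cbind(match(sub$family, unique(ds$family)),
              match(sub$replicate, unique(ds$replicate)))] <- sub$value
      oracle <- rcbd_ss_oracle(m)
      expect_equal(key$sumsq, c(oracle$ss_rep, oracle$ss_fam, oracle$ss_err),
                   tolerance = 1e-8)
      expect_equal(sum(key$sumsq),
                   oracle$ss_rep + oracle$ss_fam + oracle$ss_err,
                   tolerance = 1e-8)
    }
  }
})

test_that("ANOVA refuses degenerate designs", {
  ds <- tiny_rcbd()
  expect_error(rcbd_anova(ds[ds$replicate == "r1", ]),
               class = "mahp_df_error")
  expect_error(rcbd_anova(ds[ds$family == "A", ]),
               class = "mahp_df_error")
})

test_that("heritability estimator reproduces known cells and identities", {
  # published-table checks: DTH-normal and SFW-normal mean squares
  expect_equal(round(variance_components(53.089, 5.925, 3)$h2, 3), 0.888)
  sfw <- variance_components(985.280, 1214.939, 3)
  expect_equal(sfw$h2_raw, -0.2331, tolerance = 1e-4)
  expect_equal(sfw$h2, 0)
  # no family variance beyond error
  expect_equal(variance_components(5, 5, 3)$h2, 0)
  # identity: variance ratio equals 1 - MSe/MSf to 1e-12
  set.seed(1)
  msf <- runif(50, 0.1, 100); mse <- runif(50, 0.1, 100)
  vc <- variance_components(msf, mse, 3)
  expect_equal(vc$h2_raw, vc$sigma2_g / vc$sigma2_p, tolerance = 1e-12)
  expect_equal(vc$h2_raw, 1 - mse / msf, tolerance = 1e-12)
  expect_true(all(vc$h2 >= 0 & vc$h2 <= 1))
  expect_true(all(vc$sigma2_p >= vc$sigma2_g | vc$sigma2_g < 0))
})

test_that("expected genetic advance follows the truncation-selection formula", {
  expect_equal(expected_genetic_advance(0.5, 4, 10, k = 2.063),
               tibble::tibble(ega = 2.063, ega_pct = 20.63))
  # no heritable variance, no advance
  expect_equal(expected_genetic_advance(0, 4, 10)$ega, 0)
  expect_equal(expected_genetic_advance(-0.2, 4, 10)$ega_pct, 0)
  # linear in k
  e1 <- expected_genetic_advance(0.6, 2, 5, k = 1)
  e2 <- expected_genetic_advance(0.6, 2, 5, k = 2)
  expect_equal(e2$ega, 2 * e1$ega)
  expect_error(expected_genetic_advance(0.5, 4, 0),
               class = "mahp_parameter_error")
})

test_that("genetic_params wires ANOVA, components and EGA together", {
  ds <- random_trial(3, g = 6, r = 3)
  gp <- genetic_params(ds)
  an <- rcbd_anova(ds)
  for (i in seq_len(nrow(gp))) {
    fam <- an[an$trait == gp$trait[i] & an$condition == gp$condition[i] &
                an$term == "families", ]
    expect_equal(gp$ms_families[i], fam$meansq)
    expect_equal(gp$h2_raw[i], 1 - gp$ms_error[i] / gp$ms_families[i])
  }
  expect_equal(gp$n_families[1], 6L)
  expect_equal(gp$n_reps[1], 3L)
})

test_that("genetic correlation matches the cross-product oracle", {
  set.seed(42)
  for (i in 1:4) {
    mx <- matrix(rnorm(8, 10, 2), 4, 2)
    my <- matrix(rnorm(8, 5, 1), 4, 2)
    ds <- rbind(long_from_matrix(mx, trait = "x"),
                long_from_matrix(my, trait = "y"))
    got <- genetic_correlation(ds, "x", "y", "normal")
    cov_o <- cov_g_oracle(mx, my)
    expect_equal(got$cov_g, cov_o, tolerance = 1e-10)
    sx <- cov_g_oracle(mx, mx); sy <- cov_g_oracle(my, my)
    expect_equal(got$r_g, cov_o / sqrt(abs(sx) * abs(sy)), tolerance = 1e-10)
    # symmetry
    expect_equal(genetic_correlation(ds, "y", "x", "normal")$r_g, got$r_g)
    expect_lte(abs(got$r_g_capped), 1)
  }
})

test_that("self-correlation is exactly 1 and collinear traits reach 1", {
  ds <- random_trial(5, g = 5, r = 3)
  expect_equal(genetic_correlation(ds, "x", "x", "normal")$r_g, 1)
  # y = 2x + block effects, no error: perfect genetic collinearity
  g_eff <- rnorm(5, 0, 2); b <- c(0, 1, -1)
  mx <- outer(g_eff, rep(1, 3)) + outer(rep(1, 5), b)
  my <- 2 * mx + 3
  dd <- rbind(long_from_matrix(mx, trait = "x"),
              long_from_matrix(my, trait = "y"))
  expect_equal(genetic_correlation(dd, "x", "y", "normal")$r_g, 1,
               tolerance = 1e-9)
  # zero genetic variance is an explicit error
  flat <- dd
  flat$value[flat$trait == "y"] <-
    rep(b, times = 5) + 0 # block-only signal, no family variance
  expect_error(genetic_correlation(flat, "x", "y", "normal"),
               class = "mahp_undefined_correlation_error")
})
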