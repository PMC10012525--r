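test_that("lower-better reflection maps the maximum to zero", {
  expect_equal(lower_better_transform(c(3, 1, 2)), c(0, 2, 1))
  expect_equal(lower_better_transform(rep(4, 5)), rep(0, 5))
  # range identity: transformed maximum equals input range
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(10)
    expect_equal(max(lower_better_transform(x)), max(x) - min(x))
  }
})

test_that("comparison matrices are reciprocal, rank-one and cascade-consistent", {
  expect_equal(unclass(comparison_matrix(c(1, 1, 1)))[1:3, 1:3],
               matrix(1, 3, 3), ignore_attr = TRUE)
  a <- comparison_matrix(c(1, 2, 4))
  expect_equal(a[1, 2], 0.5)
  expect_equal(a[1, 3], 0.25)
  expect_equal(a[2, 3], 0.5)
  set.seed(6)
  v <- runif(6, 0.5, 3)
  a <- comparison_matrix(v)
  expect_equal(unclass(a) * t(unclass(a)), matrix(1, 6, 6),
               tolerance = 1e-12, ignore_attr = TRUE)
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_equal(a[i, j] * a[j, k], a[i, k], tolerance = 1e-12)
  }
  expect_equal(qr(unclass(a))$rank, 1L)
  expect_error(comparison_matrix(c(1, 0, 2)),
               class = "mahp_zero_division_error")
})

test_that("principal eigenpair: closed form agrees with a dense eigensolver", {
  # all-ones matrix: lambda = N, uniform unit vector
  got <- principal_eigenpair(matrix(1, 4, 4))
  expect_equal(got$lambda, 4)
  expect_equal(got$vector, rep(0.5, 4))
  set.seed(13)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    v <- runif(n, 0.1, 5) * sample(c(-1, 1), n, replace = TRUE)
    direct <- principal_eigenpair(v)
    dense <- principal_eigenpair(comparison_matrix(v))
    expect_equal(direct$lambda, n)
    expect_equal(dense$lambda, n, tolerance = 1e-9)
    expect_equal(dense$vector, direct$vector, tolerance = 1e-9)
    expect_equal(sum(direct$vector^2), 1, tolerance = 1e-12)
    expect_gt(sum(direct$vector * v), 0)
  }
  expect_error(principal_eigenpair(c(0, 0)), class = "mahp_degenerate_error")
})

test_that("trait weights are unit-norm columns summed across parameters", {
  tw <- trait_weights(tibble::tibble(trait = c("a", "b"), p1 = c(3, 4)))
  expect_equal(tw$p1, c(0.6, 0.8))
  expect_equal(tw$final_weight, c(0.6, 0.8))

  ptab <- tibble::tibble(trait = c("a", "b", "c"),
                         p1 = c(1, 2, 2), p2 = c(-1, 3, 1), p3 = c(5, 5, 1))
  tw <- trait_weights(ptab)
  for (p in c("p1", "p2", "p3")) {
    expect_equal(sum(tw[[p]]^2), 1, tolerance = 1e-9)
  }
  expect_equal(tw$final_weight, rowSums(tw[c("p1", "p2", "p3")]),
               tolerance = 1e-9)
  # lower-better direction reflects before normalizing
  tw2 <- trait_weights(ptab, directions = c(p1 = "lower_better"))
  expect_equal(tw2$p1, lower_better_transform(ptab$p1) /
                 sqrt(sum(lower_better_transform(ptab$p1)^2)))
  # reproduction mode skips the reflection
  tw3 <- trait_weights(ptab, directions = c(p1 = "lower_better"),
                       transform = FALSE)
  expect_equal(tw3$p1, tw$p1)
  expect_error(trait_weights(tibble::tibble(trait = "a", p = NA_real_)),
               class = "mahp_parameter_error")
  expect_error(trait_weights(tibble::tibble(trait = c("a", "b"),
                                            p = c(0, 0))),
               class = "mahp_degenerate_error")
})

test_that("raising a trait's parameter value never lowers its final weight", {
  set.seed(31)
  for (i in 1:10) {
    ptab <- tibble::tibble(trait = paste0("t", 1:4),
                           p1 = runif(4, 0.1, 2), p2 = runif(4, 0.1, 2))
    w0 <- trait_weights(ptab)$final_weight
    j <- sample(4, 1)
    ptab$p1[j] <- ptab$p1[j] * 1.5
    w1 <- trait_weights(ptab)$final_weight
    expect_gte(w1[j] - w0[j], -1e-12)
  }
})

test_that("family scores are weighted unit-norm eigenvector sums", {
  tm <- tibble::tibble(family = c("f1", "f2"), a = c(3, 4))
  w <- trait_weights(tibble::tibble(trait = "a", p = c(1)))
  w$final_weight <- 1
  sc <- family_scores(tm, w)
  expect_equal(sc$score, c(0.6, 0.8))

  set.seed(8)
  tm <- tibble::tibble(family = paste0("f", 1:5),
                       a = runif(5, 1, 9), b = runif(5, 1, 9))
  w <- tibble::tibble(trait = c("a", "b"), final_weight = c(0.3, 1.7))
  sc <- family_scores(tm, w)
  # brute-force oracle
  ea <- tm$a / sqrt(sum(tm$a^2)); eb <- tm$b / sqrt(sum(tm$b^2))
  expect_equal(sc$score, 0.3 * ea + 1.7 * eb, tolerance = 1e-9)
  # scaling a trait column cancels in the normalization
  tm2 <- tm; tm2$a <- tm$a * 42
  expect_equal(family_scores(tm2, w)$score, sc$score, tolerance = 1e-12)
  # lower-better trait direction reflects family values
  sc3 <- family_scores(tm, w, directions = c(a = "lower_better"))
  ta <- lower_better_transform(tm$a)
  expect_equal(sc3$score, 0.3 * ta / sqrt(sum(ta^2)) + 1.7 * eb,
               tolerance = 1e-9)
  expect_error(family_scores(tm[, c("family", "a")], w),
               class = "mahp_alignment_error")
})

test_that("selection ranks descending with a stable input-order tie-break", {
  sc <- tibble::tibble(family = c("f1", "f2", "f3"), score = c(1, 3, 2))
  sel <- select_top(sc, count = 2)
  expect_equal(sel$family, c("f2", "f3", "f1"))
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE))
  expect_true(all(select_top(sc, fraction = 1)$selected))
  expect_equal(sum(select_top(sc, fraction = 0.5)$selected), 2) # ceiling
  # exhaustive tie policy on 3-element inputs
  for (scores in list(c(2, 2, 1), c(1, 2, 2), c(2, 1, 2), c(2, 2, 2))) {
    sc <- tibble::tibble(family = c("a", "b", "c"), score = scores)
    sel1 <- select_top(sc, count = 1)
    # the selected family is the first-listed among the maxima
    expect_equal(sel1$family[sel1$selected],
                 sc$family[which.max(sc$score)])
    sel2 <- select_top(sc, count = 2)
    top2 <- sc$family[order(-sc$score)][1:2]
    expect_setequal(sel2$family[sel2$selected], top2)
  }
  expect_error(select_top(sc, fraction = 1.2), class = "mahp_parameter_error")
  expect_error(select_top(sc, count = 9), class = "mahp_parameter_error")
  expect_error(select_top(sc), class = "mahp_parameter_error")
})
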