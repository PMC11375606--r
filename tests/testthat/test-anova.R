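test_that("split-plot decomposition matches the closed-form cell-means oracle", {
  # balanced toy set: two subjects per group, two pictures
  toy <- tibble::tibble(
    participant_id = rep(c("y1", "y2", "o1", "o2"), each = 2),
    group = rep(c("younger", "older"), each = 4),
    picture_id = rep(c("han_river", "beach"), 4),
    dv = c(10, 12, 11, 13, 8, 9, 7, 10))
  got <- mixed_anova(toy, "dv", within = "picture_id")
  want <- split_plot_oracle(data.frame(subject = toy$participant_id,
                                       group = toy$group, w = toy$picture_id,
                                       y = toy$dv))
  expect_equal(got$SS[got$effect == "group"], want$SS_group)
  expect_equal(got$SS[got$effect == "picture_id"], want$SS_w)
  expect_equal(got$SS[got$effect == "group:picture_id"], want$SS_gw)
  expect_equal(got$SS_error[got$effect == "group"], want$SS_subj)
  expect_equal(got$F[got$effect == "group"], want$F_group)
  expect_equal(got$F[got$effect == "picture_id"], want$F_w)
  expect_equal(got$F[got$effect == "group:picture_id"], want$F_gw)

  withr::local_seed(51)
  for (rep in 1:20) {
    m <- rand_metrics_2x2(n1 = 8, n2 = 8, group_shift = runif(1, -1, 1))
    got <- mixed_anova(m, "y", within = "picture_id")
    want <- split_plot_oracle(data.frame(subject = m$participant_id,
                                         group = m$group, w = m$picture_id,
                                         y = m$y))
    expect_equal(got$F[got$effect == "group"], want$F_group)
    expect_equal(got$F[got$effect == "picture_id"], want$F_w)
    expect_equal(got$F[got$effect == "group:picture_id"], want$F_gw)
  }
})

test_that("sums of squares partition the total variation", {
  withr::local_seed(52)
  for (rep in 1:20) {
    m <- rand_metrics_2x2(group_shift = rnorm(1))
    a <- mixed_anova(m, "y", within = "picture_id")
    ss_total <- sum((m$y - mean(m$y))^2)
    parts <- sum(a$SS) + sum(unique(a$SS_error))
    expect_lt(abs(parts - ss_total) / ss_total, 1e-8)
  }
})

test_that("between-group F equals the squared pooled t on subject means", {
  withr::local_seed(53)
  m <- rand_metrics_2x2(group_shift = 0.8)
  a <- mixed_anova(m, "y", within = "picture_id")
  sm <- aggregate(y ~ participant_id + group, m, mean)
  tt <- two_sample_t(sm$y[sm$group == "younger"], sm$y[sm$group == "older"],
                     pooled = TRUE)
  expect_equal(a$F[a$effect == "group"], tt$t^2, tolerance = 1e-10)
  expect_equal(a$df_error[a$effect == "group"], tt$df)
})

test_that("three-way mixed design tests every effect against df_error 44", {
  withr::local_seed(54)
  m <- rand_metrics_2x2()
  m_verb <- m
  m_verb$y <- m$y + rnorm(nrow(m))
  long <- dplyr::bind_rows(tibble::tibble(m, pos = "noun"),
                           tibble::tibble(m_verb, pos = "verb"))
  a <- mixed_anova(long, "y", within = c("picture_id", "pos"))
  expect_setequal(a$effect,
                  c("group", "picture_id", "group:picture_id", "pos",
                    "group:pos", "picture_id:pos", "group:picture_id:pos"))
  expect_true(all(a$df == 1))
  expect_true(all(a$df_error == 44))
  # partial eta squared computed from SS equals the F/df identity
  expect_equal(a$partial_eta_sq,
               partial_eta_from_F(a$F, a$df, a$df_error), tolerance = 1e-10)
})

test_that("degenerate and malformed designs are handled explicitly", {
  m <- rand_metrics_2x2(n1 = 3, n2 = 3)
  m$y <- 5
  a <- mixed_anova(m, "y", within = "picture_id")
  expect_true(all(a$SS == 0))
  expect_true(all(is.na(a$F)))

  m2 <- rand_metrics_2x2(n1 = 3, n2 = 3)
  m2 <- m2[-1, ]  # first subject lacks one picture
  expect_error(mixed_anova(m2, "y", within = "picture_id"), "A01",
               class = "prespeech_validation_error")

  m3 <- rand_metrics_2x2(n1 = 3, n2 = 3)
  m3$group[m3$participant_id == "A01"] <- "middle"
  expect_error(mixed_anova(m3, "y", within = "picture_id"),
               class = "prespeech_design_error")
})

test_that("partial eta squared follows the F-to-effect-size identity", {
  expect_equal(partial_eta_from_F(0, 1, 44), 0)
  expect_equal(round(partial_eta_from_F(26.812, 1, 44), 3), 0.379)
  expect_equal(round(partial_eta_from_F(192.764, 1, 44), 3), 0.814)
  expect_equal(round(partial_eta_from_F(5.067, 1, 44), 3), 0.103)
  expect_error(partial_eta_from_F(-1, 1, 44),
               class = "prespeech_domain_error")
})

test_that("two-sample t supports pooled and Welch degrees of freedom", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  withr::local_seed(55)
  a <- rnorm(24); b <- rnorm(22, sd = 3)
  expect_equal(two_sample_t(a, b, pooled = TRUE)$df, 44)
  welch <- two_sample_t(a, b, pooled = FALSE)
  expect_equal(welch$df, unname(t.test(a, b)$parameter))
  expect_lt(welch$df, 44)

  expect_warning(res0 <- two_sample_t(rep(1, 3), rep(1, 3)), "constant")
  expect_true(is.na(res0$t))
  expect_error(two_sample_t(1, c(1, 2)), class = "prespeech_domain_error")
})
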