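brute_metrics <- function(P, G) {
  np <- 0; ng <- 0; ni <- 0
  for (i in seq_along(P)) {
    if (P[i] != 0) np <- np + 1
    if (G[i] != 0) ng <- ng + 1
    if (P[i] != 0 && G[i] != 0) ni <- ni + 1
  }
  list(
    dsc = if (np + ng == 0) 1 else 2 * ni / (np + ng),
    ppv = if (np == 0) (if (ng == 0) 1 else 0) else ni / np,
    sens = if (ng == 0) (if (np == 0) 1 else 0) else ni / ng
  )
}

test_that("mask metrics match hand counts and conventions", {
  # |P| = 2, |G| = 4, |P n G| = 2 on a 3 x 3 toy mask
  P <- matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  G <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(dsc(P, G), 2 * 2 / 6)
  expect_equal(ppv(P, G), 1)
  expect_equal(sensitivity(P, G), 0.5)

  M <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dsc(M, M), 1)
  expect_equal(ppv(M, M), 1)
  D <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(dsc(M, D), 0)

  # over-segmentation signature: P strictly contains G
  G2 <- matrix(c(1, 0, 0, 0), 2, 2)
  P2 <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(ppv(P2, G2), 1)
  expect_equal(sensitivity(P2, G2), 1)

  # empty-mask conventions
  Z <- matrix(0, 2, 2)
  expect_equal(dsc(Z, Z), 1)
  expect_equal(ppv(Z, Z), 1)
  expect_equal(sensitivity(Z, Z), 1)
  expect_equal(ppv(Z, G2), 0)
  expect_equal(sensitivity(P2, Z), 0)
  expect_equal(sensitivity(Z, G2), 0)
  expect_error(dsc(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("metrics match brute-force set counting on random masks", {
  set.seed(81)
  for (i in 1:100) {
    d <- c(sample(3:6, 1), sample(3:6, 1))
    P <- matrix(rbinom(prod(d), 1, runif(1)), d[1], d[2])
    G <- matrix(rbinom(prod(d), 1, runif(1)), d[1], d[2])
    b <- brute_metrics(P, G)
    expect_equal(dsc(P, G), b$dsc)
    expect_equal(ppv(P, G), b$ppv)
    expect_equal(sensitivity(P, G), b$sens)
    # DSC is the harmonic mean of PPV and sensitivity when both defined
    if (sum(P) > 0 && sum(G) > 0 && b$ppv + b$sens > 0) {
      expect_equal(b$dsc, 2 * b$ppv * b$sens / (b$ppv + b$sens),
                   tolerance = 1e-12)
    }
    # simultaneous spatial permutation leaves all metrics unchanged
    idx <- sample(prod(d))
    Pp <- matrix(P[idx], d[1], d[2]); Gp <- matrix(G[idx], d[1], d[2])
    expect_equal(dsc(Pp, Gp), b$dsc)
    expect_equal(ppv(Pp, Gp), b$ppv)
    expect_equal(sensitivity(Pp, Gp), b$sens)
  }
})

test_that("case evaluation scores all three regions on 3-D volumes", {
  params <- phantom_params(volume_shape = c(24L, 24L, 10L),
                           tumor_probability = 1)
  cs <- generate_case(params, seed = 5)
  rep0 <- evaluate_case(cs$labels, cs$labels)
  expect_identical(rep0$region, c("complete", "core", "enhancing"))
  expect_true(all(abs(rep0$dsc - 1) < 1e-12))
  expect_true(all(abs(rep0$ppv - 1) < 1e-12))
  expect_true(all(abs(rep0$sensitivity - 1) < 1e-12))

  # relabeling edema to background hurts only the complete region
  pred <- cs$labels
  pred[pred == 2L] <- 0L
  rep1 <- evaluate_case(pred, cs$labels)
  expect_lt(rep1$dsc[rep1$region == "complete"], 1)
  expect_equal(rep1$dsc[rep1$region == "core"], 1)
  expect_equal(rep1$dsc[rep1$region == "enhancing"], 1)

  # an all-background prediction has zero sensitivity everywhere
  rep2 <- evaluate_case(array(0L, dim = dim(cs$labels)), cs$labels)
  expect_true(all(rep2$sensitivity == 0))
  expect_error(evaluate_case(pred[, , 1:3], cs$labels), "differ")
})

test_that("cohort evaluation averages per-case reports unweighted", {
  params <- phantom_params(volume_shape = c(20L, 20L, 8L),
                           tumor_probability = 1)
  a <- generate_case(params, seed = 1)
  b <- generate_case(params, seed = 2)
  one <- evaluate_cohort(list(c1 = list(pred = a$labels, truth = a$labels)))
  expect_equal(one$mean$dsc, c(1, 1, 1))

  degraded <- a$labels
  degraded[degraded == 2L] <- 0L
  coh <- evaluate_cohort(list(
    c1 = list(pred = degraded, truth = a$labels),
    c2 = list(pred = b$labels, truth = b$labels)
  ))
  r1 <- evaluate_case(degraded, a$labels)
  expect_equal(coh$mean$dsc[coh$mean$region == "complete"],
               mean(c(r1$dsc[r1$region == "complete"], 1)))
  # order invariance
  coh2 <- evaluate_cohort(list(
    c2 = list(pred = b$labels, truth = b$labels),
    c1 = list(pred = degraded, truth = a$labels)
  ))
  expect_equal(coh$mean, coh2$mean)
  # CSV and JSON report writers produce parseable files
  csv <- tempfile(fileext = ".csv")
  evaluate_cohort(list(c1 = list(pred = b$labels, truth = b$labels)),
                  csv = csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 3)
  js <- tempfile(fileext = ".json")
  write_report_json(coh$mean, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$dsc, coh$mean$dsc, tolerance = 1e-12)
})
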