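perturbed_controls <- function() {
  feature_matrix(
    rbind(c(0, -1, 0), c(0, -1, 0), c(5500, 1, 120000), c(0, -1, 60000)),
    classes = c("A", "A", "B", "B"),
    feature_names = c("dispersion", "focus", "wavenhl")
  )
}

test_that("class summaries give probabilities, centroids and pooled spread", {
  M <- perturbed_controls()
  cs <- class_summaries(M)
  expect_equal(vapply(cs, `[[`, numeric(1), "P"), c(0.5, 0.5))
  a <- cs[[1]]; b <- cs[[2]]
  expect_equal(unname(a$mu), c(0, -1, 0))
  expect_equal(a$Vk2, 0)
  expect_equal(unname(b$mu), c(2750, 0, 90000))
  expect_equal(b$Vk2, 907562501)  # mean squared distance to the centroid
})

test_that("the perturbed control configuration yields F that rounds to 18", {
  res <- fisher_coefficient(perturbed_controls())
  expect_equal(res$D2, 8107562501)
  expect_equal(res$V2, 453781250.5)
  expect_equal(round(res$F), 18)
  expect_false(res$capped)
})

test_that("pure control configurations are capped with zero within-class variance", {
  for (preset in c("t3", "t1p5")) {
    cp <- control_points(preset)
    M <- add_controls(
      feature_matrix(matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, cp$feature_names)),
                     character(0)),
      cp$c_min, cp$c_max, replicates = 2)
    res <- fisher_coefficient(M, f_max = 1e6)
    expect_true(res$capped)
    expect_equal(res$F, 1e6)
    expect_equal(res$V2, 0)
    expect_equal(loo_1nn_mde(M)$mde_percent, 0)
  }
})

test_that("identical class means give F = 0 and single classes error", {
  M <- feature_matrix(rbind(c(1, 2), c(3, 0), c(1, 2), c(3, 0)),
                      classes = c("A", "A", "B", "B"))
  expect_equal(fisher_coefficient(M)$F, 0)
  single <- feature_matrix(rbind(c(1, 2), c(3, 4)), classes = c("A", "A"))
  expect_error(fisher_coefficient(single), "two classes")
})

test_that("LOO 1-NN reproduces the worked misclassification errors", {
  expect_equal(loo_1nn_mde(perturbed_controls())$mde_percent, 25)
  far <- feature_matrix(rbind(c(0, 0), c(10, 10)), classes = c("A", "B"))
  expect_equal(loo_1nn_mde(far)$mde_percent, 100)  # LOO empties own class
  paired <- feature_matrix(rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9)),
                           classes = c("A", "A", "B", "B"))
  expect_equal(loo_1nn_mde(paired)$mde_percent, 0)
})

test_that("nearest-neighbour ties break toward the lowest sample index", {
  M <- feature_matrix(rbind(c(0, 0), c(1, 0), c(-1, 0)),
                      classes = c("A", "A", "B"))
  res <- loo_1nn_mde(M)  # sample 1 ties between 2 and 3; index 2 wins
  expect_false(res$misclassified[1])
})

test_that("standardization z-scores features and drops constant ones", {
  M <- feature_matrix(cbind(c(0, 0, 10, 12), c(5, 5, 5, 5)),
                      classes = c("A", "A", "B", "B"))
  expect_warning(res <- loo_1nn_mde(M, standardize = TRUE),
                 "zero-variance")
  expect_equal(res$mde_percent, 0)
})

test_that("control injection appends without touching existing rows", {
  M <- perturbed_controls()
  cp <- control_points("t1p5")
  expect_equal(cp$c_max, c(307, 1, 120000))
  M2 <- add_controls(M, cp$c_min, cp$c_max, replicates = 2)
  expect_equal(nrow(M2$x), 8)
  expect_equal(M2$x[1:4, ], M$x, ignore_attr = TRUE)
  expect_equal(M2$classes[5:8],
               rep(c("control_min", "control_max"), each = 2))
  expect_equal(unname(M2$x[7, ]), c(307, 1, 120000))
  expect_error(add_controls(M, c(0, -1), cp$c_max), "dimension")
})

test_that("F matches the explicit double-loop oracle on 50 seeded matrices", {
  for (s in 1:50) {
    M <- random_feature_matrix(seed = s, n_classes = 2 + s %% 3,
                               dim = 1 + s %% 5, per_class = 4 + s %% 7)
    got <- fisher_coefficient(M)
    want <- oracle_fisher(M$x, M$classes)
    expect_equal(got$D2, want$D2, tolerance = 1e-9, info = s)
    expect_equal(got$V2, want$V2, tolerance = 1e-9, info = s)
    expect_equal(got$F, want$F, tolerance = 1e-9, info = s)
  }
})

test_that("F and MDE are invariant under global affine feature maps", {
  for (s in 1:20) {
    M <- random_feature_matrix(seed = 100 + s)
    a <- c(0.04, 7, -3)[s %% 3 + 1]
    b <- c(-55, 0.3, 1200)[s %% 3 + 1]
    Mt <- feature_matrix(a * M$x + b, M$classes)
    expect_equal(fisher_coefficient(Mt)$F, fisher_coefficient(M)$F,
                 tolerance = 1e-8, info = s)
    expect_equal(loo_1nn_mde(Mt)$mde_percent, loo_1nn_mde(M)$mde_percent,
                 info = s)
  }
})

test_that("F grows with class-mean separation at fixed noise", {
  mean_F <- function(sep) {
    mean(vapply(1:20, function(s) {
      set.seed(s)
      X <- NULL; labs <- character(0)
      for (k in 1:4) {
        X <- rbind(X, matrix(rnorm(30, sd = 1), 10, 3) +
                     matrix(sep * k * c(1, -1, 0.5), 10, 3, byrow = TRUE))
        labs <- c(labs, rep(paste0("r", k), 10))
      }
      fisher_coefficient(feature_matrix(X, labs))$F
    }, numeric(1)))
  }
  Fs <- vapply(c(0.5, 1, 2, 4), mean_F, numeric(1))
  expect_true(all(diff(Fs) > 0))
})

test_that("per-feature ranking isolates the discriminative axis", {
  set.seed(4)
  X <- cbind(separating = rep(c(0, 10), each = 8) + rnorm(16, sd = 0.2),
             noise = rnorm(16))
  M <- feature_matrix(X, rep(c("A", "B"), each = 8))
  fr <- fisher_per_feature(M)
  expect_gt(fr[["separating"]], fr[["noise"]])
})

test_that("feature matrices round trip through CSV", {
  M <- perturbed_controls()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(M, path)
  back <- read_feature_matrix(path)
  expect_equal(back$x, M$x, ignore_attr = TRUE)
  expect_equal(back$classes, M$classes)
  expect_equal(back$feature_names, M$feature_names)
  expect_error(feature_matrix(rbind(c(1, NA)), "A"), "missing")
})

test_that("bundled control fixtures match the documented coordinates", {
  Mp <- control_matrix("t3_perturbed")
  expect_equal(unname(Mp$x), unname(perturbed_controls()$x))
  M3 <- control_matrix("t3")
  expect_equal(unname(M3$x[3, ]), c(5500, 1, 120000))
  M15 <- control_matrix("t1p5")
  expect_equal(unname(M15$x[3, ]), c(307, 1, 120000))
})
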