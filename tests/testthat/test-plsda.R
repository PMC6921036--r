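# positives and negatives fully separated on `sig`; `noise` uninformative
sep_toy <- function(n = 30, seed = 3) {
  withr::with_seed(seed, {
    x <- cbind(sig = c(runif(n, 1, 2), runif(n, -2, -1)),
               noise = rnorm(2 * n))
  })
  list(x = x, y = rep(c(1, 0), each = n))
}

test_that("a separating descriptor yields correct training classes", {
  toy <- sep_toy()
  fit <- plsda_fit(toy$x, toy$y, n_components = 1)
  pred <- predict(fit, toy$x)
  expect_equal(pred$class, toy$y)
  scores <- pred$score
  expect_true(all(scores[toy$y == 1] > 0.5) && all(scores[toy$y == 0] < 0.5))
  # determinism: a row equal to a training row scores identically
  expect_equal(predict(fit, toy$x[3, , drop = FALSE])$score,
               fit$fitted[3], tolerance = 1e-12)
})

test_that("one-component prediction equals OLS on the first latent direction", {
  x <- matrix(c(1.2, -0.7, 0.3, 2.1, -1.5, 0.9,
                0.4, 1.1, -0.2, -0.8, 0.6, -1.3), ncol = 2)
  y <- c(1, 0, 1, 1, 0, 0)
  fit <- plsda_fit(x, y, n_components = 1)
  # oracle: autoscale, weight = X'y direction, regress y on t by normal
  # equations
  xs <- scale(x)
  w <- crossprod(xs, y - mean(y))
  w <- w / sqrt(sum(w^2))
  t_score <- xs %*% w
  q <- solve(crossprod(t_score), crossprod(t_score, y - mean(y)))
  oracle_pred <- drop(t_score %*% q) + mean(y)
  expect_equal(unname(fit$fitted), oracle_pred, tolerance = 1e-8)
})

test_that("duplicating a descriptor column does not change predictions", {
  toy <- sep_toy(seed = 8)
  x1 <- toy$x[, "sig", drop = FALSE]
  fit1 <- plsda_fit(x1, toy$y, n_components = 1)
  xdup <- cbind(sig = x1[, 1], sig2 = x1[, 1])
  fit2 <- plsda_fit(xdup, toy$y, n_components = 1)
  expect_equal(unname(fit1$fitted), unname(fit2$fitted), tolerance = 1e-8)
})

test_that("training scores are orthogonal and X residual norm non-increasing", {
  withr::with_seed(21, {
    x <- matrix(rnorm(200), 40, 5)
    y <- rep(c(0, 1), 20)
  })
  fit <- plsda_fit(x, y, n_components = 4)
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(fit$x_residual_norm) <= 1e-10))
})

test_that("zero-variance descriptors are dropped and schema enforced", {
  toy <- sep_toy()
  xz <- cbind(toy$x, const = 1)
  expect_warning(fit <- plsda_fit(xz, toy$y, n_components = 1), "const")
  expect_false("const" %in% fit$columns)
  expect_error(predict(fit, xz[, "sig", drop = FALSE]), "Missing: noise")
  extra <- cbind(toy$x, rogue = 1)
  expect_error(predict(fit, extra), "Extra: rogue")
})

test_that("Q2 approaches 1 for predictable y and hugs 0 under permuted labels", {
  # duplicated-signal toy: y is (almost) a linear function of x
  y <- rep(c(1, 0), each = 40)
  x <- withr::with_seed(12, cbind(s1 = y + rnorm(80, sd = 0.02),
                                  s2 = y + rnorm(80, sd = 0.02)))
  q2 <- plsda_q2(x, y, n_components = 1, seed = 1)
  expect_gt(q2, 0.95)

  null_q2 <- vapply(1:20, function(s) {
    y_perm <- withr::with_seed(1000 + s, sample(y))
    plsda_q2(x, y_perm, n_components = 1, seed = s)
  }, numeric(1))
  expect_lt(mean(null_q2), 0.05)

  # optimism: cross-validated Q2 never beats the training fit
  fit <- plsda_fit(x, y, n_components = 1)
  expect_lte(q2, fit$r_squared + 1e-10)
})

test_that("automatic component selection maximises the Q2 trace", {
  toy <- sep_toy(n = 25, seed = 31)
  fit <- suppressWarnings(plsda_fit(toy$x, toy$y, max_components = 2,
                                    seed = 4))
  trace <- fit$training_meta$component_selection
  expect_equal(nrow(trace), 2L)
  expect_equal(fit$n_components, which.max(trace$q2))
})

test_that("evaluation reports counts/metrics and enforces disjointness", {
  corpus <- generate_corpus(synth_config(n_per_class = 50,
                                         separation = "strong", seed = 9))
  parts <- split_peptides(corpus, seed = 2)
  desc <- suppressWarnings(peptide_descriptors(parts$train))
  fit <- suppressWarnings(plsda_fit(descriptor_matrix(desc), parts$train$label,
                                    n_components = 3,
                                    sequences = parts$train$sequence))
  res <- suppressWarnings(plsda_evaluate(fit, parts$test))
  expect_s3_class(res, "plsda_eval")
  expect_equal(res$counts$tp + res$counts$fn + res$counts$tn + res$counts$fp,
               nrow(parts$test))
  # metrics recomputable from the serialized counts
  expect_equal(res$metrics, confusion_metrics(res$counts))

  overlap <- dplyr::bind_rows(parts$test, parts$train[1, ])
  expect_error(suppressWarnings(plsda_evaluate(fit, overlap)), "overlap")

  # fixed seed -> identical report on rerun
  res2 <- suppressWarnings(plsda_evaluate(fit, parts$test))
  expect_identical(res$counts, res2$counts)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  withr::with_seed(5, {
    x <- matrix(rnorm(80), 20, 4)
    colnames(x) <- paste0("v", 1:4)
  })
  y <- rep(c(0, 1), 10)
  fit <- plsda_fit(x, y, n_components = 2)
  m <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = TRUE)
  ref <- predict(m, x)$predict[, 1, 2]
  expect_equal(unname(fit$fitted), unname(ref), tolerance = 1e-10)
  expect_equal(abs(unname(m$variates$X)), abs(unname(fit$scores)),
               tolerance = 1e-10)
})

test_that("known CPPs score as CPP-like under a synthetic-trained model", {
  corpus <- generate_corpus(synth_config(n_per_class = 200,
                                         separation = "strong", seed = 1))
  d <- suppressWarnings(peptide_descriptors(corpus))
  fit <- suppressWarnings(plsda_fit(descriptor_matrix(d), d$label,
                                    n_components = 3))
  ref <- suppressWarnings(peptide_descriptors(
    tibble::tibble(id = c("Pen", "Cys-Pen", "pVEC", "Cys-pVEC"),
                   sequence = c(PEN, CYS_PEN, PVEC, CYS_PVEC))
  ))
  scores <- predict(fit, descriptor_matrix(ref)[, fit$columns])$score
  # all four well above the negative class; the two strongly amphipathic
  # ones clear the 0.5 class cut outright
  neg_level <- mean(fit$fitted[corpus$label == 0])
  expect_true(all(scores > neg_level + 0.1))
  expect_true(all(scores[1:2] > 0.5))
})

test_that("models round-trip through JSON serialization", {
  toy <- sep_toy(seed = 17)
  fit <- plsda_fit(toy$x, toy$y, n_components = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_plsda(fit, path)
  back <- read_plsda(path)
  expect_equal(predict(back, toy$x)$score, predict(fit, toy$x)$score,
               tolerance = 1e-12)
  expect_equal(back$n_components, fit$n_components)
})

test_that("tidy and glance expose the model state", {
  toy <- sep_toy()
  fit <- plsda_fit(toy$x, toy$y, n_components = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 2)
  expect_named(td, c("component", "term", "weight", "loading", "y_loading"))
  gl <- glance(fit)
  expect_equal(gl$n_components, 2L)
  expect_gt(gl$r_squared, 0)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
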