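trend_data <- function(ids, gre, ngre) {
  data.frame(gene_id = ids, gre = gre, ngre = ngre,
             stringsAsFactors = FALSE)
}

test_that("zero-intercept slope is sum(xy)/sum(x^2)", {
  expect_equal(fit_zero_intercept(c(1, 2), c(1, 3)), 1.4)
  # exact proportionality
  x <- c(1, 5, 9)
  expect_equal(fit_zero_intercept(x, 2 * x), 2)
  # repeated single point
  expect_equal(fit_zero_intercept(rep(1, 5), rep(1, 5)), 1)
  expect_error(fit_zero_intercept(c(0, 0), c(1, 2)), "degenerate")
})

test_that("rre_fit residuals satisfy the normal equation and exact fits", {
  d <- trend_data(sprintf("g%02d", 1:40),
                  gre = rep(1:10, 4),
                  ngre = 0.03 * rep(1:10, 4) + rep(c(-0.01, 0, 0.01, 0), 10))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.05)
  # least-squares through origin: sum(x * residual) = 0
  expect_lt(abs(sum(fit$x * fit$residuals)) /
              max(abs(fit$x * fit$residuals)), 1e-9)
  # y = 2x exactly: slope 2, all residuals 0
  d2 <- trend_data(letters[1:10], 1:10, 2 * (1:10))
  fit2 <- rre_fit(ngre ~ gre,
                  setNames(d2, c("gene_id", "gre", "ngre")),
                  fraction = 0.2)
  expect_equal(fit2$slope, 2)
  expect_equal(unname(fit2$residuals), rep(0, 10))
})

test_that("extreme sets have size round_half_away(fraction * N)", {
  expect_equal(extreme_set_size(24070, 0.05), 1204L)
  expect_equal(extreme_set_size(3095, 0.05), 155L)
  expect_equal(extreme_set_size(100, 0.05), 5L)
  set.seed(5)
  d <- trend_data(sprintf("g%04d", 1:999), rpois(999, 10) + 1,
                  runif(999))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.05)
  m <- extreme_set_size(999, 0.05)  # 0.05 * 999 = 49.95 -> 50
  expect_equal(sum(fit$labels == "enriched"), m)
  expect_equal(sum(fit$labels == "deficient"), m)
})

test_that("labels partition the items and respect residual ordering", {
  set.seed(9)
  d <- trend_data(sprintf("g%03d", 1:200), rpois(200, 20) + 1, runif(200))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.1)
  expect_equal(sum(table(fit$labels)), 200)
  r <- fit$residuals
  expect_true(min(r[fit$labels == "enriched"]) >=
                max(r[fit$labels == "intermediate"]))
  expect_true(max(r[fit$labels == "deficient"]) <=
                min(r[fit$labels == "intermediate"]))
  # deterministic: same input, same labels
  fit2 <- rre_fit(ngre ~ gre, d, fraction = 0.1)
  expect_identical(fit$labels, fit2$labels)
})

test_that("residual ties break lexicographically by id", {
  # eight items on two residual levels; ids decide within a level
  d <- trend_data(c("b", "a", "d", "c", "f", "e", "h", "g"),
                  gre = rep(1, 8),
                  ngre = c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.25)
  expect_setequal(extremes(fit)$enriched, c("a", "b"))
  expect_setequal(extremes(fit)$deficient, c("e", "f"))
})

test_that("items with undefined relative score are excluded and counted", {
  d <- trend_data(sprintf("g%02d", 1:50), rep(1:10, 5),
                  c(rep(NA, 5), runif(45)))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.1)
  expect_equal(fit$n_excluded, 5L)
  expect_equal(length(fit$ids), 45L)
  expect_false(any(sprintf("g%02d", 1:5) %in% fit$ids))
})

test_that("classify_extremes dispatches on gene and pathway columns", {
  set.seed(2)
  gd <- trend_data(sprintf("g%02d", 1:50), rpois(50, 9) + 1, runif(50))
  expect_s3_class(classify_extremes(gd, 0.1), "rre_fit")
  pd <- data.frame(pathway_id = sprintf("p%02d", 1:50),
                   pii = rpois(50, 9) + 1, npii = runif(50))
  pfit <- classify_extremes(pd, 0.1)
  expect_equal(pfit$xname, "pii")
  expect_error(classify_extremes(data.frame(a = 1:9, b = 1:9)), "columns")
  expect_error(rre_fit(ngre ~ gre, gd, fraction = 0.7), "fraction")
})

test_that("rre_fit methods behave like a standard model object", {
  set.seed(4)
  d <- trend_data(sprintf("g%02d", 1:60), rpois(60, 15) + 1, runif(60))
  fit <- rre_fit(ngre ~ gre, d, fraction = 0.05)
  expect_named(coef(fit), "gre")
  expect_equal(fitted(fit) + residuals(fit),
               setNames(fit$y, fit$ids))
  expect_equal(unname(predict(fit, data.frame(gre = c(0, 10)))),
               c(0, 10 * fit$slope))
  expect_output(print(fit), "Zero-intercept")
  expect_output(print(summary(fit)), "Residual quantiles")
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 60)
  expect_true(all(c("item_id", "gre", "ngre", "residual", "label")
                  %in% names(df)))
  pdf_file <- tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_silent(plot(fit))
  grDevices::dev.off()
})

test_that("planted genes are recovered among the enriched extreme", {
  fx <- small_sim_scores(seed = 31)
  fit <- classify_extremes(fx$agg, fraction = 0.05)
  planted <- fx$truth$planted_gene_ids
  rate <- mean(planted %in% extremes(fit)$enriched)
  expect_gt(rate, 0.5)  # chance level would be 0.05
})
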