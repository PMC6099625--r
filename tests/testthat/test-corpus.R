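test_that("corpus measurement counts composite-text characters", {
  docs <- list(Document("a", "ab", "cde"), Document("b", "xyz"))
  co <- measureCorpus(docs)
  expect_equal(unname(sizeChars(co)), c(6, 3))  # 2 + 1 separator + 3
  expect_equal(fileIds(co), c("a", "b"))
  expect_equal(nFiles(measureCorpus(list())), 0)
})

test_that("measuring PubTator files matches independent character counts", {
  dir <- withr::local_tempdir()
  docs <- list(Document("d1", "Title one.", "Body one."),
               Document("d2", "Second"),
               Document("d3", "T", "A longer body text here."))
  paths <- vapply(seq_along(docs), function(k) {
    p <- file.path(dir, paste0("d", k, ".txt"))
    writePubTator(docs[k], p)
    p
  }, character(1))
  co <- measureCorpus(paths)
  # oracle: counts done directly on the strings
  expect_equal(unname(sizeChars(co)),
               c(nchar("Title one. Body one."), nchar("Second"),
                 nchar("T A longer body text here.")))
  expect_error(measureCorpus(file.path(dir, "absent.txt")), "absent.txt")
})

test_that("two exact points fit an exact line", {
  m <- fitTimeModel(data.frame(size = c(1, 2), seconds = c(10, 20)))
  expect_equal(modelIntercept(m), 0)
  expect_equal(modelSlope(m), 10)
})

test_that("the benchmark size-time table fits the reported affine model", {
  pts <- with(referenceSerialTimes("size"),
              data.frame(size = size_mb, seconds = total))
  m <- fitTimeModel(pts, sizeUnit = "MB")
  # oracle: closed-form least squares, computed independently of lm()
  sx <- mean(pts$size); sy <- mean(pts$seconds)
  slope <- sum((pts$size - sx) * (pts$seconds - sy)) /
    sum((pts$size - sx)^2)
  intercept <- sy - slope * sx
  expect_equal(modelSlope(m), slope, tolerance = 1e-10)
  expect_equal(modelIntercept(m), intercept, tolerance = 1e-10)
  expect_equal(slope, 1128.4649, tolerance = 1e-6)
  expect_equal(intercept, 847.9517, tolerance = 1e-5)
  # residuals under 15% of each observation
  pred <- predictCost(m, pts$size * 1e6)
  expect_true(all(abs(pred - pts$seconds) / pts$seconds < 0.15))
  expect_equal(predictCost(m, 4e6), 5680.40, tolerance = 0.15)
})

test_that("degenerate fits are refused", {
  expect_error(fitTimeModel(data.frame(size = 1, seconds = 5)),
               "at least two")
  expect_error(fitTimeModel(data.frame(size = c(2, 2),
                                       seconds = c(5, 7))), "degenerate")
})

test_that("cost prediction is affine, increasing and unit-aware", {
  m <- WorkloadModel(0, 1, "chars")
  expect_equal(predictCost(m, 7), 7)
  m2 <- WorkloadModel(3, 2, "chars")
  s <- c(10, 25, 400)
  expect_equal(predictCost(m2, 2 * s) - predictCost(m2, s), 2 * s)
  expect_true(all(diff(predictCost(m2, sort(s))) > 0))
  mb <- WorkloadModel(100, 1000, "MB")
  expect_equal(predictCost(mb, 5e5), 100 + 1000 * 0.5)
})

test_that("noiseless linear data recovers intercept and slope", {
  set.seed(7)
  for (rep in 1:10) {
    a <- runif(1, 0, 100); b <- runif(1, 0.1, 50)
    x <- sample(1:1000, 20)
    m <- fitTimeModel(data.frame(size = x, seconds = a + b * x))
    expect_equal(modelIntercept(m), a, tolerance = 1e-8)
    expect_equal(modelSlope(m), b, tolerance = 1e-8)
  }
})

test_that("slope recovery under 5% noise has small relative bias", {
  set.seed(11)
  a <- 50; b <- 2
  x <- seq(100, 2000, length.out = 25)
  slopes <- replicate(200, {
    y <- a + b * x + rnorm(length(x), 0, 0.05 * mean(a + b * x))
    # noisy draws may fit a slightly negative intercept; that is expected
    suppressWarnings(
      modelSlope(fitTimeModel(data.frame(size = x, seconds = y))))
  })
  expect_lt(abs(mean(slopes) - b) / b, 0.02)
})

test_that("synthetic corpora are reproducible and respect their distribution", {
  expect_equal(nFiles(generateCorpus(0, "uniform", seed = 1)), 0)
  a <- generateCorpus(50, "pareto", seed = 42)
  b <- generateCorpus(50, "pareto", seed = 42)
  expect_identical(sizeChars(a), sizeChars(b))
  expect_false(identical(sizeChars(a),
                         sizeChars(generateCorpus(50, "pareto", seed = 43))))

  # uniform mean within 3 standard errors of (min+max)/2
  u <- generateCorpus(1e4, "uniform", params = list(min = 100, max = 200),
                      seed = 5)
  se <- sqrt((200 - 100)^2 / 12 / 1e4)
  expect_lt(abs(mean(sizeChars(u)) - 150), 3 * se + 0.5)  # 0.5 for rounding

  # KS-style check against the generating CDFs at n = 1e4
  ks <- suppressWarnings(stats::ks.test(
    unname(sizeChars(u)), function(q) punif(q, 100, 200)))
  expect_gt(ks$p.value, 0.01)
  ln <- generateCorpus(1e4, "lognormal",
                       params = list(meanlog = log(5000), sdlog = 1),
                       seed = 6)
  ksl <- suppressWarnings(stats::ks.test(
    unname(sizeChars(ln)), function(q) plnorm(q, log(5000), 1)))
  expect_gt(ksl$p.value, 0.01)
  pa <- generateCorpus(1e4, "pareto",
                       params = list(xmin = 1000, alpha = 1.5), seed = 7)
  ksp <- suppressWarnings(stats::ks.test(
    unname(sizeChars(pa)),
    function(q) ifelse(q < 1000, 0, 1 - (1000 / q)^1.5)))
  expect_gt(ksp$p.value, 0.01)

  expect_error(generateCorpus(10, "uniform",
                              params = list(min = 10, max = 5), seed = 1),
               "invalid parameters")
  expect_error(generateCorpus(10, "pareto", params = list(alpha = -1),
                              seed = 1), "invalid parameters")
})

test_that("materialised files have exactly the recorded sizes", {
  dir <- withr::local_tempdir()
  co <- generateCorpus(8, "uniform", params = list(min = 1, max = 500),
                       seed = 3)
  paths <- materializeCorpus(co, dir, seed = 3)
  expect_equal(unname(sizeChars(measureCorpus(unname(paths)))),
               unname(sizeChars(co)))
  # biomedical vocabulary keeps sizes exact too
  paths2 <- materializeCorpus(co, file.path(dir, "bio"), seed = 3,
                              vocabulary = "biomedical")
  expect_equal(unname(sizeChars(measureCorpus(unname(paths2)))),
               unname(sizeChars(co)))
})

test_that("manifests and model files round-trip", {
  dir <- withr::local_tempdir()
  co <- generateCorpus(12, "twopoint", seed = 9)
  mf <- file.path(dir, "manifest.tsv")
  writeManifest(co, mf)
  back <- readManifest(mf)
  expect_equal(fileIds(back), fileIds(co))
  expect_equal(sizeChars(back), sizeChars(co))

  m <- WorkloadModel(847.95, 1128.46, "MB")
  pf <- file.path(dir, "model.txt")
  writeWorkloadModel(m, pf)
  m2 <- readWorkloadModel(pf)
  expect_equal(modelIntercept(m2), 847.95)
  expect_equal(modelSlope(m2), 1128.46)
  expect_equal(sizeUnit(m2), "MB")
})
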