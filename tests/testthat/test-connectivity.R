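mkPanel <- function(x, tr = 2.46) {
  new("TimeSeriesPanel", data = x, subject = "s1", condition = "W", tr = tr)
}

test_that("temporal cleaning removes trends, nuisance and out-of-band power", {
  nT <- 200
  t <- seq_len(nT)
  ## exact quadratic series vanishes under detrending
  quad <- cbind(3 + 0.5 * t - 0.01 * t^2, -1 + 0.2 * t + 0.002 * t^2)
  out <- cleanTimeSeries(mkPanel(quad), band = NULL, trim = 0L)
  expect_lt(max(abs(out@data)), 1e-8)

  ## regressing a signal on itself leaves nothing
  set.seed(1)
  x <- matrix(rnorm(nT * 3), nT)
  out2 <- cleanTimeSeries(mkPanel(x), band = NULL, nuisance = x, trim = 0L)
  expect_lt(max(abs(out2@data)), 1e-8)

  ## 0.2 Hz sinusoid suppressed by the (0.01, 0.1) Hz band at tr = 2.46 s
  tr <- 2.46
  sine <- matrix(sin(2 * pi * 0.2 * (t * tr)), ncol = 1)
  filt <- cleanTimeSeries(mkPanel(sine, tr), band = c(0.01, 0.1), trim = 0L)
  expect_lt(sum(filt@data^2) / sum(sine^2), 0.1)

  ## detrending is idempotent
  set.seed(2)
  y <- matrix(rnorm(nT * 2), nT) + t
  once <- cleanTimeSeries(mkPanel(y), band = NULL, trim = 4L)
  twice <- cleanTimeSeries(mkPanel(once@data), band = NULL, trim = 0L)
  expect_lt(max(abs(once@data - twice@data)), 1e-10)

  ## trimming removes the first volumes
  expect_equal(nrow(once@data), nT - 4L)
  expect_error(cleanTimeSeries(mkPanel(x), band = c(0.01, 0.3)), "Nyquist")
  expect_warning(
    cleanTimeSeries(mkPanel(x), band = NULL,
                    nuisance = cbind(x[, 1], x[, 1]), trim = 0L),
    "rank-deficient")
})

test_that("correlation matrices follow the textbook formula and invariants", {
  x <- cbind(a = c(1, 2, 3, 5), b = c(2, 4, 6, 10), c = c(4, 1, 0, -3))
  r <- correlationMatrix(mkPanel(x))
  expect_equal(connectivityValues(r)[1, 2], 1)
  expect_equal(connectivityValues(r)[2, 3],
               cor(x[, 2], x[, 3]))
  ## explicit summation oracle
  oracle <- function(u, v) {
    su <- sum((u - mean(u))^2); sv <- sum((v - mean(v))^2)
    sum((u - mean(u)) * (v - mean(v))) / sqrt(su * sv)
  }
  expect_equal(connectivityValues(r)[1, 3], oracle(x[, 1], x[, 3]),
               tolerance = 1e-12)

  neg <- correlationMatrix(mkPanel(cbind(x[, 1], -x[, 1] + 0.5)))
  expect_equal(connectivityValues(neg)[1, 2], -1)

  ## affine rescaling of a column leaves r unchanged; symmetry within 1e-12
  set.seed(3)
  y <- matrix(rnorm(40 * 6), 40)
  r1 <- connectivityValues(correlationMatrix(mkPanel(y)))
  y[, 2] <- 5 * y[, 2] - 7
  r2 <- connectivityValues(correlationMatrix(mkPanel(y)))
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_lt(max(abs(r1 - t(r1))), 1e-12)

  const <- y; const[, 4] <- 2
  expect_error(correlationMatrix(mkPanel(const)), "constant.*3")
})

test_that("correlation summaries match hand counts and a sort oracle", {
  m <- matrix(1, 3, 3)
  m[1, 2] <- m[2, 1] <- -0.5
  m[1, 3] <- m[3, 1] <- 0.1
  m[2, 3] <- m[3, 2] <- 0.3
  s <- correlationSummary(list(asConn(m)))
  expect_equal(s$median, 0.1)
  expect_equal(s$propNegative, 1 / 3)
  expect_equal(s$propAbove04, 0)

  flat <- matrix(0.2, 4, 4)
  s2 <- correlationSummary(list(asConn(flat)))
  expect_equal(s2$median, 0.2)
  expect_equal(c(s2$propNegative, s2$propAbove04, s2$propWithin04),
               c(0, 0, 1))

  set.seed(4)
  rnd <- matrix(runif(400, -1, 1), 20)
  rnd <- (rnd + t(rnd)) / 2
  v <- sort(rnd[upper.tri(rnd)])
  s3 <- correlationSummary(list(asConn(rnd)))
  expect_equal(s3$median, median(v))
  expect_equal(s3$propNegative, sum(v < 0) / length(v))
  expect_equal(sum(s3$histogram), length(v))
})

test_that("KS comparison equals an explicit ECDF scan", {
  expect_equal(ksCompare(1:10, 1:10)$D, 0)
  expect_equal(ksCompare(1:10, 101:110)$D, 1)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50, 0.4)
  res <- ksCompare(a, b)
  expect_equal(res$D, oracleKS(a, b), tolerance = 1e-12)
  expect_true(res$p > 0 && res$p <= 1)
  expect_error(ksCompare(numeric(), a), "empty")
})

test_that("distance binning uses half-open 9 mm bins with remainder bin", {
  a <- toyAtlas(10)
  d <- euclideanDistances(a)
  m <- matrix(0.5, 10, 10)
  bt <- binByDistance(asConn(m), d)
  expect_equal(nrow(bt), 15)
  expect_equal(bt$center, (1:15 - 0.5) * 9)
  expect_equal(sum(bt$nPairs), 45)

  ## pair at 4 mm -> bin 0; pair at exactly 9 mm -> bin 1
  a2 <- ROIAtlas(0:2, c("a", "b", "c"), c("Fcx", "Fcx", "Thl"),
                 x = c(0, 4, 9), y = c(0, 0, 0), z = c(0, 0, 0))
  d2 <- euclideanDistances(a2)
  m2 <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3)
  b2 <- binByDistance(asConn(m2), d2, binWidth = 9, nBins = 3)
  expect_equal(b2$nPairs, c(2L, 1L, 0L))     # 4 and 5 mm in bin 0; 9 mm in bin 1
  expect_equal(b2$meanR[2], 0.4)
  expect_warning(binByDistance(asConn(m2), d2, binWidth = 1000, nBins = 2),
                 "single distance bin")
})
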