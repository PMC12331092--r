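test_that("Mann-Whitney exact path matches hand-enumerated small cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-15)
  expect_equal(r$method, "exact")
})

test_that("identical samples give p = 1 on the tie-corrected approximation path", {
  r <- mann_whitney_u(1:5, 1:5)
  expect_equal(r$method, "normal-approximation")
  expect_equal(r$p_value, 1.0)
})

test_that("exact path agrees with the enumeration oracle across random cases", {
  set.seed(61)
  for (rep in 1:200) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    repeat {
      x <- round(rnorm(n1), 6); y <- round(rnorm(n2), 6)
      if (anyDuplicated(c(x, y)) == 0L) break
    }
    got <- mann_whitney_u(x, y)
    want <- mwu_exact_oracle(x, y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("U-statistic identity and shift/scale invariance hold", {
  set.seed(62)
  for (rep in 1:100) {
    n1 <- sample(2:40, 1); n2 <- sample(2:40, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$statistic + b$statistic, n1 * n2)
    shifted <- mann_whitney_u(3 * x + 7, 3 * y + 7)
    expect_equal(shifted$p_value, a$p_value, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("box summaries follow the Tukey convention", {
  b <- box_summary(1:9)
  expect_equal(b$median, 5); expect_equal(b$q1, 3); expect_equal(b$q3, 7)
  expect_length(b$outliers, 0L)
  b2 <- box_summary(c(1, 1, 1, 1, 100))
  expect_equal(b2$outliers, 100)
  expect_equal(b2$whisker_high, 1)
})

test_that("box summaries agree with direct quantile computation on random data", {
  set.seed(63)
  for (rep in 1:50) {
    v <- rnorm(sample(5:200, 1), sd = sample(1:5, 1))
    b <- box_summary(v)
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    expect_equal(c(b$q1, b$median, b$q3), q)
    iqr <- q[3] - q[1]
    out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    expect_equal(b$outliers, sort(out))
    expect_gte(b$whisker_low, min(v)); expect_lte(b$whisker_high, max(v))
    expect_true(b$q1 <= b$median && b$median <= b$q3)
  }
})

make_hdx <- function(ua, ub, tps = c(10, 100, 1000, 10000), start = 292,
                     end = 302) {
  # ua/ub: function(timepoint) -> replicate vector
  rows <- list()
  for (tp in tps) {
    for (st in c("apo", "bound")) {
      u <- if (st == "apo") ua(tp) else ub(tp)
      rows[[length(rows) + 1]] <- data.frame(
        peptide_start = start, peptide_end = end, state = st,
        timepoint_s = tp, replicate = seq_along(u), uptake_Da = u)
    }
  }
  do.call(rbind, rows)
}

test_that("sub-floor differences are never significant regardless of p", {
  # delta = 0.15 Da with tiny variance: p ~ 1e-3 but below the 0.2 Da floor
  d <- make_hdx(function(tp) c(1.00, 1.01, 0.99),
                function(tp) c(1.15, 1.16, 1.14))
  cmp <- hdx_compare(d, "apo", "bound")
  expect_true(all(cmp$p_value < 0.05))
  expect_true(all(abs(cmp$delta_Da - 0.15) < 1e-9))
  expect_false(any(cmp$significant))
})

test_that("identical states give zero delta and no significance", {
  d <- make_hdx(function(tp) c(1, 1.1, 0.9), function(tp) c(1, 1.1, 0.9))
  cmp <- hdx_compare(d, "apo", "bound")
  expect_true(all(cmp$delta_Da == 0))
  expect_false(any(cmp$significant))
  expect_equal(hdx_classify_regions(cmp)$peptide_class, "ns")
})

test_that("a clear 0.5 Da difference is significant at every timepoint", {
  set.seed(64)
  d <- make_hdx(function(tp) 1 + rnorm(3, sd = 0.05),
                function(tp) 1.5 + rnorm(3, sd = 0.05))
  cmp <- suppressWarnings(hdx_compare(d, "apo", "bound"))
  expect_true(all(cmp$significant))
  expect_equal(hdx_classify_regions(cmp)$peptide_class, "increased")
})

test_that("significance requires BOTH p < 0.05 and |delta| >= 0.2 over a grid", {
  set.seed(65)
  for (delta in c(0, 0.05, 0.1, 0.19, 0.21, 0.5, -0.1, -0.3)) {
    for (sigma in c(0.01, 0.1, 0.5)) {
      u_a <- 3 + rnorm(3, sd = sigma)
      u_b <- u_a - mean(u_a) + 3 + delta
      d <- make_hdx(function(tp) u_a, function(tp) u_b, tps = 10)
      cmp <- hdx_compare(d, "apo", "bound")
      if (abs(cmp$delta_Da) < 0.2) expect_false(cmp$significant)
      if (cmp$significant) {
        expect_lt(cmp$p_value, 0.05)
        expect_gte(abs(cmp$delta_Da), 0.2)
      }
    }
  }
})

test_that("the pooled-variance t test is equivalent to a two-group one-way ANOVA", {
  set.seed(66)
  for (rep in 1:20) {
    a <- rnorm(3, mean = 1, sd = 0.1); b <- rnorm(3, mean = 1.4, sd = 0.1)
    p_t <- t.test(b, a, var.equal = TRUE)$p.value
    df <- data.frame(u = c(a, b), g = rep(c("A", "B"), each = 3))
    p_f <- summary(aov(u ~ g, data = df))[[1]][["Pr(>F)"]][1]
    expect_equal(p_t, p_f, tolerance = 1e-10)
  }
})

test_that("region classification covers all direction combinations", {
  base <- make_hdx(function(tp) c(1, 1.01, 0.99),
                   function(tp) c(2, 2.01, 1.99), tps = c(10, 100))
  up <- hdx_compare(base, "apo", "bound")
  expect_equal(hdx_classify_regions(up)$peptide_class, "increased")
  down <- hdx_compare(base, "bound", "apo")
  expect_equal(hdx_classify_regions(down)$peptide_class, "decreased")
  # one significant positive + one significant negative timepoint -> mixed
  mix <- make_hdx(function(tp) if (tp == 10) c(1, 1.01, 0.99) else c(2, 2.01, 1.99),
                  function(tp) if (tp == 10) c(2, 2.01, 1.99) else c(1, 1.01, 0.99),
                  tps = c(10, 100))
  cmp <- suppressWarnings(hdx_compare(mix, "apo", "bound"))
  expect_equal(hdx_classify_regions(cmp)$peptide_class, "mixed")
})

test_that("classification is invariant under timepoint order", {
  set.seed(67)
  d <- make_hdx(function(tp) 1 + rnorm(3, sd = 0.05),
                function(tp) 1.5 + rnorm(3, sd = 0.05))
  cmp <- suppressWarnings(hdx_compare(d, "apo", "bound"))
  shuf <- cmp[sample(nrow(cmp)), ]
  expect_equal(hdx_classify_regions(cmp), hdx_classify_regions(shuf))
})

test_that("data-completeness problems are reported by name", {
  d <- make_hdx(function(tp) c(1, 1.1, 0.9), function(tp) c(1, 1.1, 0.9))
  expect_error(hdx_compare(d, "apo", "nosuch"), "absent")
  d1 <- d[!(d$state == "bound" & d$replicate > 1), ]
  expect_error(hdx_compare(d1, "apo", "bound"), ">= 2 replicates")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[, -6], f, row.names = FALSE)
  expect_error(read_hdx_csv(f), "uptake_Da")
})
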