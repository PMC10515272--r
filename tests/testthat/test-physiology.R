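test_that("RWC formula and saturation identities", {
  expect_equal(rwc(2.0, 2.5, 0.5), 75)
  expect_equal(rwc(2.5, 2.5, 0.5), 100)  # FW = SW
  expect_equal(rwc(0.5, 2.5, 0.5), 0)    # FW = DW
  expect_error(rwc(1, 1, 1), "undefined")
  expect_warning(out <- rwc(3.0, 2.5, 0.5), "outside")
  expect_equal(out, 125)
  # scale invariance: rwc(cFW, cSW, cDW) = rwc(FW, SW, DW)
  withr::with_seed(8, {
    for (i in 1:20) {
      dw <- runif(1, 0.1, 1); sw <- dw + runif(1, 0.5, 2)
      fw <- runif(1, dw, sw); cc <- runif(1, 0.1, 10)
      expect_equal(rwc(cc * fw, cc * sw, cc * dw), rwc(fw, sw, dw))
    }
  })
})

test_that("REC formula and bounds", {
  expect_equal(rec(1.2, 1.2), 100)
  expect_equal(rec(0.3, 1.2), 25)
  expect_equal(rec(0, 1.2), 0)
  expect_error(rec(1, 0), "positive")
  expect_warning(rec(1.5, 1.2), "above 100")
})

test_that("MDA formula matches the hand-derived worked example", {
  # (0.155 * 4 / 1.55e5 * 1e9) / (0.3 * 1 / 3) = 40,000 nM/g
  expect_equal(mda(0.175, 0.02, vr = 4, wt = 0.3, vt = 1, v = 3), 40000)
  expect_equal(mda(0.1, 0.1, vr = 4, wt = 0.3, vt = 1, v = 3), 0)
  # linear in the absorbance difference; inversely proportional to Wt
  base <- mda(0.12, 0.02, vr = 4, wt = 0.3, vt = 1, v = 3)
  expect_equal(mda(0.22, 0.02, vr = 4, wt = 0.3, vt = 1, v = 3), 2 * base)
  expect_equal(mda(0.12, 0.02, vr = 4, wt = 0.6, vt = 1, v = 3), base / 2)
  expect_warning(neg <- mda(0.02, 0.12, vr = 4, wt = 0.3, vt = 1, v = 3),
                 "negative")
  expect_equal(neg, -base)
  expect_error(mda(0.1, 0.05, vr = 0, wt = 0.3, vt = 1, v = 3), "positive")
})

test_that("compute_physiology appends whichever metrics the table supports", {
  p <- simulate_physiology(n_per_group = 3, seed = 2)
  out <- compute_physiology(p)
  expect_true(all(c("rwc", "rec", "mda") %in% names(out)))
  expect_equal(out$rwc, rwc(p$fw, p$sw, p$dw))
  partial <- compute_physiology(p[, c("sample_id", "k1", "k2")])
  expect_true("rec" %in% names(partial))
  expect_false("rwc" %in% names(partial))
})

test_that("group comparison separates well-separated groups", {
  withr::with_seed(42, {
    d <- data.frame(
      g = rep(c("a_grp", "b_grp"), each = 15),
      y = c(rnorm(15, 0, 1), rnorm(15, 5, 1))
    )
  })
  gc <- group_compare(d, "y", "g")
  td <- tidy(gc)
  expect_lt(glance(gc)$p_value, 1e-6)
  expect_false(td$letter[1] == td$letter[2])
})

test_that("identical groups share a single letter", {
  d2 <- data.frame(g = rep(c("x", "y"), each = 4), y = rep(3.3, 8))
  gc2 <- group_compare(d2, "y", "g")
  expect_equal(dplyr::n_distinct(tidy(gc2)$letter), 1)
  d3 <- data.frame(g = rep(c("x", "y", "z"), each = 4), y = rep(1.1, 12))
  gc3 <- group_compare(d3, "y", "g")
  expect_equal(unique(tidy(gc3)$letter), tidy(gc3)$letter[1])
  expect_error(group_compare(d3[1:4, ], "y", "g"), ">= 2 groups")
})

test_that("ANOVA p-values are uniform under label permutation", {
  withr::with_seed(99, {
    y <- rnorm(24)
    g <- rep(c("a", "b", "c"), each = 8)
    pvals <- vapply(seq_len(400), function(i) {
      summary(stats::aov(y ~ gp, data = data.frame(y = y, gp = sample(g))))[[1]][["Pr(>F)"]][1]
    }, numeric(1))
    ks <- stats::ks.test(pvals, "punif")
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("planted physiology effects give the expected group ordering", {
  p <- compute_physiology(simulate_physiology(seed = 12))
  gc <- group_compare(p, "rwc", "treatment")
  m <- tidy(gc)
  expect_gt(m$mean[m$group == "well_watered"], m$mean[m$group == "drought_cep10"])
  expect_gt(m$mean[m$group == "drought_cep10"], m$mean[m$group == "drought"])
  expect_false(m$letter[m$group == "well_watered"] ==
                 m$letter[m$group == "drought"])
  gc_rec <- group_compare(p, "rec", "treatment")
  m2 <- tidy(gc_rec)
  expect_gt(m2$mean[m2$group == "drought"], m2$mean[m2$group == "well_watered"])
})
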