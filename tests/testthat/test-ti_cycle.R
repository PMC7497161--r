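test_that("dH/dlambda averaging returns the mean with block-averaged SE", {
  const <- lambda_series(0.5, rep(3.25, 100))
  expect_equal(average_dhdl(const), c(mean = 3.25, se = 0))

  withr::with_seed(99, {
    x <- stats::rnorm(1e4, mean = 5, sd = 1)
  })
  est <- average_dhdl(lambda_series(0.2, x))
  expect_equal(unname(est["mean"]), mean(x))
  expect_lt(abs(est[["mean"]] - 5), 3 / sqrt(1e4))
  # block SE is in the same ballpark as the iid SE for iid data
  expect_lt(est[["se"]], 3 / sqrt(1e4))
  expect_gt(est[["se"]], 0.3 / sqrt(1e4))

  half <- lambda_series(0, c(rep(0, 50), rep(1, 50)))
  expect_equal(average_dhdl(half, discard_fraction = 0.5)[["mean"]], 1)
  expect_error(average_dhdl(half, discard_fraction = 1), "discard_fraction")
})

test_that("TI integration is exact for constant, linear and cubic curves", {
  lam <- seq(0, 1, length.out = 11)

  const <- ti_profile_from_means(lam, rep(4.2, 11))
  expect_equal(integrate_ti(const, "trapezoid")$dG, 4.2, tolerance = 1e-12)
  expect_equal(integrate_ti(const, "spline-101")$dG, 4.2, tolerance = 1e-9)

  a <- 2.5; b <- -8
  lin <- ti_profile_from_means(lam, a + b * lam)
  expect_equal(integrate_ti(lin, "trapezoid")$dG, a + b / 2, tolerance = 1e-12)
  expect_equal(integrate_ti(lin, "spline-101")$dG, a + b / 2, tolerance = 1e-9)

  # cubic mean curve: spline-101 must match the analytic integral closely
  cf <- c(5, -10, 12, -4)
  cubic_mean <- sapply(lam, function(l) sum(cf * l^(0:3)))
  analytic <- sum(cf / (1:4))
  cub <- ti_profile_from_means(lam, cubic_mean)
  expect_equal(integrate_ti(cub, "spline-101")$dG, analytic, tolerance = 1e-6)

  expect_error(integrate_ti(ti_profile_from_means(c(0, 0.5), c(1, 1))), "span")
  expect_error(integrate_ti(ti_profile_from_means(c(0, 1.2), c(1, 1))),
               "lambda")
})

test_that("propagated integration uncertainty follows the quadrature weights", {
  lam <- seq(0, 1, length.out = 11)
  se <- rep(0.5, 11)
  prof <- ti_profile_from_means(lam, rep(0, 11), se)
  # equidistant trapezoid weights: h/2 at the ends, h inside
  h <- 0.1
  w <- c(h / 2, rep(h, 9), h / 2)
  expect_equal(integrate_ti(prof, "trapezoid")$sd, sqrt(sum((w * se)^2)),
               tolerance = 1e-12)
  # spline weights still sum to one (they integrate the constant exactly)
  expect_gt(integrate_ti(prof, "spline-101")$sd, 0)
})

test_that("ddg arithmetic: leg differences, antisymmetry, catalytic split", {
  bound <- free_energy_leg("bound", "Asp323Thr", -3.0, 0.3)
  apo <- free_energy_leg("apo", "Asp323Thr", 4.5, 0.4)
  d <- ddg_leg(bound, apo)
  expect_equal(d$ddg, -7.5)
  expect_equal(d$sd, 0.5)
  expect_equal(ddg_leg(apo, bound)$ddg, 7.5)
  expect_equal(ddg_leg(bound, bound)$ddg, 0)
  other <- free_energy_leg("apo", "His226Ala", 1, 0.1)
  expect_error(ddg_leg(bound, other), "different mutations")

  cd <- ddg_catalytic(c(-7.5, 0.8), c(-11.2, 3.4), mutation = "Asp323Thr")
  expect_equal(cd$ddg_cat[["value"]], 3.7)
  expect_equal(cd$ddg_cat[["sd"]], sqrt(0.8^2 + 3.4^2))
  eq <- ddg_catalytic(c(2, 0), c(2, 0))
  expect_equal(eq$ddg_cat[["value"]], 0)
})

test_that("cycle totals and closure reproduce the reference ledgers", {
  l <- ti_reference_ledgers()
  t1 <- cycle_total(l$path1)
  t2 <- cycle_total(l$path2)
  expect_equal(unname(t1["total"]), 2.1, tolerance = 1e-9)
  expect_equal(unname(t2["total"]), 2.7, tolerance = 1e-9)
  expect_equal(cycle_closure(l$path1, l$path2), 0.6, tolerance = 1e-9)
  expect_equal(cycle_closure(l$path1, l$path1), 0)

  single <- cycle_ledger(data.frame(mutation = "m", ddg = -1.25, sd = 0.1))
  expect_equal(unname(cycle_total(single)["total"]), -1.25)
  expect_error(cycle_ledger(data.frame(mutation = character(),
                                       ddg = numeric())), "nrow")
  mismatched <- cycle_ledger(data.frame(mutation = "other", ddg = 1))
  expect_error(cycle_closure(l$path1, mismatched), "endpoint")
})

test_that("closure vanishes for ledgers built from a state function", {
  # per-state scalar free energies guarantee path independence
  withr::with_seed(21, {
    for (rep in 1:10) {
      g <- stats::rnorm(5, sd = 10)  # states: wt, +m1, +m1m2, +m1m2m3, full
      muts <- paste0("mut", 1:4)
      p1 <- cycle_ledger(data.frame(mutation = muts, ddg = diff(g)), path_id = 1)
      g_rev <- c(g[1], g[1] + cumsum(rev(diff(g))))
      p2 <- cycle_ledger(data.frame(mutation = rev(muts), ddg = diff(g_rev)),
                         path_id = 2)
      expect_lt(cycle_closure(p1, p2), 1e-9)
    }
  })
})

test_that("replicate combination uses the n-1 sample standard deviation", {
  expect_equal(combine_replicates(rep(2.5, 4)), c(mean = 2.5, sd = 0))
  got <- combine_replicates(1:6)
  expect_equal(unname(got["mean"]), 3.5)
  expect_equal(unname(got["sd"]), sqrt(3.5), tolerance = 1e-9)
  withr::with_seed(3, {
    x <- stats::rnorm(12)
  })
  expect_equal(combine_replicates(sample(x)), combine_replicates(x))
  expect_error(combine_replicates(1), "at least 2")
})

test_that("dhdl TSVs and manifests rebuild ledgers end to end", {
  dir <- withr::local_tempdir()
  # two mutations, complex/apo legs, constant mean curves with known ddg
  legs <- list(
    m1_complex = c(4, 4), m1_apo = c(1, 1),   # ddg 3
    m2_complex = c(-2, -2), m2_apo = c(0.5, 0.5))  # ddg -2.5
  for (nm in names(legs)) {
    lam <- rep(seq(0, 1, length.out = 5), each = 20)
    df <- data.frame(lambda = lam, time = seq_along(lam) * 0.04,
                     dhdl = rep(legs[[nm]][1], length(lam)))
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    endpoint = "double",
    paths = list(list(path_id = 1, steps = list(
      list(mutation = "mut1", complex = "m1_complex.tsv", apo = "m1_apo.tsv"),
      list(mutation = "mut2", complex = "m2_complex.tsv", apo = "m2_apo.tsv"))))),
    manifest)
  ledgers <- read_ti_manifest(manifest)
  expect_named(ledgers, "path1")
  expect_equal(ledgers$path1$steps$ddg, c(3, -2.5), tolerance = 1e-9)
  expect_equal(unname(cycle_total(ledgers$path1)["total"]), 0.5,
               tolerance = 1e-9)
})
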