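reg <- mcid_registry()

# convenience: a bare difference object for classification tests
diff_of <- function(outcome, diff) {
  structure(list(outcome = outcome, diff = diff, gray = FALSE),
            class = "oscar_diff")
}

test_that("group differences are upper-minus-lower in outcome units", {
  upper <- group_with(fev1_l = rep(1.0, 60))
  lower <- group_with(fev1_l = rep(1.138, 60))
  d <- compute_group_difference(upper, lower, "fev1_ml", reg)
  expect_equal(d$diff, -138, tolerance = 1e-9)
  expect_identical(d$summary_kind, "mean")
  expect_identical(c(d$n_upper, d$n_lower), c(60L, 60L))

  same <- compute_group_difference(upper, upper, "fev1_ml", reg)
  expect_identical(same$diff, 0)

  # binary outcomes compare proportions in percentage points
  du <- group_with(dead_3y = rep(c(1, 0), c(40, 60)))
  dl <- group_with(dead_3y = rep(c(1, 0), c(61, 39)))
  dd <- compute_group_difference(du, dl, "dead_3y", reg)
  expect_equal(dd$diff, -21)
  expect_identical(dd$summary_kind, "proportion")
})

test_that("empty outcome data gives a gray cell, not a failure", {
  upper <- group_with(sgrq = c(NA_real_, NA_real_, NA_real_))
  lower <- group_with(sgrq = c(30, 40, 50))
  d <- compute_group_difference(upper, lower, "sgrq", reg)
  expect_true(d$gray)
  expect_identical(classify_mcid(d, reg), "gray")
})

test_that("MCID classification reproduces the published quartile contrasts", {
  # inflammatory-panel contrasts: upper quartile clinically worse
  expect_identical(classify_mcid(diff_of("fev1_ml", -138), reg), "red")
  expect_identical(classify_mcid(diff_of("smwd", -59), reg), "red")
  expect_identical(classify_mcid(diff_of("sgrq", 10.7), reg), "red")
  expect_identical(classify_mcid(diff_of("bode", 1.75), reg), "red")
  # injury-and-repair contrasts: upper quartile clinically better
  expect_identical(classify_mcid(diff_of("fev1_ml", 345), reg), "green")
  expect_identical(classify_mcid(diff_of("smwd", 83.5), reg), "green")
  expect_identical(classify_mcid(diff_of("sgrq", -18.4), reg), "green")
  expect_identical(classify_mcid(diff_of("bode", -1.5), reg), "green")
})

test_that("differences inside the MCID are yellow; the MCID itself is not", {
  for (oc in c("fev1_ml", "smwd", "sgrq", "mmrc", "bode")) {
    m <- reg[[oc]]$mcid
    eps <- m * 1e-9
    expect_identical(classify_mcid(diff_of(oc, m - eps), reg), "yellow")
    expect_identical(classify_mcid(diff_of(oc, -(m - eps)), reg), "yellow")
    expect_false(classify_mcid(diff_of(oc, m), reg) == "yellow")
  }
  expect_error(classify_mcid(diff_of("nonesuch", 1), reg), "nonesuch")
  expect_error(classify_mcid(diff_of("dead_3y", 10), reg), "no MCID")
})

test_that("color antisymmetry: flipping sign and direction swaps green and red", {
  set.seed(31)
  flip_dir <- function(r, oc) {
    r[[oc]]$direction <- if (r[[oc]]$direction == "higher_is_better")
      "lower_is_better" else "higher_is_better"
    r
  }
  swap <- c(green = "red", red = "green", yellow = "yellow", gray = "gray")
  for (i in 1:100) {
    oc <- sample(c("fev1_ml", "smwd", "sgrq", "mmrc", "bode"), 1)
    d <- runif(1, -3, 3) * reg[[oc]]$mcid
    a <- classify_mcid(diff_of(oc, d), reg)
    # flipping only the direction of benefit swaps green and red
    expect_identical(classify_mcid(diff_of(oc, d), flip_dir(reg, oc)),
                     unname(swap[a]))
    # re-expressing the outcome on the opposite scale (negated values AND
    # flipped direction, as in survival -> death) preserves the color
    expect_identical(classify_mcid(diff_of(oc, -d), flip_dir(reg, oc)), a)
  }
})

test_that("exchanging the groups negates the difference and swaps colors", {
  set.seed(32)
  swap <- c(green = "red", red = "green", yellow = "yellow")
  for (i in 1:25) {
    u <- group_with(sgrq = runif(30, 0, 100))
    l <- group_with(sgrq = runif(30, 0, 100))
    d1 <- compute_group_difference(u, l, "sgrq", reg)
    d2 <- compute_group_difference(l, u, "sgrq", reg)
    expect_equal(d2$diff, -d1$diff)
    expect_identical(classify_mcid(d2, reg),
                     unname(swap[classify_mcid(d1, reg)]))
  }
})

test_that("fallback tests color by significance and direction", {
  # identical groups: yellow with p = 1
  g <- group_with(dead_3y = rep(c(1, 0), 10), dlco_pct = rep(40:49, 2))
  res <- classify_by_test(g, g, "dead_3y", reg)
  expect_identical(res$color, "yellow")
  expect_equal(res$p_value, 1)
  res2 <- classify_by_test(g, g, "dlco_pct", reg)
  expect_identical(res2$color, "yellow")
  expect_gt(res2$p_value, 0.99)

  # fully separated 2x2 table: p < 0.001, direction-colored
  u <- group_with(dead_3y = rep(1, 10))
  l <- group_with(dead_3y = rep(0, 10))
  sep <- classify_by_test(u, l, "dead_3y", reg)
  expect_lt(sep$p_value, 0.001)
  expect_identical(sep$color, "red")   # more death in the upper group
  expect_identical(classify_by_test(l, u, "dead_3y", reg)$color, "green")

  # sparse table (expected count < 1) switches to the exact conditional test
  us <- group_with(dead_3y = rep(c(1, 0), c(1, 9)))
  ls <- group_with(dead_3y = rep(0, 10))
  sparse <- classify_by_test(us, ls, "dead_3y", reg)
  expect_identical(sparse$method, "exact")
  expect_equal(sparse$p_value, fisher.test(rbind(c(1, 9), c(0, 10)))$p.value,
               tolerance = 1e-10)

  expect_error(classify_by_test(u, l, "sgrq", reg), "no fallback")
})

test_that("the exact 2x2 p-value matches an independent enumeration oracle", {
  set.seed(33)
  tabs <- c(list(matrix(c(10, 0, 0, 10), 2, 2),
                 matrix(c(1, 0, 0, 1), 2, 2),
                 matrix(c(0, 5, 5, 0), 2, 2)),
            lapply(1:30, function(i) matrix(rpois(4, 4), 2, 2)))
  for (tab in tabs) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(oscarpanel:::exact_test_2x2(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("mortality separates by inflammatory quartile in a coupled cohort", {
  co <- make_cohort(2000, seed = 12)
  score <- composite_panel_score(co, ib_panel)
  grp <- extreme_groups(co, assign_quartiles(score))
  res <- classify_by_test(grp$upper, grp$lower, "dead_3y", reg)
  expect_identical(res$color, "red")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$diff$diff, 0)  # more death in the high-inflammation quartile
})

test_that("the OSCAR matrix reproduces the qualitative published pattern", {
  co <- make_cohort(2530, seed = 42)
  mat <- build_oscar_matrix(co)
  expect_s3_class(mat, "oscar_matrix")
  # complete over requested biomarkers x outcomes
  expect_equal(nrow(mat$cells), 8 * length(mat$outcomes))
  ib_colors <- as.vector(mat$colors[ib_panel, ])
  irb_colors <- as.vector(mat$colors[irb_panel, ])
  # inflammatory rows skew red, never green; injury-and-repair rows skew
  # green, never red
  expect_identical(sum(ib_colors == "green"), 0L)
  expect_gt(sum(ib_colors == "red"), length(ib_colors) / 3)
  expect_identical(sum(irb_colors == "red"), 0L)
  expect_gt(sum(irb_colors == "green"), length(irb_colors) / 2)
  # determinism given the cohort
  expect_identical(mat$colors, build_oscar_matrix(co)$colors)
})

test_that("panel mode yields one composite row", {
  co <- make_cohort(500, seed = 8)
  mat <- build_oscar_matrix(co, biomarkers = ib_panel, mode = "panel")
  expect_identical(mat$biomarkers, "panel")
  expect_equal(nrow(mat$cells), length(mat$outcomes))
})

test_that("an uncoupled cohort is predominantly yellow", {
  yellows <- vapply(1:3, function(s) {
    co <- make_cohort(253, seed = 100 + s, coupling = "independent")
    mat <- build_oscar_matrix(co)
    mean(mat$cells$color == "yellow")
  }, numeric(1))
  expect_gt(mean(yellows), 0.80)
})

test_that("OSCAR matrices round-trip through JSON", {
  co <- make_cohort(253, seed = 15)
  mat <- build_oscar_matrix(co, biomarkers = c("il6", "mmp9"))
  path <- tempfile(fileext = ".json")
  write_oscar_matrix(mat, path)
  back <- read_oscar_matrix(path)
  expect_identical(back$colors, mat$colors)
  expect_equal(back$cells$diff, mat$cells$diff, tolerance = 1e-9)
})
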