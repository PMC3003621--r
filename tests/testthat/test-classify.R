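mk_diff <- function(mean, cov, id = "g") {
  structure(list(gene_id = id, mean = mean, cov = cov),
            class = "diff_posterior")
}

test_that("grid thresholds come from the across-gene SD of posterior means", {
  d1 <- mk_diff(c(-1, -1), diag(2), "a")
  d2 <- mk_diff(c(1, 1), diag(2), "b")
  g <- build_grid(list(d1, d2), c_mult = 1.5)
  expect_equal(g$thr_ge, c(-1.5 * sqrt(2), 1.5 * sqrt(2)))
  expect_equal(g$thr_m, c(-1.5 * sqrt(2), 1.5 * sqrt(2)))
  expect_error(build_grid(list(d1, d2), c_mult = 0), "c_mult")
  expect_error(build_grid(list(d1, d1)), "constant")
  # sampling check against the generative SD
  set.seed(5)
  ds <- lapply(1:20000, function(i)
    mk_diff(c(rnorm(1, 0, 2), rnorm(1, 0, 2)), diag(2), paste0("g", i)))
  gg <- build_grid(ds)
  expect_equal(gg$sd_ge, 2, tolerance = 0.04)
})

test_that("independent axes factor into the product of univariate bins", {
  g <- build_grid(list(mk_diff(c(-1, -1), diag(2)),
                       mk_diff(c(1, 1), diag(2))), 1)
  d <- mk_diff(c(0.3, -0.2), diag(c(0.8, 1.3)))
  p <- region_probs(d, g)
  px <- diff(pnorm(c(-Inf, g$thr_ge, Inf), 0.3, sqrt(0.8)))
  py <- diff(pnorm(c(-Inf, g$thr_m, Inf), -0.2, sqrt(1.3)))
  oracle <- as.vector(outer(py, px))   # meth inner, expression outer
  expect_equal(unname(p), oracle, tolerance = 1e-7)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("huge thresholds put all mass in the center region", {
  g <- structure(list(c_mult = 50, sd_ge = 1, sd_m = 1,
                      thr_ge = c(-50, 50), thr_m = c(-50, 50)),
                 class = "region_grid")
  p <- region_probs(mk_diff(c(0, 0), diag(2)), g)
  expect_equal(unname(p["NG/NM"]), 1, tolerance = 1e-9)
})

test_that("correlated region probabilities match Monte Carlo", {
  g <- structure(list(c_mult = 1.5, sd_ge = 0.6, sd_m = 0.5,
                      thr_ge = c(-0.9, 0.9), thr_m = c(-0.75, 0.75)),
                 class = "region_grid")
  cases <- list(
    list(mean = c(0, 0), rho = 0.6, s = c(1, 1)),
    list(mean = c(0.8, -0.4), rho = 0.6, s = c(0.7, 1.2)),
    list(mean = c(-1.2, 0.9), rho = -0.7, s = c(1.1, 0.6)),
    list(mean = c(0.2, 0.1), rho = 0.95, s = c(0.5, 0.5)),
    list(mean = c(2, 2), rho = -0.3, s = c(1.5, 0.4)))
  set.seed(11)
  n <- 1e6
  for (cs in cases) {
    C <- diag(cs$s) %*% matrix(c(1, cs$rho, cs$rho, 1), 2) %*% diag(cs$s)
    p <- region_probs(mk_diff(cs$mean, C), g)
    x <- mvtnorm::rmvnorm(n, cs$mean, C)
    bx <- cut(x[, 1], c(-Inf, g$thr_ge, Inf), labels = c("DN", "NG", "UP"))
    by <- cut(x[, 2], c(-Inf, g$thr_m, Inf), labels = c("HO", "NM", "HR"))
    emp <- table(by, bx) / n
    for (e in c("DN", "NG", "UP")) for (m in c("HO", "NM", "HR")) {
      phat <- emp[m, e]
      se <- sqrt(phat * (1 - phat) / n)
      expect_lt(abs(p[paste(e, m, sep = "/")] - phat), 3 * se + 1e-6)
    }
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("assignment rules use the cutoff and a fixed tie-break", {
  labs <- category_labels()
  probs <- rbind(
    g1 = ifelse(labs == "NG/HO", 0.8, 0.2 / 8),
    g2 = ifelse(labs == "UP/NM", 0.55, 0.45 / 8),
    g3 = rep(1 / 9, 9))
  colnames(probs) <- labs
  a_max <- assign_categories(probs, "max")
  expect_equal(a_max$assigned, c("NG/HO", "UP/NM", labs[1]))
  a_06 <- assign_categories(probs, "max>0.6")
  expect_equal(a_06$assigned, c("NG/HO", "UNASSIGNED", "UNASSIGNED"))
  a_07 <- assign_categories(probs, "max>0.7")
  expect_equal(a_07$assigned, c("NG/HO", "UNASSIGNED", "UNASSIGNED"))
})

test_that("the posterior-probability FDR follows its defining sums", {
  labs <- category_labels()
  mk <- function(p) { m <- matrix((1 - p) / 8, length(p), 9,
                                  dimnames = list(NULL, labs))
                      m[, "UP/HO"] <- p; m }
  r <- fdr_report(mk(c(1, 1, 1)), "UP/HO", 0.5)
  expect_equal(r$n_selected, 3); expect_equal(r$fdr_hat, 0)
  r2 <- fdr_report(mk(c(0.9, 0.8, 0.7)), "UP/HO", 0.75)
  expect_equal(r2$n_selected, 2)
  expect_equal(r2$D, 0.3)
  expect_equal(r2$fdr_hat, 0.15)
  r3 <- fdr_report(mk(c(0.9, 0.8)), "UP/HO", 1)
  expect_equal(r3$n_selected, 0)
  expect_true(is.na(r3$fdr_hat))
})

test_that("raising kappa never grows the selection or its error mass", {
  set.seed(21)
  p <- runif(200, 0.3, 1)
  labs <- category_labels()
  m <- matrix((1 - p) / 8, 200, 9, dimnames = list(NULL, labs))
  m[, "NG/NM"] <- p
  ks <- seq(0.3, 1, by = 0.05)
  rep_ <- lapply(ks, fdr_report, prob_matrix = m, category = "NG/NM")
  ns <- vapply(rep_, `[[`, numeric(1), "n_selected")
  Ds <- vapply(rep_, `[[`, numeric(1), "D")
  expect_true(all(diff(ns) <= 0))
  expect_true(all(diff(Ds) <= 1e-12))
})

test_that("category tables tally assignments and show rule nesting", {
  labs <- category_labels()
  set.seed(4)
  # concentrated, so that rules differ
  n <- 50
  p <- matrix(0, n, 9, dimnames = list(paste0("g", 1:n), labs))
  for (i in 1:n) {
    k <- sample(9, 1)
    w <- runif(1, 0.4, 0.95)
    p[i, ] <- (1 - w) / 8; p[i, k] <- w
  }
  rules <- c("max", "max>0.6", "max>0.7")
  asg <- lapply(rules, assign_categories, prob_matrix = p)
  tab <- category_table(asg)
  counts <- attr(tab, "counts")
  # totals per rule equal assigned gene counts
  for (r in seq_along(rules))
    expect_equal(sum(counts[r, , ]),
                 sum(asg[[r]]$assigned != "UNASSIGNED"))
  # nesting in every cell
  expect_true(all(counts[1, , ] >= counts[2, , ]))
  expect_true(all(counts[2, , ] >= counts[3, , ]))
  # oracle tally by direct set arithmetic for one cell
  expect_equal(counts[1, "NM", "UP"],
               sum(asg[[1]]$assigned == "UP/NM"))
  expect_match(tab[1, 1], "^[0-9]+/[0-9]+/[0-9]+$")
})
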