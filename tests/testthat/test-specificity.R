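tissues7 <- paste0("t", 1:7)

mat1 <- function(e, name = "g1") {
  m <- matrix(e, nrow = 1, dimnames = list(name, tissues7))
  m
}

test_that("entropy scores match the closed forms for archetypal genes", {
  # exclusive expression: perfectly specific
  sc <- entropy_scores(mat1(c(50, 0, 0, 0, 0, 0, 0)), pseudocount = 0)
  expect_equal(unname(sc$H["g1"]), 0)
  expect_equal(unname(sc$Q["g1", "t1"]), 0)
  expect_true(all(is.infinite(sc$Q["g1", -1])))
  # uniform expression: maximally unspecific
  sc <- entropy_scores(mat1(rep(8, 7)), pseudocount = 0)
  expect_equal(unname(sc$H["g1"]), log2(7), tolerance = 1e-12)
  expect_equal(unname(sc$Q["g1", ]), rep(2 * log2(7), 7), tolerance = 1e-12)
})

test_that("entropy scores equal a brute-force formula oracle", {
  e <- c(70, 5, 5, 5, 5, 5, 5)
  want <- oracle_entropy(e)
  sc <- entropy_scores(mat1(e), pseudocount = 0)
  expect_equal(unname(sc$H["g1"]), want$H, tolerance = 1e-12)
  expect_equal(unname(sc$Q["g1", ]), want$Q, tolerance = 1e-12)
  # random vectors, with pseudocount
  withr::with_seed(7, {
    for (i in 1:20) {
      e <- runif(7, 0, 200)
      want <- oracle_entropy(e, pseudocount = 1e-3)
      sc <- entropy_scores(mat1(e))
      expect_equal(unname(sc$Q["g1", ]), want$Q, tolerance = 1e-12)
    }
  })
})

test_that("entropy scores obey their structural invariants", {
  withr::with_seed(11, {
    expr <- matrix(rexp(100 * 7, 1 / 50), 100, 7,
                   dimnames = list(sprintf("g%03d", 1:100), tissues7))
  })
  sc <- entropy_scores(expr)
  expect_true(all(sc$Q >= sc$H - 1e-12)) # Q_t = H - log2 p_t >= H
  expect_true(all(sc$H >= 0 & sc$H <= log2(7) + 1e-12))
  # Q minimized in the tissue of maximal share
  expect_equal(unname(apply(sc$Q, 1, which.min)),
               unname(apply(expr, 1, which.max)))
  # invariance under global rescaling of a gene's expression vector
  expect_equal(entropy_scores(expr * 7, pseudocount = 0)$Q,
               entropy_scores(expr, pseudocount = 0)$Q, tolerance = 1e-9)
  # degenerate inputs
  expect_error(entropy_scores(expr[, 1, drop = FALSE]), "2 tissues")
  zero <- entropy_scores(rbind(expr, gz = rep(0, 7)), pseudocount = 0)
  expect_true("gz" %in% zero$zero_genes)
  expect_true(is.na(zero$H["gz"]))
})

test_that("Laplace tail threshold matches the analytic quantile", {
  withr::with_seed(123, {
    x <- rexp(20000) - rexp(20000) # standard Laplace(0, 1)
  })
  thr <- laplace_specific_threshold(x, tail_area = 0.01)
  expect_equal(thr, log(0.02), tolerance = 0.05 / abs(log(0.02)))
  expect_lt(abs(thr - log(0.02)), 0.05) # within 0.05 bits at n = 20,000
  # center: half the area lies below the median
  expect_equal(laplace_specific_threshold(x, tail_area = 0.5), median(x))
  # location equivariance
  expect_equal(laplace_specific_threshold(x + 4.2, 0.01), thr + 4.2,
               tolerance = 1e-9)
  expect_error(laplace_specific_threshold(rep(1, 50)), "zero scale")
  expect_error(laplace_specific_threshold(x[1:10]), ">= 30")
})

toy_tables <- function() {
  t1 <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(2, 2, 3),
                   padj = c(1e-5, 1e-5, 1e-5), focal_counts = c(100, 100, 100))
  t2 <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(2, 0.5, 3),
                   padj = c(1e-5, 1e-5, 0.01), focal_counts = c(100, 100, 100))
  attr(t1, "focal") <- "hair"; attr(t2, "focal") <- "hair"
  list(t1, t2)
}

test_that("DEG intersection applies all three filters in every comparison", {
  tabs <- toy_tables()
  expect_equal(deg_intersection(tabs), "A") # B fails lfc, C fails padj once
  # counts filter
  tabs2 <- tabs
  tabs2[[1]]$focal_counts <- c(10, 100, 100)
  expect_equal(deg_intersection(tabs2), character(0))
  # genes missing from any table are excluded
  tabs3 <- tabs
  tabs3[[2]] <- tabs3[[2]][tabs3[[2]]$gene_id != "A", ]
  expect_equal(deg_intersection(tabs3), character(0))
  # vacuous filters keep every gene present in all tables
  expect_setequal(deg_intersection(tabs, lfc_min = -Inf, padj_max = 1.01,
                                   min_counts = -1), c("A", "B", "C"))
  # inconsistent focal tissues are an error
  tabs4 <- tabs
  attr(tabs4[[2]], "focal") <- "root"
  expect_error(deg_intersection(tabs4), "inconsistent")
})

test_that("relaxing any DEG threshold never shrinks the returned set", {
  withr::with_seed(5, {
    mk <- function() {
      tb <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       log2fc = rnorm(40, 1, 1),
                       padj = runif(40),
                       focal_counts = rexp(40, 1 / 80))
      attr(tb, "focal") <- "hair"
      tb
    }
    tabs <- list(mk(), mk(), mk())
  })
  strict <- deg_intersection(tabs, lfc_min = 1, padj_max = 0.05, min_counts = 50)
  for (relaxed in list(deg_intersection(tabs, 0.5, 0.05, 50),
                       deg_intersection(tabs, 1, 0.2, 50),
                       deg_intersection(tabs, 1, 0.05, 10))) {
    expect_true(all(strict %in% relaxed))
  }
})

test_that("bona fide classification requires both arms plus expression for display", {
  expr <- matrix(c(50, 1, 1, 1, 1, 1, 1,
                   30, 28, 30, 29, 30, 31, 30,
                   10, 0.1, 0.2, 0.1, 0.1, 0.2, 0.1),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), tissues7))
  sc <- entropy_scores(expr)
  cls <- classify_bona_fide(sc, degs = c("gA", "gB"), focal = "t1",
                            expr = expr, q_threshold = 3.9, expr_min = 20)
  a <- cls[cls$gene_id == "gA", ]
  expect_true(a$bona_fide && a$highly_expressed) # specific + DEG + high FPKM
  b <- cls[cls$gene_id == "gB", ] # ubiquitous: fails the entropy arm
  expect_false(b$bona_fide)
  cc <- cls[cls$gene_id == "gC", ] # specific but not a DEG
  expect_true(cc$entropy_specific)
  expect_false(cc$bona_fide)
  # invariant: bona_fide implies both arms
  expect_true(all(!cls$bona_fide | (cls$entropy_specific & cls$deg_all)))
  expect_error(classify_bona_fide(sc, "gA", "nope", expr), "focal")
})

test_that("ranking orders by Q, breaks ties by expression then id", {
  cls <- data.frame(
    gene_id = c("skor", "msl10", "glr36", "kdm1", "tieB", "tieA", "low"),
    q_focal = c(2.1, 1.13, 1.92, 1.70, 3.0, 3.0, 1.0),
    focal_expr = c(40, 120, 60, 90, 20.5, 41, 5),
    entropy_specific = TRUE, deg_all = TRUE, bona_fide = TRUE,
    highly_expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  rk <- rank_specific(cls)
  expect_equal(rk$gene_id, c("msl10", "kdm1", "glr36", "skor", "tieA", "tieB"))
  expect_equal(rank_specific(cls, n = 2)$gene_id, c("msl10", "kdm1"))
  none <- cls; none$bona_fide <- FALSE
  expect_equal(nrow(rank_specific(none)), 0)
})
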