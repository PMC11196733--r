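test_that("pseudo-bulk signatures aggregate and normalize per type", {
  counts <- matrix(c(1, 3,   3, 1,   0, 5), nrow = 2,
                   dimnames = list(c("g1", "g2"),
                                   c("c1", "c2", "c3")))
  sig <- build_signature(counts, c("A", "A", "B"))
  # two type-A cells with counts (1,3) and (3,1) sum to (4,4)
  expect_equal(unname(sig[, "A"]), c(5000, 5000))
  expect_equal(unname(sig[, "B"]), c(0, 10000))
  expect_equal(unname(colSums(sig)), c(1e4, 1e4))

  # single cell per type: column proportional to that cell
  s1 <- build_signature(counts[, 1, drop = FALSE], "A")
  expect_equal(unname(s1[, "A"]), 1e4 * c(1, 3) / 4)

  # genes with zero total expression are dropped
  counts0 <- rbind(counts, g3 = c(0, 0, 0))
  expect_equal(nrow(build_signature(counts0, c("A", "A", "B"))), 2)

  bad <- counts; rownames(bad) <- c("g1", "g1")
  expect_error(build_signature(bad, c("A", "A", "B")), "duplicate")
  expect_error(build_signature(counts, c("A", "A")), "one label per cell")
  expect_error(build_signature(counts, c("A", "", "B")), "empty")
})

test_that("constrained deconvolution recovers exact mixtures", {
  sig <- ref_signature()$sig
  # vertex of the simplex: bulk identical to one signature column
  b <- sig[, "Neutr", drop = FALSE]
  colnames(b) <- "s1"
  d <- deconvolve(sig, b)
  expect_equal(unname(d$fractions[1, "Neutr"]), 1, tolerance = 1e-6)
  expect_lt(max(d$fractions[1, colnames(sig) != "Neutr"]), 1e-6)

  # interior point, noise-free: exact recovery
  f <- c(0.3, 0.7)
  b2 <- 0.3 * sig[, "Bcell"] + 0.7 * sig[, "Tcell"]
  d2 <- deconvolve(sig, matrix(b2, ncol = 1,
                               dimnames = list(rownames(sig), "mix")))
  expect_equal(unname(d2$fractions[1, "Bcell"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(d2$fractions[1, "Tcell"]), 0.7, tolerance = 1e-6)

  # simplex constraints hold for arbitrary bulk input
  set.seed(1)
  noisy <- matrix(stats::rlnorm(nrow(sig) * 4, 1, 1), ncol = 4,
                  dimnames = list(rownames(sig), paste0("s", 1:4)))
  d3 <- deconvolve(sig, noisy)
  expect_equal(unname(rowSums(d3$fractions)), rep(1, 4), tolerance = 1e-6)
  expect_gte(min(d3$fractions), 0)

  expect_error(deconvolve(sig, matrix(1, 2, 1,
                                      dimnames = list(c("zzz1", "zzz2"),
                                                      "s"))),
               "no shared genes")
})

test_that("deconvolution is invariant to gene order", {
  sig <- ref_signature()$sig
  set.seed(3)
  f <- matrix(c(0.2, 0.1, 0.25, 0.15, 0.2, 0.1), nrow = 1,
              dimnames = list("s1", colnames(sig)))
  bulk <- synth_bulk_mixtures(sig, f, noise_cv = 0.05, seed = 5)
  perm <- sample(nrow(sig))
  d1 <- deconvolve(sig, bulk)
  d2 <- deconvolve(sig[perm, ], bulk)
  expect_lt(max(abs(d1$fractions - d2$fractions)), 1e-12)
})

test_that("gene-module scores are z-score means with per-type summaries", {
  # constant expression: all scores zero, all type means equal
  const <- matrix(3, nrow = 4, ncol = 6,
                  dimnames = list(paste0("g", 1:4), paste0("c", 1:6)))
  sc <- score_gene_module(const, rep(c("A", "B"), each = 3),
                          paste0("g", 1:4))
  expect_equal(unname(sc$type_means), c(0, 0))

  # a type shifted upward on the module genes scores highest
  set.seed(11)
  expr <- matrix(stats::rnorm(50 * 30), nrow = 50,
                 dimnames = list(paste0("g", 1:50), NULL))
  labs <- rep(c("lo", "mid", "hi"), each = 10)
  expr[1:10, labs == "hi"] <- expr[1:10, labs == "hi"] + 2
  sc2 <- score_gene_module(expr, labs, paste0("g", 1:10))
  expect_equal(names(which.max(sc2$type_means)), "hi")

  # singleton module equals that gene's z-scored expression
  sc3 <- score_gene_module(expr, labs, "g20")
  z <- (expr["g20", ] - mean(expr["g20", ])) / stats::sd(expr["g20", ])
  expect_equal(unname(sc3$cell_scores), unname(z))

  # adding genes absent from the matrix changes nothing
  sc4 <- score_gene_module(expr, labs, c(paste0("g", 1:10), "ghost1"))
  expect_equal(sc4$type_means, sc2$type_means)
  # per-type mean equals the arithmetic mean of member-cell scores
  expect_equal(unname(sc2$type_means["hi"]),
               mean(sc2$cell_scores[labs == "hi"]))
  expect_error(score_gene_module(expr, labs, "ghost1"), "no module gene")
})

test_that("sparse MTX triplet counts round-trip into signatures", {
  td <- withr::local_tempdir()
  ref <- ref_signature()$ref
  sub <- ref$counts[1:50, 1:20]
  sp <- Matrix::Matrix(sub, sparse = TRUE)
  Matrix::writeMM(sp, file.path(td, "counts.mtx"))
  writeLines(rownames(sub), file.path(td, "genes.txt"))
  writeLines(colnames(sub), file.path(td, "cells.txt"))
  m <- read_mtx_counts(file.path(td, "counts.mtx"),
                       file.path(td, "genes.txt"),
                       file.path(td, "cells.txt"))
  expect_equal(as.matrix(m), sub)
  sig_sparse <- build_signature(m, ref$labels[1:20])
  sig_dense <- build_signature(sub, ref$labels[1:20])
  expect_equal(sig_sparse, sig_dense)
  expect_error(read_mtx_counts(file.path(td, "counts.mtx"),
                               file.path(td, "cells.txt"),
                               file.path(td, "cells.txt")),
               "do not match")
})

test_that("correlation wrapper returns Pearson rho with two-sided p", {
  expect_equal(correlate(1:5, 2 * (1:5) + 1)$rho, 1)
  expect_equal(correlate(1:5, -(1:5))$rho, -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  r <- correlate(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
  expect_equal(r$p_value,
               stats::cor.test(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))$p.value)
  expect_error(correlate(1:3, c(1, 1, 1)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
  expect_error(correlate(1:4, 1:3), "equal length")

  # pairing by shared labels
  r2 <- correlate(c(a = 1, b = 2, c = 3), c(c = 3, a = 1, b = 2),
                  paired_by = list(c("a", "b", "c"), c("c", "a", "b")))
  expect_equal(r2$rho, 1)

  # matrix variant flags significant pairs
  set.seed(2)
  X <- matrix(stats::rnorm(60), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  Y <- cbind(y1 = X[, 1] * 2 + stats::rnorm(30, 0, 0.01),
             y2 = stats::rnorm(30))
  cm <- correlate_matrix(X, Y)
  expect_equal(dim(cm$rho), c(2, 2))
  expect_true(cm$significant["x1", "y1"])
  expect_equal(cm$significant, cm$p_value < 0.05)
})
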