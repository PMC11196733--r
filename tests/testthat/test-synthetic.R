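test_that("noise-free datasets reproduce the true trajectory exactly", {
  g <- core_nf_data()
  traj_obs <- observe(g$truth$trajectory)
  key_d <- paste(g$data$observable, g$data$time_days)
  key_t <- paste(traj_obs$observable, traj_obs$time_days)
  expect_equal(g$data$mean, traj_obs$value[match(key_d, key_t)])
  expect_true(all(g$data$sd > 0))   # floor keeps the dataset usable
  expect_equal(unique(g$data$n), 3)
})

test_that("count generators are pure functions of config and seed", {
  a <- synth_counts_dataset(ibd_model("core"), cv = 0.08, seed = 42)
  b <- synth_counts_dataset(ibd_model("core"), cv = 0.08, seed = 42)
  c2 <- synth_counts_dataset(ibd_model("core"), cv = 0.08, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data$mean, c2$data$mean))
  expect_error(synth_counts_dataset(ibd_model("core"), cv = 0.1, n_reps = 1),
               "n_reps >= 2")
  expect_error(synth_counts_dataset(ibd_model("core"), cv = -0.1), "cv >= 0")
})

test_that("replicate noise magnitude matches the configured CV", {
  g <- synth_counts_dataset(ibd_model("core"), cv = 0.1, n_reps = 1000,
                            seed = 9)
  # records where the SD floor cannot bind: sd/mean ~ cv within 10%
  d <- g$data
  lev <- tapply(abs(d$mean), d$observable, mean)
  fl <- 0.05 * as.numeric(lev[d$observable])
  sel <- 0.1 * d$mean > 1.5 * fl
  expect_gt(sum(sel), 0)
  expect_lt(max(abs(d$sd[sel] / d$mean[sel] - 0.1)), 0.01)
})

test_that("single-cell reference generator builds marker structure", {
  ref <- synth_reference_scrnaseq(n_genes = 200, cells_per_type = 25,
                                  markers_per_type = 15, fold = 10, seed = 2)
  expect_equal(dim(ref$counts), c(200, 25 * 6))
  expect_length(ref$labels, 150)
  sig <- build_signature(ref$counts, ref$labels)
  cc <- stats::cor(sig)
  expect_lt(max(cc[upper.tri(cc)]), 0.9)

  # without marker up-regulation types are exchangeable
  flat <- synth_reference_scrnaseq(n_genes = 200, cells_per_type = 100,
                                   markers_per_type = 15, fold = 1, seed = 2)
  sig_flat <- build_signature(flat$counts, flat$labels)
  cf <- stats::cor(sig_flat)
  expect_gt(min(cf[upper.tri(cf)]), 0.95)

  expect_identical(ref$counts,
                   synth_reference_scrnaseq(n_genes = 200,
                                            cells_per_type = 25,
                                            markers_per_type = 15,
                                            fold = 10, seed = 2)$counts)
  expect_error(synth_reference_scrnaseq(n_genes = 50, markers_per_type = 20),
               "infeasible")
})

test_that("bulk mixtures are convex combinations with optional noise", {
  sig <- ref_signature()$sig
  k <- ncol(sig)
  vert <- diag(k)[1, , drop = FALSE]
  colnames(vert) <- colnames(sig)
  b <- synth_bulk_mixtures(sig, vert, noise_cv = 0)
  expect_equal(unname(b[, 1]), unname(sig[, 1]))

  set.seed(4)
  f <- matrix(stats::runif(3 * k), nrow = 3)
  f <- f / rowSums(f)
  colnames(f) <- colnames(sig)
  b2 <- synth_bulk_mixtures(sig, f, noise_cv = 0)
  d <- deconvolve(sig, b2)
  expect_lt(max(abs(d$fractions - f)), 1e-6)

  b3 <- synth_bulk_mixtures(sig, f, noise_cv = 0.1, seed = 8)
  expect_identical(b3, synth_bulk_mixtures(sig, f, noise_cv = 0.1, seed = 8))
  expect_false(identical(b2, b3))

  bad <- f; bad[1, 1] <- bad[1, 1] + 0.5
  expect_error(synth_bulk_mixtures(sig, bad), "sum to 1")
})

test_that("module-turnover fixture carries the constructed monotone signal", {
  tv <- c(Bcell = 0.36, Mac = 0.43, Neutr = 0.8, Tcell = 0.42, Epi = 0.9)
  md <- synth_module_turnover(tv, seed = 6)
  sc <- score_gene_module(md$expression, md$labels, md$module)
  r <- correlate(sc$type_means[names(tv)], tv)
  expect_gt(r$rho, 0.9)

  # permutation null: shuffled turnover assignments decorrelate the score
  set.seed(10)
  perm_rho <- replicate(500, {
    correlate(sc$type_means[names(tv)], sample(unname(tv)))$rho
  })
  expect_lt(abs(mean(perm_rho)), 0.2)
  expect_gt(r$rho, stats::quantile(perm_rho, 0.9))

  expect_identical(md, synth_module_turnover(tv, seed = 6))
  expect_error(synth_module_turnover(c(A = 1, B = 1, C = 1)), "degenerate")
  expect_error(synth_module_turnover(c(A = 1, B = 2)), ">= 3")
})
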