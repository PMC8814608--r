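# Helper: small catalog sampled from fixed signature mixtures.
toy_catalog <- function(n_samples, n_mut, sigs, weights, seed) {
  set.seed(seed)
  k <- ncol(sigs)
  X <- t(vapply(seq_len(n_samples), function(i) {
    w <- weights[i, ]
    p <- as.vector(sigs %*% w)
    as.numeric(stats::rmultinom(1, n_mut, p))
  }, numeric(nrow(sigs))))
  colnames(X) <- rownames(sigs)
  rownames(X) <- sprintf("S%03d", seq_len(n_samples))
  X
}

test_that("rank-1 catalogs are recovered exactly up to normalisation", {
  profile <- stats::setNames(rep(0, 96), sbs96_channels())
  profile[c("A[C>A]A", "T[T>G]T", "C[C>T]G")] <- c(0.5, 0.3, 0.2)
  X <- outer(c(50, 100, 200), profile)
  rownames(X) <- c("a", "b", "c"); colnames(X) <- names(profile)
  fit <- extract_signatures(X, k = 1, n_restarts = 3, seed = 1)
  expect_equal(as.numeric(fit$signatures), as.numeric(profile),
               tolerance = 1e-6)
  expect_equal(as.numeric(rowSums(fit$exposures)), c(50, 100, 200),
               tolerance = 1e-4)
})

test_that("extraction is deterministic given the seed", {
  sigs <- mutscape:::default_signatures()
  w <- cbind(runif(10), 1); w <- w / rowSums(w)
  X <- toy_catalog(10, 300, sigs, w, seed = 2)
  f1 <- extract_signatures(X, k = 2, n_restarts = 3, seed = 9)
  f2 <- extract_signatures(X, k = 2, n_restarts = 3, seed = 9)
  expect_identical(f1$signatures, f2$signatures)
  expect_identical(f1$exposures, f2$exposures)
})

test_that("NMF objective is non-increasing across iterations", {
  sigs <- mutscape:::default_signatures()
  set.seed(4)
  w <- matrix(runif(40), 20); w <- w / rowSums(w)
  X <- toy_catalog(20, 500, sigs, w, seed = 4)
  fit <- extract_signatures(X, k = 2, n_restarts = 2, seed = 5)
  obj <- fit$diagnostics$objective
  expect_true(all(diff(obj) <= 1e-8 * obj[1]))
})

test_that("row sums are conserved through extraction on well-fit data", {
  sigs <- mutscape:::default_signatures()
  set.seed(6)
  w <- matrix(rgamma(60, 0.5), 30); w <- w / rowSums(w)
  X <- toy_catalog(30, 1000, sigs, w, seed = 6)
  fit <- extract_signatures(X, k = 2, n_restarts = 5, seed = 6)
  rel <- abs(rowSums(fit$exposures) - rowSums(X)) / rowSums(X)
  expect_lt(max(rel), 0.05)
})

test_that("select_k flags rank-1 catalogs and honours single-candidate ranges", {
  profile <- stats::setNames(rep(1 / 96, 96), sbs96_channels())
  set.seed(8)
  X <- t(vapply(1:20, function(i)
    as.numeric(stats::rmultinom(1, 500, profile)), numeric(96)))
  colnames(X) <- names(profile); rownames(X) <- paste0("s", 1:20)
  sel <- select_k(X, k_range = 1:3, seed = 2, n_restarts = 5)
  expect_equal(sel$k, 1L)

  sel3 <- select_k(X, k_range = 3, seed = 2, n_restarts = 3)
  expect_equal(sel3$k, 3L)
  expect_equal(nrow(sel3$table), 1L)
  expect_error(select_k(X, k_range = integer(0)), "empty")
})

test_that("cosine annotation finds the right reference column", {
  ref <- mutscape:::default_signatures()
  # identity: similarity exactly 1
  ann <- cosine_annotate(ref, ref)
  expect_equal(ann$best_match, colnames(ref))
  expect_equal(ann$similarity, c(1, 1), tolerance = 1e-12)

  # disjoint support: similarity 0, flagged novel
  orth <- matrix(0, 96, 1, dimnames = list(sbs96_channels(), "q"))
  orth[grepl("\\[T>G\\]", rownames(orth)), 1] <- 1 / 16
  ann0 <- cosine_annotate(orth, ref)
  expect_equal(ann0$similarity, 0)
  expect_equal(ann0$annotation, "novel")

  # perturbed column recovered; cosine agrees with the direct formula
  set.seed(10)
  pert <- ref[, 1] + 0.05 / 96
  pert <- pert / sum(pert)
  m <- matrix(pert, ncol = 1, dimnames = list(rownames(ref), "p"))
  ann1 <- cosine_annotate(m, ref)
  expect_equal(ann1$best_match, "synthSig1")
  brute <- sum(pert * ref[, 1]) / sqrt(sum(pert^2) * sum(ref[, 1]^2))
  expect_equal(ann1$similarity, brute, tolerance = 1e-12)

  # channel mismatch is an error
  bad <- m; rownames(bad)[1] <- "XXX"
  expect_error(cosine_annotate(bad, ref), "mismatch")
})

test_that("exposure attribution matches NNLS ground truth and a grid oracle", {
  sigs <- mutscape:::default_signatures()
  # pure sample: all mass on one signature
  x <- matrix(100 * sigs[, 1], nrow = 1,
              dimnames = list("s1", rownames(sigs)))
  at <- attribute_exposures(x, sigs)
  expect_equal(as.numeric(at$exposures), c(100, 0), tolerance = 1e-8)
  expect_equal(at$dominant[["s1"]], 1L)

  # all-zero sample
  z <- matrix(0, 1, 96, dimnames = list("z", rownames(sigs)))
  expect_equal(as.numeric(attribute_exposures(z, sigs)$exposures), c(0, 0))

  # random nonnegative mixture: NNLS equals an exhaustive grid search
  set.seed(12)
  truth <- c(40, 70)
  x2 <- as.vector(sigs %*% truth) + abs(rnorm(96, 0, 0.05))
  x2m <- matrix(x2, 1, dimnames = list("m", rownames(sigs)))
  at2 <- attribute_exposures(x2m, sigs)
  grid <- expand.grid(a = seq(0, 120, 0.25), b = seq(0, 120, 0.25))
  rss <- colSums((matrix(x2, 96, nrow(grid)) -
                    sigs %*% t(as.matrix(grid)))^2)
  best <- unlist(grid[which.min(rss), ])
  expect_equal(as.numeric(at2$exposures), unname(best), tolerance = 0.3)
})

test_that("signature-clinical Fisher tests behave at the boundaries", {
  # dominant membership independent of group: OR 1, p 1
  dom <- stats::setNames(rep(c(1, 2), each = 20), paste0("s", 1:40))
  grp <- stats::setNames(factor(rep(c("A", "B"), 20)), paste0("s", 1:40))
  res <- signature_clinical_tests(dom, list(g = grp))
  expect_equal(res$p, c(1, 1))
  expect_equal(res$odds_ratio, c(1, 1), tolerance = 1e-9)

  # perfectly separated table: p equals hypergeometric enumeration
  dom2 <- stats::setNames(rep(c(1, 2), each = 20), paste0("s", 1:40))
  grp2 <- stats::setNames(factor(rep(c("A", "B"), each = 20)),
                          paste0("s", 1:40))
  res2 <- signature_clinical_tests(dom2, list(g = grp2))
  expect_equal(res2$p[1], fisher_p_enum(20, 0, 0, 20), tolerance = 1e-12)

  # empty arm: flagged, not tested
  grp3 <- stats::setNames(factor(rep("A", 40), levels = c("A", "B")),
                          paste0("s", 1:40))
  res3 <- signature_clinical_tests(dom, list(g = grp3))
  expect_true(all(res3$skipped))

  # BH FDR is monotone in p and never below p
  expect_true(all(res2$fdr >= res2$p - 1e-12))
})
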