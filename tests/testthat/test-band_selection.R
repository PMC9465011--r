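# wrap a loading matrix as a pc_decomposition for candidate tests
fake_pc <- function(loadings, axis) {
  loadings <- sweep(loadings, 2, sqrt(colSums(loadings^2)), "/")
  structure(list(loadings = loadings,
                 explained_variance_ratio = rep(1 / ncol(loadings),
                                                ncol(loadings)),
                 center = rep(0, nrow(loadings)), axis = axis),
            class = "pc_decomposition")
}

# dataset wrapper around a plain feature matrix (one "band" per column)
as_dataset <- function(X, y, split) {
  ax <- tiny_axis(ncol(X), from = 500, by = 10)
  structure(list(spectra = X, labels = y,
                 apple = rep(1L, nrow(X)), line = seq_len(nrow(X)),
                 sample = seq_len(nrow(X)), axis = ax, purity = 1,
                 split = split),
            class = "pixel_spectra_dataset")
}

sfs_sim_data <- function(n = 150, p = 8, informative = 3, delta = 2.5,
                         seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("bruise", "sound"), each = n),
              levels = c("bruise", "sound"))
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  for (j in informative)
    X[y == "bruise", j] <- X[y == "bruise", j] - delta
  split <- factor(rep(c("train", "test"), length.out = 2 * n),
                  levels = c("train", "test"))
  as_dataset(X, y, split)
}

test_that("a single Gaussian bump yields exactly one candidate at its center", {
  ax <- tiny_axis(41, from = 400, by = 10)
  wl <- ax$wavelengths_nm
  pc <- fake_pc(cbind(exp(-0.5 * ((wl - 600) / 40)^2)), ax)
  cand <- preselect_candidates(pc, n_components = 1)
  expect_equal(cand$pool, 600)
  expect_equal(cand$per_pc$PC1$polarity, "peak")
})

test_that("a sinusoidal loading yields alternating peak/valley candidates", {
  ax <- tiny_axis(121, from = 400, by = 5)
  wl <- ax$wavelengths_nm
  pc <- fake_pc(cbind(sin(2 * pi * (wl - 400) / 200)), ax)
  cand <- preselect_candidates(pc, n_components = 1)
  per <- cand$per_pc$PC1
  expect_equal(sort(per$wavelength_nm[per$polarity == "peak"]),
               c(450, 650, 850))
  expect_equal(sort(per$wavelength_nm[per$polarity == "valley"]),
               c(550, 750, 950))
  expect_true(!is.unsorted(cand$pool))
  expect_false(any(duplicated(cand$pool)))
})

test_that("constant loadings give no candidates; all-constant is an error", {
  ax <- tiny_axis(20)
  wl <- ax$wavelengths_nm
  pc <- fake_pc(cbind(rep(1, 20), exp(-0.5 * ((wl - 560) / 20)^2)), ax)
  cand <- preselect_candidates(pc, n_components = 2)
  expect_equal(nrow(cand$per_pc$PC1), 0)
  expect_equal(cand$pool, 560)
  flat <- fake_pc(cbind(rep(1, 20)), ax)
  expect_error(preselect_candidates(flat, 1), "no candidate")
})

test_that("SFS first picks the only informative candidate (brute force)", {
  ds <- sfs_sim_data(informative = 3)
  cands <- ds$axis$wavelengths_nm
  traj <- run_sfs(ds, cands, "lda", k_max = 3, seed = 2)
  # brute-force oracle over single-feature CV accuracies
  tr <- ds$split == "train"
  fold_id <- bruisebands:::make_folds(droplevels(ds$labels[tr]), 5, 2)
  single <- vapply(seq_along(cands), function(j)
    cv_accuracy(ds$spectra[tr, j, drop = FALSE], ds$labels[tr], "lda",
                fold_id = fold_id), numeric(1))
  expect_equal(traj$wavelengths_nm[1], cands[which.max(single)])
  expect_equal(traj$wavelengths_nm[1], cands[3])
  expect_equal(traj$cv_accuracy[1], max(single))
})

test_that("selected sets are nested and accuracies bounded", {
  ds <- sfs_sim_data(informative = c(2, 5))
  traj <- run_sfs(ds, ds$axis$wavelengths_nm, "qda", k_max = 4, seed = 3)
  expect_equal(length(unique(traj$wavelengths_nm)), 4)
  expect_true(all(traj$cv_accuracy >= 0 & traj$cv_accuracy <= 1))
  expect_true(all(traj$test_accuracy >= 0 & traj$test_accuracy <= 1))
  # rerun under the same seed is identical
  traj2 <- run_sfs(ds, ds$axis$wavelengths_nm, "qda", k_max = 4, seed = 3)
  expect_identical(traj$wavelengths_nm, traj2$wavelengths_nm)
  expect_identical(traj$cv_accuracy, traj2$cv_accuracy)
})

test_that("all-noise candidates stay within the binomial band around 0.5", {
  ds <- sfs_sim_data(informative = integer(0), p = 6, n = 100, seed = 4)
  traj <- run_sfs(ds, ds$axis$wavelengths_nm, "lda", k_max = 3, seed = 4)
  # training fold size ~100 per class; 3 sigma of a fair coin on n=200
  ci <- 3 * sqrt(0.25 / 200)
  expect_true(all(abs(traj$cv_accuracy - 0.5) < ci + 0.05))
})

test_that("exhaustive best pair is at least as good as the greedy pair", {
  ds <- sfs_sim_data(informative = c(1, 4), p = 6, seed = 5)
  cands <- ds$axis$wavelengths_nm
  traj <- run_sfs(ds, cands, "lda", k_max = 2, seed = 5)
  tr <- ds$split == "train"
  fold_id <- bruisebands:::make_folds(droplevels(ds$labels[tr]), 5, 5)
  pairs <- utils::combn(seq_along(cands), 2)
  pair_acc <- apply(pairs, 2, function(jj)
    cv_accuracy(ds$spectra[tr, jj], ds$labels[tr], "lda",
                fold_id = fold_id))
  expect_gte(max(pair_acc), traj$cv_accuracy[2] - 1e-12)
  # the greedy pair contains the step-1 winner by construction
  expect_true(traj$wavelengths_nm[1] %in% traj$wavelengths_nm[1:2])
})

test_that("the plateau rule picks the documented count", {
  mk <- function(cv) structure(list(cv_accuracy = cv,
                                    test_accuracy = cv,
                                    classifier = "x"),
                               class = "sfs_trajectory")
  tr4 <- replicate(4, mk(c(0.90, 0.95, 0.96, 0.961, 0.962)),
                   simplify = FALSE)
  expect_equal(choose_optimal_count(tr4, epsilon = 0.01), 3)
  # monotone large gains: k_max with a warning flag
  big <- replicate(4, mk(c(0.5, 0.6, 0.7, 0.8, 0.9)), simplify = FALSE)
  out <- choose_optimal_count(big)
  expect_equal(as.integer(out), 5)
  expect_true(attr(out, "warning_flag"))
  # floor keeps low-accuracy plateaus from terminating early
  low <- replicate(4, mk(c(0.80, 0.805, 0.95, 0.951, 0.951)),
                   simplify = FALSE)
  expect_equal(choose_optimal_count(low), 3)
})

test_that("three wavebands are optimal on the default cohort", {
  st <- default_state()
  expect_equal(st$sel$optimal_count, 3L)
  expect_false(st$sel$warning_flag)
})

test_that("candidate pool of the default cohort includes the key wavebands", {
  st <- default_state()
  expect_true(all(c(424.5, 553.9, 774.2, 812.5) %in%
                    st$sel$candidates$pool))
})
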