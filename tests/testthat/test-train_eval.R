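test_that("metrics match hand-computed confusion tables", {
  # perfect multiclass prediction
  m <- compute_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(unname(m[c("ACC", "F1_weighted", "F1_macro")]), c(1, 1, 1))

  # perfect binary ranking gives AUC 1
  m2 <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                        scores = c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unname(m2[c("ACC", "F1", "AUC")]), c(1, 1, 1))

  # total failure
  m3 <- compute_metrics(c(0, 1), c(1, 0), scores = c(0.9, 0.1))
  expect_equal(unname(m3["ACC"]), 0)
  expect_equal(unname(m3["AUC"]), 0)

  # asymmetric multiclass case, F1 per class worked out by hand:
  # true (0,0,1,2), pred (0,1,1,1): F1_0 = 2/3, F1_1 = 1/2, F1_2 = 0
  m4 <- compute_metrics(c(0, 0, 1, 2), c(0, 1, 1, 1))
  expect_equal(unname(m4["ACC"]), 0.5)
  expect_equal(unname(m4["F1_macro"]), (2 / 3 + 1 / 2 + 0) / 3)
  expect_equal(unname(m4["F1_weighted"]), (2 * 2 / 3 + 1 / 2) / 4)

  expect_error(compute_metrics(c(1, 1), c(1, 0), scores = c(1, 0)),
               "one class")
})

test_that("training is deterministic, finite and fits separable data", {
  ds <- tiny_dataset(n = 45L)
  cfg <- fast_config(epochs = 250L, seed = 3L)
  sp <- trustomics:::stratified_split(ds$labels, 0.2, cfg$seed)
  m1 <- train_model(ds, sp$train, cfg)
  m2 <- train_model(ds, sp$train, cfg)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$loss_trace)))

  pr <- predict(m1, ds)
  expect_true(all(pr$pred %in% 0:2))
  expect_gte(mean(pr$true[sp$train] == pr$pred[sp$train]), 0.99)
  expect_gte(mean(pr$true[sp$test] == pr$pred[sp$test]), 0.9)
  expect_true(all(pr$u > 0 & pr$u <= 1))
  # confidences plus uncertainty renormalise (subjective-logic identity)
  expect_lt(max(abs(rowSums(as.matrix(pr[grep("^p_", names(pr))])) + pr$u - 1)),
            1e-6)

  expect_error(train_model(ds, which(ds$labels != 0)), "every class")
})

test_that("vacuous fused opinions predict class 0 by the tie rule", {
  P <- matrix(0, 3, 3)
  expect_equal(max.col(P, ties.method = "first") - 1L, c(0L, 0L, 0L))
})

test_that("cross-validation partitions samples into near-equal test folds", {
  ds <- tiny_dataset(n = 33L)
  cfg <- fast_config(epochs = 40L)
  rep <- cross_validate(ds, cfg, n_folds = 5L)
  fold <- attr(rep, "fold_assignment")
  expect_equal(length(fold), 33L)
  expect_true(all(sort(unique(fold)) == 1:5))
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1L)
  # each sample in exactly one test fold by construction
  expect_equal(sum(sizes), 33L)
  expect_length(rep$per_fold, 5L)
  expect_true(all(rep$mean >= 0 & rep$mean <= 1))
  expect_error(stratified_folds(c(rep(0, 9), 1), 5L), "fewer")
})

test_that("cross-validation is reproducible and strong on separable data", {
  ds <- tiny_dataset(n = 40L)
  cfg <- fast_config(epochs = 250L, seed = 5L)
  r1 <- cross_validate(ds, cfg, n_folds = 4L)
  r2 <- cross_validate(ds, cfg, n_folds = 4L)
  expect_identical(r1$mean, r2$mean)
  expect_gte(unname(r1$mean["ACC"]), 0.9)
})

test_that("ablation variants share folds and report per-variant rows", {
  ds <- tiny_dataset(n = 30L)
  cfg <- fast_config(epochs = 25L)
  ks <- c(1L, 3L, 6L)
  tab <- ablation_run(ds, cfg, axis = "k_sweep", ks = ks, n_folds = 3L)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$variant, paste0("k=", ks))
  reps <- attr(tab, "reports")
  folds <- lapply(reps, attr, "fold_assignment")
  expect_identical(folds[[1]], folds[[2]]) # controlled comparison
  expect_identical(folds[[1]], folds[[3]])

  tab2 <- ablation_run(ds, cfg, axis = "omics_subsets", n_folds = 3L)
  expect_equal(nrow(tab2), 7L) # 2^3 - 1 non-empty subsets

  tab3 <- ablation_run(ds, cfg, axis = "fusion", n_folds = 3L)
  expect_equal(tab3$variant, c("trusted", "mean_evidence"))
})

test_that("noise experiment reports the reference row at sigma 0", {
  ds <- tiny_dataset(n = 30L)
  cfg <- fast_config(epochs = 30L)
  tab <- noise_experiment(ds, cfg, sigmas = c(0, 4), target_omics = 1L,
                          n_repeats = 2L)
  expect_equal(tab$sigma, c(0, 4))
  per <- attr(tab, "per_repeat")
  # sigma = 0 equals an unperturbed run with the same derived seed
  seed_r <- derive_seed(cfg$seed, "noise-rep", 1L)
  sp <- trustomics:::stratified_split(ds$labels, cfg$test_fraction, seed_r)
  cfg_r <- cfg
  cfg_r$seed <- seed_r
  ref <- trustomics:::fit_and_score(ds, sp$train, sp$test, cfg_r)
  expect_equal(per$acc[per$sigma == 0 & per$rep == 1],
               unname(ref$metrics["ACC"]))
  expect_true(all(is.finite(tab$mean_u)))
})

test_that("permutation importance ranks planted features above noise", {
  # single block, binary task, a single planted marker: the class signal
  # is not redundant, so permuting the marker must measurably hurt while
  # noise columns stay near zero
  ds <- simulate_multiomics(synthetic_spec(
    n_samples = 40L, n_classes = 2L, n_features = c(om = 6L),
    informative_fraction = 1 / 6, effect_size = 5, seed = 11L
  ))
  cfg <- fast_config(epochs = 250L, seed = 4L)
  sp <- trustomics:::stratified_split(ds$labels, 0.25, cfg$seed)
  model <- train_model(ds, sp$train, cfg)
  imp <- feature_importance(model, ds, cfg, n_repeats = 2L)

  # every retained feature appears exactly once
  expect_equal(nrow(imp), sum(sapply(ds$matrices, ncol)))
  expect_false(any(duplicated(imp[c("omics", "feature_index")])))
  expect_equal(imp$rank, seq_len(nrow(imp)))

  man <- attr(ds, "manifest")
  key <- paste(imp$omics, imp$feature_index)
  inf_key <- unlist(lapply(names(man), function(nm) {
    paste(nm, man[[nm]]$informative)
  }))
  mean_inf <- mean(imp$importance[key %in% inf_key])
  mean_noise <- mean(imp$importance[!key %in% inf_key])
  expect_gt(mean_inf, mean_noise)

  # permuting a constant column cannot change anything
  ds2 <- ds
  ds2$matrices[[1]][, 1] <- 1
  model2 <- train_model(ds2, sp$train, cfg)
  imp2 <- feature_importance(model2, ds2, cfg, n_repeats = 2L)
  expect_equal(imp2$importance[imp2$omics == ds2$omics_names[1] &
                                 imp2$feature_index == 1], 0)
})

test_that("graph structure and euclidean similarity variants train", {
  ds <- tiny_dataset(n = 24L)
  for (cfg in list(fast_config(epochs = 20L, structure = "graph"),
                   fast_config(epochs = 20L, similarity = "euclidean"),
                   fast_config(epochs = 20L, fusion = "mean_evidence"))) {
    sp <- trustomics:::stratified_split(ds$labels, 0.25, cfg$seed)
    m <- train_model(ds, sp$train, cfg)
    pr <- predict(m, ds, sp$test)
    expect_true(all(pr$pred %in% 0:2))
    if (cfg$fusion == "mean_evidence") expect_true(all(is.na(pr$u)))
  }
})
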