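test_that("AUC follows the rank statistic with midrank ties", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(perfect$auc, 1)
  expect_identical(perfect$n_pos, 2L)
  expect_identical(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "negative")
  expect_error(roc_auc(1:3, c(0, 0, 0)), "positive")

  # uninformative scores on many pairs sit near 0.5
  set.seed(5)
  expect_equal(roc_auc(runif(4000), rbinom(4000, 1, 0.4))$auc, 0.5,
               tolerance = 0.05)
})

test_that("AUC equals the brute-force pair-comparison count", {
  set.seed(6)
  for (rep in 1:15) {
    n <- sample(10:200, 1)
    scores <- round(runif(n), 2)          # force some ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(scores, labels)$auc, mean(cmp), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (rep in 1:5) {
    scores <- c(rnorm(40, 1), rnorm(60))
    labels <- rep(c(1, 0), c(40, 60))
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("negating all scores complements the AUC", {
  set.seed(8)
  scores <- rnorm(100); labels <- rbinom(100, 1, 0.5)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - roc_auc(scores, labels)$auc,
               tolerance = 1e-12)
})

test_that("scenario 1 ranks held-out ligands by structure", {
  ds <- toy_fixture_dataset()
  res <- scenario1_new_ligand(ds)
  expect_s3_class(res, "roc_result")
  expect_true(res$auc >= 0.95)     # planted substructures determine activity
  expect_identical(res$n_pos + res$n_neg, nrow(ds$indices))
  # deterministic: no randomness anywhere in the scenario
  expect_identical(scenario1_new_ligand(ds)$auc, res$auc)
  # degenerate dataset: a single ligand cannot be left out
  tiny <- ds; tiny$ligands <- ds$ligands[1]
  expect_error(scenario1_new_ligand(tiny), "at least two ligands")
})

test_that("scenario 2 scores held-out targets with binary coefficients", {
  ds <- toy_fixture_dataset()
  res <- scenario2_new_target(ds, frame = 7)
  expect_true(res$auc >= 0.9)      # planted motifs determine specificity
  expect_identical(res$scenario, 2L)
  expect_true(all(abs(res$pairs$B) <= 1 + 1e-12))
  expect_identical(scenario2_new_target(ds, frame = 7)$auc, res$auc)
  # an oversized frame surfaces the scoring error with protein context
  expect_error(scenario2_new_target(ds, frame = 10000), "held-out protein")
})

test_that("scenario 3 uses fuzzy coefficients but binary truth labels", {
  ds <- toy_fixture_dataset()
  res2 <- scenario2_new_target(ds, frame = 7)
  res3 <- scenario3_both_new(ds, frame = 7)
  expect_identical(res3$scenario, 3L)
  expect_true(res3$auc >= 0.75)
  expect_true(res3$auc <= res2$auc + 0.05)
  expect_setequal(unique(res3$pairs$label), c(0L, 1L))
  expect_identical(scenario3_both_new(ds, frame = 7)$auc, res3$auc)
})

test_that("pairs losing their last interactor are skipped with a warning", {
  # hand-built map: L9 has exactly one interactor (P1), so holding out P1
  # leaves it unscorable; thresholds here are deliberately sub-curation
  prot <- setNames(vapply(1:4, function(i) random_protein(30), character(1)),
                   paste0("P", 1:4))
  ligs <- suppressWarnings(parse_smiles(
    setNames(c("CCO", "CCN", "CCC", "CCOC"), paste0("L", 1:4))))
  idx <- expand.grid(protein_id = names(prot), ligand_id = names(ligs)[1:3],
                     stringsAsFactors = FALSE)
  idx$index <- 1L
  idx <- rbind(idx, data.frame(protein_id = c("P1", "P2"),
                               ligand_id = c("L4", "L4"),
                               index = c(1L, 0L)))
  ds <- structure(list(proteins = prot, ligands = ligs, indices = idx,
                       parameter = "Ki", cutoff_umol = 1, mna_level = 2L),
                  class = "InteractionDataset")
  expect_warning(res <- scenario2_new_target(ds, frame = 5), "skipped")
  expect_identical(res$skipped, 1L)
  # the skipped pair is (P1, L4); everything else is still scored
  expect_false(any(res$pairs$protein_id == "P1" & res$pairs$ligand_id == "L4"))
})

test_that("the per-ligand macro average is reported on request", {
  ds <- toy_fixture_dataset()
  res <- scenario1_new_ligand(ds, per_ligand = TRUE)
  expect_true(is.numeric(res$macro_auc))
  expect_true(res$macro_auc >= 0 && res$macro_auc <= 1)
})
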