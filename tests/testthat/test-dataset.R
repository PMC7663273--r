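idx_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(protein_id = paste0("P", m[, 1]), ligand_id = paste0("L", m[, 2]),
             index = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

test_that("eligibility keeps a feasible map unchanged and empties gracefully", {
  full <- expand.grid(protein_id = paste0("P", 1:3),
                      ligand_id = paste0("L", 1:3), stringsAsFactors = FALSE)
  full$index <- 1L
  expect_identical(eligibility_fixpoint(full), full)
  empty <- full[0, ]
  expect_identical(nrow(eligibility_fixpoint(empty)), 0L)
  bad <- full; bad$index[1] <- NA_integer_
  expect_error(eligibility_fixpoint(bad), "0/1")
})

test_that("an under-connected protein is removed and the cascade re-checked", {
  # P1..P3 x L1..L3 all positive; P4 has only two positive ligands
  base <- expand.grid(protein_id = paste0("P", 1:3),
                      ligand_id = paste0("L", 1:3), stringsAsFactors = FALSE)
  base$index <- 1L
  extra <- idx_df(4, 1, 1, 4, 2, 1, 4, 3, 0)
  out <- eligibility_fixpoint(rbind(base, extra))
  expect_false("P4" %in% out$protein_id)
  expect_identical(sort(unique(out$protein_id)), paste0("P", 1:3))
  # removing P4 deletes its 0-entry too
  expect_identical(nrow(out), 9L)
})

test_that("the fixpoint is idempotent and removal-order independent", {
  greedy_fixpoint <- function(indices, order_seed) {
    set.seed(order_seed)
    repeat {
      pos <- indices[indices$index == 1L, , drop = FALSE]
      pbad <- setdiff(unique(indices$protein_id),
                      names(which(table(pos$protein_id) >= 3)))
      lbad <- setdiff(unique(indices$ligand_id),
                      names(which(table(pos$ligand_id) >= 3)))
      victims <- c(if (length(pbad)) paste0("p:", pbad),
                   if (length(lbad)) paste0("l:", lbad))
      if (!length(victims)) return(indices)
      v <- sample(victims, 1)            # remove ONE entity, any order
      if (startsWith(v, "p:"))
        indices <- indices[indices$protein_id != sub("p:", "", v), , drop = FALSE]
      else
        indices <- indices[indices$ligand_id != sub("l:", "", v), , drop = FALSE]
    }
  }
  key <- function(d) sort(paste(d$protein_id, d$ligand_id, d$index))
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    grid <- expand.grid(protein_id = paste0("P", 1:n),
                        ligand_id = paste0("L", 1:n), stringsAsFactors = FALSE)
    grid$index <- rbinom(nrow(grid), 1, 0.65)
    grid <- grid[runif(nrow(grid)) < 0.85, ]       # sparse map
    fp <- eligibility_fixpoint(grid)
    expect_identical(key(eligibility_fixpoint(fp)), key(fp))   # idempotent
    for (s in 1:3)
      expect_identical(key(greedy_fixpoint(grid, s)), key(fp))
  }
})

test_that("build_dataset composes the curation stages", {
  ds <- toy_dataset()
  expect_s3_class(ds, "InteractionDataset")
  expect_identical(length(ds$proteins), 4L)
  expect_identical(length(ds$ligands), 4L)
  expect_identical(nrow(ds$indices), 16L)
  pos <- ds$indices[ds$indices$index == 1L, ]
  expect_true(all(table(pos$protein_id) >= 3))
  expect_true(all(table(pos$ligand_id) >= 3))
})

test_that("build_dataset consults only the selected parameter", {
  prot <- setNames(vapply(1:4, function(i) random_protein(30), character(1)),
                   paste0("P", 1:4))
  smi <- data.frame(ligand_id = paste0("L", 1:4),
                    smiles = c("CCO", "CCN", "CCC", "CCOC"))
  grid <- expand.grid(p = 1:4, l = 1:4)
  ki <- affinity_records(paste0("P", grid$p), paste0("L", grid$l), "Ki",
                         "EQ", 100)
  kd <- affinity_records(paste0("P", grid$p), paste0("L", grid$l), "Kd",
                         "EQ", 99000)
  ds <- suppressWarnings(build_dataset(rbind(ki, kd), prot, smi, "Ki", 1.0))
  expect_identical(sum(ds$indices$index == 1L), 16L)   # Kd rows ignored
  expect_error(suppressWarnings(
    build_dataset(rbind(ki, kd), prot, smi, "Kd", 1.0)))  # all-negative map
})

test_that("curation errors name a protein that lacks a sequence", {
  ds <- toy_dataset()
  prot <- c(T1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA",
            T2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQG",
            T3 = "GSHMLEDPVDAFWEIQQLRRTVGELEARLKVSEA")
  rec <- affinity_records(rep(paste0("T", 1:4), each = 4),
                          rep(c("L1", "L2", "L3", "L4"), 4), "Ki", "EQ",
                          rep(c(50000, 100, 100, 100, 100, 50000, 100, 100,
                                100, 100, 50000, 100, 100, 100, 100, 50000)))
  smi <- data.frame(ligand_id = paste0("L", 1:4),
                    smiles = c("CCO", "CCCO", "CCN", "CCC(F)(F)F"))
  expect_error(suppressWarnings(build_dataset(rec, prot, smi, "Ki", 1.0)),
               "T4")
})

test_that("merged duplicates remap their affinity records", {
  prot <- setNames(vapply(1:4, function(i) random_protein(30), character(1)),
                   paste0("P", 1:4))
  # L1 and L1b are the same compound under different registry ids
  smi <- data.frame(ligand_id = c("L1", "L1b", "L2", "L3"),
                    smiles = c("CCO", "OCC", "CCN", "CCC"))
  grid <- expand.grid(p = paste0("P", 1:4), l = c("L1", "L2", "L3"),
                      stringsAsFactors = FALSE)
  rec <- affinity_records(grid$p, grid$l, "Ki", "EQ", 100)
  # the duplicate id carries extra, agreeing measurements
  rec <- rbind(rec, affinity_records(paste0("P", 1:4), rep("L1b", 4), "Ki",
                                     "EQ", 120))
  ds <- suppressWarnings(build_dataset(rec, prot, smi, "Ki", 1.0))
  expect_false("L1b" %in% names(ds$ligands))
  expect_setequal(ds$ligands$L1$source_ids, c("L1", "L1b"))
  expect_identical(sum(ds$indices$ligand_id == "L1"), 4L)
})
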