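# shared toy objects, built once per test run

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

toy_structures <- function() memo("structs", function() {
  suppressWarnings(parse_smiles(c(
    meth = "C", eth = "CC", ethanol = "CCO", dme = "COC",
    amine = "CCN", cf3 = "CCC(F)(F)F", ester = "CCC(=O)OC",
    tma = "C[N+](C)(C)C", acetate = "CC(=O)[O-]")))
})

# 4 proteins x 4 ligands, all pairs measured, diagonal non-interacting:
# every protein has 3 established ligands and vice versa
toy_dataset <- function() memo("toy_ds", function() {
  prot <- c(T1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA",
            T2 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQG",
            T3 = "GSHMLEDPVDAFWEIQQLRRTVGELEARLKVSEA",
            T4 = "GSHMLEDPVDAFWEIQQLRRTVGELEARLKVSEG")
  ligs <- c(L1 = "CCO", L2 = "CCCO", L3 = "CCN", L4 = "CCC(F)(F)F")
  pid <- character(); lid <- character(); rel <- character(); val <- numeric()
  for (i in 1:4) for (j in 1:4) {
    pid <- c(pid, names(prot)[i]); lid <- c(lid, names(ligs)[j])
    rel <- c(rel, "EQ")
    val <- c(val, if (i == j) 50000 else 100)   # diagonal: non-interacting
  }
  rec <- affinity_records(pid, lid, "Ki", rel, val)
  suppressWarnings(build_dataset(rec, prot, data.frame(
    ligand_id = names(ligs), smiles = unname(ligs)), "Ki", 1.0))
})

# small planted-signal fixture for fast scenario tests
toy_fixture <- function() memo("toy_fx", function() {
  suppressWarnings(generate_fixture(fixture_spec(
    n_classes = 2, n_proteins = 8, n_ligands = 16, seq_len = 80,
    motif_len = 12, neg_density = 0.8, interval_fraction = 0,
    noise_rate = 0, seed = 11)))
})

toy_fixture_dataset <- function() memo("toy_fx_ds", function() {
  suppressWarnings(curate_fixture(toy_fixture(), cutoff_umol = 1.0))
})

# the study-condition fixture used by the acceptance-level checks
acceptance_dataset <- function() memo("acc_ds", function() {
  fx <- suppressWarnings(generate_fixture(fixture_spec(seed = 1)))
  suppressWarnings(curate_fixture(fx, cutoff_umol = 1.0))
})

# naive positional-score oracle: enumerate all (i, h) segment pairs,
# score each by direct comparison, and spread the max onto covered positions
oracle_positional_scores <- function(Q, K, F) {
  q <- strsplit(Q, "")[[1]]; k <- strsplit(K, "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- length(q); n <- length(k)
  S <- numeric(m)
  for (i in seq_len(m - F + 1)) {
    for (h in (1 - i):(n - F + 1 - i)) {
      j <- i:(i + F - 1)
      r <- sum(q[j] == k[j + h] & q[j] %in% std)
      p <- i:(i + F - 1)
      S[p] <- pmax(S[p], r)
    }
  }
  S
}

random_protein <- function(len, alphabet = strsplit("ACDEFG", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
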