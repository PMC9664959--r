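# Synthetic dataset generator: determinism, constraint satisfaction,
# frequency recovery.

test_that("config validation rejects bad probabilities and positions", {
  expect_error(synth_config(), "mandatory")
  expect_error(synth_config(seed = 1, substitution_rates = c(Y42F = 1.5)))
  expect_error(synth_config(seed = 1, motif_spec = list(A = c("200" = "C"))),
               "reference positions")
  expect_error(generate_family(synth_config(seed = 1), "Z", 5), "unknown clade")
})

test_that("zero mutation rate yields identical copies of the ancestor", {
  cfg <- synth_config(seed = 5, site_mutation_rate = 0)
  fam <- generate_family(cfg, "A", 3)
  expect_equal(nrow(fam), 3)
  expect_equal(length(unique(fam$residues)), 1)
})

test_that("motif positions are forced when substitution rates are zero", {
  cfg <- synth_config(seed = 6, substitution_rates = c(Y42F = 0)[0])
  fam <- generate_family(cfg, "A", 40)
  expect_true(all(substr(fam$residues, 42, 42) == "Y"))
  expect_true(all(substr(fam$residues, 46, 46) == "E"))
  expect_true(all(substr(fam$residues, 69, 69) == "C"))
  expect_true(all(substr(fam$residues, 92, 92) == "F"))
  # clade C conserves Met100 instead of the Phe92/Phe96 pair
  famC <- generate_family(cfg, "C", 40)
  expect_true(all(substr(famC$residues, 100, 100) == "M"))
  expect_true(all(substr(famC$residues, 69, 69) == "C"))
})

test_that("within-family identity matches an independent resimulation", {
  # Oracle: re-simulate the generator equations (random splitting of a
  # lineage pool, per-site uniform replacement) in plain code and compare
  # mean pairwise identity (ungapped sequences of equal length).
  sim_mean_identity <- function(seed, size, len, rate) {
    set.seed(seed)
    aa <- pypfam::aa_alphabet()
    bg <- pypfam::blosum62_background()
    anc <- sample(aa, len, replace = TRUE, prob = bg)
    mut <- function(s) {
      hit <- which(runif(len) < rate)
      for (i in hit) s[i] <- sample(setdiff(aa, s[i]), 1)
      s
    }
    pool <- list(anc)
    while (length(pool) < size) {
      i <- sample.int(length(pool), 1)
      par <- pool[[i]]
      pool[[i]] <- mut(par)
      pool[[length(pool) + 1]] <- mut(par)
    }
    m <- do.call(rbind, pool)
    tot <- 0; np <- 0
    for (i in 1:(size - 1)) for (j in (i + 1):size) {
      tot <- tot + mean(m[i, ] == m[j, ]); np <- np + 1
    }
    tot / np
  }
  mean_ident <- function(fam) {
    n <- nrow(fam); tot <- 0; np <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      a <- strsplit(fam$residues[i], "")[[1]]
      b <- strsplit(fam$residues[j], "")[[1]]
      tot <- tot + mean(a == b); np <- np + 1
    }
    tot / np
  }
  rate <- 0.05
  got <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = s, site_mutation_rate = rate,
                        substitution_rates = c(Y42F = 0)[0])
    mean_ident(generate_family(cfg, "A", 50))
  }, 0)
  want <- vapply(101:110, function(s)
    sim_mean_identity(s, 50, 125, rate), 0)
  expect_lt(abs(mean(got) - mean(want)), 0.05)
})

test_that("datasets are byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 31, genomes_per_phylum = c(PA = 8, PB = 6),
                      pyp_prevalence = c(PA = 0.8, PB = 0.4),
                      n_decoy_families = 1, decoy_family_size = 6)
  d1 <- tempfile(); d2 <- tempfile()
  write_dataset(generate_dataset(cfg), d1)
  write_dataset(generate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # different seed changes the sequences
  cfg2 <- synth_config(seed = 32, genomes_per_phylum = c(PA = 8, PB = 6),
                       pyp_prevalence = c(PA = 0.8, PB = 0.4),
                       n_decoy_families = 1, decoy_family_size = 6)
  d3 <- tempfile()
  write_dataset(generate_dataset(cfg2), d3)
  expect_false(unname(tools::md5sum(file.path(d1, "sequences.fasta"))) ==
                 unname(tools::md5sum(file.path(d3, "sequences.fasta"))))
})

test_that("genome counts are honored exactly and prevalence 0 excludes", {
  cfg <- synth_config(seed = 33, genomes_per_phylum = c(PA = 10, PB = 4),
                      pyp_prevalence = c(PA = 1, PB = 0),
                      n_decoy_families = 0)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$taxonomy), 14)
  expect_equal(length(unique(ds$taxonomy$genome_id)), 14)
  fam <- ds$sequences[ds$sequences$planted_family == "PYP", ]
  expect_equal(sort(unique(ds$taxonomy$phylum[match(fam$genome_id,
                                                    ds$taxonomy$genome_id)])),
               "PA")
  expect_equal(nrow(fam), 10)  # prevalence 1 -> every PA genome carries
})

test_that("forced neighbor frequencies appear in every gene table", {
  cfg <- synth_config(seed = 34, genomes_per_phylum = c(PA = 12),
                      pyp_prevalence = c(PA = 1),
                      neighbor_freqs = c(TAL = 1.0), n_decoy_families = 0)
  ds <- generate_dataset(cfg)
  for (g in unique(ds$genes$genome_id)) {
    tab <- ds$genes[ds$genes$genome_id == g, ]
    focal <- tab$index[tab$category == "PYP"]
    tal <- tab$index[tab$category == "TAL"]
    expect_length(tal, 1)
    expect_lte(abs(tal - focal), 5)
  }
})

test_that("neighbor frequencies are recovered over many genomes", {
  cfg <- synth_config(seed = 35, genomes_per_phylum = c(PA = 220),
                      pyp_prevalence = c(PA = 1),
                      neighbor_freqs = c(TAL = 0.3, pCL = 0.6),
                      n_decoy_families = 0)
  ds <- generate_dataset(cfg)
  n <- length(unique(ds$genes$genome_id))
  expect_gte(n, 200)
  frac <- function(cat) {
    mean(vapply(split(ds$genes, ds$genes$genome_id), function(tab) {
      focal <- tab$index[tab$category == "PYP"]
      any(tab$category == cat & abs(tab$index - focal) <= 5)
    }, TRUE))
  }
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(frac("TAL") - 0.3), 3 * se(0.3))
  expect_lt(abs(frac("pCL") - 0.6), 3 * se(0.6))
})

test_that("gene tables honor the coordinate conventions", {
  cfg <- synth_config(seed = 36, genomes_per_phylum = c(PA = 10),
                      pyp_prevalence = c(PA = 1), n_decoy_families = 0)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$genes$start <= ds$genes$end))
  for (g in unique(ds$genes$genome_id)) {
    tab <- ds$genes[ds$genes$genome_id == g, ]
    expect_equal(tab$index, seq_len(nrow(tab)))
    expect_true(all(diff(tab$start) > 0))  # index follows coordinate order
  }
  # planted substitutions appear at roughly their configured rates
  expect_true(all(ds$genes$strand %in% c("+", "-")))
})
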