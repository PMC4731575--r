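# Ground-truthed synthetic proteins, planted PTMs and simulated spectra.

test_that("generation is deterministic under the seed", {
  cfg <- sim_config(seed = 7, n_proteins = 3)
  a <- generate_proteome(cfg)
  b <- generate_proteome(cfg)
  expect_equal(vapply(a, `[[`, character(1), "sequence"),
               vapply(b, `[[`, character(1), "sequence"))
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(s1$spectra, p1)
  write_mgf(s2$spectra, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an empty proteome request is not an error", {
  expect_length(generate_proteome(sim_config(seed = 1, n_proteins = 0)), 0L)
})

test_that("C-terminal tails are lysine-enriched as configured", {
  cfg <- sim_config(seed = 8, n_proteins = 40, lysine_enrichment = 0.3)
  ps <- generate_proteome(cfg)
  kfrac <- vapply(ps, function(p) {
    ctd <- p$domains[p$domains$label == "CTD", ]
    s <- substr(p$sequence, ctd$start - 1L, ctd$end - 1L)  # mature indices
    mean(strsplit(s, "")[[1]] == "K")
  }, numeric(1))
  expect_gte(mean(kfrac), 0.25)
})

test_that("generated proteins carry the H1 domain architecture", {
  ps <- generate_proteome(sim_config(seed = 9, n_proteins = 5))
  for (p in ps) {
    expect_true(p$met_removed)
    expect_equal(substr(p$sequence, 1, 1), "S")
    expect_equal(p$domains$label, c("NTD", "GH1", "CTD"))
    expect_gt(nrow(find_stpxk_motifs(p)), 0)
  }
})

test_that("planted modifications respect residue targets and density", {
  cfg0 <- sim_config(seed = 10, n_proteins = 4, mod_density = 0)
  ps <- generate_proteome(cfg0)
  expect_equal(nrow(plant_modifications(ps, cfg0)$truth), 0L)
  cfg_ph <- sim_config(seed = 10, n_proteins = 10, mod_density = 3,
                       mods = "phospho")
  truth <- plant_modifications(generate_proteome(cfg_ph), cfg_ph)$truth
  expect_gt(nrow(truth), 0)
  expect_true(all(truth$residue %in% c("S", "T", "Y")))
  expect_true(all(truth$name == "phospho"))
  # reproducible under the seed
  truth2 <- plant_modifications(generate_proteome(cfg_ph), cfg_ph)$truth
  expect_identical(truth, truth2)
})

test_that("planted residues agree with the protein sequence", {
  cfg <- sim_config(seed = 12, n_proteins = 5, mod_density = 4)
  ps <- generate_proteome(cfg)
  truth <- plant_modifications(ps, cfg)$truth
  by_id <- setNames(ps, vapply(ps, `[[`, character(1), "id"))
  for (r in seq_len(nrow(truth))) {
    p <- by_id[[truth$protein_id[r]]]
    mature <- truth$position[r] - p$numbering_offset + 1L
    expect_equal(substr(p$sequence, mature, mature), truth$residue[r])
  }
})

test_that("noiseless spectra equal the theoretical ladders exactly", {
  cfg <- sim_config(seed = 13, n_proteins = 3, ppm_sigma = 0,
                    dropout_prob = 0, noise_peaks = 0L,
                    unmodified_fraction = 0)
  sim <- simulate_study(cfg)
  expect_gt(length(sim$spectra), 0)
  for (i in seq_along(sim$spectra)) {
    tr <- sim$truth[i, ]
    mp <- modified_peptide(tr$sequence,
                           data.frame(position = tr$local_site, name = tr$name,
                                      mass = tr$mass, class = tr$class))
    frags <- theoretical_fragments(mp, charges = 1L, include_internal = FALSE,
                                   losses = NULL)
    expect_equal(sim$spectra[[i]]$peaks[, "mz"], sort(frags$mz),
                 tolerance = 1e-9, ignore_attr = TRUE)
    neutral <- (sim$spectra[[i]]$pepmass - PROTON_MASS) * tr$charge
    expect_equal(neutral, peptide_mass_mp(mp), tolerance = 1e-6)
  }
})

test_that("the applied m/z error distribution has the configured width", {
  cfg <- sim_config(seed = 14, n_proteins = 70, mod_density = 4,
                    ppm_sigma = 3, dropout_prob = 0, noise_peaks = 0L,
                    unmodified_fraction = 0.5)
  sim <- simulate_study(cfg)
  errs <- numeric(0)
  for (i in seq_along(sim$spectra)) {
    tr <- sim$truth[i, ]
    pl <- if (is.na(tr$name)) NULL else
      data.frame(position = tr$local_site, name = tr$name, mass = tr$mass,
                 class = tr$class)
    frags <- theoretical_fragments(modified_peptide(tr$sequence, pl),
                                   charges = 1L, include_internal = FALSE,
                                   losses = NULL)
    theo <- sort(frags$mz)
    obs <- sim$spectra[[i]]$peaks[, "mz"]
    errs <- c(errs, (obs - theo) / theo * 1e6)
  }
  expect_gt(length(errs), 1e4)
  expect_gt(stats::sd(errs), 2.5)
  expect_lt(stats::sd(errs), 3.5)
})

test_that("every emitted modified spectrum has one ground-truth record", {
  cfg <- sim_config(seed = 15, n_proteins = 5, mod_density = 4)
  sim <- simulate_study(cfg)
  expect_equal(length(sim$spectra), nrow(sim$truth))
  expect_equal(vapply(sim$spectra, `[[`, character(1), "title"),
               sim$truth$spectrum)
  modified <- sim$truth[!is.na(sim$truth$name), ]
  expect_equal(anyDuplicated(modified[, c("protein_id", "position", "name")]),
               0L)
})

test_that("simulate_study writes standard FASTA, MGF and TSV artifacts", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 16, n_proteins = 2)
  sim <- simulate_study(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "proteome.fasta")))
  back <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_length(back, length(sim$spectra))
  tsv <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tsv), nrow(sim$truth))
})
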