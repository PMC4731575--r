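# MGF round-trips and tolerance-based peak matching.

make_spectra <- function() {
  list(
    spectrum("first scan", 500.123456, 2L,
             cbind(c(100.123456, 200.2, 300.3), c(10, 20, 30)),
             extra = c(RTINSECONDS = "12.5")),
    spectrum("second", 601.5, 3L, cbind(c(150.111111), c(5))),
    spectrum("empty-ish", 700.1, 1L, cbind(numeric(0), numeric(0)))
  )
}

test_that("MGF write/read round-trips spectra losslessly", {
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(make_spectra(), path)
  back <- read_mgf(path)
  expect_length(back, 3L)
  orig <- make_spectra()
  for (i in 1:3) {
    expect_equal(back[[i]]$title, orig[[i]]$title)
    expect_equal(back[[i]]$pepmass, orig[[i]]$pepmass, tolerance = 1e-8)
    expect_equal(back[[i]]$charge, orig[[i]]$charge)
    expect_equal(back[[i]]$peaks, orig[[i]]$peaks, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  expect_equal(back[[1]]$extra[["RTINSECONDS"]], "12.5")
})

test_that("malformed MGF input raises located errors", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=broken", "CHARGE=2+",
               "100.1 5", "END IONS"), path)
  expect_error(read_mgf(path), "no PEPMASS")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.1", "CHARGE=2+",
               "100.1 oops", "END IONS"), path)
  expect_error(read_mgf(path), "line 5")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.1", "CHARGE=2+",
               "100.1 5"), path)
  expect_error(read_mgf(path), "unterminated")
})

test_that("the CHARGE header uses the trailing-sign convention", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.25 1000",
               "CHARGE=2+", "100.2 7", "END IONS"), path)
  sp <- read_mgf(path)[[1]]
  expect_equal(sp$charge, 2L)
  expect_equal(sp$pepmass, 500.25)
})

test_that("exact theoretical peaks all match at zero error", {
  frags <- theoretical_fragments(modified_peptide("SAMPLEK"), charges = 1L,
                                 include_internal = FALSE)
  sp <- spectrum("t", 500, 2L, cbind(frags$mz, rep(1, nrow(frags))))
  m <- match_peaks(sp, frags)
  expect_equal(nrow(m), nrow(frags))
  expect_true(all(abs(m$error_ppm) < 1e-6))
})

test_that("peaks beyond tolerance stay unmatched", {
  frags <- data.frame(series = "b", idx = 1L, from = 1L, to = 1L,
                      charge = 1L, loss = "", loss_mass = 0,
                      mz = 400, label = "b1")
  sp <- spectrum("t", 500, 2L, cbind(400 + 2 * 0.004, 1))
  expect_equal(nrow(match_peaks(sp, frags, tol_ppm = 10, tol_da = 1)), 0L)
  sp2 <- spectrum("t", 500, 2L, cbind(400 + 0.003, 1))
  expect_equal(nrow(match_peaks(sp2, frags, tol_ppm = 10, tol_da = 1)), 1L)
})

test_that("the closer of two theoretical ions wins a contested peak", {
  frags <- data.frame(series = c("b", "y"), idx = c(1L, 1L),
                      from = c(1L, 2L), to = c(1L, 2L), charge = 1L,
                      loss = "", loss_mass = 0,
                      mz = c(500.000, 500.004), label = c("b1", "y1"))
  sp <- spectrum("t", 600, 2L, cbind(500.003, 9))
  m <- match_peaks(sp, frags, tol_ppm = 10, tol_da = 1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$label, "y1")
})

test_that("one observed peak is never assigned twice", {
  frags <- data.frame(series = c("b", "b"), idx = c(1L, 2L),
                      from = c(1L, 1L), to = c(1L, 2L), charge = 1L,
                      loss = "", loss_mass = 0,
                      mz = c(500.000, 500.002), label = c("b1", "b2"))
  sp <- spectrum("t", 600, 2L, cbind(c(500.0005, 500.0020), c(1, 2)))
  m <- match_peaks(sp, frags, tol_ppm = 10, tol_da = 1)
  expect_equal(nrow(m), 2L)
  expect_equal(sort(m$observed_mz), c(500.0005, 500.0020))
})

test_that("matching is invariant under peak-order permutation", {
  set.seed(41)
  frags <- theoretical_fragments(modified_peptide("TESTPEPK"), charges = 1L,
                                 include_internal = FALSE)
  mz <- frags$mz * (1 + rnorm(nrow(frags), 0, 3e-6))
  perm <- sample(length(mz))
  a <- match_peaks(spectrum("t", 500, 2L, cbind(mz, seq_along(mz))), frags)
  b <- match_peaks(spectrum("t", 500, 2L, cbind(mz[perm], seq_along(mz)[perm])),
                   frags)
  expect_equal(a$label, b$label)
  expect_equal(a$observed_mz, b$observed_mz)
})

test_that("synthetic 3-ppm spectra match nearly completely at 10 ppm", {
  cfg <- sim_config(seed = 5, n_proteins = 8, mod_density = 4,
                    dropout_prob = 0, noise_peaks = 0L,
                    unmodified_fraction = 0)
  sim <- simulate_study(cfg)
  total <- 0L; matched <- 0L
  for (i in seq_along(sim$spectra)) {
    tr <- sim$truth[i, ]
    pl <- if (is.na(tr$name)) NULL else
      data.frame(position = tr$local_site, name = tr$name, mass = tr$mass,
                 class = tr$class)
    frags <- theoretical_fragments(modified_peptide(tr$sequence, pl),
                                   charges = 1L, include_internal = FALSE,
                                   losses = NULL)
    m <- match_peaks(sim$spectra[[i]], frags, tol_ppm = 10, tol_da = 1)
    total <- total + nrow(frags)
    matched <- matched + nrow(m)
  }
  expect_gt(total, 1000)
  expect_gte(matched / total, 0.99)
})
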