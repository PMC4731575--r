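# Delta-mass inference: precursor deltas, localization, mass refinement,
# registry matching and composition enumeration.

test_that("precursor deltas recover planted modification masses", {
  sp0 <- exact_spectrum("SAMPLEK")
  expect_equal(precursor_delta(sp0, "SAMPLEK"), 0, tolerance = 1e-6)
  phospho <- data.frame(position = 2L, name = "phospho", mass = 79.966331,
                        class = "phospho")
  expect_equal(precursor_delta(exact_spectrum("SAMPLEK", phospho), "SAMPLEK"),
               79.96633, tolerance = 1e-4)
  kv <- data.frame(position = 7L, name = "KV-adduct", mass = 227.163377,
                   class = "aa-adduct")
  expect_equal(precursor_delta(exact_spectrum("SAMPLEK", kv), "SAMPLEK"),
               227.1634, tolerance = 1e-4)
})

test_that("a full b/y ladder localizes a planted site exactly", {
  phospho <- data.frame(position = 3L, name = "phospho", mass = 79.966331,
                        class = "phospho")
  sp <- exact_spectrum("ASTGKA", phospho)
  ann <- annotate_open(sp, "ASTGKA", precursor_delta(sp, "ASTGKA"))
  loc <- localize_shift(ann$delta, ann, "ASTGKA")
  expect_equal(loc$start, 3L)
  expect_equal(loc$end, 3L)
  expect_true(loc$site_specific)
  expect_false(loc$ambiguous)
  expect_gt(loc$supporting_b, 0)
  expect_gt(loc$supporting_y, 0)
})

test_that("sparse ladders give honest localization intervals", {
  # only b1 and y1, both unshifted, on a 6-mer: site somewhere in 2..5
  m <- data.frame(series = c("b", "y"), idx = c(1L, 1L),
                  from = c(1L, 6L), to = c(1L, 6L), charge = 1L,
                  shifted = FALSE)
  loc <- localize_shift(80, m, "ASTGKA")
  expect_equal(c(loc$start, loc$end), c(2L, 5L))
  expect_false(loc$site_specific)
  # no shifted ions at all: maximal interval
  loc2 <- localize_shift(80, m[1, ], "ASTGKA")
  expect_equal(c(loc2$start, loc2$end), c(2L, 6L))
  # nothing matched: whole peptide
  loc3 <- localize_shift(80, m[0, ], "ASTGKA")
  expect_equal(c(loc3$start, loc3$end), c(1L, 6L))
})

test_that("contradictory ladders are flagged ambiguous, not errors", {
  m <- data.frame(series = c("b", "b"), idx = c(2L, 2L),
                  from = c(1L, 1L), to = c(2L, 2L), charge = 1L,
                  shifted = c(TRUE, FALSE))
  loc <- localize_shift(80, m, "ASTGKA")
  expect_true(loc$ambiguous)
  expect_false(loc$site_specific)
  expect_equal(c(loc$start, loc$end), c(1L, 6L))
  # b-ladder bracketing below a y-ladder bracket: empty interval
  m2 <- data.frame(series = c("b", "y"), idx = c(3L, 4L),
                   from = c(1L, 3L), to = c(3L, 6L), charge = 1L,
                   shifted = c(FALSE, FALSE))
  expect_true(localize_shift(80, m2, "ASTGKA")$ambiguous)
})

test_that("shifted internal ions shrink the localization interval", {
  m <- data.frame(series = c("b", "internal"), idx = c(1L, NA),
                  from = c(1L, 3L), to = c(1L, 4L), charge = 1L,
                  shifted = c(FALSE, TRUE))
  loc <- localize_shift(80, m, "ASTGKA")
  expect_equal(c(loc$start, loc$end), c(3L, 4L))
  expect_equal(loc$supporting_internal, 1L)
})

test_that("modification mass refinement prefers low-m/z ions", {
  one <- data.frame(mz = 300, shift = 109.05234)
  expect_equal(as.numeric(estimate_mod_mass(one)), 109.05234)
  four <- data.frame(mz = c(200, 300, 400, 500), shift = rep(42.0106, 4))
  expect_equal(as.numeric(estimate_mod_mass(four)), 42.0106)
  mixed <- data.frame(mz = c(250, 400, 700, 1500),
                      shift = c(109.0524, 109.0524, 109.0524, 109.10))
  est <- estimate_mod_mass(mixed, mz_cutoff = 800)
  expect_equal(as.numeric(est), 109.0524)
  expect_equal(attr(est, "n_ions"), 3L)
  # permutation invariance
  perm <- mixed[c(3, 1, 4, 2), ]
  expect_equal(as.numeric(estimate_mod_mass(perm, 800)), as.numeric(est))
  # all ions above the cutoff: fall back to the full mean
  high <- data.frame(mz = c(900, 1000), shift = c(10, 12))
  expect_equal(as.numeric(estimate_mod_mass(high, 800)), 11)
  expect_error(estimate_mod_mass(high[0, ]), "no ion shifts")
})

test_that("registry matching separates near-isobaric modifications", {
  reg <- default_registry()
  prop <- match_known_ptms(56.026, reg, "K")
  expect_equal(prop$name[1], "propionyl")
  expect_lt(prop$abs_diff[1], 0.0003)
  dm <- match_known_ptms(28.0313, reg, "K", tol = 0.01)
  expect_equal(dm$name, "dimethyl")   # formyl is 0.036 Da away: excluded
  expect_equal(nrow(match_known_ptms(0.0, reg, "K")), 0L)
  # residue context filters candidates
  expect_equal(nrow(match_known_ptms(156.1011, reg, "K", tol = 0.01)), 0L)
  expect_equal(match_known_ptms(156.1011, reg, "E", tol = 0.01)$name,
               "R-adduct")
})

test_that("methylpyrroline is the unique CHNO composition within 0.01 Da", {
  hits <- enumerate_compositions(109.05248, 0.01)
  expect_equal(hits$formula, "C6H7NO")
  wider <- enumerate_compositions(109.05248, 0.02)
  expect_equal(wider$formula[1:2], c("C6H7NO", "C5H7N3"))
})

test_that("radical search finds the arginine-delta alternatives", {
  hits <- enumerate_compositions(156.1016, 0.005, n_max = 4,
                                 allow_radical = TRUE)
  expect_true(all(c("C8H14NO2", "C6H12N4O") %in% hits$formula))
  arg <- hits[hits$formula == "C6H12N4O", ]
  expect_lt(arg$abs_diff, 0.001)       # arginine residue, the second hit
  expect_true(hits[hits$formula == "C8H14NO2", "radical"])
})

test_that("composition enumeration agrees with a quadruple-loop oracle", {
  set.seed(51)
  for (i in 1:20) {
    delta <- runif(1, 30, 300)
    allow <- i %% 2 == 0
    got <- enumerate_compositions(delta, 0.01, allow_radical = allow)
    want <- oracle_compositions(delta, 0.01, allow_radical = allow)
    expect_equal(sort(got$formula), want)
  }
  expect_error(enumerate_compositions(100, -1), "tolerance")
})

test_that("registry combinations explain composite deltas", {
  reg <- default_registry()
  one <- suggest_mod_combinations(42.011, reg, max_mods = 1, tol = 0.01)
  expect_equal(one$combo, "acetyl")
  many <- suggest_mod_combinations(190, reg, max_mods = 3, tol = 0.5)
  sets <- lapply(strsplit(many$combo, "+", fixed = TRUE), sort)
  expect_true(list(sort(c("phospho", "crotonyl", "acetyl"))) %in% sets)
  expect_true(all(abs(many$diff) <= 0.5))
  expect_equal(nrow(suggest_mod_combinations(0, reg, max_mods = 3,
                                             tol = 0.001)), 0L)
})

test_that("site classification converts to Met-inclusive coordinates", {
  prot <- protein_record("h1", paste(rep("A", 120), collapse = ""),
                         met_removed = TRUE,
                         domains = data.frame(label = c("NTD", "GH1"),
                                              start = c(2L, 41L),
                                              end = c(40L, 111L)))
  span <- data.frame(protein_id = "h1", start = 55L, end = 66L,
                     sequence = "AAAAAAAAAAAA")
  loc <- list(start = 3L, end = 3L, site_specific = TRUE)
  site <- classify_site(loc, span, prot)
  expect_equal(site$position, 57L)
  expect_equal(site$residue, "A")
  expect_equal(site$domain, "GH1")
  span2 <- data.frame(protein_id = "h1", start = 2L, end = 13L,
                      sequence = "AAAAAAAAAAAA")
  expect_equal(classify_site(list(start = 1L, end = 1L, site_specific = TRUE),
                             span2, prot)$position, 2L)
  expect_error(classify_site(list(start = 1L, end = 4L,
                                  site_specific = FALSE), span, prot),
               "not site-specific")
})

test_that("ladder-based localization recovers random planted sites", {
  set.seed(52)
  reg <- default_registry()
  tab <- registry_table(reg)
  for (i in 1:15) {
    n <- sample(6:18, 1)
    seq <- random_sequence(n)
    pos <- sample(n, 1)
    mod <- tab[sample(nrow(tab), 1), ]
    sp <- exact_spectrum(seq, data.frame(position = pos, name = mod$name,
                                         mass = mod$mono, class = mod$class))
    ann <- annotate_open(sp, seq, precursor_delta(sp, seq))
    loc <- localize_shift(ann$delta, ann, seq)
    expect_true(loc$site_specific)
    expect_equal(loc$start, pos)
    # refined mass equals the planted delta exactly at zero noise
    expect_equal(as.numeric(estimate_mod_mass(ann)), mod$mono,
                 tolerance = 1e-9)
  }
})
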