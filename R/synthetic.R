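# Ground-truthed synthetic data: H1-like proteins (acidic N-segment,
# globular core, lysine-rich C-tail), planted modifications drawn from the
# registry, and noisy HCD spectra with Gaussian ppm mass error, peak dropout
# and uniform noise peaks. Identical config + seed gives identical output.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: Orbitrap-like mass error
#' (`ppm_sigma = 3`), 10 percent fragment peak dropout, tryptic digestion and
#' singly charged HCD b/y ladders. Intensities follow a rank-based
#' exponential decay with no physical meaning and are never used for
#' inference.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of proteins to generate.
#' @param length_range Mature protein length range (residues).
#' @param lysine_enrichment Fraction of lysines in the C-terminal tail.
#' @param mod_density Expected planted modifications per 100 residues.
#' @param mods Character vector of registry names to plant (default: all
#'   entries of `registry`).
#' @param registry A [mod_registry()].
#' @param ppm_sigma Gaussian m/z error, ppm.
#' @param dropout_prob Probability that an emitted fragment peak is deleted.
#' @param noise_peaks Uniform-random noise peaks added per spectrum.
#' @param unmodified_fraction Fraction of additional unmodified-peptide
#'   spectra emitted (relative to modified ones).
#' @param precursor_charges,precursor_charge_probs Precursor charge states
#'   and their probabilities.
#' @param fragment_charges Fragment charges emitted.
#' @param protease,max_missed,min_len,max_len Digest settings for spectrum
#'   emission.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_proteins = 6L, length_range = c(190L, 280L),
                       lysine_enrichment = 0.3, mod_density = 3,
                       mods = NULL, registry = default_registry(),
                       ppm_sigma = 3, dropout_prob = 0.1, noise_peaks = 10L,
                       unmodified_fraction = 0.25,
                       precursor_charges = c(2L, 3L),
                       precursor_charge_probs = c(0.7, 0.3),
                       fragment_charges = 1L,
                       protease = "trypsin", max_missed = 1L,
                       min_len = 6L, max_len = 30L) {
  stopifnot(ppm_sigma >= 0, dropout_prob >= 0, dropout_prob <= 1,
            lysine_enrichment >= 0, lysine_enrichment <= 1,
            mod_density >= 0, length_range[1] <= length_range[2],
            length(precursor_charges) == length(precursor_charge_probs))
  if (is.null(mods)) mods <- registry_table(registry)$name
  structure(as.list(environment()), class = "sim_config")
}

#' Read a simulation configuration from YAML
#' @param path YAML file; keys are [sim_config()] arguments.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

.sample_seq <- function(n, alphabet, probs) {
  paste(sample(alphabet, n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate an H1-like synthetic proteome
#'
#' Each protein has an acidic, serine/threonine-rich N-segment starting with
#' serine (the initiator Met is removed, so mature numbering starts at 2), a
#' globular (GH1-like) core of ~70 residues, and a lysine-rich C-tail with
#' embedded S/TPxK motifs. Domains are annotated NTD/GH1/CTD in
#' Met-inclusive coordinates.
#'
#' @param cfg A [sim_config()].
#' @return List of [protein_record()] objects; deterministic under the seed.
#' @export
generate_proteome <- function(cfg) {
  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_proteins), function(i) {
    len <- sample(cfg$length_range[1]:cfg$length_range[2], 1L)
    ntd <- max(20L, round(0.22 * len))
    gh1 <- 71L
    ctd <- len - ntd - gh1
    acid <- .sample_seq(ntd - 1L,
                        c("S", "T", "E", "D", "A", "P", "G", "V", "K"),
                        c(.16, .10, .16, .10, .18, .12, .08, .06, .04))
    core <- .sample_seq(gh1,
                        c("K", "R", "A", "L", "V", "I", "F", "Y", "S", "T",
                          "E", "G", "N", "P"),
                        c(.14, .05, .12, .09, .08, .06, .05, .04, .10, .08,
                          .07, .07, .03, .02))
    kf <- cfg$lysine_enrichment
    rest <- (1 - kf) / 6
    tail_ <- .sample_seq(ctd, c("K", "A", "P", "T", "S", "V", "G"),
                         c(kf, rest, rest, rest, rest, rest, rest))
    seq <- paste0("S", acid, core, tail_)
    # embed S/TPxK motifs: one near the NTD/CTD pattern of real H1 tails
    put_motif <- function(s, at, motif) {
      paste0(substr(s, 1, at - 1), motif, substr(s, at + 4, nchar(s)))
    }
    if (ctd > 30) {
      at1 <- ntd + gh1 + sample(3:(ctd %/% 2), 1L)
      at2 <- ntd + gh1 + ctd %/% 2 + sample(3:(ctd %/% 2 - 8), 1L)
      seq <- put_motif(seq, at1, sample(c("SPAK", "TPVK"), 1L))
      seq <- put_motif(seq, at2, sample(c("SPKK", "TPAK"), 1L))
    }
    protein_record(
      sprintf("SYNH1.%02d", i), seq, description = "synthetic H1-like",
      met_removed = TRUE,
      domains = data.frame(
        label = c("NTD", "GH1", "CTD"),
        start = c(2L, ntd + 2L, ntd + gh1 + 2L),
        end = c(ntd + 1L, ntd + gh1 + 1L, nchar(seq) + 1L),
        stringsAsFactors = FALSE))
  })
}

#' Plant ground-truth modifications on a proteome
#'
#' Sites are drawn respecting each modification's residue targets, at most
#' one modification per residue; the number of sites per protein is Poisson
#' with mean `mod_density` per 100 residues. A registry entry with no valid
#' target residue in a protein is skipped for that protein.
#'
#' @param proteins List of [protein_record()] objects.
#' @param cfg A [sim_config()].
#' @return List with `proteins` (unchanged) and `truth`: data.frame
#'   (`protein_id`, `position` Met-inclusive, `residue`, `name`, `class`,
#'   `mass`).
#' @export
plant_modifications <- function(proteins, cfg) {
  if (!length(cfg$mods)) stop("empty registry subset")
  set.seed(cfg$seed + 1L)
  mods <- lapply(cfg$mods, registry_get, registry = cfg$registry)
  names(mods) <- cfg$mods
  residue_targets <- lapply(mods, function(m)
    intersect(m$targets, .residue_table$residue))
  rows <- list()
  for (p in proteins) {
    aa <- strsplit(p$sequence, "")[[1]]
    targetable <- which(aa %in% unique(unlist(residue_targets)))
    if (!length(targetable)) next
    n_sites <- min(stats::rpois(1L, cfg$mod_density / 100 * length(aa)),
                   length(targetable))
    if (n_sites == 0L) next
    sites <- sort(sample(targetable, n_sites))
    for (i in sites) {
      ok <- names(mods)[vapply(residue_targets,
                               function(t) aa[i] %in% t, logical(1))]
      nm <- if (length(ok) == 1L) ok else sample(ok, 1L)
      m <- mods[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = p$id, position = mature_to_coord(p, i),
        residue = aa[i], name = nm, class = m$class, mass = m$mono,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), position = integer(0),
               residue = character(0), name = character(0),
               class = character(0), mass = numeric(0),
               stringsAsFactors = FALSE)
  list(proteins = proteins, truth = truth)
}

#' Simulate HCD spectra for digest peptides with planted modifications
#'
#' Each digest peptide carrying exactly one planted modification yields one
#' spectrum (peptides carrying several planted sites are skipped so that
#' every emitted modified spectrum has exactly one ground-truth record); a
#' fraction of unmodified peptides is emitted as well. Theoretical b/y
#' ladders are perturbed with Gaussian ppm error, peaks are deleted with
#' `dropout_prob`, and uniform-random noise peaks are added at the 10th
#' percentile of signal intensity. The precursor m/z is perturbed likewise.
#'
#' @param proteins List of [protein_record()] objects.
#' @param truth Ground-truth data.frame from [plant_modifications()].
#' @param cfg A [sim_config()].
#' @return List with `spectra` (list of [spectrum()]) and `truth`: per-
#'   spectrum provenance (`spectrum`, `protein_id`, `start`, `end`,
#'   `sequence`, `name`, `class`, `mass`, `local_site`, `position`,
#'   `charge`; NA mod fields for unmodified spectra).
#' @export
simulate_digest_spectra <- function(proteins, truth, cfg) {
  set.seed(cfg$seed + 2L)
  spectra <- list()
  rows <- list()
  counter <- 0L
  emit <- function(pep, placements, prov) {
    counter <<- counter + 1L
    mp <- modified_peptide(pep, placements)
    frags <- theoretical_fragments(mp, charges = cfg$fragment_charges,
                                   include_internal = FALSE, losses = NULL)
    z <- sample(cfg$precursor_charges, 1L, prob = cfg$precursor_charge_probs)
    neutral <- peptide_mass_mp(mp)
    pre_mz <- (neutral + z * PROTON_MASS) / z
    pre_mz <- pre_mz * (1 + stats::rnorm(1L, 0, cfg$ppm_sigma) * 1e-6)
    mz <- frags$mz * (1 + stats::rnorm(nrow(frags), 0, cfg$ppm_sigma) * 1e-6)
    keep <- stats::runif(nrow(frags)) >= cfg$dropout_prob
    mz <- mz[keep]
    # rank-based exponential intensity decay (arbitrary units)
    intens <- 1e4 * exp(-0.15 * sample(seq_along(mz)))
    if (cfg$noise_peaks > 0 && length(mz)) {
      noise_mz <- stats::runif(cfg$noise_peaks, 100, max(mz) + 50)
      noise_int <- rep(stats::quantile(intens, 0.1), cfg$noise_peaks)
      mz <- c(mz, noise_mz)
      intens <- c(intens, noise_int)
    }
    title <- sprintf("synspec_%04d", counter)
    spectra[[length(spectra) + 1L]] <<-
      spectrum(title, pre_mz, z, cbind(mz, intens))
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(spectrum = title, stringsAsFactors = FALSE), prov,
      data.frame(charge = z))
  }
  for (p in proteins) {
    peps <- digest(p, cfg$protease, max_missed = cfg$max_missed,
                   min_len = cfg$min_len, max_len = cfg$max_len)
    pt <- truth[truth$protein_id == p$id, , drop = FALSE]
    seen_mod <- character(0)
    unmod_pool <- list()
    for (k in seq_len(nrow(peps))) {
      sp <- peps[k, , drop = FALSE]
      inside <- pt[pt$position >= sp$start & pt$position <= sp$end, ,
                   drop = FALSE]
      if (nrow(inside) == 1L) {
        site_key <- paste(p$id, inside$position, inside$name)
        if (site_key %in% seen_mod) next  # one spectrum per planted site
        seen_mod <- c(seen_mod, site_key)
        local <- inside$position - sp$start + 1L
        emit(sp$sequence,
             data.frame(position = local, name = inside$name,
                        mass = inside$mass, class = inside$class,
                        stringsAsFactors = FALSE),
             data.frame(protein_id = p$id, start = sp$start, end = sp$end,
                        sequence = sp$sequence, name = inside$name,
                        class = inside$class, mass = inside$mass,
                        local_site = local, position = inside$position,
                        stringsAsFactors = FALSE))
      } else if (nrow(inside) == 0L && sp$missed_cleavages == 0L) {
        unmod_pool[[length(unmod_pool) + 1L]] <- sp
      }
    }
    n_unmod <- round(cfg$unmodified_fraction * length(seen_mod))
    if (n_unmod > 0L && length(unmod_pool)) {
      pick <- sample(seq_along(unmod_pool), min(n_unmod, length(unmod_pool)))
      for (k in pick) {
        sp <- unmod_pool[[k]]
        emit(sp$sequence, NULL,
             data.frame(protein_id = p$id, start = sp$start, end = sp$end,
                        sequence = sp$sequence, name = NA_character_,
                        class = NA_character_, mass = NA_real_,
                        local_site = NA_integer_, position = NA_integer_,
                        stringsAsFactors = FALSE))
      }
    }
  }
  truth_out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(spectrum = character(0))
  list(spectra = spectra, truth = truth_out)
}

#' Run the full synthetic study: proteome, planted PTMs, spectra
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, writes `proteome.fasta`,
#'   `spectra.mgf` and `truth.tsv`.
#' @return List with `proteins`, `planted` (per-protein ground truth),
#'   `spectra`, `truth` (per-spectrum provenance).
#' @export
simulate_study <- function(cfg, out_dir = NULL) {
  proteins <- generate_proteome(cfg)
  planted <- plant_modifications(proteins, cfg)
  sim <- simulate_digest_spectra(proteins, planted$truth, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(out_dir, "proteome.fasta"))
    write_mgf(sim$spectra, file.path(out_dir, "spectra.mgf"))
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(proteins = proteins, planted = planted$truth,
       spectra = sim$spectra, truth = sim$truth)
}

#' Score recovery of planted modifications
#'
#' A planted modification counts as recovered when its spectrum is assigned
#' to the right peptide, the top registry hit names the planted
#' modification, and the site is localized site-specifically at the planted
#' protein position.
#'
#' @param results [discover_ptms()] output.
#' @param truth Per-spectrum ground truth from [simulate_digest_spectra()].
#' @return List: `n_planted`, `n_recovered`, `rate`, and the merged
#'   data.frame `detail`.
#' @export
evaluate_recovery <- function(results, truth) {
  planted <- truth[!is.na(truth$name), , drop = FALSE]
  merged <- merge(planted, as.data.frame(results), by = "spectrum",
                  all.x = TRUE, suffixes = c(".true", ".found"))
  ok <- !is.na(merged$mod_name) &
    merged$mod_name == merged$name &
    merged$site_specific %in% TRUE &
    !is.na(merged$position.found) &
    merged$position.found == merged$position.true
  list(n_planted = nrow(planted), n_recovered = sum(ok),
       rate = if (nrow(planted)) sum(ok) / nrow(planted) else NA_real_,
       detail = merged)
}
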