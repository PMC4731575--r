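# End-to-end open search driver: digest the protein database, assign each
# spectrum to the digest peptide that best explains its fragments under the
# precursor delta, then localize, refine and identify the modification.

#' Open-search PTM discovery over a set of spectra
#'
#' For each spectrum the precursor delta is computed against every digest
#' peptide; peptides with delta inside `delta_range` are scored by the
#' number of singly-charged b/y ladder masses (unshifted or delta-shifted)
#' explained by the spectrum, and the best-scoring peptide (ties toward the
#' smaller |delta|) is fully annotated with both fragment hypotheses
#' ([annotate_open()]). Deltas within `tol_da` of zero are reported
#' as unmodified; otherwise the shift is localized ([localize_shift()]), its
#' mass refined from low-m/z ion shifts ([estimate_mod_mass()]) and matched
#' against the registry ([match_known_ptms()]) using the localized residue as
#' context when the site is unambiguous.
#'
#' @param spectra List of [spectrum()] objects.
#' @param proteins List of [protein_record()] objects.
#' @param registry A [mod_registry()].
#' @param protease,max_missed,min_len,max_len Digest settings (see [digest()]).
#' @param tol_ppm,tol_da Fragment matching tolerances.
#' @param delta_range Precursor deltas considered (Da).
#' @param min_matched Minimum matched ions for a confident assignment.
#' @param mz_cutoff Low-m/z preference threshold for mass refinement.
#' @param charges Fragment charges annotated.
#' @param mod_tol Tolerance for registry matching (Da).
#' @return data.frame of class `ptm_results`, one row per assigned spectrum:
#'   peptide/protein assignment, precursor delta, refined modification mass,
#'   localization interval and evidence counts, top registry candidate, and
#'   protein-coordinate site classification for site-specific rows.
#' @export
discover_ptms <- function(spectra, proteins, registry = default_registry(),
                          protease = "trypsin", max_missed = 2L,
                          min_len = 5L, max_len = 40L,
                          tol_ppm = 10, tol_da = 0.01,
                          delta_range = c(-0.5, 700), min_matched = 3L,
                          mz_cutoff = 800, charges = 1L, mod_tol = 0.01) {
  peps <- do.call(rbind, lapply(proteins, digest, protease = protease,
                                max_missed = max_missed, min_len = min_len,
                                max_len = max_len))
  peps <- peps[!duplicated(peps[, c("protein_id", "start", "end")]), ,
               drop = FALSE]
  pmass <- vapply(peps$sequence, peptide_mass, numeric(1), USE.NAMES = FALSE)
  prot_by_id <- stats::setNames(proteins,
                                vapply(proteins, `[[`, character(1), "id"))
  # singly-charged b/y ladders, precomputed once per peptide for fast scoring
  mv <- .residue_vector("mono")
  ladders <- lapply(peps$sequence, function(s) {
    cum <- cumsum(unname(mv[strsplit(s, "")[[1]]]))
    n <- length(cum)
    c(cum + PROTON_MASS,                                   # b_1..b_n
      cum[n] - cum[seq_len(n - 1L)] + .WATER_MONO + PROTON_MASS)  # y_(n-1)..y_1
  })
  quick_score <- function(obs, theo, delta) {
    theo <- c(theo, theo + delta)
    tol <- pmin(tol_da, theo * tol_ppm * 1e-6)
    i <- findInterval(theo, obs)
    dl <- ifelse(i >= 1L, theo - obs[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(obs), obs[pmin(i + 1L, length(obs))] - theo, Inf)
    sum(pmin(dl, dr) <= tol)
  }
  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    if (nrow(sp$peaks) == 0L) next
    obs <- sp$peaks[, "mz"]
    neutral <- (sp$pepmass - PROTON_MASS) * sp$charge
    deltas <- neutral - pmass
    cand <- which(deltas >= delta_range[1] & deltas <= delta_range[2])
    if (!length(cand)) next
    qs <- vapply(cand, function(k) quick_score(obs, ladders[[k]], deltas[k]),
                 numeric(1))
    ord <- order(-qs, abs(deltas[cand]))
    best_k <- cand[ord[1]]
    best_delta <- deltas[best_k]
    best <- annotate_open(sp, peps$sequence[best_k], best_delta,
                          tol_ppm = tol_ppm, tol_da = tol_da,
                          charges = charges)
    best_score <- best$n_matched
    if (best_score < min_matched) next
    span <- peps[best_k, , drop = FALSE]
    prot <- prot_by_id[[span$protein_id]]
    unmodified <- abs(best_delta) <= tol_da
    if (unmodified) {
      rows[[si]] <- data.frame(
        spectrum = sp$title, protein_id = span$protein_id,
        peptide = span$sequence, start = span$start, end = span$end,
        delta = best_delta, n_matched = best_score,
        modified = FALSE, refined_mass = NA_real_, n_ions_used = NA_integer_,
        loc_start = NA_integer_, loc_end = NA_integer_,
        site_specific = FALSE, ambiguous = FALSE,
        supporting_b = 0L, supporting_y = 0L, supporting_internal = 0L,
        mod_name = NA_character_, mod_class = NA_character_,
        mod_diff = NA_real_, position = NA_integer_,
        residue = NA_character_, domain = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    loc <- localize_shift(best_delta, best, span$sequence)
    refined <- if (nrow(best$ion_shifts))
      estimate_mod_mass(best, mz_cutoff = mz_cutoff) else best_delta
    n_used <- attr(refined, "n_ions")
    site <- if (loc$site_specific) classify_site(loc, span, prot) else
      list(position = NA_integer_, residue = NA_character_,
           domain = NA_character_)
    hits <- match_known_ptms(as.numeric(refined), registry,
                             residue = if (loc$site_specific) site$residue
                                       else NULL,
                             tol = mod_tol)
    rows[[si]] <- data.frame(
      spectrum = sp$title, protein_id = span$protein_id,
      peptide = span$sequence, start = span$start, end = span$end,
      delta = best_delta, n_matched = best_score,
      modified = TRUE, refined_mass = as.numeric(refined),
      n_ions_used = if (is.null(n_used)) 0L else n_used,
      loc_start = loc$start, loc_end = loc$end,
      site_specific = loc$site_specific, ambiguous = loc$ambiguous,
      supporting_b = loc$supporting_b, supporting_y = loc$supporting_y,
      supporting_internal = loc$supporting_internal,
      mod_name = if (nrow(hits)) hits$name[1] else NA_character_,
      mod_class = if (nrow(hits)) hits$class[1] else NA_character_,
      mod_diff = if (nrow(hits)) hits$diff[1] else NA_real_,
      position = site$position, residue = site$residue, domain = site$domain,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  class(out) <- c("ptm_results", class(out))
  out
}

#' @export
print.ptm_results <- function(x, ...) {
  if (all(c("modified", "site_specific") %in% names(x)))
    cat(sprintf("<ptm_results> %d assigned spectra (%d modified, %d site-specific)\n",
                nrow(x), sum(x$modified), sum(x$site_specific)))
  NextMethod()
}
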