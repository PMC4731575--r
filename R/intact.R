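# Intact (deconvoluted) protein mass assignment. Intact comparisons use
# AVERAGE masses, mirroring linear-mode MALDI-TOF; peptide and fragment work
# elsewhere in the package uses monoisotopic masses (Orbitrap).

#' Average (abundance-weighted) mass of a mature protein
#'
#' Sum of average residue masses + average water mass, + 42.037 Da when the
#' N-terminus is acetylated.
#'
#' @param protein A [protein_record()] (mature sequence, Met removed when
#'   flagged) or a plain sequence string.
#' @param nterm_acetyl Logical; include an N-terminal acetyl group.
#' @return Average mass in Da.
#' @export
protein_average_mass <- function(protein, nterm_acetyl = FALSE) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence else protein
  aa <- .check_sequence(seq)
  mv <- .residue_vector("average")
  sum(mv[aa]) + .WATER_AVG + if (nterm_acetyl) .ACETYL_AVG else 0
}

#' Assign an observed intact mass to candidate sequence variants
#'
#' Candidates whose theoretical average mass lies within a relative tolerance
#' of the observed mass are returned ranked by |delta| (ties broken by
#' protein id). The default tolerance of 0.2 percent reflects linear-mode
#' MALDI-TOF accuracy; a satellite peak's positive delta can be forwarded to
#' [suggest_mod_combinations()] to propose modification combinations.
#'
#' @param observed_mass Deconvoluted intact mass (Da, average-mass scale).
#' @param candidates List of [protein_record()] objects.
#' @param tol_fraction Relative tolerance (> 0), default 0.002.
#' @param nterm_acetyl Compute candidate masses with an acetylated N-terminus.
#' @return data.frame (`protein_id`, `theoretical`, `delta`, `rank`); zero
#'   rows when nothing is within tolerance.
#' @export
match_intact <- function(observed_mass, candidates, tol_fraction = 0.002,
                         nterm_acetyl = FALSE) {
  stopifnot(tol_fraction > 0, observed_mass > 0)
  theo <- vapply(candidates, protein_average_mass, numeric(1),
                 nterm_acetyl = nterm_acetyl)
  ids <- vapply(candidates, `[[`, character(1), "id")
  delta <- observed_mass - theo
  keep <- abs(delta) <= tol_fraction * observed_mass
  out <- data.frame(protein_id = ids[keep], theoretical = theo[keep],
                    delta = delta[keep], stringsAsFactors = FALSE)
  out <- out[order(abs(out$delta), out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Read a plain table of observed intact masses
#'
#' @param path TSV with columns `label` and `mass` (Da).
#' @return data.frame.
#' @export
read_intact_masses <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
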